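#' Stage profile for the synthetic cohort generator
#'
#' Holds everything the generator needs for one GOLD stage: its mixture
#' weight, stage-conditional clinical means/SDs, the probability of mMRC >= 2,
#' three-year mortality, and the biomarker marginals for that stage.
#'
#' @param stage GOLD stage, integer 1-4.
#' @param n_frac Mixture weight in \[0, 1\].
#' @param clinical_means Named list; each element a list with `mean` and `sd`.
#'   Expected names: age, bmi, fev1_l, fev1_pct, ic_tlc, dlco_pct, smwd, sgrq.
#' @param mmrc2plus_frac P(mMRC >= 2).
#' @param mortality_3y P(death within 3 years).
#' @param biomarker_marginals Named list of [biomarker_marginal].
#' @param female_frac,smoker_frac Optional demographic fractions (defaults
#'   0.5/0.5); smoking status is generated but never used downstream.
#' @return An object of class `stage_profile`.
#' @export
stage_profile <- function(stage, n_frac, clinical_means, mmrc2plus_frac,
                          mortality_3y, biomarker_marginals,
                          female_frac = 0.5, smoker_frac = 0.5) {
  stopifnot(stage %in% 1:4, n_frac >= 0, n_frac <= 1)
  probs <- c(mmrc2plus = mmrc2plus_frac, mortality = mortality_3y,
             female = female_frac, smoker = smoker_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("stage ", stage, ": probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- vapply(clinical_means, function(x) x$sd, numeric(1))
  if (any(sds < 0)) stop("stage ", stage, ": SDs must be >= 0", call. = FALSE)
  structure(list(stage = as.integer(stage), n_frac = n_frac,
                 clinical_means = clinical_means,
                 mmrc2plus_frac = mmrc2plus_frac, mortality_3y = mortality_3y,
                 biomarker_marginals = biomarker_marginals,
                 female_frac = female_frac, smoker_frac = smoker_frac),
            class = "stage_profile")
}

#' Cohort generator configuration
#'
#' @param n_patients Number of patients to draw (>= 8 so that downstream
#'   quartile groups are non-degenerate).
#' @param seed Integer master seed; per-stage and per-variable substreams are
#'   derived from it deterministically.
#' @param stage_profiles List of [stage_profile]; mixture weights must sum
#'   to 1 (tolerance 1e-9).
#' @param copula A [copula_spec] shared by all stages.
#' @param coupling_mode `"stage_linked"` draws each patient's biomarker panel
#'   from their own stage's marginals (inducing biomarker-outcome
#'   association); `"independent"` pools the overall marginals so biomarkers
#'   carry no outcome signal (the null world used for calibration checks).
#' @param overall_marginals Named list of [biomarker_marginal] used in
#'   `"independent"` mode (and as the pooled reference elsewhere).
#' @param lod_policy Detection-limit policy, see [apply_detection_limit], or
#'   `"none"` to skip censoring.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed, stage_profiles, copula,
                          coupling_mode = c("stage_linked", "independent"),
                          overall_marginals = NULL,
                          lod_policy = c("floor_at_lod", "half_lod", "none")) {
  coupling_mode <- match.arg(coupling_mode)
  lod_policy <- match.arg(lod_policy)
  stopifnot(n_patients >= 8, inherits(copula, "copula_spec"))
  fr <- vapply(stage_profiles, function(p) p$n_frac, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("stage mixture weights sum to %.12f, not 1", sum(fr)),
         call. = FALSE)
  }
  if (coupling_mode == "independent" && is.null(overall_marginals)) {
    stop("independent coupling requires overall_marginals", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 stage_profiles = stage_profiles, copula = copula,
                 coupling_mode = coupling_mode,
                 overall_marginals = overall_marginals,
                 lod_policy = lod_policy),
            class = "cohort_config")
}

#' Load the built-in COPD calibration
#'
#' Reads the packaged transcription of the published GOLD-stage-stratified
#' cohort summaries (stage mixture, clinical means/SDs, stage mortality,
#' biomarker median/IQR marginals, ELISA detection limits) and the published
#' 8x8 biomarker Spearman matrix. Stage-stratified DLCO percent-predicted
#' profiles are synthetic stand-ins (no published stage table exists for
#' them); everything else is as printed.
#'
#' @param path Optional path to an alternative calibration JSON with the same
#'   schema.
#' @return A list with `stage_profiles`, `copula`, `overall_marginals`,
#'   `lod`, `biomarkers`, and `stage_n` (the published per-stage counts).
#' @examples
#' cal <- copd_calibration()
#' names(cal$overall_marginals)
#' @export
copd_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "copd_calibration.json",
                        package = "oscarpanel", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bio <- unlist(raw$biomarkers)
  sp_target <- do.call(rbind, lapply(raw$spearman_target, unlist))
  cop <- copula_spec(bio, sp_target)
  lod <- unlist(raw$lod)

  make_marginals <- function(mk) {
    out <- lapply(bio, function(b) {
      m <- mk[[b]]
      biomarker_marginal(m$median, m$q1, m$q3, lod = lod[[b]], name = b)
    })
    names(out) <- bio
    out
  }

  total_n <- sum(vapply(raw$stages, function(s) s$n, numeric(1)))
  profiles <- lapply(raw$stages, function(s) {
    cm <- lapply(s$clinical, function(v) list(mean = v$mean, sd = v$sd))
    # SGRQ is published as median [IQR]; a normal approximation treats the
    # median as the mean and IQR/1.349 as the SD.
    cm$sgrq <- list(mean = s$sgrq$median,
                    sd = (s$sgrq$q3 - s$sgrq$q1) / (2 * .z75))
    stage_profile(stage = s$stage, n_frac = s$n / total_n,
                  clinical_means = cm,
                  mmrc2plus_frac = s$mmrc2plus_frac,
                  mortality_3y = s$mortality_3y,
                  biomarker_marginals = make_marginals(s$markers),
                  female_frac = s$female_frac, smoker_frac = s$smoker_frac)
  })
  list(stage_profiles = profiles, copula = cop,
       overall_marginals = make_marginals(raw$overall$markers),
       lod = lod, biomarkers = bio,
       stage_n = vapply(raw$stages, function(s) as.integer(s$n), integer(1)))
}
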