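# Shared fixtures, built in code. Calibration and the larger generated
# cohorts are cached per test file to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

get_calibration <- function() {
  if (is.null(.fixture_env$cal)) .fixture_env$cal <- copd_calibration()
  .fixture_env$cal
}

make_cohort <- function(n, seed, coupling = "stage_linked",
                        lod_policy = "floor_at_lod") {
  key <- paste("cohort", n, seed, coupling, lod_policy, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    cal <- get_calibration()
    cfg <- cohort_config(n, seed, cal$stage_profiles, cal$copula,
                         coupling_mode = coupling,
                         overall_marginals = cal$overall_marginals,
                         lod_policy = lod_policy)
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# Hand-built 3-record cohort covering every mandatory column; values are
# internally consistent (GOLD vs FEV1%, BODE from its components).
tiny_cohort <- function() {
  data.frame(
    id = c("A1", "A2", "A3"),
    age = c(59, 66, 63),
    sex = c("F", "M", "M"),
    bmi = c(26, 29, 20),
    gold = c(1L, 2L, 4L),
    fev1_l = c(2.25, 1.54, 0.65),
    fev1_pct = c(91, 61, 23),
    ic_tlc = c(0.44, 0.36, 0.19),
    dlco_pct = c(75, 62, 35),
    smwd = c(530, 475, 314),
    sgrq = c(10, 29, 60),
    mmrc = c(0L, 1L, 4L),
    bode = c(0L, 1L, 8L),
    dead_3y = c(0L, 0L, 1L),
    il6 = c(4.0, 4.9, 9.3),
    il8 = c(9.0, 9.1, 11.2),
    il16 = c(314, 312, 385),
    tnfa = c(13.1, 11.7, 26.5),
    mmp9 = c(18088, 10311, 4214),
    vegf = c(100.5, 117.2, 42.1),
    parc = c(54177, 51358, 54232),
    mcp1 = c(567, 484, 609),
    stringsAsFactors = FALSE
  )
}

# A patient-record data.frame with a single interesting outcome column set;
# used to exercise group differences without a full cohort.
group_with <- function(...) {
  cols <- list(...)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

ib_panel <- c("il6", "il8", "il16", "tnfa")
irb_panel <- c("vegf", "mmp9")
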