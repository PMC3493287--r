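#' MCID registry for OSCAR outcomes
#'
#' One entry per analyzed outcome: how to extract its per-patient values, the
#' direction of clinical benefit, its minimal clinically important difference
#' (MCID) when one is established, and the statistical fallback test used
#' when none is. Defaults:
#'
#' * `fev1_ml` — FEV1 in mL (from `fev1_l`), MCID 100 mL, higher is better.
#' * `smwd` — 6-minute walk distance, MCID 37 m (the conservative lower bound
#'   of the published 37-71 m range), higher is better.
#' * `sgrq` — SGRQ total, MCID 4 points, lower is better.
#' * `mmrc` — mMRC grade, MCID 1 point, lower is better.
#' * `bode` — BODE index, MCID 1 point, lower is better.
#' * `dlco_pct` — DLCO % predicted; no established MCID, rank-sum fallback,
#'   higher is better.
#' * `ic_tlc` — the published threshold is prognostic (`IC/TLC < 0.25`), not
#'   a difference; compared as the proportion below 0.25 via the chi-square
#'   fallback (a below-threshold patient is worse, so lower proportion is
#'   better).
#' * `dead_3y` — death within 3 years; chi-square fallback, lower is better.
#'   The engine works on death (not survival) throughout: one fixed internal
#'   orientation avoids double-negation bugs, so a published "survival -21%"
#'   is the engine's death +21 points.
#'
#' @param outcomes Optional character vector to subset/reorder the defaults.
#' @return An object of class `mcid_registry` (named list of entries).
#' @export
mcid_registry <- function(outcomes = NULL) {
  entry <- function(mcid, direction, type, fallback = NA_character_,
                    derive = NULL, label = NULL) {
    list(mcid = mcid, direction = direction, type = type, fallback = fallback,
         derive = derive, label = label)
  }
  reg <- list(
    fev1_ml = entry(100, "higher_is_better", "continuous",
                    derive = function(cohort) cohort$fev1_l * 1000,
                    label = "FEV1 (mL)"),
    smwd = entry(37, "higher_is_better", "continuous", label = "6MWD (m)"),
    sgrq = entry(4, "lower_is_better", "continuous", label = "SGRQ (pts)"),
    mmrc = entry(1, "lower_is_better", "continuous", label = "mMRC (grade)"),
    bode = entry(1, "lower_is_better", "continuous", label = "BODE (pts)"),
    dlco_pct = entry(NA_real_, "higher_is_better", "continuous",
                     fallback = "rank_sum", label = "DLCO (%)"),
    ic_tlc = entry(NA_real_, "lower_is_better", "binary",
                   fallback = "chi_square",
                   derive = function(cohort) as.numeric(cohort$ic_tlc < 0.25),
                   label = "IC/TLC < 0.25 (%)"),
    dead_3y = entry(NA_real_, "lower_is_better", "binary",
                    fallback = "chi_square", label = "Death 3y (%)")
  )
  if (!is.null(outcomes)) {
    unknown <- setdiff(outcomes, names(reg))
    if (length(unknown)) {
      stop("no registry entry for outcome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[outcomes]
  }
  structure(reg, class = "mcid_registry")
}

.registry_entry <- function(registry, outcome) {
  e <- registry[[outcome]]
  if (is.null(e)) {
    stop("outcome '", outcome, "' is not in the MCID registry", call. = FALSE)
  }
  e
}

# Per-patient outcome values for a registry entry (derived or raw column).
.outcome_values <- function(cohort, outcome, entry) {
  if (!is.null(entry$derive)) return(entry$derive(cohort))
  v <- cohort[[outcome]]
  if (is.null(v)) {
    stop("outcome column '", outcome, "' not found in cohort", call. = FALSE)
  }
  v
}

#' Upper-minus-lower group difference for one outcome
#'
#' Summarizes one outcome in the upper and lower biomarker-quartile groups
#' and returns the signed difference in upper-minus-lower orientation: the
#' mean for continuous outcomes, the proportion (in percentage points) for
#' binary ones.
#'
#' @param upper,lower Disjoint data.frames of patient records.
#' @param outcome Outcome name present in `registry`.
#' @param registry An [mcid_registry].
#' @return An object of class `oscar_diff`: `outcome`, `diff`,
#'   `summary_kind` (`"mean"` or `"proportion"`), `upper_summary`,
#'   `lower_summary`, `n_upper`, `n_lower`, `p_value` (NA until a fallback
#'   test runs), `gray` (TRUE when either group has < 2 usable values).
#' @export
compute_group_difference <- function(upper, lower, outcome, registry) {
  e <- .registry_entry(registry, outcome)
  vu <- .outcome_values(upper, outcome, e)
  vl <- .outcome_values(lower, outcome, e)
  vu <- vu[!is.na(vu)]
  vl <- vl[!is.na(vl)]
  kind <- if (e$type == "binary") "proportion" else "mean"
  if (length(vu) < 2 || length(vl) < 2) {
    return(structure(list(outcome = outcome, diff = NA_real_,
                          summary_kind = kind, upper_summary = NA_real_,
                          lower_summary = NA_real_, n_upper = length(vu),
                          n_lower = length(vl), p_value = NA_real_,
                          gray = TRUE),
                     class = "oscar_diff"))
  }
  if (e$type == "binary") {
    su <- 100 * mean(vu)
    sl <- 100 * mean(vl)
  } else {
    su <- mean(vu)
    sl <- mean(vl)
  }
  structure(list(outcome = outcome, diff = su - sl, summary_kind = kind,
                 upper_summary = su, lower_summary = sl,
                 n_upper = length(vu), n_lower = length(vl),
                 p_value = NA_real_, gray = FALSE),
            class = "oscar_diff")
}

#' @export
print.oscar_diff <- function(x, ...) {
  cat(sprintf("<oscar_diff> %s: diff %+.4g (%s; upper %g vs lower %g; n %d/%d)\n",
              x$outcome, x$diff, x$summary_kind, signif(x$upper_summary, 5),
              signif(x$lower_summary, 5), x$n_upper, x$n_lower))
  invisible(x)
}

# Signed-difference color given the direction of benefit: green when the
# upper-biomarker group is clinically better, red when worse.
.direction_color <- function(diff, direction) {
  better <- (direction == "higher_is_better" && diff > 0) ||
    (direction == "lower_is_better" && diff < 0)
  if (better) "green" else "red"
}

#' Classify a group difference against its MCID
#'
#' A difference smaller in magnitude than the outcome's MCID is clinically
#' unimportant (`"yellow"`); otherwise the sign and the outcome's direction
#' of benefit decide `"green"` (upper-biomarker group better) or `"red"`
#' (worse).
#'
#' @param diff An [compute_group_difference] result (or any list with `diff`
#'   and `outcome`).
#' @param registry An [mcid_registry]; the outcome must carry an MCID.
#' @return `"green"`, `"red"`, `"yellow"`, or `"gray"` for an empty cell.
#' @examples
#' reg <- mcid_registry()
#' d <- structure(list(outcome = "fev1_ml", diff = -138, gray = FALSE),
#'                class = "oscar_diff")
#' classify_mcid(d, reg)  # "red"
#' @export
classify_mcid <- function(diff, registry) {
  e <- .registry_entry(registry, diff$outcome)
  if (is.na(e$mcid)) {
    stop("outcome '", diff$outcome,
         "' has no MCID; use classify_by_test()", call. = FALSE)
  }
  if (isTRUE(diff$gray) || is.na(diff$diff)) return("gray")
  if (abs(diff$diff) < e$mcid) return("yellow")
  .direction_color(diff$diff, e$direction)
}

#' Exact two-sided test for a 2x2 table
#'
#' Conditional (hypergeometric) enumeration; the two-sided p-value sums the
#' probabilities of all tables no more likely than the observed one, the
#' usual Fisher convention.
#'
#' @param tab 2x2 integer matrix (rows: groups, columns: outcome levels).
#' @return The two-sided p-value.
#' @keywords internal
exact_test_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[, 1])
  nn <- sum(tab[, 2])
  kk <- sum(tab[1, ])
  x <- tab[1, 1]
  support <- max(0, kk - nn):min(kk, m)
  d <- stats::dhyper(support, m, nn, kk)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

#' Classify a group difference by statistical test
#'
#' For outcomes without an established MCID the upper and lower quartile
#' groups are compared by a chi-square test (binary outcomes; switching to
#' the exact conditional test when any expected cell count falls below 1) or
#' a Wilcoxon rank-sum test (continuous outcomes). Non-significant
#' differences are `"yellow"`; significant ones are colored by the signed
#' difference and the direction of benefit.
#'
#' @param upper,lower Disjoint data.frames of patient records.
#' @param outcome Outcome name with a `fallback` entry in the registry.
#' @param registry An [mcid_registry].
#' @param alpha Significance level (default 0.05).
#' @return A list: `color`, `p_value`, `diff` (the [oscar_diff]), `method`
#'   (`"chi_square"`, `"exact"`, or `"rank_sum"`).
#' @export
classify_by_test <- function(upper, lower, outcome, registry, alpha = 0.05) {
  e <- .registry_entry(registry, outcome)
  if (is.na(e$fallback)) {
    stop("outcome '", outcome, "' has no fallback test; use classify_mcid()",
         call. = FALSE)
  }
  d <- compute_group_difference(upper, lower, outcome, registry)
  if (isTRUE(d$gray)) {
    return(list(color = "gray", p_value = NA_real_, diff = d,
                method = e$fallback))
  }
  vu <- .outcome_values(upper, outcome, e)
  vl <- .outcome_values(lower, outcome, e)
  vu <- vu[!is.na(vu)]
  vl <- vl[!is.na(vl)]
  method <- e$fallback
  if (e$fallback == "chi_square") {
    tab <- rbind(upper = c(sum(vu == 1), sum(vu == 0)),
                 lower = c(sum(vl == 1), sum(vl == 0)))
    if (any(colSums(tab) == 0)) {
      p <- 1  # outcome constant across both groups: no information
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 1)) {
        p <- exact_test_2x2(tab)
        method <- "exact"
      } else {
        p <- suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
  } else if (e$fallback == "rank_sum") {
    if (length(unique(c(vu, vl))) == 1) {
      p <- 1
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(vu, vl, exact = FALSE, correct = FALSE)$p.value)
    }
  } else {
    stop("unknown fallback test: ", e$fallback, call. = FALSE)
  }
  d$p_value <- p
  color <- if (is.na(p) || p >= alpha || d$diff == 0) "yellow"
  else .direction_color(d$diff, e$direction)
  list(color = color, p_value = p, diff = d, method = method)
}

#' Build the OSCAR matrix
#'
#' For every biomarker (or once for a composite panel score) the cohort is
#' split into quartiles, the upper and lower quartile groups are compared on
#' every outcome, and each biomarker-by-outcome cell is colored: green (upper
#' group clinically better), red (worse), yellow (no clinically important or
#' significant difference), gray (insufficient data). Outcomes with an MCID
#' use [classify_mcid]; the rest use [classify_by_test]. Each cell uses the
#' records complete for its own biomarker/outcome pair (pairwise deletion).
#'
#' @param cohort Validated cohort data.frame.
#' @param biomarkers Biomarker column names (default: the eight-panel names
#'   present in the cohort).
#' @param outcomes Outcome names (default: all registry entries).
#' @param registry An [mcid_registry].
#' @param mode `"per_biomarker"` (one row per marker, the default) or
#'   `"panel"` (a single row from the [composite_panel_score] of
#'   `biomarkers`).
#' @param alpha Significance level for fallback tests.
#' @param p_adjust `"none"` (default; the source analysis applies no
#'   correction) or `"bonferroni"` across the fallback-test cells.
#' @param k Number of quantile groups (default 4).
#' @return An object of class `oscar_matrix`: `cells` (long data.frame),
#'   `colors` (biomarkers x outcomes character matrix), `biomarkers`,
#'   `outcomes`, `alpha`, `mode`.
#' @export
build_oscar_matrix <- function(cohort, biomarkers = NULL, outcomes = NULL,
                               registry = mcid_registry(),
                               mode = c("per_biomarker", "panel"),
                               alpha = 0.05, p_adjust = c("none", "bonferroni"),
                               k = 4) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  if (is.null(biomarkers)) {
    biomarkers <- intersect(c("il6", "il8", "il16", "tnfa", "mmp9", "vegf",
                              "parc", "mcp1"), names(cohort))
  }
  if (is.null(outcomes)) outcomes <- names(registry)

  strata <- if (mode == "panel") {
    score <- composite_panel_score(cohort, biomarkers)
    stats::setNames(list(score), "panel")
  } else {
    stats::setNames(lapply(biomarkers, function(b) cohort[[b]]), biomarkers)
  }

  rows <- list()
  for (b in names(strata)) {
    asg <- assign_quartiles(strata[[b]], k = k, name = b)
    grp <- extreme_groups(cohort, asg)
    for (oc in outcomes) {
      e <- .registry_entry(registry, oc)
      if (!is.na(e$mcid)) {
        d <- compute_group_difference(grp$upper, grp$lower, oc, registry)
        color <- classify_mcid(d, registry)
        method <- "mcid"
      } else {
        res <- classify_by_test(grp$upper, grp$lower, oc, registry, alpha)
        d <- res$diff
        color <- res$color
        method <- res$method
      }
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = b, outcome = oc, diff = d$diff,
        summary_kind = d$summary_kind, upper_summary = d$upper_summary,
        lower_summary = d$lower_summary, n_upper = d$n_upper,
        n_lower = d$n_lower, p_value = d$p_value, method = method,
        color = color, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  if (p_adjust == "bonferroni") {
    idx <- cells$method != "mcid" & !is.na(cells$p_value)
    m <- sum(idx)
    if (m > 0) {
      cells$p_value[idx] <- pmin(1, cells$p_value[idx] * m)
      flip <- idx & cells$p_value >= alpha & cells$color %in% c("green", "red")
      cells$color[flip] <- "yellow"
    }
  }
  colors <- matrix("gray", length(strata), length(outcomes),
                   dimnames = list(names(strata), outcomes))
  for (i in seq_len(nrow(cells))) {
    colors[cells$biomarker[i], cells$outcome[i]] <- cells$color[i]
  }
  structure(list(cells = cells, colors = colors, biomarkers = names(strata),
                 outcomes = outcomes, alpha = alpha, mode = mode),
            class = "oscar_matrix")
}

#' @export
print.oscar_matrix <- function(x, ...) {
  cat(sprintf("<oscar_matrix> %d biomarker(s) x %d outcome(s), mode %s\n",
              length(x$biomarkers), length(x$outcomes), x$mode))
  abbrev <- c(green = "G", red = "R", yellow = "y", gray = ".")
  m <- matrix(abbrev[x$colors], nrow(x$colors), ncol(x$colors),
              dimnames = dimnames(x$colors))
  print(m, quote = FALSE)
  invisible(x)
}

#' Serialize an OSCAR matrix to JSON
#'
#' @param matrix An `oscar_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oscar_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "oscar_matrix"))
  jsonlite::write_json(list(biomarkers = matrix$biomarkers,
                            outcomes = matrix$outcomes, mode = matrix$mode,
                            alpha = matrix$alpha, cells = matrix$cells),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read back a serialized OSCAR matrix
#'
#' @param path JSON path written by [write_oscar_matrix].
#' @return An `oscar_matrix`.
#' @export
read_oscar_matrix <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- raw$cells
  colors <- matrix("gray", length(raw$biomarkers), length(raw$outcomes),
                   dimnames = list(raw$biomarkers, raw$outcomes))
  for (i in seq_len(nrow(cells))) {
    colors[cells$biomarker[i], cells$outcome[i]] <- cells$color[i]
  }
  structure(list(cells = cells, colors = colors, biomarkers = raw$biomarkers,
                 outcomes = raw$outcomes, alpha = raw$alpha, mode = raw$mode),
            class = "oscar_matrix")
}
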