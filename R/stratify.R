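#' Assign biomarker quantile groups
#'
#' Splits the non-missing values into `k` groups (quartiles by default) at the
#' empirical 25th/50th/75th percentiles computed with linear interpolation
#' between order statistics (the R type-7 default). Values tied with a
#' cut-point receive the lower label, so the top group contains strictly-high
#' values. Missing values are left unlabeled.
#'
#' @param values Numeric vector of concentrations.
#' @param k Number of groups (default 4).
#' @param name Optional biomarker name carried into the result.
#' @return An object of class `quartile_assignment`: `labels` (factor
#'   `Q1..Qk`, NA for missing input), `cutpoints` (k-1 concentrations),
#'   `name`, `k`.
#' @examples
#' assign_quartiles(1:8)
#' @export
assign_quartiles <- function(values, k = 4, name = NULL) {
  stopifnot(is.numeric(values), k >= 2)
  ok <- !is.na(values)
  if (sum(ok) < 8) {
    stop("need >= 8 non-missing values for stable quantile groups (got ",
         sum(ok), ")", call. = FALSE)
  }
  probs <- seq_len(k - 1) / k
  cuts <- stats::quantile(values[ok], probs, type = 7, names = FALSE)
  if (anyDuplicated(cuts) || length(unique(values[ok])) == 1) {
    stop("degenerate quantile cut-points (ties span a cut); values cannot be ",
         "split into ", k, " groups", call. = FALSE)
  }
  lev <- paste0("Q", seq_len(k))
  lab <- cut(values, breaks = c(-Inf, cuts, Inf), labels = lev, right = TRUE)
  structure(list(labels = lab, cutpoints = cuts, name = name, k = k),
            class = "quartile_assignment")
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat(sprintf("<quartile_assignment%s> k = %d, cut-points: %s\n",
              if (is.null(x$name)) "" else paste0(": ", x$name), x$k,
              paste(signif(x$cutpoints, 6), collapse = ", ")))
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' Extract the extreme quartile groups
#'
#' Returns the records in the lowest and highest groups of an assignment —
#' the two groups the quartile-contrast analysis compares.
#'
#' @param cohort Cohort data.frame, rows aligned with the assignment.
#' @param assignment A [quartile_assignment] built on one of its columns.
#' @return A list with `lower` and `upper` data.frames.
#' @export
extreme_groups <- function(cohort, assignment) {
  stopifnot(inherits(assignment, "quartile_assignment"),
            nrow(cohort) == length(assignment$labels))
  lev <- levels(assignment$labels)
  lower <- cohort[!is.na(assignment$labels) &
                    assignment$labels == lev[1], , drop = FALSE]
  upper <- cohort[!is.na(assignment$labels) &
                    assignment$labels == lev[length(lev)], , drop = FALSE]
  if (nrow(lower) < 2 || nrow(upper) < 2) {
    stop(sprintf("extreme groups too small (lower %d, upper %d); need >= 2 each",
                 nrow(lower), nrow(upper)), call. = FALSE)
  }
  list(lower = lower, upper = upper)
}

#' Composite panel score
#'
#' Combines several biomarkers into one per-patient score as the mean of
#' within-cohort fractional ranks (rank / number of non-missing), a
#' unit-free combination robust to the orders-of-magnitude differences across
#' analytes. With `orientation = "high_good"` the ranks are reversed so that
#' a high score always means "more of the panel's signal". A patient missing
#' more than half of the listed markers gets a missing score.
#'
#' @param cohort Cohort data.frame.
#' @param biomarkers Character vector (>= 2) of biomarker column names, or a
#'   single name (the score is then that marker's fractional rank).
#' @param orientation `"high_bad"` (default) keeps raw ranks; `"high_good"`
#'   reverses them.
#' @return Numeric score per patient in (0, 1\], NA where insufficient data.
#' @export
composite_panel_score <- function(cohort, biomarkers,
                                  orientation = c("high_bad", "high_good")) {
  orientation <- match.arg(orientation)
  missing_b <- setdiff(biomarkers, names(cohort))
  if (length(missing_b)) {
    stop("biomarker column(s) not in cohort: ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  fr <- sapply(biomarkers, function(b) {
    v <- cohort[[b]]
    ok <- !is.na(v)
    if (sum(ok) < 8) {
      stop("biomarker '", b, "' has fewer than 8 non-missing values",
           call. = FALSE)
    }
    r <- rank(v, na.last = "keep") / sum(ok)
    if (orientation == "high_good") r <- (sum(ok) + 1) / sum(ok) - r
    r
  })
  fr <- matrix(fr, nrow = nrow(cohort))
  n_obs <- rowSums(!is.na(fr))
  score <- rowMeans(fr, na.rm = TRUE)
  score[n_obs < length(biomarkers) / 2 | n_obs == 0] <- NA_real_
  score
}
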