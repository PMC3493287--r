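#' Pairwise-complete Spearman correlation matrix
#'
#' For every pair of columns the records complete for that pair are
#' rank-transformed (average ranks for ties) and Pearson-correlated. Cells
#' with fewer than `min_pairs` complete pairs or with a constant column are
#' flagged undefined rather than propagating NaN.
#'
#' @param cohort Data.frame.
#' @param columns Column names to correlate.
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return An object of class `spearman_matrix`: `names`, `r` (estimates,
#'   NA where undefined), `n` (pairwise counts), `undefined` (logical
#'   matrix).
#' @export
spearman_matrix <- function(cohort, columns, min_pairs = 3) {
  missing_c <- setdiff(columns, names(cohort))
  if (length(missing_c)) {
    stop("column(s) not in cohort: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  k <- length(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  n <- matrix(0L, k, k, dimnames = list(columns, columns))
  undef <- matrix(FALSE, k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- cohort[[columns[i]]]
      y <- cohort[[columns[j]]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        if (sum(ok) >= min_pairs && length(unique(x[ok])) > 1) {
          r[i, j] <- 1
        } else {
          undef[i, j] <- TRUE
        }
        next
      }
      if (sum(ok) < min_pairs || length(unique(x[ok])) == 1 ||
          length(unique(y[ok])) == 1) {
        undef[i, j] <- undef[j, i] <- TRUE
        next
      }
      rx <- rank(x[ok])
      ry <- rank(y[ok])
      r[i, j] <- r[j, i] <- stats::cor(rx, ry)
    }
  }
  structure(list(names = columns, r = r, n = n, undefined = undef),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("<spearman_matrix> %d variables, pairwise-complete\n",
              length(x$names)))
  print(round(x$r, 2))
  if (any(x$undefined)) cat("(NA cells are undefined: constant column or too few pairs)\n")
  invisible(x)
}

#' One-way trend test across GOLD stages
#'
#' Compares a variable across the GOLD stages present in the cohort by
#' one-way ANOVA (equal-variance F), Kruskal-Wallis, or chi-square on a
#' stage-by-level contingency table for categorical variables.
#'
#' @param cohort Cohort data.frame with a `gold` column.
#' @param variable Column to test.
#' @param kind `"anova"`, `"kruskal_wallis"`, or `"chi_square"`.
#' @return A list: `statistic`, `p_value`, `df`, `kind`, `n`.
#' @export
stage_trend_test <- function(cohort, variable,
                             kind = c("anova", "kruskal_wallis",
                                      "chi_square")) {
  kind <- match.arg(kind)
  if (is.null(cohort[[variable]])) {
    stop("variable '", variable, "' not in cohort", call. = FALSE)
  }
  ok <- !is.na(cohort[[variable]]) & !is.na(cohort$gold)
  v <- cohort[[variable]][ok]
  g <- factor(cohort$gold[ok])
  counts <- table(g)
  if (sum(counts >= 2) < 2) {
    stop("need >= 2 stages with >= 2 observations each", call. = FALSE)
  }
  if (kind == "anova") {
    fit <- stats::anova(stats::lm(v ~ g))
    res <- list(statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
                df = fit$Df[1])
  } else if (kind == "kruskal_wallis") {
    kt <- stats::kruskal.test(v, g)
    res <- list(statistic = unname(kt$statistic), p_value = kt$p.value,
                df = unname(kt$parameter))
  } else {
    tab <- table(g, v)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                df = unname(ct$parameter))
  }
  c(res, list(kind = kind, n = length(v)))
}

#' Concordance (C) statistic for a binary outcome
#'
#' Probability that a randomly chosen case carries a higher score than a
#' randomly chosen control, ties counted one half — the area under the ROC
#' curve. Computed by the rank identity in O(n log n).
#'
#' @param score Numeric risk scores.
#' @param y Binary outcome (0/1).
#' @return C in \[0, 1\].
#' @export
concordance_stat <- function(score, y) {
  ok <- !is.na(score) & !is.na(y)
  score <- score[ok]
  y <- y[ok]
  stopifnot(all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present to compute C", call. = FALSE)
  }
  r <- rank(score)  # average ranks handle ties as half-wins
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic mortality model and its C statistic
#'
#' Fits death-by-3-years on a predictor set by iteratively reweighted least
#' squares with a small ridge penalty (default 1e-6) that stabilizes the fit
#' under complete separation. Biomarker predictors are entered
#' log-transformed (they are right-skewed and floored at the assay detection
#' limit); all predictors are standardized before fitting. The C statistic is
#' computed on the fitted linear predictor. With no event times in the data
#' model, this is the binary-outcome (ROC-area) concordance, not a
#' time-to-event concordance.
#'
#' @param cohort Cohort data.frame with a `dead_3y` column.
#' @param predictors Column names to enter.
#' @param log_biomarkers Log-transform biomarker columns first (default
#'   TRUE).
#' @param ridge Ridge penalty on the standardized coefficients (default
#'   1e-6; the intercept is unpenalized).
#' @param max_iter IRLS iteration cap; non-convergence is an error reporting
#'   the gradient norm.
#' @param tol Convergence tolerance on the penalized gradient norm.
#' @return An object of class `mortality_model`: `coefficients` (log-odds
#'   per SD of each predictor), `c_statistic`, `linear_predictor`, `n`,
#'   `n_events`, `predictors`, `iterations`.
#' @export
fit_mortality_model <- function(cohort, predictors, log_biomarkers = TRUE,
                                ridge = 1e-6, max_iter = 100, tol = 1e-8) {
  biomarker_cols <- c("il6", "il8", "il16", "tnfa", "mmp9", "vegf", "parc",
                      "mcp1")
  missing_c <- setdiff(c(predictors, "dead_3y"), names(cohort))
  if (length(missing_c)) {
    stop("column(s) not in cohort: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(cohort[predictors])
  if (log_biomarkers) {
    for (b in intersect(predictors, biomarker_cols)) {
      X[, b] <- log(pmax(X[, b], .Machine$double.eps))
    }
  }
  y <- cohort$dead_3y
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  stopifnot(all(y %in% c(0, 1)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(predictors[sds == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- scale(X)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(Xd)
  pen <- c(0, rep(ridge, p - 1))  # intercept unpenalized
  beta <- numeric(p)
  it <- 0
  repeat {
    it <- it + 1
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) break
    if (it > max_iter) {
      stop(sprintf("IRLS failed to converge in %d iterations (gradient norm %.3e)",
                   max_iter, sqrt(sum(grad^2))), call. = FALSE)
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, w * Xd) + diag(pen, p)
    step <- solve(H, grad)
    # halve the step while the penalized deviance worsens
    dev <- function(b) {
      e <- drop(Xd %*% b)
      log1pexp <- ifelse(e > 30, e, log1p(exp(pmin(e, 30))))
      -2 * sum(y * e - log1pexp) + sum(pen * b^2)
    }
    d0 <- dev(beta)
    s <- 1
    while (dev(beta + s * step) > d0 + 1e-12 && s > 1e-8) s <- s / 2
    beta <- beta + s * step
  }
  lp <- drop(Xd %*% beta)
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 c_statistic = concordance_stat(lp, y),
                 linear_predictor = lp, n = length(y), n_events = sum(y),
                 predictors = predictors, iterations = it),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("<mortality_model> n = %d (%d deaths), C = %.3f\n", x$n,
              x$n_events, x$c_statistic))
  print(round(x$coefficients, 4))
  invisible(x)
}
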