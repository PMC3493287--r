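#' Copula specification for a biomarker panel
#'
#' Pairs an ordered set of biomarker names with a target Spearman rank
#' correlation matrix. The matrix must be symmetric with unit diagonal; the
#' implied Pearson matrix (after [spearman_to_pearson]) is repaired to the
#' nearest valid correlation matrix if needed (see [nearest_correlation]).
#'
#' @param biomarker_names Character vector of panel members.
#' @param spearman_target Square numeric matrix of target rank correlations.
#' @return An object of class `copula_spec` with elements `names`, `spearman`,
#'   `pearson` (converted and, if necessary, repaired) and `repaired`.
#' @export
copula_spec <- function(biomarker_names, spearman_target) {
  k <- length(biomarker_names)
  stopifnot(is.matrix(spearman_target), nrow(spearman_target) == k,
            ncol(spearman_target) == k)
  if (max(abs(spearman_target - t(spearman_target))) > 1e-8) {
    stop("spearman_target must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(spearman_target) - 1)) > 1e-8) {
    stop("spearman_target must have unit diagonal", call. = FALSE)
  }
  if (any(abs(spearman_target) > 1 + 1e-12)) {
    stop("spearman_target entries must lie in [-1, 1]", call. = FALSE)
  }
  pearson <- spearman_to_pearson(spearman_target)
  diag(pearson) <- 1
  ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < 1e-8) {
    pearson <- nearest_correlation(pearson)
    repaired <- TRUE
    ev2 <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) < 0) {
      stop(sprintf("correlation matrix not positive semi-definite after repair (smallest eigenvalue %.3e)",
                   min(ev2)), call. = FALSE)
    }
  }
  dimnames(pearson) <- dimnames(spearman_target) <-
    list(biomarker_names, biomarker_names)
  structure(list(names = biomarker_names, spearman = spearman_target,
                 pearson = pearson, repaired = repaired),
            class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("<copula_spec> %d biomarkers: %s%s\n", length(x$names),
              paste(x$names, collapse = ", "),
              if (x$repaired) " (PSD-repaired)" else ""))
  invisible(x)
}

#' Repair a symmetric matrix to a valid correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by re-normalization to unit diagonal.
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor. Default 1e-8.
#' @return A symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Sample a rank-correlated biomarker panel
#'
#' Draws `n` patients' worth of biomarker concentrations whose rank
#' correlation structure matches the copula target and whose marginals are the
#' log-normal fits of the supplied median/IQR summaries.
#'
#' The sampler uses restricted pairing in the Iman-Conover tradition: random
#' normal scores are linearly adjusted so their sample Pearson correlation
#' equals the converted target exactly, their ranks are then mapped onto the
#' stratified uniform grid `(rank - 0.5)/n`, and each column is pushed through
#' its log-normal quantile function. Consequences: sample medians and
#' quartiles recover the fitted marginals to O(1/n) rather than O(1/sqrt(n)),
#' and the sample Spearman matrix concentrates tightly around the target. For
#' very small `n` (fewer than `length(copula$names) + 2` rows) the exact
#' correlation adjustment is rank-deficient and plain Cholesky coloring is
#' used instead.
#'
#' @param copula A [copula_spec].
#' @param marginals Named list of [biomarker_marginal] objects covering every
#'   name in `copula$names`.
#' @param n Number of rows to draw (>= 2).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data.frame of concentrations, one column per biomarker, in the
#'   copula's column order.
#' @export
sample_biomarker_panel <- function(copula, marginals, n, seed) {
  stopifnot(inherits(copula, "copula_spec"), n >= 2)
  missing_m <- setdiff(copula$names, names(marginals))
  if (length(missing_m)) {
    stop("no marginal supplied for: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  k <- length(copula$names)
  Z <- local_rng(seed, matrix(stats::rnorm(n * k), n, k))
  Zt <- .color_scores(Z, copula$pearson)
  out <- vector("list", k)
  names(out) <- copula$names
  for (j in seq_len(k)) {
    fit <- fit_lognormal_from_quartiles(marginals[[copula$names[j]]])
    if (fit$sigma == 0) {
      out[[j]] <- rep(exp(fit$mu), n)
    } else {
      u <- (rank(Zt[, j], ties.method = "first") - 0.5) / n
      out[[j]] <- stats::qlnorm(u, meanlog = fit$mu, sdlog = fit$sigma)
    }
  }
  as.data.frame(out)
}

# Impose a target correlation on the columns of a score matrix. When n is
# large enough the sample correlation is matched exactly (whiten by the sample
# Cholesky factor, recolor by the target's); otherwise fall back to
# population-level Cholesky coloring.
.color_scores <- function(Z, target) {
  n <- nrow(Z)
  k <- ncol(Z)
  Rt <- chol(target + diag(1e-12, k))
  if (n >= k + 2) {
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    S <- crossprod(Zc) / (n - 1)
    ok <- tryCatch({
      Rs <- chol(S)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(Zc %*% backsolve(Rs, diag(k)) %*% Rt)
  }
  Z %*% Rt
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' library internals never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
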