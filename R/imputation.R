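#' @title Imputation results
#' @description Container returned by the three imputation methods: the
#'   completed matrix plus method metadata and a per-entry provenance mask.
#'   All methods are interpolating (observed entries pass through unchanged)
#'   and return values in `[-1, +1]`.
#' @param scores completed matrix.
#' @param method method tag.
#' @param iterations iterations/passes used.
#' @param trace per-iteration convergence metric.
#' @param converged logical.
#' @param imputed logical matrix flagging imputed entries.
#' @return an object of class `imputation_result` with elements `scores`,
#'   `method`, `iterations`, `trace`, `converged`, `imputed`.
#' @keywords internal
imputation_result <- function(scores, method, iterations, trace, converged,
                              imputed) {
  structure(list(scores = scores, method = method, iterations = iterations,
                 trace = trace, converged = converged, imputed = imputed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method=%s  %d x %d  imputed=%d  iterations=%d  converged=%s\n",
              x$method, nrow(x$scores), ncol(x$scores), sum(x$imputed),
              x$iterations, x$converged))
  invisible(x)
}

## completed matrix from an imputation_result or plain matrix
imp_scores <- function(x) if (inherits(x, "imputation_result")) x$scores else x

#' Mean imputation
#'
#' Each missing entry is replaced by the mean of its marker's observed
#' scores (the expected allele value at that marker).
#'
#' @param m marker matrix.
#' @return an `imputation_result`.
#' @export
impute_mean <- function(m) {
  as_marker_matrix(m)
  miss <- is.na(m)
  if (any(colSums(!miss) == 0)) fail("marker with no observed entries")
  out <- m
  if (any(miss)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    out[idx] <- mu[idx[, 2]]
  }
  imputation_result(out, "Mean", 1L, numeric(0), TRUE, miss)
}

#' Multivariate-normal EM imputation
#'
#' Treats each centred marker column as a draw from a zero-mean multivariate
#' normal over lines whose covariance is proportional to the realized
#' additive relationship matrix `A` among the lines.  Starting from the
#' mean-imputed completion, the algorithm alternates:
#' \describe{
#'   \item{E-step}{each column's missing entries are set to their conditional
#'     expectation given the observed entries,
#'     `mu_m + A_mo (A_oo + eps I)^{-1} (x_o - mu_o)`, where `o`/`m` index
#'     the observed/missing lines of that column, `mu` is the column's
#'     observed mean and `eps = 1e-6 trace(A_oo)/|o|` is a ridge guarding
#'     near-singular kinship among the observed lines;}
#'   \item{M-step}{`A` is re-estimated from the completed matrix with
#'     [realized_relationship()].}
#' }
#' Iteration stops when the Frobenius norm of the change in `A`, divided by
#' `trace(A)`, falls below `tol`, or after `max_iter` iterations (returning
#' the final iterate with `converged = FALSE`).  Imputed values are clipped
#' to `[-1, +1]`.  Columns sharing a missingness pattern share one
#' factorisation.
#'
#' @param m marker matrix.
#' @param tol relative Frobenius-change threshold on `A` (default 0.02).
#' @param max_iter maximum EM iterations.
#' @return an `imputation_result`; element `trace` holds the per-iteration
#'   relative change of `A`, and attribute `monotone` of the result records
#'   whether that metric was non-increasing after the first iteration.
#' @export
impute_mvn_em <- function(m, tol = 0.02, max_iter = 100) {
  as_marker_matrix(m)
  if (nrow(m) < 2) fail("need at least 2 lines")
  miss <- is.na(m)
  if (any(colSums(!miss) == 0)) fail("marker with no observed entries")
  if (!any(miss))
    return(imputation_result(m, "MVN-EM", 1L, 0, TRUE, miss))
  mu <- colMeans(m, na.rm = TRUE)
  C <- m
  idx <- which(miss, arr.ind = TRUE)
  C[idx] <- mu[idx[, 2]]
  A <- realized_relationship(C)
  cols_with_na <- which(colSums(miss) > 0)
  pattern <- vapply(cols_with_na,
                    function(j) paste(which(miss[, j]), collapse = ","),
                    character(1))
  groups <- split(cols_with_na, pattern)
  tr <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (grp in groups) {
      mm <- which(miss[, grp[1]])
      oo <- which(!miss[, grp[1]])
      Aoo <- A[oo, oo, drop = FALSE]
      ridge <- 1e-6 * sum(diag(Aoo)) / length(oo)
      K <- A[mm, oo, drop = FALSE] %*%
        chol2inv(chol(Aoo + diag(ridge, length(oo))))
      W <- sweep(m[oo, grp, drop = FALSE], 2, mu[grp])   # observed, centred
      C[mm, grp] <- clip(sweep(K %*% W, 2, mu[grp], `+`))
    }
    A_new <- realized_relationship(C)
    delta <- sqrt(sum((A_new - A)^2)) / sum(diag(A))
    tr <- c(tr, delta)
    A <- A_new
    if (delta < tol) { converged <- TRUE; break }
  }
  res <- imputation_result(C, "MVN-EM", it, tr, converged, miss)
  attr(res, "monotone") <- length(tr) < 3 || all(diff(tr[-1]) <= 1e-8)
  res
}

#' Iterative random-forest imputation
#'
#' missForest-style imputation: missing entries are initialised with marker
#' means; then, visiting markers in ascending order of missing count, each
#' incomplete marker is regressed (random forest, \pkg{ranger}) on the
#' `n_predictors` other markers most correlated with it in the current
#' completed matrix, and its missing entries are replaced by forest
#' predictions.  Passes repeat until the mean absolute change of the imputed
#' entries falls below 0.01 or `max_iter` passes.  Predictions are clipped
#' to `[-1, +1]`.  Because the predictor set is already screened down to the
#' most correlated markers, every screened predictor is a split candidate at
#' every node (randomness enters through the bootstrap) and the minimum node
#' size is 1, so a marker in complete LD with the target drives the leaves
#' to purity on `{-1, +1}` targets.  Forests are grown single-threaded with
#' per-marker derived seeds, so results are deterministic given `seed`.
#'
#' @param m marker matrix (>= 2 markers).
#' @param n_trees trees per forest.
#' @param n_predictors predictor markers per forest (most correlated by
#'   absolute Pearson correlation; all others if fewer are available).
#' @param max_iter maximum passes over the markers.
#' @param seed integer seed.
#' @return an `imputation_result`; `trace` holds the per-pass mean absolute
#'   change of imputed entries.
#' @export
impute_rf <- function(m, n_trees = 100, n_predictors = 30, max_iter = 5,
                      seed = 1) {
  as_marker_matrix(m)
  if (ncol(m) < 2) fail("need at least 2 markers")
  miss <- is.na(m)
  if (any(colSums(!miss) == 0)) fail("marker with no observed entries")
  if (!any(miss))
    return(imputation_result(m, "RF", 0L, numeric(0), TRUE, miss))
  C <- imp_scores(impute_mean(m))
  colnames(C) <- colnames(m)
  na_count <- colSums(miss)
  order_j <- order(na_count, colnames(m))
  order_j <- order_j[na_count[order_j] > 0]
  tr <- numeric(0)
  converged <- FALSE
  pass <- 0L
  while (pass < max_iter) {
    pass <- pass + 1L
    prev <- C[miss]
    cc <- abs(suppressWarnings(stats::cor(C)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    for (j in order_j) {
      pred <- order(cc[, j], decreasing = TRUE)[seq_len(min(n_predictors,
                                                            ncol(m) - 1))]
      obs <- which(!miss[, j])
      fit <- ranger::ranger(x = C[obs, pred, drop = FALSE],
                            y = m[obs, j],
                            num.trees = n_trees,
                            mtry = length(pred),
                            min.node.size = 1,
                            seed = substream_seed(seed, "rf", pass, j),
                            num.threads = 1)
      hit <- which(miss[, j])
      C[hit, j] <- clip(predict_ranger(fit, C[hit, pred, drop = FALSE]))
    }
    tr <- c(tr, mean(abs(C[miss] - prev)))
    if (tr[pass] < 0.01) { converged <- TRUE; break }
  }
  imputation_result(C, "RF", pass, tr, converged, miss)
}

predict_ranger <- function(fit, newx) {
  stats::predict(fit, data = newx, num.threads = 1)$predictions
}

#' Imputation accuracy over masked entries
#'
#' Scores an imputation against the truth on exactly the entries removed by
#' [apply_missingness()] (its `"masked"` attribute, or any logical matrix of
#' the same shape).
#'
#' @param truth complete marker matrix.
#' @param imputed an `imputation_result` or completed matrix.
#' @param mask logical matrix of evaluated entries; defaults to the
#'   `"masked"` attribute carried by a masked matrix.
#' @return list with `mse` (mean squared error) and `sign_rate` (fraction of
#'   masked entries whose imputed value predicts the true allele; the
#'   predicted allele is `+1` when the imputed score is >= 0).
#' @export
imputation_accuracy <- function(truth, imputed, mask) {
  x <- imp_scores(imputed)
  stopifnot(identical(dim(truth), dim(x)))
  if (inherits(mask, "matrix") || is.matrix(mask)) masked <- mask
  else fail("mask must be a logical matrix")
  if (!any(masked)) fail("empty mask")
  err <- x[masked] - truth[masked]
  pred_allele <- ifelse(x[masked] >= 0, 1, -1)
  list(mse = mean(err^2),
       sign_rate = mean(pred_allele == truth[masked]))
}
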