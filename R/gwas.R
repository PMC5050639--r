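#' REML variance components of the null polygenic model
#'
#' Fits `y = Q v + u + e` with `u ~ N(0, A sigma2_g)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood, using the
#' one-time spectral decomposition of `A` projected off the fixed effects
#' (EMMA-style): the restricted likelihood is a 1-D function of
#' `lambda = sigma2_e / sigma2_g`, profiled on a grid of 101 points in
#' `log10(lambda)` over `[-5, 5]` and then refined by golden-section /
#' parabolic search.  When the likelihood is flat in `lambda` (e.g. `A`
#' proportional to the identity), the largest `lambda` among ties is
#' returned, attributing the variance to the residual.
#'
#' These population parameters are estimated once and reused for every
#' marker test (P3D).
#'
#' @param y complete phenotype vector.
#' @param A relationship matrix (lines x lines), e.g. from
#'   [realized_relationship()].
#' @param Q fixed-effect design matrix with intercept (default: intercept
#'   only).  See [make_Q()].
#' @return list with `sigma2_g`, `sigma2_e`, `lambda`, `loglik`, `n`, `q`.
#' @export
estimate_null_varcomp <- function(y, A, Q = NULL) {
  n <- length(y)
  if (anyNA(y)) fail("phenotype must be complete for the null model")
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  q <- ncol(Q)
  S <- diag(n) - Q %*% solve(crossprod(Q), t(Q))
  M <- S %*% A %*% S
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- eg$values[seq_len(n - q)]
  xi[xi < 0] <- 0                      # numerically negative null directions
  eta <- drop(crossprod(eg$vectors[, seq_len(n - q), drop = FALSE], y))
  rll <- function(log10d) {
    d <- 10^log10d
    ss <- sum(eta^2 / (xi + d))
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(ss)) -
             sum(log(xi + d)))
  }
  grid <- seq(-5, 5, length.out = 101)
  vals <- vapply(grid, rll, numeric(1))
  best <- max(vals)
  cand <- grid[vals >= best - 1e-8]
  gbest <- max(cand)                   # tie-break: largest lambda
  opt <- stats::optimize(rll, c(max(-5, gbest - 0.2), min(5, gbest + 0.2)),
                         maximum = TRUE, tol = 1e-8)
  if (opt$objective > best + 1e-10) {
    log10d <- opt$maximum; ll <- opt$objective
  } else {
    log10d <- gbest; ll <- best
  }
  d <- 10^log10d
  s2g <- sum(eta^2 / (xi + d)) / (n - q)
  if (!is.finite(ll)) fail("non-finite restricted likelihood")
  list(sigma2_g = s2g, sigma2_e = d * s2g, lambda = d, loglik = ll,
       n = n, q = q)
}

#' Fixed-effect design for population structure
#'
#' Intercept plus drop-first indicator columns for subpopulation membership.
#'
#' @param subpop factor of subpopulation labels (or `NULL` for intercept
#'   only).
#' @param n number of lines (needed when `subpop` is `NULL`).
#' @return design matrix with full column rank.
#' @export
make_Q <- function(subpop = NULL, n = NULL) {
  if (is.null(subpop)) {
    stopifnot(!is.null(n))
    return(matrix(1, n, 1))
  }
  subpop <- droplevels(as.factor(subpop))
  if (nlevels(subpop) == 1) return(matrix(1, length(subpop), 1))
  stats::model.matrix(~subpop)
}

#' Single-marker mixed-model association test
#'
#' Generalised-least-squares fit of `y` on `[Q, x]` over the lines where the
#' marker is observed, with covariance proportional to
#' `sigma2_g A_ss + sigma2_e I` on that subset (variance components fixed
#' from the null model, P3D).  The system is whitened by the Cholesky factor
#' of the subset covariance and the marker coefficient is tested two-sided
#' against a t distribution with `n_used - ncol(Q) - 1` degrees of freedom,
#' with the residual scale re-estimated from the whitened fit (so with
#' `A = I` and intercept-only `Q` the test reduces exactly to the ordinary
#' least-squares t-test).
#'
#' Markers that are constant on the retained lines, or retain fewer than
#' `ncol(Q) + 2` lines, are skipped with an explicit skip code instead of a
#' fabricated p-value.
#'
#' @param y phenotype vector.
#' @param x marker scores (may contain `NA`).
#' @param A relationship matrix.
#' @param Q fixed-effect design (default intercept).
#' @param varcomp output of [estimate_null_varcomp()].
#' @return list with `beta`, `se`, `p`, `n_used`, `skip` (`NA` when tested).
#' @export
single_marker_test <- function(y, x, A, Q = NULL, varcomp) {
  n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  s <- which(!is.na(x) & !is.na(y))
  ctx <- marker_test_context(y, A, Q, varcomp, s)
  if (is.character(ctx))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = length(s), skip = ctx))
  marker_test_on_context(ctx, x)
}

## Whitened per-missingness-pattern context: everything that does not depend
## on the marker values themselves, so complete matrices share one
## factorisation across markers.
marker_test_context <- function(y, A, Q, varcomp, s) {
  q <- ncol(Q)
  if (length(s) < q + 2) return("too_few_lines")
  V <- varcomp$sigma2_g * A[s, s, drop = FALSE] +
    diag(varcomp$sigma2_e, length(s))
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return("singular_covariance")
  Qt <- backsolve(L, Q[s, , drop = FALSE], transpose = TRUE)
  yt <- backsolve(L, y[s], transpose = TRUE)
  list(s = s, L = L, Qt = Qt, yt = yt, q = q)
}

marker_test_on_context <- function(ctx, x) {
  s <- ctx$s
  xs <- x[s]
  n_used <- length(s)
  if (max(xs) - min(xs) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = n_used, skip = "monomorphic"))
  xt <- backsolve(ctx$L, xs, transpose = TRUE)
  W <- cbind(ctx$Qt, xt)
  qr_ <- qr(W)
  if (qr_$rank < ncol(W))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = n_used, skip = "collinear"))
  beta <- qr.coef(qr_, ctx$yt)
  res <- ctx$yt - W %*% beta
  df <- n_used - ncol(W)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * XtXinv[ncol(W), ncol(W)])
  b <- beta[ncol(W)]
  tval <- b / se
  list(beta = b, se = se, p = 2 * stats::pt(-abs(tval), df),
       n_used = n_used, skip = NA_character_)
}

#' Genome-wide single-marker mixed-model scan
#'
#' Applies [single_marker_test()] to every marker of `m` passing `min_maf`
#' on its non-missing subset, with variance components estimated once on the
#' null model (P3D) unless supplied.  Covariance factorisations are cached
#' per missingness pattern, which makes scans of complete (imputed) matrices
#' share a single factorisation; the cached path is algebraically identical
#' to calling [single_marker_test()] per marker.
#'
#' @param y phenotype vector (named or in line order of `m`).
#' @param m marker matrix (raw or imputed coding).
#' @param A relationship matrix; default [realized_relationship()] of `m`.
#' @param Q fixed-effect design or `NULL` for intercept.
#' @param min_maf skip markers below this MAF on their observed subset
#'   (default 0: matrices are assumed pre-filtered).
#' @param varcomp optional precomputed [estimate_null_varcomp()] output.
#' @return object of class `gwas_result`: data frame with columns `marker`,
#'   `beta`, `se`, `p`, `n_used`, `skip`, and attributes `varcomp`, `n`.
#' @export
run_gwas <- function(y, m, A = NULL, Q = NULL, min_maf = 0, varcomp = NULL) {
  if (!is.null(names(y)) && !is.null(rownames(m))) {
    if (!all(rownames(m) %in% names(y))) fail("phenotype/matrix line mismatch")
    y <- y[rownames(m)]
  }
  n <- nrow(m)
  stopifnot(length(y) == n)
  if (is.null(A)) A <- realized_relationship(m)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  if (is.null(varcomp)) varcomp <- estimate_null_varcomp(y, A, Q)
  maf <- marker_maf(m)
  cache <- new.env(parent = emptyenv())
  out <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    if (!is.nan(maf[j]) && maf[j] < min_maf) {
      out[[j]] <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                       n_used = sum(!is.na(m[, j])), skip = "low_maf")
      next
    }
    x <- m[, j]
    s <- which(!is.na(x) & !is.na(y))
    key <- paste(s, collapse = ",")
    ctx <- cache[[key]]
    if (is.null(ctx)) {
      ctx <- marker_test_context(y, A, Q, varcomp, s)
      cache[[key]] <- ctx
    }
    out[[j]] <- if (is.character(ctx))
      list(beta = NA_real_, se = NA_real_, p = NA_real_,
           n_used = length(s), skip = ctx)
    else marker_test_on_context(ctx, x)
  }
  res <- data.frame(marker = colnames(m),
                    beta = vapply(out, `[[`, numeric(1), "beta"),
                    se = vapply(out, `[[`, numeric(1), "se"),
                    p = vapply(out, `[[`, numeric(1), "p"),
                    n_used = vapply(out, `[[`, numeric(1), "n_used"),
                    skip = vapply(out, `[[`, character(1), "skip"))
  attr(res, "varcomp") <- varcomp
  attr(res, "n") <- n
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Quantile-quantile plot data
#'
#' @param result a `gwas_result`.
#' @return data frame of `expected` and `observed` `-log10(p)` for the
#'   tested markers, sorted by expected quantile.
#' @export
qq_data <- function(result) {
  p <- sort(result$p[!is.na(result$p)])
  k <- length(p)
  data.frame(expected = -log10((seq_len(k) - 0.5) / k),
             observed = -log10(p))[k:1, , drop = FALSE]
}

#' Slope of the central part of a QQ plot
#'
#' Least-squares slope through the origin of observed on expected
#' `-log10(p)`, restricted to the central `central` fraction of the
#' distribution; near 1 for well-calibrated null p-values.
#'
#' @param result a `gwas_result`, or a numeric vector of p-values.
#' @param central central fraction retained (default 0.9).
#' @return slope (numeric scalar).
#' @export
qq_slope <- function(result, central = 0.9) {
  p <- if (is.numeric(result)) result else result$p
  p <- sort(p[!is.na(p)])
  k <- length(p)
  e <- (seq_len(k) - 0.5) / k
  keep <- e >= (1 - central) / 2 & e <= 1 - (1 - central) / 2
  o <- -log10(p[keep]); e <- -log10(e[keep])
  sum(o * e) / sum(e^2)
}

#' Manhattan plot data
#'
#' @param result a `gwas_result`.
#' @param map genetic map covering the scanned markers.
#' @return data frame `marker`, `chrom`, `pos_cM`, `bin`, `neg_log10_p`.
#' @export
manhattan_data <- function(result, map) {
  map <- as_genetic_map(map, markers = result$marker)
  i <- match(result$marker, map$marker)
  data.frame(marker = result$marker, chrom = map$chrom[i],
             pos_cM = map$pos_cM[i], bin = map$bin[i],
             neg_log10_p = -log10(result$p))
}

#' Effective number of independent markers (Li & Ji)
#'
#' Computes the eigenvalues `lambda_i` of the marker-marker correlation
#' matrix and returns `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)) ]`.  The eigenvalues are obtained from the singular
#' values of the standardised (mean-filled, centred, unit-variance) genotype
#' matrix, which is exact for complete data and avoids forming an M x M
#' matrix; eigenvalues beyond the matrix rank are zero and contribute
#' nothing.  Zero-variance markers are excluded with a warning.
#'
#' @param m marker matrix (missing entries are mean-filled before
#'   standardisation).
#' @return `Meff` in `[1, M]`.
#' @export
effective_num_markers_liji <- function(m) {
  if (ncol(m) < 2) fail("need at least 2 markers")
  mu <- colMeans(m, na.rm = TRUE)
  Z <- sweep(m, 2, mu)
  Z[is.na(Z)] <- 0
  sdv <- sqrt(colSums(Z^2) / (nrow(m) - 1))
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad)) {
    warning(sprintf("%d zero-variance markers excluded from Meff", sum(bad)),
            call. = FALSE)
    Z <- Z[, !bad, drop = FALSE]
    sdv <- sdv[!bad]
  }
  M <- ncol(Z)
  if (M < 1) fail("no markers with variance")
  Z <- sweep(Z, 2, sdv, `/`)
  d <- svd(Z, nu = 0, nv = 0)$d
  lambda <- d^2 / (nrow(m) - 1)
  lambda[lambda < 0] <- 0
  near <- abs(lambda - round(lambda)) < 1e-9   # snap float noise at integers
  lambda[near] <- round(lambda[near])
  meff <- sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda)))
  min(max(meff, 1), M)
}

#' Per-test significance cutoff
#'
#' The three threshold rules used to declare markers significant:
#' Bonferroni (`alpha / M`), Bonferroni on the Li & Ji effective number of
#' markers (`alpha / Meff`), and a liberal fixed level (`alpha`, by
#' convention 0.01).
#'
#' @param method `"bonferroni"`, `"liji"` or `"liberal"`.
#' @param alpha significance level; defaults to 0.05 for the corrected
#'   rules and to the liberal level 0.01 for `"liberal"`.
#' @param M number of markers (required for `"bonferroni"`).
#' @param Meff effective number of markers (required for `"liji"`).
#' @return list of class `threshold_spec` with the inputs and the resulting
#'   per-test `cutoff`.
#' @export
make_threshold <- function(method = c("bonferroni", "liji", "liberal"),
                           alpha = NULL, M = NULL, Meff = NULL) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- if (method == "liberal") 0.01 else 0.05
  if (alpha <= 0 || alpha >= 1) fail("alpha must be in (0, 1)")
  cutoff <- switch(method,
    bonferroni = { stopifnot(!is.null(M)); alpha / M },
    liji = {
      if (is.null(Meff)) fail("liji threshold needs Meff")
      alpha / Meff
    },
    liberal = alpha)
  structure(list(method = method, alpha = alpha, M = M, Meff = Meff,
                 cutoff = cutoff), class = "threshold_spec")
}
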