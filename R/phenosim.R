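#' Sample QTL positions from LD blocks
#'
#' Draws `n_qtl` distinct LD blocks uniformly without replacement, then one
#' marker uniformly at random within each chosen block, so that simulated
#' QTL are mutually independent at the block level (at most one QTL per
#' block by construction).
#'
#' @param blocks block partition (see [single_linkage_blocks()]).
#' @param n_qtl number of QTL; must not exceed the number of blocks.
#' @param seed integer seed.
#' @return data frame with columns `block_id`, `marker`.
#' @export
select_qtl <- function(blocks, n_qtl, seed = 1) {
  ids <- unique(blocks$block_id)
  if (n_qtl > length(ids))
    fail("n_qtl (%d) exceeds the number of blocks (%d)", n_qtl, length(ids))
  withr::with_seed(substream_seed(seed, "qtl"), {
    chosen <- ids[sample.int(length(ids), n_qtl)]
    marker <- vapply(chosen, function(b) {
      cand <- blocks$marker[blocks$block_id == b]
      if (length(cand) == 1) cand else sample(cand, 1)
    }, character(1))
  })
  data.frame(block_id = chosen, marker = marker)
}

#' Draw QTL effect sizes
#'
#' Effects are iid draws from a Beta(2, 6) distribution (mean 0.25, support
#' (0, 1)); no sign flip or marker-variance standardisation is applied, so
#' every QTL increases the trait through its `+1` allele.
#'
#' @param n_qtl number of effects.
#' @param seed integer seed.
#' @return numeric vector of effects in (0, 1).
#' @export
draw_effects <- function(n_qtl, seed = 1) {
  stopifnot(n_qtl >= 1)
  withr::with_seed(substream_seed(seed, "effects"),
                   stats::rbeta(n_qtl, 2, 6))
}

#' Split QTL into major and minor effect classes
#'
#' A QTL is major when its effect exceeds 75 % of the largest effect in the
#' simulated set; the maximum itself is therefore always major.
#'
#' @param effects numeric vector of effects.
#' @return logical vector, `TRUE` for major QTL.
#' @export
classify_major_minor <- function(effects) {
  stopifnot(length(effects) >= 1)
  effects > 0.75 * max(effects)
}

#' Build a complete QTL set
#'
#' Convenience wrapper combining [select_qtl()], [draw_effects()] and
#' [classify_major_minor()] under one seed.
#'
#' @inheritParams select_qtl
#' @return data frame with columns `marker`, `block_id`, `effect`,
#'   `is_major`.
#' @export
make_qtl_set <- function(blocks, n_qtl, seed = 1) {
  q <- select_qtl(blocks, n_qtl, seed = seed)
  q$effect <- draw_effects(n_qtl, seed = seed)
  q$is_major <- classify_major_minor(q$effect)
  q[, c("marker", "block_id", "effect", "is_major")]
}

#' Simulate a phenotype with controlled heritability
#'
#' The genetic value of line `i` is `g_i = sum_k x_ik * effect_k` over the
#' QTL markers, using the `{-1, +1}` (or imputed real-valued) scores
#' directly.  A missing QTL score is replaced by that marker's observed mean
#' (the centred-population expectation), so phenotypes remain defined when
#' simulating on a not-imputed matrix.  The residual variance is set from
#' the realised genetic variance, `sigma2_e = (1 - h2) * sigma2_g / h2` with
#' `sigma2_g = var(g)`, so the parameter-level heritability is exactly `h2`;
#' at `h2 = 1` the residual is identically zero.
#'
#' @param m marker matrix the QTL are read from.
#' @param qtl QTL set (see [make_qtl_set()]); its markers must be columns of
#'   `m`.
#' @param h2 heritability in (0, 1].
#' @param seed integer seed for the residual draw (ignored when
#'   `residual_z` is given).
#' @param residual_z optional standard-normal vector (length = lines) reused
#'   across heritabilities / matrices for paired designs.
#' @return list with elements `y` (named phenotype vector), `g` (genetic
#'   values), `qtl`, `h2`, `sigma2_g`, `sigma2_e`.
#' @export
simulate_phenotype <- function(m, qtl, h2, seed = 1, residual_z = NULL) {
  if (h2 <= 0 || h2 > 1) fail("h2 must be in (0, 1]")
  if (!all(qtl$marker %in% colnames(m)))
    fail("QTL markers absent from matrix")
  X <- m[, qtl$marker, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  g <- drop(X %*% qtl$effect)
  s2g <- stats::var(g)
  if (!is.finite(s2g) || s2g == 0) fail("zero realized genetic variance")
  s2e <- (1 - h2) * s2g / h2
  if (is.null(residual_z)) {
    residual_z <- withr::with_seed(substream_seed(seed, "residual"),
                                   stats::rnorm(nrow(m)))
  }
  stopifnot(length(residual_z) == nrow(m))
  y <- g + sqrt(s2e) * residual_z
  names(y) <- rownames(m)
  list(y = y, g = g, qtl = qtl, h2 = h2, sigma2_g = s2g, sigma2_e = s2e)
}

#' Simulate QTL and phenotype in one step
#'
#' Chooses a QTL set on `blocks` and simulates a phenotype on `m`.  If the
#' realised genetic variance is zero (all chosen QTL monomorphic on `m`),
#' the QTL set is resampled once with a derived seed before giving up.
#'
#' @inheritParams simulate_phenotype
#' @inheritParams select_qtl
#' @return as [simulate_phenotype()].
#' @export
simulate_qtl_phenotype <- function(m, blocks, n_qtl, h2, seed = 1,
                                   residual_z = NULL) {
  qtl <- make_qtl_set(blocks, n_qtl, seed = seed)
  tryCatch(simulate_phenotype(m, qtl, h2, seed = seed,
                              residual_z = residual_z),
           error = function(e) {
             if (!grepl("zero realized genetic variance", conditionMessage(e)))
               stop(e)
             qtl2 <- make_qtl_set(blocks, n_qtl,
                                  seed = substream_seed(seed, "resample"))
             simulate_phenotype(m, qtl2, h2, seed = seed,
                                residual_z = residual_z)
           })
}
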