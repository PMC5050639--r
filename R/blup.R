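#' Fit an alpha-lattice trial model
#'
#' REML fit (via \pkg{lme4}) of the plot-level model
#' `y_ijk = mu + a_i + beta_j + delta_k(j) + eps_ijk` with fixed
#' replications `beta_j`, random genotypes `a_i ~ N(0, sigma2_g)`, random
#' incomplete blocks within replication `delta_k(j) ~ N(0, sigma2_B)` and
#' residuals `eps ~ N(0, sigma2_e)`; returns the genotype BLUPs used as
#' adjusted phenotypes for GWAS on real traits.
#'
#' @param trial data frame with columns `genotype`, `rep`, `block`,
#'   `phenotype` (block labels nested in rep, as produced by
#'   [generate_trial()]; crossed labels are nested automatically).
#' @return object of class `trial_fit`: list with `blup` (named vector, one
#'   per genotype), `sigma2_g`, `sigma2_B`, `sigma2_e`, `rep_effects`,
#'   `converged`, and the underlying `model`.
#' @export
fit_alpha_lattice <- function(trial) {
  need <- c("genotype", "rep", "block", "phenotype")
  if (!all(need %in% names(trial))) fail("trial needs columns %s",
                                         paste(need, collapse = ", "))
  if (length(unique(trial$rep)) < 2) fail("need at least 2 replications")
  d <- trial
  d$genotype <- factor(d$genotype)
  d$rep <- factor(d$rep)
  d$blk <- factor(paste(d$rep, d$block, sep = ":"))   # ensure nesting
  fit <- withCallingHandlers(
    lme4::lmer(phenotype ~ rep + (1 | genotype) + (1 | blk), data = d,
               REML = TRUE),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(g) vc$vcov[match(g, vc$grp)]
  re <- lme4::ranef(fit)$genotype
  blup <- stats::setNames(re[, 1], rownames(re))
  conv <- is.null(fit@optinfo$conv$lme4$code)
  structure(list(blup = blup,
                 sigma2_g = getvc("genotype"),
                 sigma2_B = getvc("blk"),
                 sigma2_e = getvc("Residual"),
                 rep_effects = lme4::fixef(fit),
                 n_rep = length(unique(d$rep)),
                 converged = conv,
                 model = fit),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat(sprintf("<trial_fit> %d genotypes, %d reps | sigma2_g=%.4g sigma2_B=%.4g sigma2_e=%.4g\n",
              length(x$blup), x$n_rep, x$sigma2_g, x$sigma2_B, x$sigma2_e))
  invisible(x)
}

#' Broad-sense heritability from a trial fit
#'
#' Entry-mean basis (default): `h2 = sigma2_g / (sigma2_g + sigma2_e /
#' n_rep)`, the repeatability of genotype means over `n_rep` replications.
#' The plot basis `sigma2_g / (sigma2_g + sigma2_B + sigma2_e)` is
#' available as an alternative.
#'
#' @param fit a `trial_fit`.
#' @param n_rep number of replications (default: taken from the fit).
#' @param basis `"entry-mean"` or `"plot"`.
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_h2 <- function(fit, n_rep = fit$n_rep,
                           basis = c("entry-mean", "plot")) {
  basis <- match.arg(basis)
  denom <- switch(basis,
    "entry-mean" = fit$sigma2_g + fit$sigma2_e / n_rep,
    "plot" = fit$sigma2_g + fit$sigma2_B + fit$sigma2_e)
  if (denom <= 0) fail("zero total variance")
  fit$sigma2_g / denom
}
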