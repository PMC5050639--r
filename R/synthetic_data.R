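#' Specification of a synthetic inbred marker panel
#'
#' Describes the geometry and population structure of a simulated biallelic
#' inbred panel.  Lines are built as recombinant mosaics of founder
#' haplotypes along a cM map, which creates block-wise linkage
#' disequilibrium, and subpopulation structure arises from disjoint founder
#' pools.  Inter-marker spacing is drawn from a two-component mixture: mostly
#' short exponential gaps plus occasional long gaps (at least
#' `gap_large_min` cM), which delimit the recombination-bin labels carried by
#' the map and reproduce the clustered marker spacing of real SNP-array and
#' GBS maps.
#'
#' @param n_lines number of inbred lines.
#' @param chromosomes data frame with columns `label`, `n_markers` and
#'   `length_cM` (target expected length; realised lengths vary around it).
#' @param n_founders founder haplotypes per subpopulation.
#' @param n_subpops number of subpopulations; lines are split according to
#'   `subpop_sizes` (default: as equal as possible).
#' @param subpop_sizes optional integer vector of lines per subpopulation.
#' @param min_maf minimum minor allele frequency every marker must reach;
#'   violating markers have their founder alleles redrawn a bounded number of
#'   times and are dropped if still violating.
#' @param gap_frac_large probability that an inter-marker gap comes from the
#'   long-gap component.
#' @param gap_large_min minimum length (cM) of a long gap; long gaps are
#'   `gap_large_min + Exp(gap_large_mean)`.
#' @param gap_large_mean mean of the exponential excess of long gaps (cM).
#' @param seed integer seed; all output is deterministic given the spec.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_lines,
                       chromosomes,
                       n_founders = 8,
                       n_subpops = 1,
                       subpop_sizes = NULL,
                       min_maf = 0.1,
                       gap_frac_large = 0.12,
                       gap_large_min = 1.5,
                       gap_large_mean = 3.5,
                       seed = 1) {
  stopifnot(is.data.frame(chromosomes),
            all(c("label", "n_markers", "length_cM") %in% names(chromosomes)),
            n_lines >= 1, n_founders >= 1, n_subpops >= 1,
            min_maf >= 0, min_maf < 0.5,
            all(chromosomes$n_markers >= 1), all(chromosomes$length_cM > 0),
            gap_frac_large >= 0, gap_frac_large < 1)
  if (is.null(subpop_sizes)) {
    base <- n_lines %/% n_subpops
    subpop_sizes <- rep(base, n_subpops)
    extra <- n_lines - sum(subpop_sizes)
    if (extra > 0) subpop_sizes[seq_len(extra)] <- subpop_sizes[seq_len(extra)] + 1
  }
  stopifnot(sum(subpop_sizes) == n_lines, length(subpop_sizes) == n_subpops)
  structure(list(n_lines = n_lines, chromosomes = chromosomes,
                 n_founders = n_founders, n_subpops = n_subpops,
                 subpop_sizes = subpop_sizes, min_maf = min_maf,
                 gap_frac_large = gap_frac_large,
                 gap_large_min = gap_large_min,
                 gap_large_mean = gap_large_mean, seed = seed),
            class = "panel_spec")
}

#' Barley-like SNP-array panel specification
#'
#' Preset emulating a complete barley SNP-array panel: 122 inbred lines,
#' 1,096 markers on 7 chromosomes with array-like marker counts and map
#' lengths, one population, MAF floor 0.10.
#'
#' @param seed integer seed.
#' @param markers_per_chrom optionally scale the per-chromosome marker
#'   counts (default: the array-like counts summing to 1,096).
#' @param n_lines number of lines.
#' @return a [panel_spec()].
#' @export
barley_panel_spec <- function(seed = 1,
                              markers_per_chrom = c(125, 187, 178, 131, 201, 147, 127),
                              n_lines = 122) {
  lengths <- c(139.78, 150.27, 170.88, 121.65, 194.03, 129.38, 166.56)
  k <- markers_per_chrom / c(125, 187, 178, 131, 201, 147, 127)
  panel_spec(n_lines = n_lines,
             chromosomes = data.frame(label = paste0("chr", 1:7),
                                      n_markers = markers_per_chrom,
                                      length_cM = lengths * k),
             n_founders = 8, n_subpops = 1, min_maf = 0.1, seed = seed)
}

#' Wheat-like GBS panel specification
#'
#' Preset emulating a GBS wheat panel: 384 inbred lines drawn from three
#' breeding origins (186 / 55 / 143), 21 chromosomes, MAF floor 0.10.  The
#' marker count is a free scale parameter because full GBS marker densities
#' (thousands per genome) are rarely needed to exercise the pipeline.
#'
#' @param markers_per_chrom markers on each of the 21 chromosomes (recycled).
#' @param seed integer seed.
#' @param n_lines number of lines.
#' @return a [panel_spec()].
#' @export
wheat_panel_spec <- function(markers_per_chrom = 40, seed = 1, n_lines = 384) {
  labs <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  nm <- rep_len(markers_per_chrom, 21)
  sizes <- round(n_lines * c(186, 55, 143) / 384)
  sizes[1] <- n_lines - sum(sizes[-1])
  panel_spec(n_lines = n_lines,
             chromosomes = data.frame(label = labs, n_markers = nm,
                                      length_cM = pmax(5, nm * 1.0)),
             n_founders = 6, n_subpops = 3, subpop_sizes = sizes,
             min_maf = 0.1, seed = seed)
}

#' Generate a synthetic inbred marker panel
#'
#' Founder haplotypes are iid `{-1, +1}` per marker within each
#' subpopulation's pool; each line is a recombinant mosaic of its pool's
#' founders with crossovers following a Haldane process (Poisson count with
#' expectation length/100, uniform positions, no interference).  Markers
#' whose panel-wide MAF falls below `spec$min_maf` have their founder alleles
#' redrawn (the mosaic paths are kept) for a bounded number of rounds and are
#' dropped if still violating; an error results if no marker can be kept.
#'
#' Bin labels on the returned map index the maximal runs of markers
#' separated by gaps smaller than `spec$gap_large_min` (numbered within each
#' chromosome).
#'
#' @param spec a [panel_spec()].
#' @param max_resample rounds of founder-allele redrawing for markers below
#'   the MAF floor.
#' @return list with elements `geno` (lines x markers `{-1, +1}` matrix),
#'   `map` (data frame `marker`, `chrom`, `pos_cM`, `bin`) and `subpop`
#'   (factor of subpopulation labels per line).
#' @export
generate_panel <- function(spec, max_resample = 50) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(substream_seed(spec$seed, "panel"), {
    chroms <- spec$chromosomes
    maps <- vector("list", nrow(chroms))
    genos <- vector("list", nrow(chroms))
    subpop <- factor(rep(paste0("pop", seq_len(spec$n_subpops)),
                         spec$subpop_sizes))
    for (ci in seq_len(nrow(chroms))) {
      m <- chroms$n_markers[ci]
      pos <- draw_positions(m, chroms$length_cM[ci], spec)
      paths <- mosaic_paths(spec, pos, subpop)
      founders <- draw_founders(spec, m)
      geno <- founder_scores(founders, paths, subpop)
      ## redraw founder alleles at markers below the MAF floor
      for (r in seq_len(max_resample)) {
        low <- which(marker_maf(nameless(geno)) < spec$min_maf)
        if (!length(low)) break
        for (sp in seq_len(spec$n_subpops))
          founders[[sp]][, low] <- sample(c(-1, 1),
                                          spec$n_founders * length(low),
                                          replace = TRUE)
        geno <- founder_scores(founders, paths, subpop)
      }
      low <- which(marker_maf(nameless(geno)) < spec$min_maf)
      if (length(low)) {
        warning(sprintf("dropping %d markers below the MAF floor on %s",
                        length(low), chroms$label[ci]), call. = FALSE)
        geno <- geno[, -low, drop = FALSE]
        pos <- pos[-low]
      }
      maps[[ci]] <- data.frame(chrom = rep(chroms$label[ci], length(pos)),
                               pos_cM = pos)
      genos[[ci]] <- geno
    }
    map <- do.call(rbind, maps)
    if (!nrow(map)) fail("infeasible panel spec: no marker reaches min_maf")
    geno <- do.call(cbind, genos)
    ids <- sprintf("M%04d", seq_len(nrow(map)))
    map$marker <- ids
    rownames(geno) <- sprintf("L%03d", seq_len(spec$n_lines))
    colnames(geno) <- ids
    map$bin <- gap_bins(map, spec$gap_large_min)
    map <- map[, c("marker", "chrom", "pos_cM", "bin")]
    rownames(map) <- NULL
    list(geno = geno, map = map, subpop = subpop)
  })
}

nameless <- function(g) {
  rownames(g) <- sprintf("l%d", seq_len(nrow(g)))
  colnames(g) <- sprintf("m%d", seq_len(ncol(g)))
  g
}

## Inter-marker gaps: mixture of short exponentials and long (>= gap_large_min)
## gaps.  The short-gap mean is set so the expected chromosome length matches
## the spec; if the target mean spacing is too tight for the long component,
## the map degenerates to pure exponential spacing (dense GBS-like maps).
draw_positions <- function(m, length_cM, spec) {
  if (m == 1) return(0)
  mu <- length_cM / (m - 1)
  f <- spec$gap_frac_large
  large_mean <- spec$gap_large_min + spec$gap_large_mean
  small_mean <- (mu - f * large_mean) / (1 - f)
  if (small_mean <= 0.05 * mu || f == 0) {
    gaps <- stats::rexp(m - 1, 1 / mu)
  } else {
    big <- stats::runif(m - 1) < f
    gaps <- stats::rexp(m - 1, 1 / small_mean)
    gaps[big] <- spec$gap_large_min + stats::rexp(sum(big), 1 / spec$gap_large_mean)
  }
  cumsum(c(0, gaps))
}

## founder index path per line along one chromosome (Haldane crossovers)
mosaic_paths <- function(spec, pos, subpop) {
  n <- spec$n_lines
  m <- length(pos)
  len <- max(pos)
  paths <- matrix(1L, n, m)
  for (i in seq_len(n)) {
    nco <- stats::rpois(1, len / 100)
    cuts <- sort(stats::runif(nco, 0, len))
    seg <- findInterval(pos, cuts) + 1L          # segment index per marker
    founders <- sample.int(spec$n_founders, nco + 1L, replace = TRUE)
    paths[i, ] <- founders[seg]
  }
  paths
}

draw_founders <- function(spec, m) {
  lapply(seq_len(spec$n_subpops), function(sp)
    matrix(sample(c(-1, 1), spec$n_founders * m, replace = TRUE),
           spec$n_founders, m))
}

founder_scores <- function(founders, paths, subpop) {
  n <- nrow(paths); m <- ncol(paths)
  geno <- matrix(0, n, m)
  sp_idx <- as.integer(subpop)
  for (i in seq_len(n)) {
    f <- founders[[sp_idx[i]]]
    geno[i, ] <- f[cbind(paths[i, ], seq_len(m))]
  }
  geno
}

## bin label per marker: runs delimited by gaps >= min_gap, per chromosome
gap_bins <- function(map, min_gap) {
  bins <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    o <- i[order(map$pos_cM[i])]
    gaps <- diff(map$pos_cM[o])
    bins[o] <- cumsum(c(1L, as.integer(gaps >= min_gap)))
  }
  bins
}

#' Mask genotype calls at random
#'
#' Adds missing values to a marker matrix to emulate GBS-style incomplete
#' coverage.  Per-marker missing rates are drawn from a Beta distribution
#' with mean `rate` and concentration `dispersion` (so GBS-like marker-biased
#' missingness is available), with `dispersion = Inf` giving the uniform rate
#' used when masking a complete array.  Within each marker, exactly
#' `round(rate_j * n_observed)` currently observed entries are masked, so the
#' realised overall fraction is within 1/(2 n_lines) of the target per
#' marker.  Only observed entries are ever masked; already-missing entries
#' are untouched.
#'
#' @param m marker matrix (complete, or with prior missingness).
#' @param rate target overall missing fraction in `[0, 1)`.
#' @param dispersion Beta concentration of per-marker rates (`Inf` =
#'   identical rate for every marker).
#' @param seed integer seed.
#' @return the masked matrix, with attribute `"masked"`: a logical
#'   lines x markers matrix flagging the entries masked by this call (the
#'   ledger used by [imputation_accuracy()]).
#' @export
apply_missingness <- function(m, rate, dispersion = Inf, seed = 1) {
  as_marker_matrix(m)
  if (rate < 0 || rate >= 1) fail("missing rate must be in [0, 1)")
  out <- m
  mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  if (rate > 0) {
    withr::with_seed(substream_seed(seed, "mask"), {
      rates <- if (is.infinite(dispersion)) rep(rate, ncol(m))
               else stats::rbeta(ncol(m), rate * dispersion,
                                 (1 - rate) * dispersion)
      for (j in seq_len(ncol(m))) {
        obs <- which(!is.na(m[, j]))
        k <- round(rates[j] * length(obs))
        if (k > 0) {
          hit <- obs[sample.int(length(obs), k)]
          out[hit, j] <- NA
          mask[hit, j] <- TRUE
        }
      }
    })
  }
  attr(out, "masked") <- mask
  out
}

#' Specification of an alpha-lattice field trial
#'
#' @param n_geno number of genotypes (one plot per genotype per replication).
#' @param n_rep number of complete replications.
#' @param n_blocks_per_rep incomplete blocks per replication; genotypes are
#'   randomised into blocks of (near-)equal size within each replication.
#' @param sigma2_g,sigma2_B,sigma2_e genotype, block-within-rep and residual
#'   variance components (>= 0).
#' @param mu overall mean.
#' @param rep_effects fixed replication effects (length `n_rep`; default 0).
#' @param seed integer seed.
#' @return a `trial_spec` list.
#' @export
trial_spec <- function(n_geno, n_rep, n_blocks_per_rep,
                       sigma2_g, sigma2_B = 0, sigma2_e = 0,
                       mu = 0, rep_effects = NULL, seed = 1) {
  stopifnot(n_geno >= 2, n_rep >= 1, n_blocks_per_rep >= 1,
            n_blocks_per_rep <= n_geno,
            sigma2_g >= 0, sigma2_B >= 0, sigma2_e >= 0)
  if (is.null(rep_effects)) rep_effects <- rep(0, n_rep)
  stopifnot(length(rep_effects) == n_rep)
  structure(list(n_geno = n_geno, n_rep = n_rep,
                 n_blocks_per_rep = n_blocks_per_rep,
                 sigma2_g = sigma2_g, sigma2_B = sigma2_B,
                 sigma2_e = sigma2_e, mu = mu,
                 rep_effects = rep_effects, seed = seed),
            class = "trial_spec")
}

#' Simulate an alpha-lattice trial
#'
#' Generates plot phenotypes `y = mu + a_i + beta_j + delta_k(j) + eps_ijk`
#' with random genotype effects `a ~ N(0, sigma2_g)`, random incomplete-block
#' effects `delta ~ N(0, sigma2_B)` nested in fixed replications, and
#' residuals `eps ~ N(0, sigma2_e)`.
#'
#' @param spec a [trial_spec()].
#' @return data frame with columns `genotype`, `rep`, `block`, `phenotype`
#'   (factors `genotype`, `rep`, `block`; `block` labels are nested in rep),
#'   and attribute `"effects"` holding the true genotype effects `a`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  withr::with_seed(substream_seed(spec$seed, "trial"), {
    g_ids <- sprintf("G%04d", seq_len(spec$n_geno))
    a <- stats::rnorm(spec$n_geno, 0, sqrt(spec$sigma2_g))
    names(a) <- g_ids
    block_of <- rep(seq_len(spec$n_blocks_per_rep),
                    length.out = spec$n_geno)   # balanced-as-possible sizes
    rows <- lapply(seq_len(spec$n_rep), function(j) {
      ord <- sample.int(spec$n_geno)
      delta <- stats::rnorm(spec$n_blocks_per_rep, 0, sqrt(spec$sigma2_B))
      data.frame(genotype = g_ids[ord], rep = sprintf("R%02d", j),
                 block = sprintf("R%02d.B%02d", j, block_of),
                 phenotype = spec$mu + a[ord] + spec$rep_effects[j] +
                   delta[block_of] +
                   stats::rnorm(spec$n_geno, 0, sqrt(spec$sigma2_e)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$genotype <- factor(out$genotype, levels = g_ids)
    out$rep <- factor(out$rep)
    out$block <- factor(out$block)
    attr(out, "effects") <- a
    out
  })
}
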