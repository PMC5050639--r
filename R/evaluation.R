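#' Bin-level confusion counts for one GWAS scan
#'
#' A bin (LD block) is "significant" when at least one of its markers has
#' `p < cutoff`.  True positives are bins holding a QTL of the requested
#' class with at least one significant marker; false negatives are the
#' remaining QTL bins of that class.  False positives and true negatives
#' are counted over the bins holding no QTL of any class (shared negatives
#' across the major/minor analyses, so a detected true QTL of the other
#' class is never booked as a false positive).  Bins with no scored marker
#' can never be significant and are counted once, in TN or FN.
#'
#' @param result a `gwas_result` (or data frame with `marker`, `p`).
#' @param cutoff per-test significance cutoff (see [make_threshold()]).
#' @param blocks block partition covering every scored marker.
#' @param truth QTL set (see [make_qtl_set()]); its markers must be in
#'   `blocks`.
#' @param qtl_class `"all"`, `"major"` or `"minor"`.
#' @return one-row data frame: `qtl_class`, `TP`, `FP`, `TN`, `FN`, `PO`,
#'   `FPR` (`PO` is `NA` when the class is empty).
#' @export
confusion_counts <- function(result, cutoff, blocks, truth,
                             qtl_class = c("all", "major", "minor")) {
  qtl_class <- match.arg(qtl_class)
  if (inherits(cutoff, "threshold_spec")) cutoff <- cutoff$cutoff
  if (!all(result$marker %in% blocks$marker))
    fail("scored markers missing from the block partition")
  if (!all(truth$marker %in% blocks$marker))
    fail("QTL markers missing from the block partition")
  sig_markers <- result$marker[!is.na(result$p) & result$p < cutoff]
  sig_blocks <- unique(blocks$block_id[match(sig_markers, blocks$marker)])
  all_blocks <- unique(blocks$block_id)
  qtl_blocks_all <- unique(blocks$block_id[match(truth$marker, blocks$marker)])
  class_markers <- switch(qtl_class,
    all = truth$marker,
    major = truth$marker[truth$is_major],
    minor = truth$marker[!truth$is_major])
  class_blocks <- unique(blocks$block_id[match(class_markers, blocks$marker)])
  neg_blocks <- setdiff(all_blocks, qtl_blocks_all)
  TP <- length(intersect(class_blocks, sig_blocks))
  FN <- length(class_blocks) - TP
  FP <- length(intersect(neg_blocks, sig_blocks))
  TN <- length(neg_blocks) - FP
  data.frame(qtl_class = qtl_class, TP = TP, FP = FP, TN = TN, FN = FN,
             PO = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
             FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_)
}

## default threshold levels: corrected rules at 0.05, liberal at 0.01
default_alphas <- function() c(bonferroni = 0.05, liji = 0.05, liberal = 0.01)

## build the four analysis matrices from a matrix with missing entries
build_matrices <- function(masked, mvn_args = list(), rf_args = list(),
                           rf_seed = 1) {
  attr(masked, "masked") <- NULL
  list(
    NImp = masked,
    Mean = imp_scores(impute_mean(masked)),
    `MVN-EM` = imp_scores(do.call(impute_mvn_em, c(list(masked), mvn_args))),
    RF = imp_scores(do.call(impute_rf,
                            c(list(masked), rf_args, list(seed = rf_seed)))))
}

## GWAS of one phenotype against the four matrices, scored at all
## threshold/class combinations -> MetricRecord rows
score_against_matrices <- function(sim, mats, As, Meffs, blocks, Q,
                                   thresholds, alphas, sim_tag, h2, n_qtl,
                                   missing_rate, iter) {
  rows <- list()
  for (g in names(mats)) {
    res <- run_gwas(sim$y, mats[[g]], A = As[[g]], Q = Q)
    M <- ncol(mats[[g]])
    for (th in thresholds) {
      cut <- make_threshold(th, alpha = unname(alphas[th]), M = M,
                            Meff = Meffs[[g]])
      for (cl in c("all", "major", "minor")) {
        cc <- confusion_counts(res, cut, blocks, sim$qtl, cl)
        rows[[length(rows) + 1]] <-
          cbind(data.frame(sim_matrix = sim_tag, gwas_matrix = g, h2 = h2,
                           n_qtl = n_qtl, threshold = th,
                           missing_rate = missing_rate, iteration = iter),
                cc)
      }
    }
  }
  do.call(rbind, rows)
}

#' Golden-standard experiment: simulate on the complete matrix
#'
#' Per iteration: a phenotype is simulated on the complete panel
#' (`Y_sim-NoNA`), missing data are created at random at `missing_rate`,
#' the four analysis matrices (`NImp`, `Mean`, `MVN-EM`, `RF`) are built,
#' and the same phenotype is scanned against each of them; detections are
#' scored at the block level against the shared truth.  Within an
#' iteration the QTL set, effects and the standard-normal residual draw are
#' shared across every heritability and analysis matrix (paired design).
#'
#' @param panel complete marker matrix.
#' @param blocks block partition of the panel's markers.
#' @param h2 heritabilities to simulate.
#' @param n_qtl numbers of QTL to simulate.
#' @param thresholds subset of `c("bonferroni", "liji", "liberal")`.
#' @param n_iter iterations.
#' @param missing_rate masking rate per iteration.
#' @param seed master seed; all stage seeds are derived sub-streams.
#' @param subpop optional subpopulation factor (builds `Q`).
#' @param mvn_args,rf_args argument lists passed on to [impute_mvn_em()] /
#'   [impute_rf()] (e.g. fewer trees for large designs).
#' @param alphas named threshold levels (default: 0.05 for the corrected
#'   rules, 0.01 liberal).
#' @param dispersion per-marker missingness dispersion (default uniform).
#' @return MetricRecord data frame: one row per (gwas matrix, h2, n_qtl,
#'   threshold, QTL class, iteration) with confusion counts, `PO` and
#'   `FPR`.
#' @export
run_golden_standard <- function(panel, blocks, h2 = c(0.2, 0.4, 0.6, 0.7, 0.9),
                                n_qtl = 25,
                                thresholds = c("bonferroni", "liji", "liberal"),
                                n_iter = 10, missing_rate = 0.5, seed = 1,
                                subpop = NULL, mvn_args = list(),
                                rf_args = list(), alphas = default_alphas(),
                                dispersion = Inf) {
  as_marker_matrix(panel)
  if (anyNA(panel)) fail("golden standard needs a complete panel")
  Q <- make_Q(subpop, n = nrow(panel))
  records <- list()
  for (it in seq_len(n_iter)) {
    masked <- apply_missingness(panel, missing_rate, dispersion = dispersion,
                                seed = substream_seed(seed, "mask", it))
    mats <- build_matrices(masked, mvn_args, rf_args,
                           rf_seed = substream_seed(seed, "rfimp", it))
    As <- lapply(mats, realized_relationship)
    Meffs <- if ("liji" %in% thresholds)
      lapply(mats, effective_num_markers_liji) else lapply(mats, function(x) NULL)
    for (nq in n_qtl) {
      qtl <- make_qtl_set(blocks, nq, seed = substream_seed(seed, "qtl", it, nq))
      z <- withr::with_seed(substream_seed(seed, "residual", it, nq),
                            stats::rnorm(nrow(panel)))
      for (h in h2) {
        sim <- simulate_phenotype(panel, qtl, h, residual_z = z)
        records[[length(records) + 1]] <-
          score_against_matrices(sim, mats, As, Meffs, blocks, Q, thresholds,
                                 alphas, "NoNA", h, nq, missing_rate, it)
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Ascertainment-bias experiment: simulate on each analysis matrix
#'
#' Per iteration: missing data are created once, the four analysis matrices
#' are built, and a phenotype is simulated separately on each of them
#' (`Y_sim-NImp`, `Y_sim-Mean`, `Y_sim-MVN-EM`, `Y_sim-RF`) with shared QTL
#' positions, effects and residual draw; every phenotype is then scanned
#' against every matrix (a 4 x 4 design), so the diagonal cells recover QTL
#' on the matrix they were simulated on.
#'
#' @inheritParams run_golden_standard
#' @return MetricRecord data frame with `sim_matrix` spanning the four tags.
#' @export
run_ascertainment <- function(panel, blocks, h2 = c(0.2, 0.4, 0.6, 0.7, 0.9),
                              n_qtl = 25,
                              thresholds = c("bonferroni", "liji", "liberal"),
                              n_iter = 10, missing_rate = 0.5, seed = 1,
                              subpop = NULL, mvn_args = list(),
                              rf_args = list(), alphas = default_alphas(),
                              dispersion = Inf) {
  as_marker_matrix(panel)
  if (anyNA(panel)) fail("the ascertainment design masks a complete panel")
  Q <- make_Q(subpop, n = nrow(panel))
  records <- list()
  for (it in seq_len(n_iter)) {
    masked <- apply_missingness(panel, missing_rate, dispersion = dispersion,
                                seed = substream_seed(seed, "mask", it))
    mats <- build_matrices(masked, mvn_args, rf_args,
                           rf_seed = substream_seed(seed, "rfimp", it))
    records[[length(records) + 1]] <-
      cross_design_records(mats, blocks, Q, h2, n_qtl, thresholds, alphas,
                           missing_rate, it, seed)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' GBS experiment: natively sparse panel, bins as blocks
#'
#' As [run_ascertainment()], but the panel arrives with its own missing
#' data (no extra masking) and the independence units are the
#' recombination bins of the map.
#'
#' @inheritParams run_golden_standard
#' @param panel marker matrix with native missingness.
#' @param map genetic map with bin labels for every marker.
#' @return MetricRecord data frame; `missing_rate` is tagged with the
#'   observed overall missing fraction of `panel`.
#' @export
run_gbs_experiment <- function(panel, map, h2 = c(0.2, 0.4, 0.6, 0.7, 0.9),
                               n_qtl = 25,
                               thresholds = c("bonferroni", "liji", "liberal"),
                               n_iter = 10, seed = 1, subpop = NULL,
                               mvn_args = list(), rf_args = list(),
                               alphas = default_alphas()) {
  as_marker_matrix(panel)
  blocks <- bins_as_blocks(as_genetic_map(map, markers = colnames(panel)))
  Q <- make_Q(subpop, n = nrow(panel))
  rate <- round(mean(is.na(panel)), 4)
  records <- list()
  for (it in seq_len(n_iter)) {
    mats <- build_matrices(panel, mvn_args, rf_args,
                           rf_seed = substream_seed(seed, "rfimp", it))
    records[[length(records) + 1]] <-
      cross_design_records(mats, blocks, Q, h2, n_qtl, thresholds, alphas,
                           rate, it, seed)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

## shared 4x4 (simulate x recover) inner loop of the ascertainment and GBS
## designs
cross_design_records <- function(mats, blocks, Q, h2, n_qtl, thresholds,
                                 alphas, missing_rate, it, seed) {
  As <- lapply(mats, realized_relationship)
  Meffs <- if ("liji" %in% thresholds)
    lapply(mats, effective_num_markers_liji) else lapply(mats, function(x) NULL)
  rows <- list()
  for (nq in n_qtl) {
    qtl <- make_qtl_set(blocks, nq, seed = substream_seed(seed, "qtl", it, nq))
    z <- withr::with_seed(substream_seed(seed, "residual", it, nq),
                          stats::rnorm(nrow(mats[[1]])))
    for (h in h2) {
      for (sim_tag in names(mats)) {
        sim <- simulate_phenotype(mats[[sim_tag]], qtl, h, residual_z = z)
        rows[[length(rows) + 1]] <-
          score_against_matrices(sim, mats, As, Meffs, blocks, Q, thresholds,
                                 alphas, sim_tag, h, nq, missing_rate, it)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise metric records
#'
#' Cell means of power and false-positive rate over iterations, with
#' Monte-Carlo standard errors and quartiles for box plots.  Cells are all
#' combinations of the design columns (everything except the iteration and
#' the counts).
#'
#' @param records MetricRecord data frame from a `run_*` function.
#' @return data frame with one row per cell: `n_iter`, `PO_mean`, `PO_se`,
#'   `FPR_mean`, `FPR_se`, `FPR_q25`, `FPR_q50`, `FPR_q75`, in a stable
#'   cell order independent of the record order.
#' @export
summarize_metrics <- function(records) {
  stopifnot(nrow(records) > 0)
  keys <- c("sim_matrix", "gwas_matrix", "h2", "n_qtl", "threshold",
            "missing_rate", "qtl_class")
  keys <- keys[keys %in% names(records)]
  cell <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(records)), cell)
  mc_se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  rows <- lapply(idx, function(i) {
    po <- records$PO[i]; fpr <- records$FPR[i]
    qs <- stats::quantile(fpr, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    cbind(records[i[1], keys, drop = FALSE],
          data.frame(n_iter = length(i),
                     PO_mean = mean(po, na.rm = TRUE), PO_se = mc_se(po[!is.na(po)]),
                     FPR_mean = mean(fpr, na.rm = TRUE), FPR_se = mc_se(fpr[!is.na(fpr)]),
                     FPR_q25 = qs[1], FPR_q50 = qs[2], FPR_q75 = qs[3]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(interaction(out[keys], drop = TRUE, lex.order = TRUE)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
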