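## Shared fixtures and independent oracles for the test suite.

## random raw {-1, 1} matrix with ids, optionally with missing entries
rand_raw_matrix <- function(n, m, seed = 1, miss = 0) {
  withr::with_seed(seed, {
    x <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m,
                dimnames = list(sprintf("L%03d", seq_len(n)),
                                sprintf("M%03d", seq_len(m))))
    if (miss > 0) x[sample(length(x), round(miss * length(x)))] <- NA
    x
  })
}

## small LD-structured panel used across modules
small_panel <- function(seed = 11, n_lines = 60, n_markers = 40,
                        length_cM = 60, n_founders = 6, n_chrom = 1) {
  spec <- panel_spec(
    n_lines = n_lines,
    chromosomes = data.frame(label = paste0("c", seq_len(n_chrom)),
                             n_markers = n_markers, length_cM = length_cM),
    n_founders = n_founders, seed = seed)
  generate_panel(spec)
}

## independent single-linkage oracle via stats::hclust on each chromosome
hclust_blocks <- function(map, min_gap = 1.5) {
  res <- integer(nrow(map))
  nxt <- 0L
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    if (length(i) == 1) { res[i] <- nxt + 1L; nxt <- nxt + 1L; next }
    hc <- stats::hclust(stats::dist(map$pos_cM[i]), method = "single")
    cl <- stats::cutree(hc, h = min_gap * (1 - 1e-9))
    res[i] <- nxt + cl
    nxt <- max(res[i])
  }
  data.frame(marker = map$marker, chrom = map$chrom, block_id = res)
}

## brute-force confusion oracle: enumerate bins one by one
brute_confusion <- function(p, markers, cutoff, blocks, truth, qtl_class) {
  sig <- markers[!is.na(p) & p < cutoff]
  cls <- switch(qtl_class, all = truth$marker,
                major = truth$marker[truth$is_major],
                minor = truth$marker[!truth$is_major])
  TP <- FP <- TN <- FN <- 0L
  for (b in unique(blocks$block_id)) {
    mb <- blocks$marker[blocks$block_id == b]
    has_sig <- any(mb %in% sig)
    has_any_qtl <- any(mb %in% truth$marker)
    has_cls_qtl <- any(mb %in% cls)
    if (has_cls_qtl) {
      if (has_sig) TP <- TP + 1L else FN <- FN + 1L
    } else if (!has_any_qtl) {
      if (has_sig) FP <- FP + 1L else TN <- TN + 1L
    }
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

## ---- expensive shared fixture: the scaled golden-standard run ------------
## Built once per test session on first use (several minutes); shared by the
## evaluation property tests and the acceptance checks.
.gs_cache <- new.env(parent = emptyenv())

gs_panel <- function() {
  if (is.null(.gs_cache$panel)) {
    spec <- barley_panel_spec(seed = 101, markers_per_chrom = rep(50, 7))
    .gs_cache$panel <- generate_panel(spec)
  }
  .gs_cache$panel
}

gs_table <- function() {
  if (is.null(.gs_cache$table)) {
    pan <- gs_panel()
    blocks <- single_linkage_blocks(pan$map)
    .gs_cache$table <- run_golden_standard(
      pan$geno, blocks,
      h2 = c(0.2, 0.4, 0.6, 0.7, 0.9), n_qtl = 25,
      thresholds = c("bonferroni", "liji", "liberal"),
      n_iter = 100, missing_rate = 0.5, seed = 2024,
      rf_args = list(n_trees = 50, n_predictors = 12, max_iter = 2))
  }
  .gs_cache$table
}
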