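test_that("null variance components behave on an identity kinship", {
  withr::with_seed(3, y <- stats::rnorm(500))
  vc <- estimate_null_varcomp(y, diag(500))
  expect_lt(abs(vc$sigma2_g + vc$sigma2_e - 1), 0.15)
  expect_lt(vc$sigma2_g, 0.01)          # flat likelihood resolves to residual
})

test_that("variance components recover the simulated heritability", {
  pan <- small_panel(seed = 57, n_lines = 100, n_markers = 140,
                     length_cM = 140, n_chrom = 2)
  A <- realized_relationship(pan$geno)
  blocks <- single_linkage_blocks(pan$map)
  h2hat <- vapply(1:60, function(s) {
    sim <- simulate_qtl_phenotype(pan$geno, blocks, 10, 0.7, seed = s)
    vc <- estimate_null_varcomp(sim$y, A)
    vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e)
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.7), 0.1)
})

test_that("kinship scale cancels: A and 2A give the same inference", {
  pan <- small_panel(seed = 59, n_markers = 60, length_cM = 70)
  A <- realized_relationship(pan$geno)
  blocks <- single_linkage_blocks(pan$map)
  sim <- simulate_qtl_phenotype(pan$geno, blocks, 8, 0.7, seed = 2)
  v1 <- estimate_null_varcomp(sim$y, A)
  v2 <- estimate_null_varcomp(sim$y, 2 * A)
  expect_equal(v1$sigma2_g / v2$sigma2_g, 2, tolerance = 1e-3)
  expect_equal(v1$sigma2_e, v2$sigma2_e, tolerance = 1e-3)
  r1 <- run_gwas(sim$y, pan$geno, A = A)
  r2 <- run_gwas(sim$y, pan$geno, A = 2 * A)
  expect_lt(max(abs(r1$p - r2$p), na.rm = TRUE), 1e-6)
})

test_that("with identity kinship the marker test is exactly the OLS t-test", {
  withr::with_seed(2, {
    m <- rand_raw_matrix(80, 20, seed = 2, miss = 0.1)
    y <- stats::rnorm(80)
  })
  names(y) <- rownames(m)
  A <- diag(80)
  vc <- estimate_null_varcomp(y, A)
  worst <- 0
  for (j in seq_len(ncol(m))) {
    st <- single_marker_test(y, m[, j], A, varcomp = vc)
    if (!is.na(st$skip)) next
    s <- which(!is.na(m[, j]))
    ols <- summary(stats::lm(y[s] ~ m[s, j]))$coefficients
    worst <- max(worst, abs(st$p - ols[2, 4]), abs(st$beta - ols[2, 1]))
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate markers get skip codes, not p-values", {
  pan <- small_panel(seed = 61, n_markers = 20)
  A <- realized_relationship(pan$geno)
  y <- stats::setNames(stats::rnorm(60), rownames(pan$geno))
  vc <- estimate_null_varcomp(y, A)

  x1 <- pan$geno[, 1]; x1[-1] <- NA           # observed on a single line
  st1 <- single_marker_test(y, x1, A, varcomp = vc)
  expect_equal(st1$skip, "too_few_lines")
  expect_true(is.na(st1$p))

  x2 <- rep(1, 60)                            # monomorphic
  st2 <- single_marker_test(y, x2, A, varcomp = vc)
  expect_equal(st2$skip, "monomorphic")
})

test_that("a single planted QTL of large effect attains the minimum p", {
  pan <- small_panel(seed = 67, n_lines = 100, n_markers = 120,
                     length_cM = 150, n_chrom = 2)
  qtl <- data.frame(marker = "M0060", block_id = 1L, effect = 1,
                    is_major = TRUE)
  sim <- simulate_phenotype(pan$geno, qtl, h2 = 0.9, seed = 3)
  res <- run_gwas(sim$y, pan$geno)
  expect_equal(res$marker[which.min(res$p)], "M0060")
})

test_that("inference is invariant to relabelling the lines", {
  pan <- small_panel(seed = 71, n_markers = 50)
  blocks <- single_linkage_blocks(pan$map)
  sim <- simulate_qtl_phenotype(pan$geno, blocks, 6, 0.6, seed = 4)
  A <- realized_relationship(pan$geno)
  r1 <- run_gwas(sim$y, pan$geno, A = A)
  withr::with_seed(5, perm <- sample(nrow(pan$geno)))
  r2 <- run_gwas(sim$y[perm], pan$geno[perm, ], A = A[perm, perm])
  # spectral decomposition order differs under permutation; agreement is to
  # the REML profile tolerance, far below any decision threshold
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("P3D and per-marker variance components agree on detections", {
  pan <- small_panel(seed = 73, n_lines = 90, n_markers = 100,
                     length_cM = 120, n_chrom = 2)
  blocks <- single_linkage_blocks(pan$map)
  sim <- simulate_qtl_phenotype(pan$geno, blocks, 10, 0.7, seed = 6)
  A <- realized_relationship(pan$geno)
  p3d <- run_gwas(sim$y, pan$geno, A = A)
  cutoff <- make_threshold("liji", M = 100,
                           Meff = effective_num_markers_liji(pan$geno))$cutoff
  # exact-EMMA flavour: variance components re-estimated per marker with the
  # marker included among the fixed effects
  p_full <- vapply(seq_len(ncol(pan$geno)), function(j) {
    x <- pan$geno[, j]
    vc_j <- estimate_null_varcomp(sim$y, A, Q = cbind(1, x))
    single_marker_test(sim$y, x, A, varcomp = vc_j)$p
  }, numeric(1))
  expect_equal(p3d$p < cutoff, p_full < cutoff)
})

test_that("null p-values are calibrated under a structured kinship", {
  spec <- panel_spec(n_lines = 150,
                     chromosomes = data.frame(label = paste0("c", 1:5),
                                              n_markers = 60, length_cM = 70),
                     n_founders = 8, seed = 11)
  pan <- generate_panel(spec)
  A <- realized_relationship(pan$geno)
  L <- chol(0.5 * A + 0.5 * diag(nrow(A)))
  ps <- unlist(lapply(1:20, function(r) {
    y <- withr::with_seed(1000 + r,
                          drop(crossprod(L, stats::rnorm(nrow(A)))))
    names(y) <- rownames(pan$geno)
    run_gwas(y, pan$geno, A = A)$p
  }))
  ps <- ps[!is.na(ps)]
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(mean(ps < 0.05) - 0.05), half + 0.01)  # LD widens the band
  expect_gt(qq_slope(ps), 0.9)
  expect_lt(qq_slope(ps), 1.1)
})

test_that("Li & Ji Meff matches closed-form eigen structures", {
  n <- 40
  withr::with_seed(6, raw <- matrix(stats::rnorm(n * 3), n, 3))
  Qm <- qr.Q(qr(cbind(1, raw)))[, 2:4]
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  # exact pairwise-0.5 empirical correlation by construction
  Y <- Qm %*% (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
  Y <- Y / max(abs(Y))
  dimnames(Y) <- list(sprintf("L%02d", 1:n), c("a", "b", "c"))
  expect_equal(effective_num_markers_liji(Y), 2, tolerance = 1e-8)

  Yo <- Qm / max(abs(Qm)); dimnames(Yo) <- dimnames(Y)
  expect_equal(effective_num_markers_liji(Yo), 3, tolerance = 1e-8)

  copies <- matrix(rep(c(-1, 1, 1, -1, 1, -1, -1, 1, 1, 1), 4), 10, 4,
                   dimnames = list(sprintf("L%d", 1:10), sprintf("M%d", 1:4)))
  expect_equal(effective_num_markers_liji(copies), 1)

  m0 <- rand_raw_matrix(30, 6, seed = 12)
  m1 <- cbind(m0, M007 = m0[, 1])
  expect_lt(abs(effective_num_markers_liji(m0) -
                  effective_num_markers_liji(m1)), 1e-6)

  zv <- m0; zv[, 2] <- 1
  expect_warning(effective_num_markers_liji(zv), "zero-variance")
})

test_that("threshold rules give the stated cutoffs", {
  expect_equal(make_threshold("bonferroni", alpha = 0.05, M = 1000)$cutoff,
               5e-5)
  expect_equal(make_threshold("liberal")$cutoff, 0.01)
  expect_equal(make_threshold("liji", alpha = 0.05, M = 200, Meff = 200)$cutoff,
               make_threshold("bonferroni", alpha = 0.05, M = 200)$cutoff)
  expect_error(make_threshold("liji", M = 10), "Meff")
  expect_error(make_threshold("bonferroni", alpha = 1.2, M = 10), "alpha")
})

test_that("scan output carries QQ and Manhattan exports", {
  pan <- small_panel(seed = 79, n_markers = 30)
  blocks <- single_linkage_blocks(pan$map)
  sim <- simulate_qtl_phenotype(pan$geno, blocks, 4, 0.6, seed = 7)
  res <- run_gwas(sim$y, pan$geno)
  expect_s3_class(res, "gwas_result")
  expect_true(all(res$n_used <= nrow(pan$geno)))
  qq <- qq_data(res)
  expect_equal(nrow(qq), sum(!is.na(res$p)))
  man <- manhattan_data(res, pan$map)
  expect_equal(man$pos_cM, pan$map$pos_cM[match(man$marker, pan$map$marker)])
  # identical inputs give bit-identical results
  expect_identical(run_gwas(sim$y, pan$geno), res)
})
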