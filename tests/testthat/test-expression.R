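test_that("TMM factors are 1 for identical samples and depth-scaled samples", {
  m <- toy_counts(50, 3, seed = 2)
  m[, 2] <- m[, 1]
  m[, 3] <- m[, 1]
  f <- tmm_norm_factors(as_count_tbl(m))
  expect_equal(f$tmm_factor, rep(1, 3))

  # pure depth change: M-values unchanged, factor stays 1
  m2 <- toy_counts(200, 3, seed = 3)
  m2[, 3] <- m2[, 1] * 2
  f2 <- tmm_norm_factors(as_count_tbl(m2))
  ref <- attr(f2, "reference_sample")
  expect_equal(prod(f2$tmm_factor)^(1 / 3), 1, tolerance = 1e-9)
  # scaling sample 1 of an identical pair leaves their relative factor at 1
  m3 <- cbind(m2[, 1], m2[, 1] * 2, m2[, 2])
  colnames(m3) <- c("a", "b", "c")
  f3 <- tmm_norm_factors(as_count_tbl(m3))
  expect_equal(f3$tmm_factor[1], f3$tmm_factor[2], tolerance = 1e-12)
})

test_that("TMM factors match the reference weighted-trimmed-mean implementation", {
  skip_if_not_installed("edgeR")
  m <- toy_counts(8, 3, seed = 5, lambda = 40)
  ours <- tmm_norm_factors(as_count_tbl(m))
  theirs <- unname(edgeR::calcNormFactors(m, method = "TMM"))
  expect_equal(ours$tmm_factor, theirs, tolerance = 1e-10)
})

test_that("all-zero samples raise a normalization error", {
  m <- toy_counts(10, 2)
  m[, 2] <- 0
  expect_error(tmm_norm_factors(as_count_tbl(m)),
               class = "pitchercomp_normalization_error")
})

test_that("low-count filter removes exactly the genes below the threshold", {
  m <- matrix(c(0, 0, 0,
                1, 0, 0,
                2, 2, 0,
                5, 5, 5), 4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  tbl <- as_count_tbl(m)
  expect_identical(suppress_logs(filter_low_counts(tbl, 1))$gene_id,
                   c("g2", "g3", "g4"))
  expect_identical(suppress_logs(filter_low_counts(tbl, 0)), tbl)
  expect_identical(suppress_logs(filter_low_counts(tbl, 5))$gene_id, c("g4"))
  expect_identical(suppress_logs(filter_low_counts(tbl, 4))$gene_id, c("g3", "g4"))
})

test_that("FPKM follows its unit definition and hand arithmetic", {
  m <- matrix(c(100, 0, 50), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  lengths <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            length_bp = c(1000, 500, 2000))
  # make the library exactly 1e6 by padding a dummy gene
  m <- rbind(m, dummy = 1e6 - sum(m))
  lengths <- dplyr::add_row(lengths, gene_id = "dummy", length_bp = 1000)
  out <- fpkm(as_count_tbl(m), lengths)
  expect_equal(out$s1[out$gene_id == "g1"], 100) # count 100 / 1 Mread / 1 kb
  expect_equal(out$s1[out$gene_id == "g2"], 0)
  expect_equal(out$s1[out$gene_id == "g3"], 25)

  # TMM factor 0.5 doubles FPKM (effective library halves)
  f <- tibble::tibble(sample_id = "s1", tmm_factor = 0.5)
  out2 <- fpkm(as_count_tbl(m), lengths, f)
  expect_equal(out2$s1, out$s1 * 2)

  expect_error(fpkm(as_count_tbl(m), lengths[1:2, ]),
               class = "pitchercomp_lookup_error")
})

test_that("FPKM is linear in counts at fixed factors and lengths", {
  m <- toy_counts(20, 3, seed = 8)
  lengths <- tibble::tibble(gene_id = rownames(m),
                            length_bp = seq(500, 500 + 19 * 100, by = 100))
  f <- tibble::tibble(sample_id = colnames(m), tmm_factor = c(0.9, 1, 1.1))
  base <- fpkm(as_count_tbl(m), lengths, f)
  # doubling all counts leaves FPKM unchanged (depth normalizes out);
  # doubling one gene's counts at fixed library size doubles its FPKM
  lib <- colSums(m)
  m2 <- m; m2[3, ] <- m[3, ] * 2
  eff <- colSums(m2)
  out2 <- fpkm(as_count_tbl(m2), lengths, f)
  rescale <- lib / eff
  expect_equal(unlist(out2[3, -1]) * rescale / rescale,
               unlist(out2[3, -1]))
  expect_equal(unname(unlist(out2[3, -1])),
               unname(unlist(base[3, -1]) * 2 * lib / eff))
})

test_that("condition means average replicates per tissue and condition", {
  samples <- dplyr::bind_rows(
    one_tissue_samples(2, 2, tissue = "lid"),
    one_tissue_samples(2, 2, tissue = "keel"))
  samples$sample_id <- sprintf("s%d", seq_len(nrow(samples)))
  m <- matrix(seq_len(16), 2, 8,
              dimnames = list(c("g1", "g2"), samples$sample_id))
  out <- condition_means(as_count_tbl(m), samples)
  expect_setequal(setdiff(names(out), "gene_id"),
                  c("lid.control", "lid.fed", "keel.control", "keel.fed"))
  expect_equal(out$lid.control, unname(rowMeans(m[, 1:2])))
  expect_equal(out$keel.fed, unname(rowMeans(m[, 7:8])))
})

test_that("high-CV selection honours eligibility, tie-breaks and exact size", {
  withr::with_seed(11, {
    vals <- matrix(runif(20 * 4, 2, 50), 20, 4)
  })
  rownames(vals) <- sprintf("g%02d", 1:20)
  colnames(vals) <- paste0("c", 1:4)
  vals[1, ] <- 30 # constant: CV 0
  vals[2, ] <- c(0.2, 0.4, 0.9, 0.6) # high CV but never above 1 FPKM: ineligible
  stats <- suppress_logs(select_high_cv_genes(as_count_tbl(vals),
                                              top_frac = 0.10, min_fpkm = 1))
  expect_equal(stats$cv[stats$gene_id == "g01"], 0)
  expect_false(stats$selected[stats$gene_id == "g01"])
  expect_false(stats$eligible[stats$gene_id == "g02"])
  expect_false(stats$selected[stats$gene_id == "g02"])
  # hand oracle: top ceiling(0.1 * 19) = 2 eligible genes by CV
  elig <- stats[stats$eligible, ]
  hand <- elig$gene_id[order(-elig$cv, elig$gene_id)][1:2]
  expect_setequal(stats$gene_id[stats$selected], hand)
  expect_equal(sum(stats$selected), ceiling(0.10 * sum(stats$eligible)))
})

test_that("z-scaling yields mean 0 / sd 1 rows, is idempotent, drops constants", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                2, 8, 14), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_warning(z <- zscale_rows(as_count_tbl(m)), "constant")
  expect_setequal(z$gene_id, c("g1", "g3"))
  zm <- as.matrix(z[-1])
  expect_true(all(abs(rowMeans(zm)) < 1e-10))
  expect_true(all(abs(apply(zm, 1, sd) - 1) < 1e-10))
  expect_equal(as.matrix(zscale_rows(z)[-1]), zm, tolerance = 1e-12)
})

test_that("PCA variance fractions behave and match a spectral oracle", {
  sim <- toy_counts(30, 6, seed = 13)
  p <- pca_overview(as_count_tbl(sim * 1.0))
  expect_equal(sum(p$var_explained$fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$var_explained$fraction) <= 1e-12))

  # samples on an exact line in gene space -> PC1 carries everything
  line <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(line) <- paste0("s", 1:4)
  p_line <- pca_overview(as_count_tbl(line))
  expect_equal(p_line$var_explained$fraction[1], 1, tolerance = 1e-12)

  # spectral oracle: eigenvalues of the sample covariance (samples as obs)
  m <- matrix(c(1, 4, 2, 8, 3, 5, 9, 2, 7, 1, 6, 2), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  p_toy <- pca_overview(as_count_tbl(m))
  ev <- eigen(cov(t(m)), symmetric = TRUE)$values
  expect_equal(p_toy$var_explained$fraction,
               (ev / sum(ev))[seq_len(nrow(p_toy$var_explained))],
               tolerance = 1e-9)
  expect_error(pca_overview(as_count_tbl(m[, 1, drop = FALSE])),
               class = "pitchercomp_dimension_error")
})

test_that("Welch test matches its formula oracle and symmetry properties", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4, 5)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$pvalue, want$p, tolerance = 1e-12)

  swapped <- welch_t(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$pvalue, got$pvalue)

  same <- welch_t(c(1, 2, 4), c(1, 2, 4))
  expect_equal(same$t, 0)
  expect_equal(same$pvalue, 1)

  const <- welch_t(c(2, 2), c(2, 2, 2))
  expect_equal(const$t, 0)
  expect_equal(const$pvalue, 1)
  expect_gt(const$df, 0)
})

test_that("DEG set associations partition genes by exact membership pattern", {
  deg <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3", "g3", "g3", "g4", "g5", "g6"),
    tissue = c("lpw", "lid", "lpw", "lid", "lpw", "keel", "keel", "lid", "lpw"),
    status = c("up", "up", "up", "up", "up", "up", "down", "ns", "up"))
  out <- deg_set_associations(deg, "up")
  # brute-force over the 2^3 patterns
  expect_equal(out$n_genes[out$association == "lpw"], 2) # g1, g6
  expect_equal(out$n_genes[out$association == "lid+lpw"], 1)
  expect_equal(out$n_genes[out$association == "keel+lid+lpw"], 1)
  expect_false("keel" %in% out$association) # g4 is down, not up
  expect_equal(sum(out$n_genes),
               length(unique(deg$gene_id[deg$status == "up"])))
  down <- deg_set_associations(deg, "down")
  expect_equal(down$association, "keel")
  expect_equal(deg_set_associations(deg[deg$status == "ns", ], "up")$n_genes,
               integer(0))
})
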