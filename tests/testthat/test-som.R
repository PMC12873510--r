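prototype_data <- function(n_genes = 200, n_feat = 8, k = 4, noise = 0.3,
                           seed = 61, sep = 4) {
  withr::with_seed(seed, {
    protos <- matrix(rnorm(k * n_feat), k, n_feat) * sep
    cls <- sample.int(k, n_genes, replace = TRUE)
    x <- protos[cls, ] + matrix(rnorm(n_genes * n_feat, sd = noise),
                                n_genes, n_feat)
    rownames(x) <- sprintf("g%04d", seq_len(n_genes))
    colnames(x) <- sprintf("f%d", seq_len(n_feat))
    list(x = x, cls = cls, protos = protos)
  })
}

test_that("hexagonal grid has equidistant nearest neighbours at unit spacing", {
  g <- som_grid(3, 4)
  expect_equal(nrow(g), 12)
  d <- pitchercomp:::grid_distances(g)
  nn <- apply(d + diag(Inf, 12), 1, min)
  expect_equal(unname(nn), rep(1, 12), tolerance = 1e-12)
})

test_that("a 1x1 grid converges to the data mean", {
  pd <- prototype_data(50, 6)
  model <- train_som(pd$x, rows = 1, cols = 1, epochs = 5, seed = 1)
  expect_equal(as.vector(model$codebook), unname(colMeans(pd$x)),
               tolerance = 1e-8)
})

test_that("training is deterministic given a seed", {
  pd <- prototype_data(100, 6)
  m1 <- train_som(pd$x, rows = 2, cols = 2, epochs = 20, seed = 9)
  m2 <- train_som(pd$x, rows = 2, cols = 2, epochs = 20, seed = 9)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$assignment, m2$assignment)
})

test_that("the partition is invariant to input row order", {
  pd <- prototype_data(120, 6)
  m1 <- train_som(pd$x, rows = 2, cols = 2, epochs = 20, seed = 9)
  withr::with_seed(62, o <- sample(nrow(pd$x)))
  m2 <- train_som(pd$x[o, ], rows = 2, cols = 2, epochs = 20, seed = 9)
  expect_identical(m1$assignment, m2$assignment)
})

test_that("every gene is assigned to exactly one unit and counts sum up", {
  pd <- prototype_data(150, 6)
  model <- train_som(pd$x, rows = 3, cols = 4, epochs = 30, seed = 3)
  expect_equal(nrow(model$assignment), 150)
  expect_true(all(model$assignment$unit %in% 1:12))
  expect_equal(sum(table(model$assignment$unit)), 150)
})

test_that("quantization error is non-increasing at a frozen radius", {
  pd <- prototype_data(300, 8)
  model <- train_som(pd$x, rows = 3, cols = 4, epochs = 40,
                     radius = rep(0.5, 40), seed = 5)
  expect_true(all(diff(model$qe) <= 1e-8))
})

test_that("well-separated planted prototypes are recovered", {
  skip_if_not_installed("mclust")
  pd <- prototype_data(400, 8, k = 4, noise = 0.3, seed = 63)
  model <- train_som(pd$x, rows = 2, cols = 2, epochs = 50, seed = 7)
  ari <- mclust::adjustedRandIndex(model$assignment$unit, pd$cls)
  expect_gte(ari, 0.8)
  # each codebook vector sits within noise scale of its nearest prototype
  d <- as.matrix(dist(rbind(model$codebook, pd$protos)))[1:4, 5:8]
  expect_lt(max(apply(d, 1, min)), 0.3 * sqrt(8))
})

test_that("training errors on too-few genes", {
  pd <- prototype_data(10, 4)
  expect_error(train_som(pd$x, rows = 3, cols = 4),
               class = "pitchercomp_training_error")
})

test_that("cluster profiles are member means and conserve the global mean", {
  pd <- prototype_data(60, 5)
  z <- t(scale(t(pd$x))) # row z-scaling
  model <- train_som(z, rows = 2, cols = 2, epochs = 20, seed = 11)
  prof <- cluster_profiles(model)
  # arithmetic oracle on one unit
  u <- prof$unit[1]
  members <- model$assignment$gene_id[model$assignment$unit == u]
  expect_equal(prof$mean_z[prof$unit == u],
               unname(colMeans(model$data[members, , drop = FALSE])))
  # single-member unit (if any) equals the gene profile; weighted mean ~ 0
  wide <- tidyr::pivot_wider(prof, id_cols = "unit", names_from = "feature",
                             values_from = "mean_z")
  w <- prof |> dplyr::distinct(.data$unit, .data$n_genes)
  wm <- colSums(as.matrix(wide[-1]) * w$n_genes) / sum(w$n_genes)
  # conservation: count-weighted unit profiles reproduce the global mean
  expect_equal(unname(wm), unname(colMeans(model$data)), tolerance = 1e-10)
  # row z-scaling makes every profile (hence the global mean) sum to 0
  expect_equal(sum(wm), 0, tolerance = 1e-10)
})

test_that("tidy, glance and autoplot summarise a SOM model", {
  pd <- prototype_data(80, 5)
  model <- train_som(pd$x, rows = 2, cols = 2, epochs = 10, seed = 13)
  expect_identical(tidy(model), model$assignment)
  g <- glance(model)
  expect_equal(g$n_genes, 80)
  expect_equal(g$n_units, 4)
  expect_s3_class(autoplot(model), "ggplot")
})

test_that("cluster matching flags matched planted modules, not shuffled ones", {
  # two species share module structure through 1:1 orthologs
  withr::with_seed(64, {
    k <- 4
    n <- 240
    cls <- sample.int(k, n, replace = TRUE)
    protos <- matrix(rnorm(k * 6), k, 6) * 4
    xa <- protos[cls, ] + matrix(rnorm(n * 6, sd = 0.3), n, 6)
    xb <- protos[cls, ] + matrix(rnorm(n * 6, sd = 0.3), n, 6)
  })
  rownames(xa) <- sprintf("A%04d", 1:n)
  rownames(xb) <- sprintf("B%04d", 1:n)
  colnames(xa) <- colnames(xb) <- paste0("f", 1:6)
  map <- pitchercomp:::new_ortho_map(
    tibble::tibble(group_id = rep(sprintf("H%04d", 1:n), 2),
                   species = rep(c("A", "B"), each = n),
                   gene_id = c(rownames(xa), rownames(xb))),
    "hierarchical", c("A", "B"))
  ma <- train_som(xa, rows = 2, cols = 2, epochs = 30, seed = 15)
  mb <- train_som(xb, rows = 2, cols = 2, epochs = 30, seed = 16)
  res <- suppress_logs(match_clusters(ma, mb, map, n_perm = 2000, seed = 17))
  # dominant-module pairing: each unit of A matches exactly one unit of B
  dom <- function(model, cls, ids) {
    sapply(split(cls[match(model$assignment$gene_id, ids)],
                 model$assignment$unit),
           function(v) as.integer(names(which.max(table(v)))))
  }
  dom_a <- dom(ma, cls, rownames(xa))
  dom_b <- dom(mb, cls, rownames(xb))
  res$matched <- dom_a[as.character(res$unit_a)] == dom_b[as.character(res$unit_b)]
  expect_true(all(res$fdr[res$matched] < 0.05))
  expect_true(all(res$fdr[!res$matched] > 0.05))

  # shuffled orthology: no pair significant
  map_shuf <- map
  withr::with_seed(65, {
    bgenes <- map_shuf$gene_id[map_shuf$species == "B"]
    map_shuf$gene_id[map_shuf$species == "B"] <- sample(bgenes)
  })
  res_shuf <- suppress_logs(match_clusters(ma, mb, map_shuf,
                                           n_perm = 2000, seed = 18))
  expect_equal(sum(res_shuf$fdr < 0.05), 0)
})

test_that("clusters with no mapped orthogroups give JC 0 and p 1", {
  pd <- prototype_data(60, 5)
  ma <- train_som(pd$x, rows = 2, cols = 2, epochs = 10, seed = 19)
  mb <- train_som(pd$x, rows = 2, cols = 2, epochs = 10, seed = 20)
  # map covers no genes at all -> every cluster set empty
  map <- pitchercomp:::new_ortho_map(
    tibble::tibble(group_id = "H1", species = "A", gene_id = "absent"),
    "hierarchical", "A")
  res <- suppress_logs(match_clusters(ma, mb, map, n_perm = 200, seed = 21))
  expect_true(all(res$jc == 0))
  expect_true(all(res$pvalue == 1))
})
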