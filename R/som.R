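#' Hexagonal SOM grid layout
#'
#' Offset hexagonal coordinates: unit at row r, column c (0-based) sits at
#' `x = c + 0.5 * (r %% 2)`, `y = r * sqrt(3) / 2`, so nearest neighbours are
#' equidistant with unit spacing 1. Units are numbered row-major from 1.
#'
#' @param rows,cols Grid dimensions.
#' @return A tibble `unit`, `row`, `col`, `x`, `y`.
#' @export
som_grid <- function(rows = 3, cols = 4) {
  g <- tidyr::expand_grid(row = seq_len(rows) - 1, col = seq_len(cols) - 1)
  g |>
    mutate(unit = dplyr::row_number(),
           x = .data$col + 0.5 * (.data$row %% 2),
           y = .data$row * sqrt(3) / 2) |>
    select("unit", "row", "col", "x", "y")
}

grid_distances <- function(grid) {
  as.matrix(stats::dist(cbind(grid$x, grid$y)))
}

#' Train a batch self-organizing map on z-scaled expression profiles
#'
#' Batch SOM on a hexagonal grid: each epoch assigns every gene to its
#' best-matching unit (BMU; minimal Euclidean distance, ties to the lowest
#' unit index), then replaces each codebook vector by the
#' neighborhood-weighted mean of the assigned data. The neighborhood is a
#' Gaussian over hexagonal grid distance, truncated at the current radius,
#' which decays linearly from two-thirds of the maximum inter-unit distance to
#' 0.5 (BMU-only updates, i.e. a k-means step) over the epochs. The codebook
#' is initialized from a seeded random sample of distinct data rows; rows are
#' processed in canonical gene-id order so the fit is invariant to input row
#' order. A unit receiving no neighborhood weight is re-seeded on the data row
#' worst served by its current BMU (empty-cluster repair, logged), which never
#' increases the quantization error.
#'
#' @param data Tibble `gene_id` plus numeric feature columns (z-scaled
#'   tissue-by-condition profiles), or a numeric matrix with gene rownames.
#' @param rows,cols Grid dimensions (default 3 x 4 = 12 units).
#' @param epochs Training epochs (default 100).
#' @param radius Optional vector of per-epoch radii overriding the linear
#'   schedule (recycled to `epochs`).
#' @param seed Integer seed for codebook initialization.
#' @return An object of class `som_model`: list with `codebook` (unit x
#'   feature), `assignment` (tibble `gene_id`, `unit`, `dist`), `grid`, `qe`
#'   (per-epoch quantization error, computed at assignment time), `data`,
#'   and `params`.
#' @export
train_som <- function(data, rows = 3, cols = 4, epochs = 100, radius = NULL,
                      seed = NULL) {
  x <- count_matrix(data, what = "profile")
  if (any(!is.finite(x))) abort_format("profiles must be finite (no missing values)")
  n_units <- rows * cols
  if (nrow(x) < n_units) {
    abort(paste0("fewer genes (", nrow(x), ") than SOM units (", n_units, ")"),
          class = "pitchercomp_training_error")
  }
  x <- x[order(rownames(x)), , drop = FALSE] # canonical gene-id order
  grid <- som_grid(rows, cols)
  d_grid <- grid_distances(grid)
  rf <- 0.5
  r0 <- max(2 / 3 * max(d_grid), rf)
  if (is.null(radius)) {
    radius <- if (epochs == 1) rf else r0 - (r0 - rf) * (seq_len(epochs) - 1) / (epochs - 1)
  } else {
    radius <- rep_len(radius, epochs)
  }

  # seeded sample of distinct data rows, weighted toward spread-out profiles
  # (squared distance to the nearest already-chosen row), so well-separated
  # structure is covered by the initial codebook almost surely
  init <- function() {
    ux <- x[!duplicated(x), , drop = FALSE]
    if (nrow(ux) < n_units) {
      abort("fewer distinct profiles than SOM units",
            class = "pitchercomp_training_error")
    }
    chosen <- sample.int(nrow(ux), 1)
    d2min <- rowSums((ux - matrix(ux[chosen, ], nrow(ux), ncol(ux),
                                  byrow = TRUE))^2)
    while (length(chosen) < n_units) {
      w <- d2min
      w[chosen] <- 0
      nxt <- if (sum(w) > 0) sample.int(nrow(ux), 1, prob = w) else
        sample(setdiff(seq_len(nrow(ux)), chosen), 1)
      chosen <- c(chosen, nxt)
      d2 <- rowSums((ux - matrix(ux[nxt, ], nrow(ux), ncol(ux), byrow = TRUE))^2)
      d2min <- pmin(d2min, d2)
    }
    ux[chosen, , drop = FALSE]
  }
  codebook <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  rownames(codebook) <- NULL

  x_sq <- rowSums(x^2)
  qe <- numeric(epochs)
  bmu <- integer(nrow(x))
  n_reseeded <- 0L
  for (e in seq_len(epochs)) {
    d2 <- outer(x_sq, rowSums(codebook^2), `+`) - 2 * x %*% t(codebook)
    d2[d2 < 0] <- 0
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- sum(d2[cbind(seq_len(nrow(x)), bmu)])
    r <- radius[e]
    h <- exp(-d_grid^2 / (2 * r^2)) * (d_grid <= r)
    w <- h[bmu, , drop = FALSE] # gene x unit neighborhood weight
    denom <- colSums(w)
    upd <- denom > 1e-12
    new_cb <- codebook
    new_cb[upd, ] <- crossprod(w[, upd, drop = FALSE], x) / denom[upd]
    # empty units are re-seeded on the rows worst served by their BMU
    # (standard empty-cluster repair; never increases quantization error)
    empty <- which(!upd)
    if (length(empty)) {
      worst <- order(d2[cbind(seq_len(nrow(x)), bmu)], decreasing = TRUE)
      new_cb[empty, ] <- x[worst[seq_along(empty)], , drop = FALSE]
      n_reseeded <- n_reseeded + length(empty)
    }
    codebook <- new_cb
  }
  # final assignment against the trained codebook
  d2 <- outer(x_sq, rowSums(codebook^2), `+`) - 2 * x %*% t(codebook)
  d2[d2 < 0] <- 0
  bmu <- max.col(-d2, ties.method = "first")
  if (n_reseeded > 0) {
    inform_stage("train_som: re-seeded ", n_reseeded, " empty unit(s)")
  }
  assignment <- tibble(gene_id = rownames(x), unit = bmu,
                       dist = sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
  structure(
    list(codebook = codebook, assignment = assignment, grid = grid,
         qe = qe, final_qe = sum(d2[cbind(seq_len(nrow(x)), bmu)]),
         data = x, features = colnames(x),
         params = list(rows = rows, cols = cols, epochs = epochs,
                       radius = radius, seed = seed)),
    class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("Batch SOM:", x$params$rows, "x", x$params$cols, "hexagonal grid,",
      nrow(x$assignment), "genes,", length(x$features), "features\n")
  cat("  epochs:", x$params$epochs, " final quantization error:",
      signif(x$final_qe, 6), "\n")
  invisible(x)
}

#' Per-unit mean expression profiles of a trained SOM
#'
#' For each grid unit, the element-wise mean of the member genes' z-profiles
#' (the per-cluster average z-score curves), with member counts.
#'
#' @param model A `som_model`.
#' @param data Optional profile tibble/matrix to average instead of the
#'   training data (must cover the assigned genes).
#' @return A tibble `unit`, `n_genes`, `feature`, `mean_z` with features in
#'   training column order.
#' @export
cluster_profiles <- function(model, data = NULL) {
  stopifnot(inherits(model, "som_model"))
  x <- if (is.null(data)) model$data else count_matrix(data, what = "profile")
  idx <- match(model$assignment$gene_id, rownames(x))
  if (anyNA(idx)) abort_lookup("profile data does not cover all assigned genes")
  x <- x[idx, , drop = FALSE]
  purrr::map_dfr(sort(unique(model$assignment$unit)), function(u) {
    rows <- model$assignment$unit == u
    tibble(unit = u, n_genes = sum(rows),
           feature = factor(colnames(x), levels = colnames(x)),
           mean_z = unname(colMeans(x[rows, , drop = FALSE])))
  })
}

#' @rdname train_som
#' @param x,object A `som_model`.
#' @param ... Unused.
#' @export
tidy.som_model <- function(x, ...) {
  x$assignment
}

#' @rdname train_som
#' @export
glance.som_model <- function(x, ...) {
  tibble(n_genes = nrow(x$assignment),
         n_units = nrow(x$grid),
         n_features = length(x$features),
         epochs = x$params$epochs,
         quantization_error = x$final_qe)
}

#' @rdname train_som
#' @export
autoplot.som_model <- function(object, ...) {
  prof <- cluster_profiles(object)
  prof |>
    mutate(label = paste0("unit ", .data$unit, " (n=", .data$n_genes, ")")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$feature, y = .data$mean_z, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "average z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Cross-species SOM cluster matching by orthogroup composition
#'
#' Converts each species' SOM clusters to hierarchical orthogroup sets (every
#' orthogroup with at least one member gene in the cluster) and tests all
#' cluster pairs for Jaccard similarity with the constrained permutation null,
#' BH-corrected across the full pair matrix. Genes not mapped to any
#' orthogroup are excluded (logged).
#'
#' @param assign_a,assign_b Assignment tibbles (`gene_id`, `unit`) from two
#'   species' SOM models (or the models themselves).
#' @param ortho_map Hierarchical orthogroup map covering both species.
#' @param n_perm Permutations per pair.
#' @param seed Master seed for the permutation streams.
#' @return A [similarity_matrix()] result with columns `unit_a`, `unit_b`.
#' @export
match_clusters <- function(assign_a, assign_b, ortho_map, n_perm = 10000,
                           seed = NULL) {
  to_assign <- function(a) if (inherits(a, "som_model")) a$assignment else as_tibble(a)
  assign_a <- to_assign(assign_a)
  assign_b <- to_assign(assign_b)
  map_min <- distinct(as_tibble(ortho_map), .data$group_id, .data$gene_id)
  sets_of <- function(assign, label) {
    joined <- left_join(assign, map_min, by = "gene_id")
    n_unmapped <- sum(is.na(joined$group_id))
    if (n_unmapped > 0) {
      inform_stage("match_clusters: excluded ", n_unmapped,
                   " unmapped gene(s) for ", label)
    }
    joined <- filter(joined, !is.na(.data$group_id))
    list(
      sets = lapply(split(joined$group_id, joined$unit), function(g) sort(unique(g))),
      universe = sort(unique(joined$group_id))
    )
  }
  a <- sets_of(assign_a, "species A")
  b <- sets_of(assign_b, "species B")
  units_a <- sort(unique(assign_a$unit))
  units_b <- sort(unique(assign_b$unit))
  empty <- character(0)
  pairs <- tidyr::expand_grid(unit_a = units_a, unit_b = units_b) |>
    mutate(
      set_a = purrr::map(.data$unit_a, ~ a$sets[[as.character(.x)]] %||% empty),
      set_b = purrr::map(.data$unit_b, ~ b$sets[[as.character(.x)]] %||% empty),
      universe_a = list(a$universe),
      universe_b = list(b$universe)
    )
  similarity_matrix(pairs, n_perm = n_perm, seed = seed)
}
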