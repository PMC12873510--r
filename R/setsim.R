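#' Jaccard similarity coefficient
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Constrained permutation test of orthogroup set similarity
#'
#' Tests whether the Jaccard similarity of two orthogroup sets exceeds what
#' random sets of the same sizes would achieve. Each permutation draws a
#' uniformly random bijection of each species' universe onto itself and maps
#' the observed set through it, which preserves set sizes and — because a
#' bijection cannot send one orthogroup to two categories — automatically
#' forbids contradictory assignments (e.g. the same orthogroup both up- and
#' downregulated in one tissue). The Jaccard coefficient is recomputed for
#' each draw; by default `p = (#{JC_perm >= JC_obs} + 1) / (n + 1)` (never
#' zero); `p_literal = TRUE` uses the uncorrected `#{JC_perm >= JC_obs} / n`.
#'
#' @param set_a,set_b Observed sets (subsets of their universes).
#' @param universe_a,universe_b Permutable universes (e.g. all orthogroups
#'   with at least one tested or clustered gene of that species).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @param p_literal Use the uncorrected Monte-Carlo p (default `FALSE`).
#' @param keep_draws Attach the permuted intersection sizes as attribute
#'   `draws` (diagnostics; default `FALSE`).
#' @return A one-row tibble: `intersection`, `union`, `jc`, `pvalue`,
#'   `n_perm`.
#' @export
permutation_test <- function(set_a, set_b, universe_a, universe_b,
                             n_perm = 10000, seed = NULL, p_literal = FALSE,
                             keep_draws = FALSE) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe_a <- unique(universe_a); universe_b <- unique(universe_b)
  if (length(setdiff(set_a, universe_a)) || length(setdiff(set_b, universe_b))) {
    abort_domain("observed sets must be subsets of their universes")
  }
  if (n_perm < 100) warn("fewer than 100 permutations; p-values will be coarse")
  glob <- union(universe_a, universe_b)
  ua <- match(universe_a, glob)
  ub <- match(universe_b, glob)
  a <- length(set_a); b <- length(set_b)
  inter_obs <- length(intersect(set_a, set_b))
  union_obs <- length(union(set_a, set_b))
  jc_obs <- if (union_obs > 0) inter_obs / union_obs else 0

  draw <- function() {
    zs <- integer(n_perm)
    if (a == 0 && b == 0) return(zs)
    mark <- logical(length(glob))
    nu_a <- length(ua); nu_b <- length(ub)
    for (i in seq_len(n_perm)) {
      pa <- ua[sample.int(nu_a, a)]
      pb <- ub[sample.int(nu_b, b)]
      mark[pa] <- TRUE
      zs[i] <- sum(mark[pb])
      mark[pa] <- FALSE
    }
    zs
  }
  zs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  jc_perm <- ifelse(a + b - zs > 0, zs / (a + b - zs), 0)
  r <- sum(jc_perm >= jc_obs)
  p <- if (p_literal) r / n_perm else (r + 1) / (n_perm + 1)
  out <- tibble(intersection = inter_obs, union = union_obs, jc = jc_obs,
                pvalue = p, n_perm = n_perm)
  if (keep_draws) attr(out, "draws") <- zs
  out
}

#' Permutation tests over a family of set pairs with BH correction
#'
#' Runs [permutation_test()] for every row of a pair table (e.g. the
#' tissue-pair grid from [response_matrix()] or all SOM cluster pairs), each
#' with an independent sub-seed derived from the master seed, and applies
#' Benjamini-Hochberg correction across the whole family.
#'
#' @param pairs Tibble with list-columns `set_a`, `set_b`, `universe_a`,
#'   `universe_b`; any other columns are carried through as labels.
#' @param n_perm Permutations per pair.
#' @param seed Master seed; pair `i` uses `derive_seed(seed, "pair<i>")`.
#' @param p_literal Passed to [permutation_test()].
#' @return The input label columns plus `intersection`, `union`, `jc`,
#'   `pvalue`, `fdr`, `n_perm`.
#' @export
similarity_matrix <- function(pairs, n_perm = 10000, seed = NULL,
                              p_literal = FALSE) {
  if (!nrow(pairs)) abort_domain("at least one pair is required")
  need <- c("set_a", "set_b", "universe_a", "universe_b")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) abort_format("pairs table lacks: ", paste(miss, collapse = ", "))
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    permutation_test(pairs$set_a[[i]], pairs$set_b[[i]],
                     pairs$universe_a[[i]], pairs$universe_b[[i]],
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, paste0("pair", i)),
                     p_literal = p_literal)
  })
  out <- dplyr::bind_cols(pairs[setdiff(names(pairs), need)], res)
  out$fdr <- bh_adjust(out$pvalue)
  out
}

#' Heatmap of a set-similarity matrix
#'
#' @param x Result tibble from [similarity_matrix()] with two label columns
#'   identifying the grid axes.
#' @param x_var,y_var Names of the label columns (defaults: first two label
#'   columns).
#' @param fill One of `"jc"`, `"fdr"`, `"intersection"`.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(x, x_var = NULL, y_var = NULL, fill = "jc") {
  labels <- setdiff(names(x), c("intersection", "union", "jc", "pvalue",
                                "fdr", "n_perm", "direction"))
  x_var <- x_var %||% labels[1]
  y_var <- y_var %||% labels[2]
  ggplot2::ggplot(x, ggplot2::aes(x = .data[[x_var]], y = .data[[y_var]],
                                  fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$intersection), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
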