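#' Select high-CV genes for clustering
#'
#' Computes, per gene, the coefficient of variation (sample sd / mean) of
#' expression across tissue-by-condition mean columns, and selects the top
#' `top_frac` of eligible genes by CV. A gene is eligible when its maximum
#' column value exceeds `min_fpkm` (expressed in at least one condition).
#' Exactly `ceiling(top_frac * n_eligible)` genes are selected; ties at the
#' cutoff are broken lexicographically by gene id for determinism.
#'
#' @param expr_means Tibble `gene_id` plus tissue-by-condition mean columns
#'   (from [condition_means()]).
#' @param top_frac Fraction of eligible genes to select (default 0.10).
#' @param min_fpkm Eligibility threshold on the per-gene maximum (default 1.0).
#' @return A tibble `gene_id`, `mean_fpkm`, `cv`, `max_fpkm`, `eligible`,
#'   `selected`.
#' @export
select_high_cv_genes <- function(expr_means, top_frac = 0.10, min_fpkm = 1.0) {
  if (top_frac <= 0 || top_frac > 1) abort_config("top_frac must lie in (0, 1]")
  x <- count_matrix(expr_means, what = "expression")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  cv <- ifelse(mu > 0, s / mu, 0)
  cv[s == 0] <- 0 # constant rows have CV exactly 0
  mx <- apply(x, 1, max)
  stats <- tibble(gene_id = rownames(x), mean_fpkm = unname(mu),
                  cv = unname(cv), max_fpkm = unname(mx),
                  eligible = unname(mx) > min_fpkm)
  n_eligible <- sum(stats$eligible)
  if (n_eligible == 0) {
    warn("no genes exceed the expression threshold; empty selection")
    stats$selected <- FALSE
    return(stats)
  }
  n_select <- ceiling(top_frac * n_eligible)
  elig <- stats |>
    filter(.data$eligible) |>
    arrange(dplyr::desc(.data$cv), .data$gene_id)
  chosen <- elig$gene_id[seq_len(n_select)]
  stats$selected <- stats$gene_id %in% chosen
  inform_stage("select_high_cv_genes: selected ", n_select, " of ",
               n_eligible, " eligible genes (", nrow(stats), " total)")
  stats
}

#' Mean-center and variance-scale expression rows
#'
#' Scales each gene's profile to mean 0 and sample standard deviation 1.
#' Constant rows (sd 0) cannot be scaled and are dropped with a warning.
#'
#' @param expr Tibble `gene_id` plus numeric profile columns.
#' @return A tibble of the same shape (minus dropped rows) with z-scaled rows.
#' @export
zscale_rows <- function(expr) {
  x <- count_matrix(expr, what = "expression")
  s <- apply(x, 1, sd)
  drop <- s == 0 | !is.finite(s)
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " constant row(s) that cannot be z-scaled"))
    x <- x[!drop, , drop = FALSE]
    s <- s[!drop]
  }
  z <- (x - rowMeans(x)) / s
  matrix_tbl(z)
}
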