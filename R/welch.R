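#' Welch's two-sided t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom, used to
#' compare expression levels (e.g. basal expression of digestive-fluid protein
#' genes) between two groups. When both groups are constant the test has a
#' defined limit: `t = 0, p = 1` for equal means, `|t| = Inf, p = 0`
#' otherwise.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A one-row tibble: `mean_a`, `mean_b`, `t`, `df`, `pvalue`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort_domain("each group needs at least 2 values")
  }
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    return(tibble(mean_a = mean(a), mean_b = mean(b),
                  t = if (d == 0) 0 else sign(d) * Inf,
                  df = length(a) + length(b) - 2,
                  pvalue = if (d == 0) 1 else 0))
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble(mean_a = mean(a), mean_b = mean(b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         pvalue = ht$p.value)
}

#' Tally DEG set associations across tissues
#'
#' Counts, for genes called in a given direction in at least one tissue, the
#' exact combination of tissues in which each gene is called (the tallies
#' behind an upset-style plot). Every gene is counted in exactly one
#' association; empty associations are omitted.
#'
#' @param deg DEG tibble with columns `gene_id`, `tissue`, `status`, covering
#'   one or more tissues.
#' @param direction `"up"` or `"down"`.
#' @return A tibble `association` (tissues sorted and joined with `+`),
#'   `tissues` (list-column), `n_genes`, sorted by decreasing count.
#' @export
deg_set_associations <- function(deg, direction = c("up", "down")) {
  direction <- match.arg(direction)
  hits <- deg |>
    filter(.data$status == direction) |>
    distinct(.data$gene_id, .data$tissue)
  if (!nrow(hits)) {
    return(tibble(association = character(), tissues = list(), n_genes = integer()))
  }
  hits |>
    group_by(.data$gene_id) |>
    summarise(tissues = list(sort(unique(.data$tissue))), .groups = "drop") |>
    mutate(association = purrr::map_chr(.data$tissues, paste, collapse = "+")) |>
    group_by(.data$association) |>
    summarise(tissues = .data$tissues[1], n_genes = dplyr::n(), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_genes), .data$association)
}
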