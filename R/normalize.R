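#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes one between-sample scaling factor per sample by the weighted
#' trimmed mean of per-gene log2 count ratios (M-values) against a reference
#' sample. Genes with a zero count in either member of a pair are excluded
#' from that pair's M/A computation; the default trims the most extreme 30%
#' of M-values and 5% of A-values (on each side), weights the surviving
#' M-values by inverse asymptotic (binomial) variance, sets the factor to
#' `2^(weighted mean M)`, and rescales all factors to geometric mean 1. The
#' reference sample is the one whose library-size-scaled 75th-percentile count
#' is closest to the mean of those quantiles across samples.
#'
#' @param counts Count table: tibble with `gene_id` plus one column per
#'   sample, or a numeric matrix with gene rownames.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @param diagnostics If `TRUE`, attach per-gene M, A and weight values
#'   against the reference as a `diagnostics` attribute.
#' @return A tibble with columns `sample_id` and `tmm_factor`, with attribute
#'   `reference_sample`.
#' @export
tmm_norm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                             diagnostics = FALSE) {
  x <- count_matrix(counts)
  if (any(x < 0) || any(!is.finite(x))) abort_format("counts must be finite and >= 0")
  lib_size <- colSums(x)
  if (any(lib_size == 0)) {
    abort(paste0("sample(s) with all-zero counts cannot be normalized: ",
                 paste(colnames(x)[lib_size == 0], collapse = ", ")),
          class = "pitchercomp_normalization_error")
  }
  nsamples <- ncol(x)
  keep_rows <- rowSums(x > 0) > 0
  x <- x[keep_rows, , drop = FALSE]
  if (nrow(x) == 0 || nsamples == 1) {
    out <- tibble(sample_id = colnames(x), tmm_factor = rep(1, nsamples))
    attr(out, "reference_sample") <- colnames(x)[1]
    return(out)
  }
  f75 <- vapply(seq_len(nsamples),
                function(j) unname(quantile(x[, j], probs = 0.75)) / lib_size[j],
                numeric(1))
  ref <- if (median(f75) < 1e-20) {
    which.max(colSums(sqrt(x)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
  fac <- vapply(seq_len(nsamples), function(j) {
    tmm_pair_factor(x[, j], x[, ref], lib_size[j], lib_size[ref], trim_m, trim_a)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  out <- tibble(sample_id = colnames(x), tmm_factor = unname(fac))
  attr(out, "reference_sample") <- colnames(x)[ref]
  if (diagnostics) {
    attr(out, "diagnostics") <- tmm_pair_ma(x, ref, lib_size)
  }
  out
}

# Weighted trimmed mean of M-values for one sample against the reference.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic variance of M from two binomial sampling fractions
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

tmm_pair_ma <- function(x, ref, lib_size) {
  purrr::map_dfr(seq_len(ncol(x)), function(j) {
    m <- log2((x[, j] / lib_size[j]) / (x[, ref] / lib_size[ref]))
    a <- (log2(x[, j] / lib_size[j]) + log2(x[, ref] / lib_size[ref])) / 2
    v <- (lib_size[j] - x[, j]) / lib_size[j] / x[, j] +
      (lib_size[ref] - x[, ref]) / lib_size[ref] / x[, ref]
    tibble(sample_id = colnames(x)[j], gene_id = rownames(x),
           M = m, A = a, w = 1 / v)
  })
}

#' Remove low-count genes
#'
#' Drops genes whose total count across all samples falls below `min_total`
#' (applied before TMM normalization).
#'
#' @param counts Count table (tibble with `gene_id`, or matrix).
#' @param min_total Minimum total count to retain a gene (default 1).
#' @return A count tibble of the surviving genes.
#' @export
filter_low_counts <- function(counts, min_total = 1) {
  if (min_total < 0) abort_config("min_total must be >= 0")
  x <- count_matrix(counts)
  keep <- rowSums(x) >= min_total
  if (!any(keep)) warn("all genes removed by the low-count filter")
  inform_stage("filter_low_counts: removed ", sum(!keep), " of ", nrow(x),
               " genes with total count < ", min_total)
  matrix_tbl(x[keep, , drop = FALSE])
}

#' FPKM expression values
#'
#' `FPKM = count / (effective library size / 1e6) / (length / 1e3)`, with the
#' effective library size equal to the column sum times the sample's TMM
#' factor.
#'
#' @param counts Count table.
#' @param lengths Tibble `gene_id`, `length_bp` covering every gene.
#' @param factors Tibble `sample_id`, `tmm_factor` from [tmm_norm_factors()],
#'   or `NULL` for unit factors.
#' @return A tibble `gene_id` plus one FPKM column per sample.
#' @export
fpkm <- function(counts, lengths, factors = NULL) {
  x <- count_matrix(counts)
  len <- lengths$length_bp[match(rownames(x), lengths$gene_id)]
  if (anyNA(len)) {
    abort_lookup("missing gene length for: ",
                 paste(head(rownames(x)[is.na(len)], 5), collapse = ", "))
  }
  f <- rep(1, ncol(x))
  if (!is.null(factors)) {
    f <- factors$tmm_factor[match(colnames(x), factors$sample_id)]
    if (anyNA(f)) abort_lookup("missing TMM factor for some samples")
  }
  eff_lib <- colSums(x) * f
  out <- sweep(x, 2, eff_lib / 1e6, `/`) / (len / 1e3)
  matrix_tbl(out)
}

#' Collapse replicate columns to tissue-by-condition means
#'
#' Averages expression columns over replicates, yielding one column per
#' `tissue.condition` combination (the profile features used for CV gene
#' selection and SOM clustering).
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param samples Sample metadata tibble covering those columns.
#' @return A tibble `gene_id` plus one column per `tissue.condition`, ordered
#'   by the metadata's tissue order with control before fed.
#' @export
condition_means <- function(expr, samples) {
  x <- count_matrix(expr, what = "expression")
  samples <- check_samples(samples)
  x <- align_counts_samples(x, samples)
  grp <- paste(samples$tissue, samples$condition, sep = ".")
  levels <- unique(paste(rep(unique(samples$tissue), each = 2),
                         c("control", "fed"), sep = "."))
  levels <- intersect(levels, grp)
  means <- vapply(levels, function(g) {
    rowMeans(x[, grp == g, drop = FALSE])
  }, numeric(nrow(x)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(x))
  colnames(means) <- levels
  rownames(means) <- rownames(x)
  matrix_tbl(means)
}
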