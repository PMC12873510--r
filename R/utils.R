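# Shared internal helpers: typed errors, seed derivation, matrix conversion.

abort_format <- function(...) {
  abort(paste0(...), class = "pitchercomp_format_error")
}

abort_consistency <- function(...) {
  abort(paste0(...), class = "pitchercomp_consistency_error")
}

abort_config <- function(...) {
  abort(paste0(...), class = "pitchercomp_config_error")
}

abort_domain <- function(...) {
  abort(paste0(...), class = "pitchercomp_domain_error")
}

abort_lookup <- function(...) {
  abort(paste0(...), class = "pitchercomp_lookup_error")
}

inform_stage <- function(...) {
  inform(paste0(...), class = "pitchercomp_log")
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministically maps a master seed and a character tag to an integer
#' below 2^31, so that each pipeline stage (or permutation-test pair) draws
#' from its own reproducible stream.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "speciesA")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(tag)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

# Convert a gene_id-keyed wide tibble (or matrix) to a numeric matrix with
# gene_id rownames. Validates uniqueness of gene ids and sample columns.
count_matrix <- function(counts, what = "count") {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      abort_format("matrix input must carry gene ids as rownames")
    }
    m <- counts
  } else {
    counts <- as_tibble(counts)
    if (!"gene_id" %in% names(counts)) {
      abort_format("expected a `gene_id` column in the ", what, " table")
    }
    m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    rownames(m) <- as.character(counts$gene_id)
  }
  if (anyDuplicated(rownames(m))) {
    abort_format("duplicate gene ids in ", what, " table")
  }
  if (anyDuplicated(colnames(m))) {
    abort_format("duplicate sample columns in ", what, " table")
  }
  storage.mode(m) <- "double"
  m
}

# Inverse of count_matrix(): matrix -> tibble with leading gene_id column.
matrix_tbl <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

check_counts_valid <- function(m) {
  if (any(!is.finite(m))) abort_format("counts must be finite")
  if (any(m < 0)) abort_format("counts must be non-negative")
  if (any(m != round(m))) abort_format("counts must be integral")
  invisible(m)
}

check_samples <- function(samples) {
  samples <- as_tibble(samples)
  req <- c("sample_id", "species", "tissue", "condition", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort_format("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort_format("duplicate sample_id in sample metadata")
  }
  bad <- setdiff(unique(samples$condition), c("control", "fed"))
  if (length(bad)) {
    abort_format("condition must be 'control' or 'fed'; found: ",
                 paste(bad, collapse = ", "))
  }
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate))) {
    abort_format("replicate must be a positive integer")
  }
  samples
}

# Align a count matrix to sample metadata: identical sample sets, metadata order.
align_counts_samples <- function(m, samples) {
  extra <- setdiff(colnames(m), samples$sample_id)
  if (length(extra)) {
    abort_consistency("sample(s) in count matrix absent from metadata: ",
                      paste(extra, collapse = ", "))
  }
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing)) {
    abort_consistency("sample(s) in metadata absent from count matrix: ",
                      paste(missing, collapse = ", "))
  }
  m[, samples$sample_id, drop = FALSE]
}
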