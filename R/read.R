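#' Read a gene-level count matrix with its sample metadata
#'
#' Reads a genes x samples TSV (first column gene ids, header row sample ids)
#' together with a sample metadata TSV, validates both, and reorders the count
#' columns to the metadata order.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the sample metadata TSV with columns
#'   `sample_id`, `species`, `tissue`, `condition` (control/fed), `replicate`.
#' @return A list with elements `counts` (tibble, `gene_id` plus one column per
#'   sample) and `samples` (tibble).
#' @export
read_counts <- function(path, meta_path) {
  samples <- read_sample_meta(meta_path)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(raw) < 2) abort_format("counts file needs a gene id column and >= 1 sample")
  names(raw)[1] <- "gene_id"
  raw$gene_id <- as.character(raw$gene_id)
  m <- count_matrix(raw, what = "count")
  check_counts_valid(m)
  m <- align_counts_samples(m, samples)
  inform_stage("read_counts: ", nrow(m), " genes x ", ncol(m), " samples from ", path)
  list(counts = matrix_tbl(m), samples = samples)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `species`, `tissue`, `condition`,
#'   `replicate`.
#' @return A validated tibble.
#' @export
read_sample_meta <- function(path) {
  samples <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_samples(samples)
}

#' Read gene lengths
#'
#' @param path TSV with columns `gene_id` and `length_bp` (>= 1, base pairs).
#' @return A tibble `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  miss <- setdiff(c("gene_id", "length_bp"), names(tbl))
  if (length(miss)) abort_format("gene length table lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tbl$gene_id)) abort_format("duplicate gene_id in gene length table")
  if (any(!is.finite(tbl$length_bp)) || any(tbl$length_bp < 1)) {
    abort_format("gene lengths must be >= 1 bp")
  }
  as_tibble(tbl[c("gene_id", "length_bp")])
}

#' Read an orthogroup membership table
#'
#' Parses the two common orthogroup table dialects: the nonhierarchical flavor
#' (first column the group id, one column per species, genes separated by
#' `", "`) and the hierarchical flavor (columns `HOG`, `OG`,
#' `Gene Tree Parent Clade`, then per-species gene lists), as produced by
#' orthology-inference tools. Groups containing genes from fewer than
#' `min_species_frac` of the species columns are dropped (ceiling rule: with 15
#' species and a 0.30 fraction, a group needs genes from at least 5 species).
#'
#' @param path Path to the TSV.
#' @param flavor `"nonhierarchical"` or `"hierarchical"`.
#' @param min_species_frac Minimum fraction of species a group must span
#'   (default 0.30).
#' @param node For the hierarchical flavor, the label of the species-tree node
#'   at which the groups are resolved (metadata only; default the most recent
#'   common ancestor of the two focal species).
#' @return A long tibble with columns `group_id`, `species`, `gene_id`, with
#'   attributes `flavor`, `species_set`, and `node`.
#' @export
read_orthogroups <- function(path,
                             flavor = c("hierarchical", "nonhierarchical"),
                             min_species_frac = 0.30,
                             node = "focal-MRCA") {
  flavor <- match.arg(flavor)
  if (min_species_frac < 0 || min_species_frac > 1) {
    abort_config("min_species_frac must lie in [0, 1]")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn("empty orthogroup table; returning an empty map")
    out <- tibble(group_id = character(), species = character(), gene_id = character())
    return(new_ortho_map(out, flavor, character(), node))
  }
  if (flavor == "hierarchical") {
    meta_cols <- intersect(c("HOG", "OG", "Gene Tree Parent Clade"), names(raw))
    if (!"HOG" %in% meta_cols) abort_format("hierarchical table lacks an HOG column")
    id_col <- "HOG"
  } else {
    id_col <- names(raw)[1]
    meta_cols <- id_col
  }
  species_cols <- setdiff(names(raw), meta_cols)
  if (!length(species_cols)) abort_format("orthogroup table has no species columns")
  long <- raw |>
    select(group_id = dplyr::all_of(id_col), dplyr::all_of(species_cols)) |>
    tidyr::pivot_longer(-"group_id", names_to = "species", values_to = "genes") |>
    filter(!is.na(.data$genes), .data$genes != "") |>
    mutate(gene_id = strsplit(.data$genes, ",[ ]?")) |>
    select(-"genes") |>
    tidyr::unnest("gene_id") |>
    mutate(gene_id = trimws(.data$gene_id)) |>
    filter(.data$gene_id != "")
  dup <- long |>
    distinct(.data$group_id, .data$gene_id) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort_consistency("gene(s) assigned to more than one ", flavor, " group: ",
                      paste(head(dup$gene_id, 5), collapse = ", "))
  }
  n_total <- length(species_cols)
  need <- ceiling(min_species_frac * n_total)
  coverage <- long |>
    group_by(.data$group_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species), .groups = "drop")
  keep <- coverage$group_id[coverage$n_species >= need]
  dropped <- nrow(coverage) - length(keep)
  if (dropped > 0) {
    inform_stage("read_orthogroups: dropped ", dropped, " of ", nrow(coverage),
                 " groups spanning < ", need, "/", n_total, " species")
  }
  out <- filter(long, .data$group_id %in% keep)
  new_ortho_map(out, flavor, species_cols, node)
}

new_ortho_map <- function(tbl, flavor, species_set, node = NULL) {
  tbl <- as_tibble(tbl)
  attr(tbl, "flavor") <- flavor
  attr(tbl, "species_set") <- species_set
  if (flavor == "hierarchical") attr(tbl, "node") <- node
  tbl
}

ortho_flavor <- function(map) attr(map, "flavor") %||% NA_character_

#' Read an external convergence-statistic table
#'
#' Convergence statistics (the protein convergence rate omega_C and the count
#' of amino-acid-changing convergent substitutions O_C^N per branch pair) are
#' computed by external phylogenetic software and consumed here as a table.
#'
#' @param path TSV with columns `group_id`, `branch_pair`, `omega_c`, `ocn`.
#' @return A tibble with those four columns.
#' @export
read_convergence <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  miss <- setdiff(c("group_id", "branch_pair", "omega_c", "ocn"), names(tbl))
  if (length(miss)) {
    abort_format("convergence table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(tbl$omega_c)) || any(!is.finite(tbl$ocn)) ||
      any(tbl$omega_c < 0) || any(tbl$ocn < 0)) {
    abort_format("omega_c and ocn must be finite and non-negative")
  }
  as_tibble(tbl[c("group_id", "branch_pair", "omega_c", "ocn")])
}
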