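#' Select candidate orthogroups for convergence testing
#'
#' A (nonhierarchical) orthogroup qualifies when it contains, from each of the
#' two focal species, at least one gene that is either upregulated in a
#' configured gland tissue (FDR < `fdr_threshold` and log2 fold change
#' strictly greater than `lfc_min` — upregulation only) or assigned to a
#' configured gland-specific SOM cluster.
#'
#' @param deg_a,deg_b DEG tibbles (`gene_id`, `tissue`, `log2fc`, `fdr`) for
#'   the two species.
#' @param assign_a,assign_b SOM assignment tibbles (`gene_id`, `unit`) or
#'   `som_model` objects.
#' @param ortho_map Nonhierarchical orthogroup map covering both species.
#' @param species_a,species_b Species ids as used in `ortho_map`.
#' @param gland_tissues_a,gland_tissues_b Gland-bearing tissue labels per
#'   species (DEG route).
#' @param gland_clusters_a,gland_clusters_b Gland-specific SOM unit ids per
#'   species (cluster route); may be empty.
#' @param fdr_threshold FDR cutoff (strict `<`, default 0.05).
#' @param lfc_min log2 fold-change cutoff (strict `>`, default 1).
#' @return Sorted character vector of qualifying orthogroup ids.
#' @export
select_candidate_orthogroups <- function(deg_a, deg_b, assign_a, assign_b,
                                         ortho_map, species_a, species_b,
                                         gland_tissues_a, gland_tissues_b,
                                         gland_clusters_a = integer(0),
                                         gland_clusters_b = integer(0),
                                         fdr_threshold = 0.05, lfc_min = 1) {
  to_assign <- function(a) {
    if (inherits(a, "som_model")) a$assignment else as_tibble(a)
  }
  assign_a <- to_assign(assign_a)
  assign_b <- to_assign(assign_b)
  check_clusters <- function(cl, assign, label) {
    bad <- setdiff(cl, unique(assign$unit))
    if (length(bad)) {
      abort_config("configured cluster id(s) absent from SOM ", label, ": ",
                   paste(bad, collapse = ", "))
    }
  }
  check_clusters(gland_clusters_a, assign_a, "A")
  check_clusters(gland_clusters_b, assign_b, "B")

  qualifying <- function(deg, assign, tissues, clusters) {
    de_genes <- deg |>
      filter(.data$tissue %in% tissues, .data$fdr < fdr_threshold,
             .data$log2fc > lfc_min) |>
      pull("gene_id")
    cl_genes <- assign$gene_id[assign$unit %in% clusters]
    unique(c(de_genes, cl_genes))
  }
  qual_a <- qualifying(deg_a, assign_a, gland_tissues_a, gland_clusters_a)
  qual_b <- qualifying(deg_b, assign_b, gland_tissues_b, gland_clusters_b)

  map <- as_tibble(ortho_map)
  groups_a <- unique(map$group_id[map$species == species_a & map$gene_id %in% qual_a])
  groups_b <- unique(map$group_id[map$species == species_b & map$gene_id %in% qual_b])
  sort(intersect(groups_a, groups_b))
}

#' Filter convergence records on substitution count and rate thresholds
#'
#' Keeps branch pairs whose number of amino-acid-changing convergent
#' substitutions and protein convergence rate both strictly exceed their
#' thresholds.
#'
#' @param records Tibble with columns `group_id`, `branch_pair`, `omega_c`,
#'   `ocn` (see [read_convergence()]).
#' @param omega_min Threshold on the protein convergence rate (strict `>`,
#'   default 3.0).
#' @param ocn_min Threshold on the convergent substitution count (strict `>`,
#'   default 3.0).
#' @return The surviving rows, with attributes `n_branch_pairs` and
#'   `n_orthogroups`.
#' @export
filter_convergence <- function(records, omega_min = 3.0, ocn_min = 3.0) {
  records <- as_tibble(records)
  miss <- setdiff(c("group_id", "branch_pair", "omega_c", "ocn"), names(records))
  if (length(miss)) {
    abort_format("convergence records lack field(s): ", paste(miss, collapse = ", "))
  }
  out <- filter(records, .data$omega_c > omega_min, .data$ocn > ocn_min)
  attr(out, "n_branch_pairs") <- nrow(out)
  attr(out, "n_orthogroups") <- dplyr::n_distinct(out$group_id)
  inform_stage("filter_convergence: ", nrow(out), " branch pair(s) in ",
               dplyr::n_distinct(out$group_id), " orthogroup(s) survive")
  out
}
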