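#' Orthogroup-level feeding-response classification
#'
#' Lifts per-gene DEG calls to orthogroup level by majority vote: member genes
#' with status `up` or `down` vote, `ns` members abstain. The call is `up`
#' when up-voters outnumber down-voters, `down` in the opposite case,
#' `conflict` on a non-empty tie, and `none` when no member votes.
#'
#' @param deg DEG tibble (`gene_id`, `tissue`, `status`) for one species.
#' @param ortho_map Long orthogroup map (`group_id`, `species`, `gene_id`),
#'   hierarchical flavor.
#' @param species Species whose genes to classify.
#' @param tissue Tissue whose DEG calls to use.
#' @param missing_genes `"warn"` (count mapped genes absent from the DEG table
#'   as `ns`) or `"error"`.
#' @return A tibble `group_id`, `species`, `tissue`, `n_up`, `n_down`, `n_ns`,
#'   `call`, one row per orthogroup containing at least one gene of the
#'   species (the tissue's testable universe).
#' @export
classify_orthogroup_response <- function(deg, ortho_map, species, tissue,
                                         missing_genes = c("warn", "error")) {
  missing_genes <- match.arg(missing_genes)
  members <- ortho_map |>
    filter(.data$species == !!species) |>
    distinct(.data$group_id, .data$gene_id)
  deg_t <- deg |> filter(.data$tissue == !!tissue) |> select("gene_id", "status")
  joined <- left_join(members, deg_t, by = "gene_id")
  n_missing <- sum(is.na(joined$status))
  if (n_missing > 0) {
    if (missing_genes == "error") {
      abort_consistency(n_missing, " mapped gene(s) absent from the DEG table")
    }
    warn(paste0(n_missing, " mapped gene(s) absent from the DEG table; counted as ns"))
    joined$status[is.na(joined$status)] <- "ns"
  }
  joined |>
    group_by(.data$group_id) |>
    summarise(n_up = sum(.data$status == "up"),
              n_down = sum(.data$status == "down"),
              n_ns = sum(.data$status == "ns"), .groups = "drop") |>
    mutate(species = !!species, tissue = !!tissue,
           call = vote_call(.data$n_up, .data$n_down)) |>
    select("group_id", "species", "tissue", "n_up", "n_down", "n_ns", "call")
}

vote_call <- function(n_up, n_down) {
  dplyr::case_when(
    n_up == 0 & n_down == 0 ~ "none",
    n_up > n_down ~ "up",
    n_down > n_up ~ "down",
    .default = "conflict"
  )
}

#' Cross-species consistent orthogroup sets
#'
#' Orthogroups called `up` in both (species A, tissue A) and (species B,
#' tissue B) form the shared-up set; analogously for `down`. Groups called
#' `conflict` or `none` in either species are never shared.
#'
#' @param resp_a,resp_b Response tibbles from
#'   [classify_orthogroup_response()].
#' @param tissue_a,tissue_b Tissues to compare.
#' @return A list with character vectors `shared_up` and `shared_down`.
#' @export
consistent_sets <- function(resp_a, tissue_a, resp_b, tissue_b) {
  pick <- function(resp, tissue, call) {
    sort(unique(resp$group_id[resp$tissue == tissue & resp$call == call]))
  }
  list(
    shared_up = intersect(pick(resp_a, tissue_a, "up"), pick(resp_b, tissue_b, "up")),
    shared_down = intersect(pick(resp_a, tissue_a, "down"), pick(resp_b, tissue_b, "down"))
  )
}

#' Build the tissue-pair grid of orthogroup set pairs for similarity testing
#'
#' For every requested tissue pair and direction, extracts the two species'
#' called orthogroup sets and their universes (all orthogroups with at least
#' one gene tested in that tissue), in the form consumed by
#' [similarity_matrix()]. In the study configuration one species contributes a
#' single tissue (its digestive zone) compared against all tissues of the
#' other.
#'
#' @param resp_a,resp_b Response tibbles covering one or more tissues each.
#' @param tissues_a,tissues_b Tissue subsets (default: all tissues present).
#' @return A tibble with columns `tissue_a`, `tissue_b`, `direction`, and
#'   list-columns `set_a`, `set_b`, `universe_a`, `universe_b`.
#' @export
response_matrix <- function(resp_a, resp_b, tissues_a = NULL, tissues_b = NULL) {
  tissues_a <- tissues_a %||% unique(resp_a$tissue)
  tissues_b <- tissues_b %||% unique(resp_b$tissue)
  tidyr::expand_grid(tissue_a = tissues_a, tissue_b = tissues_b,
                     direction = c("up", "down")) |>
    mutate(
      set_a = purrr::map2(.data$tissue_a, .data$direction, function(t, d) {
        sort(unique(resp_a$group_id[resp_a$tissue == t & resp_a$call == d]))
      }),
      set_b = purrr::map2(.data$tissue_b, .data$direction, function(t, d) {
        sort(unique(resp_b$group_id[resp_b$tissue == t & resp_b$call == d]))
      }),
      universe_a = purrr::map(.data$tissue_a, function(t) {
        sort(unique(resp_a$group_id[resp_a$tissue == t]))
      }),
      universe_b = purrr::map(.data$tissue_b, function(t) {
        sort(unique(resp_b$group_id[resp_b$tissue == t]))
      })
    )
}
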