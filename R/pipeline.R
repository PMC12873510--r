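#' Configuration for the full cross-species comparison pipeline
#'
#' @param sim A [sim_config()] for the synthetic dataset.
#' @param seed Master seed; every stage derives its own sub-seed from it via
#'   [derive_seed()].
#' @param min_total Low-count filter threshold (total count across samples).
#' @param fdr_threshold,lfc_threshold DEG thresholds.
#' @param top_frac,min_fpkm High-CV gene selection parameters.
#' @param som_rows,som_cols,som_epochs SOM grid and training length.
#' @param n_perm Permutations per similarity test.
#' @param p_literal Use uncorrected Monte-Carlo p-values.
#' @param candidate_lfc_min Strict log2FC cutoff of the candidate-selection
#'   DEG route.
#' @param convergence Optional convergence-statistic table (tibble or TSV
#'   path) to filter.
#' @param omega_min,ocn_min Convergence filter thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1,
                            min_total = 1,
                            fdr_threshold = 0.05, lfc_threshold = 1.0,
                            top_frac = 0.10, min_fpkm = 1.0,
                            som_rows = 3, som_cols = 4, som_epochs = 100,
                            n_perm = 10000, p_literal = FALSE,
                            candidate_lfc_min = 1.0,
                            convergence = NULL,
                            omega_min = 3.0, ocn_min = 3.0) {
  cfg <- as.list(environment())
  if (!inherits(cfg$sim, "sim_config")) cfg$sim <- do.call(sim_config, cfg$sim)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic cross-species comparison
#'
#' Orchestrates every stage from one configuration: simulate the two-species
#' dataset, normalize (low-count filter, TMM, FPKM), test per-tissue
#' differential expression, classify orthogroup-level responses, compare the
#' first species' gland tissue against every tissue of the second with the
#' permutation Jaccard test (up- and down-matrices corrected separately),
#' cluster high-CV genes with a SOM per species, match clusters across
#' species, and screen candidate orthogroups for convergence testing. A
#' manifest records parameters, seeds, and per-stage record counts; rerunning
#' with the same configuration reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as deterministic TSVs via [write_results()].
#' @return A list: `data` (simulated input bundle), `species` (per-species
#'   normalization, DEG, gene-selection and SOM results), `responses`,
#'   `response_similarity`, `cluster_similarity`, `gland_clusters`,
#'   `candidates`, `convergence`, `manifest`.
#' @export
run_feeding_comparison <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  manifest <- list()
  note <- function(stage, key, value) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, key = key, value = as.character(value))
  }
  note("pipeline", "seed", cfg$seed)
  note("pipeline", "n_perm", cfg$n_perm)

  sim <- simulate_feeding_dataset(cfg$sim, seed = derive_seed(cfg$seed, "simulate"))
  species <- cfg$sim$species
  note("simulate", "species", paste(species, collapse = ","))
  note("simulate", "n_genes", cfg$sim$n_genes)

  per_species <- lapply(species, function(sp) {
    d <- sim$species[[sp]]
    counts <- filter_low_counts(d$counts, min_total = cfg$min_total)
    note("filter", paste0("n_genes_", sp), nrow(counts))
    factors <- tmm_norm_factors(counts)
    expr <- fpkm(counts, d$lengths, factors)
    expr_means <- condition_means(expr, d$samples)
    deg <- bind_rows(lapply(cfg$sim$tissues[[sp]], function(t) {
      test_de(counts, d$samples, t, factors,
              fdr_threshold = cfg$fdr_threshold, lfc_threshold = cfg$lfc_threshold)
    }))
    note("deg", paste0("n_deg_", sp),
         dplyr::n_distinct(deg$gene_id[deg$status != "ns"]))
    stats <- select_high_cv_genes(expr_means, top_frac = cfg$top_frac,
                                  min_fpkm = cfg$min_fpkm)
    note("select", paste0("n_selected_", sp), sum(stats$selected))
    z <- zscale_rows(expr_means |> filter(.data$gene_id %in%
                                            stats$gene_id[stats$selected]))
    som <- train_som(z, rows = cfg$som_rows, cols = cfg$som_cols,
                     epochs = cfg$som_epochs,
                     seed = derive_seed(cfg$seed, paste0("som_", sp)))
    list(counts = counts, factors = factors, fpkm = expr,
         expr_means = expr_means, deg = deg, gene_stats = stats, som = som)
  })
  names(per_species) <- species

  hier <- sim$orthogroups$hierarchical
  responses <- bind_rows(lapply(species, function(sp) {
    bind_rows(lapply(cfg$sim$tissues[[sp]], function(t) {
      classify_orthogroup_response(per_species[[sp]]$deg, hier, sp, t)
    }))
  }))
  note("ortho", "n_response_rows", nrow(responses))

  sp_a <- species[1]
  sp_b <- species[2]
  gland_a <- cfg$sim$gland_tissue[[sp_a]]
  grid <- response_matrix(
    responses |> filter(.data$species == sp_a),
    responses |> filter(.data$species == sp_b),
    tissues_a = gland_a, tissues_b = cfg$sim$tissues[[sp_b]])
  # BH family per direction matrix, matching the per-panel correction
  response_similarity <- bind_rows(lapply(c("up", "down"), function(d) {
    similarity_matrix(grid |> filter(.data$direction == d),
                      n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, paste0("setsim_deg_", d)),
                      p_literal = cfg$p_literal)
  }))
  note("setsim", "n_tissue_pairs", nrow(response_similarity))

  cluster_similarity <- match_clusters(
    per_species[[sp_a]]$som, per_species[[sp_b]]$som, hier,
    n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "setsim_som"))
  note("setsim", "n_cluster_pairs", nrow(cluster_similarity))

  gland_clusters <- lapply(species, function(sp) {
    detect_gland_clusters(per_species[[sp]]$som, cfg$sim$gland_tissue[[sp]])
  })
  names(gland_clusters) <- species
  note("screen", "gland_clusters",
       paste(vapply(species, function(sp) {
         paste0(sp, ":", paste(gland_clusters[[sp]], collapse = "/"))
       }, character(1)), collapse = " "))

  candidates <- select_candidate_orthogroups(
    per_species[[sp_a]]$deg, per_species[[sp_b]]$deg,
    per_species[[sp_a]]$som, per_species[[sp_b]]$som,
    sim$orthogroups$nonhierarchical, sp_a, sp_b,
    gland_tissues_a = gland_a, gland_tissues_b = cfg$sim$gland_tissue[[sp_b]],
    gland_clusters_a = gland_clusters[[sp_a]],
    gland_clusters_b = gland_clusters[[sp_b]],
    fdr_threshold = cfg$fdr_threshold, lfc_min = cfg$candidate_lfc_min)
  note("screen", "n_candidates", length(candidates))

  convergence <- NULL
  if (!is.null(cfg$convergence)) {
    records <- if (is.character(cfg$convergence)) {
      read_convergence(cfg$convergence)
    } else {
      as_tibble(cfg$convergence)
    }
    records <- filter(records, .data$group_id %in% candidates)
    convergence <- filter_convergence(records, cfg$omega_min, cfg$ocn_min)
    note("screen", "n_convergent_pairs", nrow(convergence))
  }

  manifest <- bind_rows(manifest)
  result <- list(data = sim, species = per_species, responses = responses,
                 response_similarity = response_similarity,
                 cluster_similarity = cluster_similarity,
                 gland_clusters = gland_clusters,
                 candidates = candidates, convergence = convergence,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    tables <- list(
      ortho_response = responses,
      setsim_deg = response_similarity |> select(-dplyr::where(is.list)),
      setsim_clusters = cluster_similarity,
      candidates = tibble(group_id = candidates),
      manifest = manifest
    )
    for (sp in species) {
      tables[[paste0("deg_", sp)]] <- per_species[[sp]]$deg
      tables[[paste0("som_assignments_", sp)]] <- per_species[[sp]]$som$assignment
    }
    if (!is.null(convergence)) tables$convergence <- convergence
    write_results(tables, out_dir)
  }
  result
}

#' Identify gland-specific SOM clusters
#'
#' A cluster is gland-specific when its mean z-profile peaks in the species'
#' gland-bearing tissue (in either condition).
#'
#' @param model A `som_model` trained on tissue-by-condition features named
#'   `tissue.condition`.
#' @param gland_tissue The species' gland tissue label.
#' @return Integer vector of unit ids.
#' @export
detect_gland_clusters <- function(model, gland_tissue) {
  prof <- cluster_profiles(model)
  peaks <- prof |>
    group_by(.data$unit) |>
    summarise(peak = as.character(.data$feature[which.max(.data$mean_z)]),
              .groups = "drop")
  tissue_of <- sub("\\.(control|fed)$", "", peaks$peak)
  sort(peaks$unit[tissue_of == gland_tissue])
}
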