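#' Configuration for the synthetic two-species feeding experiment
#'
#' Builds the configuration object for [simulate_feeding_dataset()]. The
#' defaults emulate the design of a tissue-specific feeding-treatment RNA-seq
#' experiment in two independently evolved pitcher plant lineages: six pitcher
#' tissues per species, 4 control and 8 fed replicates per tissue,
#' negative-binomial counts, planted feeding-response genes, and planted
#' tissue-specific expression modules shared between orthologous genes.
#'
#' Orthology structure: `frac_one_to_one` of each species' genes sit in 1:1
#' orthogroups, `frac_paralog` in 2:2 orthogroups, and the remainder in
#' species-specific singletons. A configurable fraction of 1:1 ortholog pairs
#' carries the same tissue-specific expression module in both species;
#' module-sharing and the shared feeding response are what the downstream
#' cross-species similarity statistics are expected to recover.
#'
#' @param n_genes Genes per species.
#' @param frac_one_to_one Fraction of genes in 1:1 orthogroups.
#' @param frac_paralog Fraction of genes in 2:2 orthogroups.
#' @param species Character vector of two species ids.
#' @param tissues Named list (per species) of six tissue labels.
#' @param gland_tissue Named character: the gland-bearing (digestive) tissue of
#'   each species, treated as functionally matched across species.
#' @param n_control,n_fed Replicates per (tissue, condition).
#' @param n_modules Number of tissue-specific expression module classes
#'   (default 12, matching the SOM grid).
#' @param module_frac Fraction of genes carrying a strong module profile.
#' @param shared_module_frac Probability that a 1:1 ortholog pair shares its
#'   module class across species.
#' @param module_amplitude Fold elevation of a module gene in its peak
#'   tissue(s).
#' @param de_frac Background fraction of genes planted as feeding-responsive
#'   per tissue (species-specific, random direction).
#' @param n_shared_up,n_shared_down Number of 1:1 orthogroups planted with a
#'   shared up-/downregulation response in the matched gland tissues.
#' @param n_conflict Number of 2:2 orthogroups planted with opposite-sign
#'   effects in their two paralogs (exercising the conflict call).
#' @param effect_range Range of planted |log2 effect| sizes.
#' @param dispersion_range Range of per-gene NB dispersions (log-uniform).
#' @param depth_range Range of per-sample relative sequencing depth factors.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean counts at unit depth.
#' @param responder_min_baseline Planted responsive genes have their baseline
#'   floored at this mean count (responders are expressed genes).
#' @param length_range Gene length range in bp (log-uniform).
#' @param merge_frac Fraction of hierarchical orthogroups merged pairwise into
#'   coarser nonhierarchical orthogroups.
#' @param profile_jitter_sdlog Log-normal sd of mild per-gene, per-tissue
#'   profile jitter applied to every gene.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       frac_one_to_one = 0.6,
                       frac_paralog = 0.15,
                       species = c("Ngra", "Cfol"),
                       tissues = list(
                         Ngra = c("lid", "peristome", "waxy_zone",
                                  "digestive_zone", "tendril", "flat_part"),
                         Cfol = c("lid", "neck_and_rim", "upper_pitcher_wall",
                                  "lower_pitcher_wall", "central_keel", "petiole")),
                       gland_tissue = c(Ngra = "digestive_zone",
                                        Cfol = "lower_pitcher_wall"),
                       n_control = 4,
                       n_fed = 8,
                       n_modules = 12,
                       module_frac = 0.15,
                       shared_module_frac = 0.8,
                       module_amplitude = 8,
                       de_frac = 0.03,
                       n_shared_up = 150,
                       n_shared_down = 75,
                       n_conflict = 20,
                       effect_range = c(1.5, 3),
                       dispersion_range = c(0.05, 0.3),
                       depth_range = c(0.7, 1.4),
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1.2,
                       responder_min_baseline = 25,
                       length_range = c(300, 10000),
                       merge_frac = 0.1,
                       profile_jitter_sdlog = 0.1) {
  cfg <- as.list(environment())
  if (length(cfg$species) != 2) abort_config("exactly two species are required")
  if (!setequal(names(cfg$tissues), cfg$species) ||
      !setequal(names(cfg$gland_tissue), cfg$species)) {
    abort_config("tissues and gland_tissue must be named by the two species")
  }
  for (sp in cfg$species) {
    if (!cfg$gland_tissue[[sp]] %in% cfg$tissues[[sp]]) {
      abort_config("gland_tissue must be one of the species' tissues")
    }
  }
  if (cfg$de_frac < 0 || cfg$de_frac > 1) abort_config("de_frac must lie in [0, 1]")
  if (cfg$n_control < 2 || cfg$n_fed < 2) {
    abort_config("at least 2 replicates per condition are required")
  }
  if (cfg$frac_one_to_one + cfg$frac_paralog > 1) {
    abort_config("frac_one_to_one + frac_paralog must be <= 1")
  }
  if (cfg$effect_range[1] <= 0) abort_config("minimum |log2 effect| must be > 0")
  if (any(cfg$dispersion_range <= 0)) abort_config("dispersions must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-species feeding-treatment count dataset with known truth
#'
#' Generates gene-level NB count matrices, sample metadata, gene lengths and
#' orthogroup maps (hierarchical and nonhierarchical flavors) for two species,
#' together with a ground-truth object describing every planted signal. Counts
#' are drawn as
#' `NB(mean = baseline * tissue_profile * condition_effect * depth, dispersion)`;
#' feeding effects are applied multiplicatively to the mean of fed samples in
#' the configured tissues only.
#'
#' The orthology/module/shared-response structure is drawn from a design
#' stream derived from the master seed; each species' quantitative data come
#' from its own stream, so adding or regenerating one species does not perturb
#' the other's counts.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer master seed.
#' @return A list with elements `species` (per species: `counts`, `samples`,
#'   `lengths`), `orthogroups` (`hierarchical`, `nonhierarchical` long maps),
#'   and `truth` (class `feeding_truth`).
#' @export
simulate_feeding_dataset <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  design <- withr::with_seed(derive_seed(seed, "design"), sim_design(cfg))
  species_data <- lapply(cfg$species, function(sp) {
    withr::with_seed(derive_seed(seed, paste0("species_", sp)),
                     sim_species(sp, cfg, design))
  })
  names(species_data) <- cfg$species

  genes <- bind_rows(lapply(species_data, `[[`, "gene_tbl"))
  effects <- bind_rows(lapply(species_data, `[[`, "effects"))
  sample_tbl <- bind_rows(lapply(species_data, `[[`, "samples"))
  truth <- structure(
    list(genes = genes, effects = effects, samples = sample_tbl,
         modules = design$modules, config = cfg, seed = seed,
         min_effect = cfg$effect_range[1]),
    class = "feeding_truth")

  hier <- new_ortho_map(
    genes |> select(group_id = "hog", "species", "gene_id") |>
      arrange(.data$group_id, .data$species, .data$gene_id),
    "hierarchical", cfg$species, node = "focal-MRCA")
  nonhier <- new_ortho_map(
    genes |> select(group_id = "og", "species", "gene_id") |>
      arrange(.data$group_id, .data$species, .data$gene_id),
    "nonhierarchical", cfg$species)

  list(
    species = lapply(species_data, function(d) {
      list(counts = d$counts, samples = d$samples, lengths = d$lengths)
    }),
    orthogroups = list(hierarchical = hier, nonhierarchical = nonhier),
    truth = truth
  )
}

# Cross-species design: orthogroup structure, module classes, shared planted
# response orthogroups. Uses the current RNG stream.
sim_design <- function(cfg) {
  n <- cfg$n_genes
  n11 <- round(cfg$frac_one_to_one * n)
  n22 <- round(cfg$frac_paralog * n / 2)
  n_single <- n - n11 - 2 * n22
  if (n_single < 0) abort_config("orthogroup fractions exceed the gene budget")
  n_og <- n11 + n22 + 2 * n_single
  hog_ids <- sprintf("N0.HOG%07d", seq_len(n_og))
  hog_class <- c(rep("one2one", n11), rep("two2two", n22),
                 rep("A_only", n_single), rep("B_only", n_single))

  # nonhierarchical flavor: merge a fraction of adjacent multi-species HOGs
  og_index <- seq_len(n_og)
  n_multi <- n11 + n22
  n_merge <- floor(cfg$merge_frac * n_multi / 2)
  if (n_merge > 0) {
    firsts <- sample(seq_len(n_multi - 1), n_merge)
    og_index[firsts + 1] <- og_index[firsts]
  }
  og_ids <- sprintf("OG%07d", match(og_index, sort(unique(og_index))))

  # module classes on 1:1 orthogroups
  n_carrier <- min(round(cfg$module_frac * n), n11)
  carrier_idx <- sort(sample(seq_len(n11), n_carrier))
  module_a <- rep(NA_integer_, n_og)
  module_b <- rep(NA_integer_, n_og)
  m <- sample.int(cfg$n_modules, n_carrier, replace = TRUE)
  module_a[carrier_idx] <- m
  shared <- runif(n_carrier) < cfg$shared_module_frac
  m_b <- m
  if (any(!shared) && cfg$n_modules > 1) {
    m_b[!shared] <- vapply(m[!shared], function(mm) {
      sample(setdiff(seq_len(cfg$n_modules), mm), 1)
    }, integer(1))
  }
  module_b[carrier_idx] <- m_b

  # shared feeding response in the matched gland tissues, planted on 1:1 groups
  free <- seq_len(n11)
  up_idx <- sort(sample(free, min(cfg$n_shared_up, length(free))))
  free <- setdiff(free, up_idx)
  down_idx <- sort(sample(free, min(cfg$n_shared_down, length(free))))
  conflict_idx <- if (n22 > 0 && cfg$n_conflict > 0) {
    sort(sample(n11 + seq_len(n22), min(cfg$n_conflict, n22)))
  } else integer(0)

  list(hog_ids = hog_ids, og_ids = og_ids, hog_class = hog_class,
       module_a = module_a, module_b = module_b,
       shared_up = up_idx, shared_down = down_idx, conflict = conflict_idx,
       modules = module_profile_classes(cfg))
}

# Module class m peaks in tissue m (m = 1..6) or in the tissue pair
# (m - 6, m - 5) (m = 7..12), by tissue index shared across species.
module_profile_classes <- function(cfg) {
  nt <- length(cfg$tissues[[1]])
  purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
    peak <- if (m <= nt) m else c((m - nt - 1) %% nt + 1, (m - nt) %% nt + 1)
    tibble(module = m, peak_tissue_index = list(sort(unique(peak))))
  })
}

# Per-species data generation. Uses the species' own RNG stream.
sim_species <- function(sp, cfg, design) {
  side <- if (sp == cfg$species[1]) "A" else "B"
  keep <- design$hog_class %in%
    c("one2one", "two2two", paste0(side, "_only"))
  hogs <- design$hog_ids[keep]
  ogs <- design$og_ids[keep]
  cls <- design$hog_class[keep]
  modules <- (if (side == "A") design$module_a else design$module_b)[keep]
  n_members <- ifelse(cls == "two2two", 2L, 1L)
  gene_hog <- rep(hogs, n_members)
  gene_og <- rep(ogs, n_members)
  gene_module <- rep(modules, n_members)
  member_rank <- unlist(lapply(n_members, seq_len), use.names = FALSE)
  n <- length(gene_hog)
  stopifnot(n == cfg$n_genes)
  gene_id <- sprintf("%s%05d", sp, seq_len(n))

  tiss <- cfg$tissues[[sp]]
  nt <- length(tiss)
  gland <- cfg$gland_tissue[[sp]]

  length_bp <- round(exp(runif(n, log(cfg$length_range[1]), log(cfg$length_range[2]))))
  baseline <- exp(rnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog))
  dispersion <- exp(runif(n, log(cfg$dispersion_range[1]), log(cfg$dispersion_range[2])))
  jitter <- matrix(exp(rnorm(n * nt, 0, cfg$profile_jitter_sdlog)), n, nt)

  # tissue profile: module peak amplitude in peak tissues, 1 elsewhere
  profile <- matrix(1, n, nt)
  carrier <- which(!is.na(gene_module))
  for (g in carrier) {
    pk <- design$modules$peak_tissue_index[[gene_module[g]]]
    profile[g, pk] <- cfg$module_amplitude
  }

  # planted effects: shared gland response, conflict paralogs, background DE
  hog_of <- match(gene_hog, design$hog_ids)
  eff_list <- list()
  plant <- function(genes, tissue, sign, label) {
    if (!length(genes)) return(NULL)
    tibble(species = sp, tissue = tissue, gene_id = gene_id[genes],
           log2_effect = sign * runif(length(genes), cfg$effect_range[1],
                                      cfg$effect_range[2]),
           origin = label)
  }
  shared_up_genes <- which(hog_of %in% design$shared_up)
  shared_down_genes <- which(hog_of %in% design$shared_down)
  eff_list$up <- plant(shared_up_genes, gland, +1, "shared_up")
  eff_list$down <- plant(shared_down_genes, gland, -1, "shared_down")
  confl_genes1 <- which(hog_of %in% design$conflict & member_rank == 1L)
  confl_genes2 <- which(hog_of %in% design$conflict & member_rank == 2L)
  eff_list$confl_up <- plant(confl_genes1, gland, +1, "conflict")
  eff_list$confl_down <- plant(confl_genes2, gland, -1, "conflict")

  planted_gland <- c(shared_up_genes, shared_down_genes, confl_genes1, confl_genes2)
  n_bg <- round(cfg$de_frac * n)
  for (t in tiss) {
    avoid <- if (t == gland) planted_gland else integer(0)
    pool <- setdiff(seq_len(n), avoid)
    if (n_bg == 0 || !length(pool)) next
    pick <- sort(sample(pool, min(n_bg, length(pool))))
    sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
    eff_list[[paste0("bg_", t)]] <-
      tibble(species = sp, tissue = t, gene_id = gene_id[pick],
             log2_effect = sgn * runif(length(pick), cfg$effect_range[1],
                                       cfg$effect_range[2]),
             origin = "background")
  }
  effects <- bind_rows(eff_list)
  if (nrow(effects)) {
    effects$direction <- ifelse(effects$log2_effect > 0, "up", "down")
    # responders are expressed genes: floor their baseline mean
    resp <- match(unique(effects$gene_id), gene_id)
    baseline[resp] <- pmax(baseline[resp], cfg$responder_min_baseline)
  } else {
    effects <- tibble(species = character(), tissue = character(),
                      gene_id = character(), log2_effect = numeric(),
                      origin = character(), direction = character())
  }

  # sample sheet
  samples <- tidyr::expand_grid(
    tissue = tiss,
    condition = c("control", "fed")) |>
    mutate(n_rep = ifelse(.data$condition == "control", cfg$n_control, cfg$n_fed)) |>
    mutate(replicate = purrr::map(.data$n_rep, seq_len)) |>
    tidyr::unnest("replicate") |>
    select(-"n_rep") |>
    mutate(species = sp,
           sample_id = paste(sp, .data$tissue, .data$condition,
                             paste0("r", .data$replicate), sep = ".")) |>
    select("sample_id", "species", "tissue", "condition", "replicate")
  samples$depth <- runif(nrow(samples), cfg$depth_range[1], cfg$depth_range[2])

  # mean matrix and NB draw
  t_idx <- match(samples$tissue, tiss)
  mu <- baseline * profile[, t_idx, drop = FALSE] * jitter[, t_idx, drop = FALSE]
  mu <- sweep(mu, 2, samples$depth, `*`)
  if (nrow(effects)) {
    fed <- samples$condition == "fed"
    eff_gene <- match(effects$gene_id, gene_id)
    for (k in seq_len(nrow(effects))) {
      cols <- which(fed & samples$tissue == effects$tissue[k])
      mu[eff_gene[k], cols] <- mu[eff_gene[k], cols] * 2^effects$log2_effect[k]
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / dispersion, ncol(mu))),
                   nrow(mu), ncol(mu))
  rownames(counts) <- gene_id
  colnames(counts) <- samples$sample_id

  list(
    counts = matrix_tbl(counts),
    samples = select(samples, -"depth"),
    lengths = tibble(gene_id = gene_id, length_bp = length_bp),
    gene_tbl = tibble(species = sp, gene_id = gene_id, hog = gene_hog,
                      og = gene_og, module = gene_module, baseline = baseline,
                      dispersion = dispersion, length_bp = length_bp),
    effects = select(effects, "species", "tissue", "gene_id",
                     "log2_effect", "direction", "origin"),
    samples_depth = samples
  )
}

#' Expected orthogroup-level response sets from the planted truth
#'
#' Derives the orthogroup sets expected to be called up or down in a given
#' (species, tissue) by applying the same majority rule as the pipeline to the
#' planted per-gene effects: planted-up and planted-down members vote,
#' unplanted members abstain; a strict majority decides, ties are conflicts
#' and belong to neither set.
#'
#' @param truth A `feeding_truth` object from [simulate_feeding_dataset()].
#' @param species Species id.
#' @param tissue Tissue label (must belong to the species' tissue list).
#' @return A list with character vectors `up` and `down` of hierarchical
#'   orthogroup ids.
#' @export
truth_sets <- function(truth, species, tissue) {
  stopifnot(inherits(truth, "feeding_truth"))
  if (!species %in% truth$config$species) abort_lookup("unknown species: ", species)
  if (!tissue %in% truth$config$tissues[[species]]) {
    abort_lookup("unknown tissue for ", species, ": ", tissue)
  }
  eff <- truth$effects |>
    filter(.data$species == !!species, .data$tissue == !!tissue) |>
    inner_join(truth$genes |> select("gene_id", "hog"), by = "gene_id")
  tall <- eff |>
    group_by(.data$hog) |>
    summarise(n_up = sum(.data$direction == "up"),
              n_down = sum(.data$direction == "down"), .groups = "drop")
  list(up = sort(tall$hog[tall$n_up > tall$n_down]),
       down = sort(tall$hog[tall$n_down > tall$n_up]))
}
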