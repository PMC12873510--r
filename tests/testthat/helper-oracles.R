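# Independent oracles and small fixture builders shared across tests.
# Each oracle is a direct transcription of the defining formula or an
# exhaustive enumeration, kept separate from the package implementation.

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Welch's t statistic, Satterthwaite df, two-sided p.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive permutation-null p: all pairs of same-size subsets of the two
# universes are equally likely under the random-bijection null.
enum_perm_p <- function(set_a, set_b, universe_a, universe_b) {
  jc <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  jc_obs <- jc(set_a, set_b)
  subs_a <- if (length(set_a)) combn(universe_a, length(set_a), simplify = FALSE) else list(character(0))
  subs_b <- if (length(set_b)) combn(universe_b, length(set_b), simplify = FALSE) else list(character(0))
  hits <- 0
  total <- 0
  for (sa in subs_a) {
    for (sb in subs_b) {
      total <- total + 1
      if (jc(sa, sb) >= jc_obs) hits <- hits + 1
    }
  }
  hits / total
}

# Exhaustive majority-vote call over a status multiset.
vote_oracle <- function(statuses) {
  n_up <- sum(statuses == "up")
  n_down <- sum(statuses == "down")
  if (n_up == 0 && n_down == 0) return("none")
  if (n_up > n_down) return("up")
  if (n_down > n_up) return("down")
  "conflict"
}

# Small deterministic count fixture: genes x samples Poisson-like table.
toy_counts <- function(n_genes, n_samples, seed = 1, lambda = 100) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
    rownames(m) <- sprintf("g%03d", seq_len(n_genes))
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    m
  })
}

as_count_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# One-tissue sample sheet with n_ctl control and n_fed fed replicates.
one_tissue_samples <- function(n_ctl = 4, n_fed = 8, tissue = "gland",
                               species = "sp") {
  tibble::tibble(
    sample_id = c(sprintf("c%d", seq_len(n_ctl)), sprintf("f%d", seq_len(n_fed))),
    species = species, tissue = tissue,
    condition = rep(c("control", "fed"), c(n_ctl, n_fed)),
    replicate = c(seq_len(n_ctl), seq_len(n_fed)))
}

# NB counts for one tissue with optional planted log2 effects on fed samples.
sim_tissue_counts <- function(n_genes, mu, dispersion, samples,
                              lfc = NULL, seed = 1) {
  withr::with_seed(seed, {
    mu_mat <- matrix(mu, n_genes, nrow(samples))
    if (!is.null(lfc)) {
      fed <- samples$condition == "fed"
      mu_mat[, fed] <- mu_mat[, fed] * 2^lfc
    }
    m <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / dispersion),
                n_genes, nrow(samples))
    rownames(m) <- sprintf("g%04d", seq_len(n_genes))
    colnames(m) <- samples$sample_id
    m
  })
}

suppress_logs <- function(expr) {
  withCallingHandlers(expr,
    pitchercomp_log = function(c) invokeRestart("muffleMessage"))
}
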