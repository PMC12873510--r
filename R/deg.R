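#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, `q_(i) = min_{j >= i} p_(j) n / j`
#' capped at 1, computed via [stats::p.adjust()]. Input order is preserved in
#' the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort_domain("p-values must be numeric")
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort_domain("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential-expression status
#'
#' `up` when `fdr < fdr_threshold` and `log2fc >= lfc_threshold`; `down` when
#' `fdr < fdr_threshold` and `log2fc <= -lfc_threshold`; otherwise `ns`.
#' The FDR cut is strict (`<`), the fold-change cut inclusive (`>=`).
#'
#' @param log2fc,fdr Numeric vectors.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1.0).
#' @return Character vector `"up"`/`"down"`/`"ns"`.
#' @export
classify_deg <- function(log2fc, fdr, fdr_threshold = 0.05, lfc_threshold = 1.0) {
  dplyr::case_when(
    fdr < fdr_threshold & log2fc >= lfc_threshold ~ "up",
    fdr < fdr_threshold & log2fc <= -lfc_threshold ~ "down",
    .default = "ns"
  )
}

#' Estimate per-gene negative-binomial dispersions for one tissue
#'
#' Method-of-moments dispersion from within-condition residuals of
#' depth-normalized counts, pooled over the two conditions, then shrunk toward
#' the trimmed-mean common dispersion with weight proportional to the residual
#' degrees of freedom (prior weight `prior_df`), and floored at `1e-4`.
#'
#' @param counts Count table.
#' @param samples Sample metadata.
#' @param tissue Tissue to analyse.
#' @param factors Optional TMM factor tibble; unit factors if `NULL`.
#' @param prior_df Prior weight of the common dispersion (default 20).
#' @return A tibble `gene_id`, `dispersion_raw`, `dispersion`, `df`, with the
#'   common dispersion as attribute `common_dispersion`.
#' @export
estimate_dispersion <- function(counts, samples, tissue, factors = NULL,
                                prior_df = 20) {
  prep <- prep_tissue(counts, samples, tissue, factors)
  y <- prep$y
  norm <- sweep(y, 2, prep$rel_size, `/`) # depth-normalized counts
  cond <- prep$cond
  phi_num <- 0
  phi_den <- 0
  for (cc in c("control", "fed")) {
    idx <- which(cond == cc)
    nc <- length(idx)
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    phi_num <- phi_num + (nc - 1) * (v - m)
    phi_den <- phi_den + (nc - 1) * m^2
  }
  raw <- ifelse(phi_den > 0, pmax(phi_num / phi_den, 0), 0)
  df <- ncol(y) - 2
  common <- mean(raw[phi_den > 0], trim = 0.25)
  if (!is.finite(common)) common <- 0
  shrunk <- pmax((df * raw + prior_df * common) / (df + prior_df), 1e-4)
  out <- tibble(gene_id = rownames(y), dispersion_raw = unname(raw),
                dispersion = unname(shrunk), df = df)
  attr(out, "common_dispersion") <- common
  out
}

#' Per-tissue negative-binomial differential expression test
#'
#' For each gene, compares fed against control samples of one tissue with a
#' likelihood-ratio test of equal NB means (chi-squared, 1 df), holding the
#' dispersion fixed at the shrunken estimate from [estimate_dispersion()] and
#' using log effective library sizes (column sum times TMM factor) as offsets.
#' The reported `log2fc` is
#' `log2((mean fed normalized count + c) / (mean control normalized count + c))`
#' with pseudo-count `c = 0.5`, where normalized counts are counts per million
#' effective library (a depth-invariant scale). FDR is Benjamini-Hochberg over the tissue's
#' tested genes; `status` follows [classify_deg()].
#'
#' @inheritParams estimate_dispersion
#' @param fdr_threshold,lfc_threshold Thresholds for [classify_deg()].
#' @param pseudo Pseudo-count on normalized means (default 0.5).
#' @param dispersion Optional precomputed dispersion tibble.
#' @return A tibble `gene_id`, `tissue`, `log2fc`, `pvalue`, `fdr`, `status`.
#' @export
test_de <- function(counts, samples, tissue, factors = NULL,
                    fdr_threshold = 0.05, lfc_threshold = 1.0,
                    pseudo = 0.5, dispersion = NULL) {
  prep <- prep_tissue(counts, samples, tissue, factors)
  y <- prep$y
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, samples, tissue, factors)
  }
  phi <- dispersion$dispersion[match(rownames(y), dispersion$gene_id)]
  if (anyNA(phi)) abort_lookup("dispersion estimates missing for some genes")
  offset <- log(prep$eff_lib)
  fed <- prep$cond == "fed"

  fit0 <- nb_fit_mean(y, offset, phi)
  fit_c <- nb_fit_mean(y[, !fed, drop = FALSE], offset[!fed], phi)
  fit_f <- nb_fit_mean(y[, fed, drop = FALSE], offset[fed], phi)
  lrt <- pmax(2 * (fit_c$loglik + fit_f$loglik - fit0$loglik), 0)
  pval <- pchisq(lrt, df = 1, lower.tail = FALSE)

  # normalized counts per million effective library: depth-invariant scale
  norm <- sweep(y, 2, prep$eff_lib / 1e6, `/`)
  m_ctl <- rowMeans(norm[, !fed, drop = FALSE])
  m_fed <- rowMeans(norm[, fed, drop = FALSE])
  log2fc <- log2((m_fed + pseudo) / (m_ctl + pseudo))
  fdr <- bh_adjust(pval)
  tibble(gene_id = rownames(y), tissue = tissue,
         log2fc = unname(log2fc), pvalue = unname(pval), fdr = unname(fdr),
         status = classify_deg(log2fc, fdr, fdr_threshold, lfc_threshold))
}

# Shared preparation: subset one tissue, check the design, compute effective
# library sizes (full-matrix column sums x TMM factor) and relative sizes.
prep_tissue <- function(counts, samples, tissue, factors) {
  x <- count_matrix(counts)
  samples <- check_samples(samples)
  x <- align_counts_samples(x, samples)
  if (!tissue %in% samples$tissue) abort_lookup("unknown tissue: ", tissue)
  lib <- colSums(x)
  f <- rep(1, ncol(x))
  if (!is.null(factors)) {
    f <- factors$tmm_factor[match(colnames(x), factors$sample_id)]
    if (anyNA(f)) abort_lookup("missing TMM factor for some samples")
  }
  eff_lib_all <- lib * f
  idx <- which(samples$tissue == tissue)
  cond <- samples$condition[idx]
  if (sum(cond == "control") < 2 || sum(cond == "fed") < 2) {
    abort(paste0("need >= 2 replicates per condition in tissue ", tissue),
          class = "pitchercomp_estimation_error")
  }
  eff_lib <- eff_lib_all[idx]
  list(y = x[, idx, drop = FALSE], cond = cond,
       eff_lib = eff_lib, rel_size = eff_lib / mean(eff_lib))
}

# Vectorized single-mean NB fit with fixed dispersion and offsets.
# Model: y_gj ~ NB(mu_gj, phi_g), log mu_gj = beta_g + offset_j.
# Fisher scoring on beta_g, all genes simultaneously.
nb_fit_mean <- function(y, offset, phi, max_iter = 50, tol = 1e-12) {
  eo <- exp(offset)
  tot <- rowSums(y)
  beta <- log((tot + 0.1) / sum(eo))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% eo
    w <- 1 + phi * mu
    score <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 5), -5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% eo
  ll <- rowSums(dnbinom(y, size = rep(1 / phi, ncol(y)), mu = mu, log = TRUE))
  # all-zero genes: the likelihood limit as mu -> 0 is 1
  ll[tot == 0] <- 0
  beta[tot == 0] <- -Inf
  list(beta = beta, loglik = ll)
}
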