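#' PCA overview of expression samples
#'
#' Principal component analysis with samples as observations and genes as
#' features (the standard overview of a differential-expression experiment).
#' Features are centered; scaling is off by default.
#'
#' @param expr Tibble `gene_id` plus one column per sample (genes x samples);
#'   transposed internally so samples are observations.
#' @param samples Optional sample metadata joined onto the scores.
#' @param scale. Scale genes to unit variance before PCA (default `FALSE`).
#' @return An object of class `pca_overview` with `scores` (tibble: sample_id,
#'   PCs, metadata) and `var_explained` (tibble: component, variance fraction).
#' @export
pca_overview <- function(expr, samples = NULL, scale. = FALSE) {
  x <- count_matrix(expr, what = "expression")
  if (ncol(x) < 2) {
    abort("PCA needs at least 2 samples", class = "pitchercomp_dimension_error")
  }
  keep <- apply(x, 1, sd) > 0 | !scale.
  fit <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = scale.)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, .name_repair = "minimal") |>
    mutate(sample_id = colnames(x), .before = 1)
  if (!is.null(samples)) {
    scores <- left_join(scores, as_tibble(samples), by = "sample_id")
  }
  structure(
    list(scores = scores,
         var_explained = tibble(component = paste0("PC", seq_along(vf)),
                                fraction = vf),
         fit = fit),
    class = "pca_overview")
}

#' @export
print.pca_overview <- function(x, ...) {
  cat("PCA overview:", nrow(x$scores), "samples,",
      nrow(x$var_explained), "components\n")
  pc12 <- round(100 * x$var_explained$fraction[1:min(2, nrow(x$var_explained))], 1)
  cat("  variance explained:", paste0("PC", seq_along(pc12), " = ", pc12, "%",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_overview
#' @param x A `pca_overview` object.
#' @param ... Unused.
#' @export
tidy.pca_overview <- function(x, ...) {
  x$scores
}

#' @rdname pca_overview
#' @export
glance.pca_overview <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = nrow(x$var_explained),
         pc1_fraction = x$var_explained$fraction[1],
         pc2_fraction = if (nrow(x$var_explained) > 1) x$var_explained$fraction[2] else NA_real_)
}

#' @rdname pca_overview
#' @param object A `pca_overview` object.
#' @param colour_by,shape_by Optional metadata column names mapped to colour
#'   and shape.
#' @export
autoplot.pca_overview <- function(object, colour_by = NULL, shape_by = NULL, ...) {
  vf <- round(100 * object$var_explained$fraction[1:2], 1)
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  aes_extra <- list()
  if (!is.null(colour_by)) aes_extra$colour <- rlang::sym(colour_by)
  if (!is.null(shape_by)) aes_extra$shape <- rlang::sym(shape_by)
  p + ggplot2::geom_point(ggplot2::aes(!!!aes_extra), size = 2) +
    ggplot2::labs(x = paste0("PC1 (", vf[1], "%)"),
                  y = paste0("PC2 (", vf[2], "%)")) +
    ggplot2::theme_minimal()
}
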