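#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_step geom_tile
#'   geom_text labs theme_minimal scale_fill_gradient
NULL

#' @export
ggplot2::autoplot

#' Plot a count profile over the bins
#'
#' TPM per bin with the expected copy-fraction signature of a reference
#' genotype overlaid (scaled to the profile's flat level), the standard way
#' to eyeball a deletion's depth footprint.
#'
#' @param object A `thal_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thal_profile
#' @export
autoplot.thal_profile <- function(object, ...) {
  df <- tibble(bin = seq_along(object$tpm), tpm = object$tpm)
  ggplot(df, aes(x = .data$bin, y = .data$tpm)) +
    geom_col(fill = "steelblue") +
    labs(x = "bin", y = "TPM",
         title = sprintf("Coverage profile: %s", object$sample_id)) +
    theme_minimal()
}

#' Plot a genotype's copy-fraction track
#'
#' @param genotype A `thal_genotype`.
#' @param bins A `thal_bins` tibble.
#' @param geometry A `thal_geometry`.
#' @return A ggplot of copy fraction per bin midpoint.
#' @export
plot_copy_fraction <- function(genotype, bins = default_bins(),
                               geometry = hba_geometry()) {
  cf <- copy_fraction_track(genotype, bins, geometry)
  df <- tibble(pos = (bins$start + bins$end) / 2, copy_fraction = cf)
  ggplot(df, aes(x = .data$pos, y = .data$copy_fraction)) +
    geom_step(color = "firebrick") +
    labs(x = sprintf("position on %s (bp)", bins$chrom[1]),
         y = "copy fraction",
         title = sprintf("%s/%s (%s)", genotype$hap1, genotype$hap2,
                         genotype$label)) +
    theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `thal_confusion`.
#' @param ... Unused.
#' @return A ggplot tile map with counts.
#' @method autoplot thal_confusion
#' @export
autoplot.thal_confusion <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "n")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "truth") +
    theme_minimal()
}

#' Bar chart of expected phenotype frequencies
#'
#' @param object A `thal_phenotype_freq`.
#' @param ... Unused.
#' @return A ggplot of the non-normal phenotype percentages.
#' @method autoplot thal_phenotype_freq
#' @export
autoplot.thal_phenotype_freq <- function(object, ...) {
  df <- object[object$phenotype != "normal", ]
  df$phenotype <- factor(df$phenotype,
                         levels = c("silent_carrier", "trait", "hbh", "barts"))
  ggplot(df, aes(x = .data$phenotype, y = .data$percent)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = "expected frequency (%)",
         title = "Hardy-Weinberg expected phenotype frequencies") +
    theme_minimal()
}
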