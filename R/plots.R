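#' Plot the mean coverage profile around peak summits
#' @param profile A `summit_profile` from [summit_profile()].
#' @return A ggplot object.
#' @export
plot_summit_profile <- function(profile) {
  df <- tibble(position = profile$bin_mid, signal = profile$mean_profile)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::labs(x = "distance from summit (bp)", y = "mean coverage per bin") +
    ggplot2::theme_minimal()
}

#' Plot the peak-to-TSS distance distribution
#' @param stats A `tss_distance_stats` object.
#' @param binwidth Histogram bin width in bp.
#' @param max_bp Clip distances beyond this for display.
#' @return A ggplot object.
#' @export
plot_tss_distances <- function(stats, binwidth = 1000, max_bp = 1e5) {
  df <- stats$distances |>
    filter(!is.na(.data$distance)) |>
    mutate(distance = pmin(pmax(.data$distance, -max_bp), max_bp))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#41ab5d") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "signed distance to closest TSS (bp; negative = upstream)",
                  y = "peaks") +
    ggplot2::theme_minimal()
}

#' Plot the enhancers-per-gene histogram
#' @param assignments [annotate_enhancers()] output.
#' @return A ggplot object.
#' @export
plot_enhancers_per_gene <- function(assignments) {
  h <- enhancers_per_gene(assignments)$histogram
  ggplot2::ggplot(h, ggplot2::aes(factor(.data$n_regions), .data$n_genes)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::labs(x = "regulatory regions assigned to the gene", y = "genes") +
    ggplot2::theme_minimal()
}

#' Box plot of interaction frequency by bin class
#' @param bins Output of [classify_bins()].
#' @param bait_chrom Optional bait chromosome to exclude (cis bins).
#' @return A ggplot object.
#' @export
plot_contact_classes <- function(bins, bait_chrom = NULL) {
  if (!is.null(bait_chrom)) bins <- bins |> filter(.data$chrom != bait_chrom)
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin_class, .data$frequency)) +
    ggplot2::geom_boxplot(fill = "#fec44f", outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "interaction frequency (reads/bin per 1000)") +
    ggplot2::theme_minimal()
}
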