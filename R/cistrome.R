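#' Overlap two peak sets
#'
#' Reports every pair of peaks sharing at least `min_overlap_bp` bases
#' (half-open intervals: abutting peaks do not overlap) together with
#' Venn-style counts. The intersection count is taken on `a`'s side: an
#' `a`-peak overlapping one or more `b`-peaks counts once.
#'
#' @param a,b Peak tibbles (`chrom`, `start`, `end`, optionally `name`).
#' @param min_overlap_bp Minimum shared bases for a pair.
#' @return A list of class `overlap_report`: `pairs` (tibble with `a_idx`,
#'   `b_idx`, `a_name`, `b_name`, `overlap_bp`) and `venn`
#'   (`a_only`, `b_only`, `a_and_b`).
#' @export
overlap_peaks <- function(a, b, min_overlap_bp = 1) {
  check_intervals(a, "peak (a)"); check_intervals(b, "peak (b)")
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(a), intervals_to_gr(b),
                                      minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  pairs <- tibble(
    a_idx = ai, b_idx = bi,
    a_name = (a$name %||% paste0("a_", seq_len(nrow(a))))[ai],
    b_name = (b$name %||% paste0("b_", seq_len(nrow(b))))[bi],
    overlap_bp = ov
  )
  structure(list(
    pairs = pairs,
    venn = c(a_only = nrow(a) - length(unique(ai)),
             b_only = nrow(b) - length(unique(bi)),
             a_and_b = length(unique(ai)))
  ), class = "overlap_report")
}

#' @exportS3Method base::print
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> pairs:", nrow(x$pairs),
      "| a_only:", x$venn[["a_only"]],
      "b_only:", x$venn[["b_only"]],
      "a_and_b:", x$venn[["a_and_b"]], "\n")
  invisible(x)
}

#' Classify binding sites by nascent-transcription activity
#'
#' A peak is GRO-positive when it overlaps (by at least one base) a
#' divergent initiation site, i.e. the bound region itself produces
#' divergent nascent transcripts; otherwise it is GRO-negative. The
#' partition is exhaustive and exclusive. When a peak overlaps several
#' sites, the largest-overlap one (ties: leftmost) is recorded as
#' `site_id`.
#'
#' @param peaks Peak tibble.
#' @param sites Divergent-site tibble from [detect_divergent_sites()].
#' @return `peaks` with added `gro_class` (`"positive"`/`"negative"`) and
#'   `site_id` (`NA` for negative peaks).
#' @export
classify_by_gro <- function(peaks, sites) {
  check_intervals(peaks, "peak")
  out <- peaks |> mutate(gro_class = "negative", site_id = NA_character_)
  if (nrow(sites) == 0 || nrow(peaks) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(peaks), intervals_to_gr(sites),
                                      ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(peaks$end[qi], sites$end[si]) - pmax(peaks$start[qi], sites$start[si])
    best <- tibble(qi = qi, si = si, ov = ov, pos = sites$start[si]) |>
      group_by(.data$qi) |>
      arrange(desc(.data$ov), .data$pos, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    out$gro_class[best$qi] <- "positive"
    out$site_id[best$qi] <- sites$site_id[best$si]
  }
  stopifnot(sum(out$gro_class == "positive") + sum(out$gro_class == "negative") == nrow(out))
  out
}

#' Coverage profile around peak summits
#'
#' Bins total (both-strand) coverage in a fixed window centred on each
#' peak's summit. Row `i` of the matrix is the binned signal in
#' `[summit - window/2, summit + window/2)`; bins beyond the chromosome end
#' contribute 0. The mean profile is the column mean.
#'
#' @param peaks Peak tibble with `summit` offsets (midpoint used when the
#'   column is absent).
#' @param cov A [stranded_coverage()].
#' @param window_bp Window width (must be a multiple of `bin_bp`).
#' @param bin_bp Bin width.
#' @return A list of class `summit_profile`: `matrix` (peaks x bins),
#'   `mean_profile`, `bin_mid` (bin centre offsets relative to the summit).
#' @export
summit_profile <- function(peaks, cov, window_bp = 3000, bin_bp = 25) {
  check_intervals(peaks, "peak")
  if (window_bp %% bin_bp != 0) abort_validation("window_bp must be a multiple of bin_bp")
  nb <- window_bp %/% bin_bp
  summit_abs <- peaks$start +
    (peaks$summit %||% (midpoint0(peaks$start, peaks$end) - peaks$start))
  mat <- matrix(0, nrow(peaks), nb)
  for (chr in unique(peaks$chrom)) {
    i <- which(peaks$chrom == chr)
    size <- cov$chrom_sizes[[chr]]
    if (is.null(size) || is.na(size)) abort_validation(paste0("unknown chromosome ", chr))
    cs <- cumsum(cov$plus[[chr]] + cov$minus[[chr]])
    seg <- function(s, e) {
      s <- pmin(pmax(s, 0), size); e <- pmin(pmax(e, 0), size)
      ifelse(e > 0, cs[pmax(e, 1)], 0) - ifelse(s > 0, cs[pmax(s, 1)], 0)
    }
    for (k in seq_len(nb)) {
      s <- summit_abs[i] - window_bp %/% 2 + (k - 1L) * bin_bp
      mat[i, k] <- seg(s, s + bin_bp)
    }
  }
  rownames(mat) <- peaks$name %||% NULL
  structure(list(
    matrix = mat,
    mean_profile = colMeans(mat),
    bin_mid = -window_bp / 2 + (seq_len(nb) - 0.5) * bin_bp
  ), class = "summit_profile")
}

#' @exportS3Method base::print
print.summit_profile <- function(x, ...) {
  cat("<summit_profile>", nrow(x$matrix), "peaks x", ncol(x$matrix), "bins\n")
  invisible(x)
}

#' Export a summit profile matrix as TSV
#' @param profile A `summit_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summit_profile <- function(profile, path) {
  df <- as_tibble(profile$matrix, .name_repair = ~ paste0("bin_", seq_along(.x)))
  write_tsv_commented(df, path)
}

#' Signed distance from peaks to the closest TSS
#'
#' For every peak, the distance from its midpoint to the closest gene TSS,
#' signed in the gene's orientation: negative means the peak lies upstream
#' of the gene. Ties in absolute distance go to the lexicographically
#' smaller `gene_id`. Peaks on chromosomes without genes get `NA`.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble from [read_gtf()].
#' @param near_bp Distance defining "near the TSS"; the reported
#'   `fraction_beyond` is the share of peaks with `|distance| > near_bp`.
#' @return A list of class `tss_distance_stats`: `distances` (peaks with
#'   `closest_gene`, `distance`, `abs_distance`) and `fraction_beyond`.
#' @export
tss_distance_stats <- function(peaks, genes, near_bp = 10000) {
  if (nrow(genes) == 0) abort_validation("gene list is empty")
  check_intervals(peaks, "peak")
  mid <- midpoint0(peaks$start, peaks$end)
  closest <- rep(NA_character_, nrow(peaks))
  dist_signed <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0) next
    o <- order(g$tss, g$gene_id)
    g <- g[o, ]
    i <- which(peaks$chrom == chr)
    k <- findInterval(mid[i], g$tss)
    for (jj in seq_along(i)) {
      p <- i[jj]
      cand <- unique(pmin(pmax(c(k[jj], k[jj] + 1L), 1L), nrow(g)))
      dmin <- min(abs(mid[p] - g$tss[cand]))
      # expand over equal-TSS / equidistant neighbours
      all_cand <- which(abs(mid[p] - g$tss) == dmin)
      best <- all_cand[order(g$gene_id[all_cand])][1]
      raw <- mid[p] - g$tss[best]
      closest[p] <- g$gene_id[best]
      dist_signed[p] <- if (g$strand[best] == "-") -raw else raw
    }
  }
  distances <- peaks |>
    mutate(midpoint = mid, closest_gene = closest,
           distance = dist_signed, abs_distance = abs(dist_signed))
  structure(list(
    distances = distances,
    fraction_beyond = mean(distances$abs_distance > near_bp, na.rm = TRUE),
    near_bp = near_bp
  ), class = "tss_distance_stats")
}

#' @exportS3Method base::print
print.tss_distance_stats <- function(x, ...) {
  cat("<tss_distance_stats>", nrow(x$distances), "peaks;",
      sprintf("%.1f%%", 100 * x$fraction_beyond),
      "beyond", x$near_bp, "bp of the closest TSS\n")
  invisible(x)
}
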