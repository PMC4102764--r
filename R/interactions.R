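#' Bin interaction reads into fixed genomic windows
#'
#' Maps 3C-seq-style prey positions of one bait onto fixed windows
#' (`[k*bin, (k+1)*bin)` per chromosome, last window truncated) and converts
#' raw read counts into interaction frequencies: reads per bin normalised to
#' 1000 total reads, so the frequencies sum to 1000 whenever any read was
#' observed.
#'
#' @param records Tibble with columns `prey_chrom`, `prey_pos` and
#'   optionally `count` (default 1 per record); typically pre-filtered to
#'   one bait.
#' @param chrom_sizes Chromosome sizes (tibble or named vector).
#' @param bin_bp Window size (default 1 Mb).
#' @return Tibble covering the whole genome: `chrom`, `start`, `end`,
#'   `count`, `frequency`.
#' @export
bin_interactions <- function(records, chrom_sizes, bin_bp = 1e6) {
  sizes <- chrom_sizes_vec(chrom_sizes)
  cnt <- if ("count" %in% names(records)) records$count else rep(1, nrow(records))
  if (nrow(records)) {
    if (any(cnt < 1)) abort_validation("interaction counts must be >= 1")
    bad <- which(!records$prey_chrom %in% names(sizes) |
                   records$prey_pos < 0 |
                   records$prey_pos >= sizes[records$prey_chrom])
    if (length(bad)) {
      abort_validation(sprintf("prey position outside genome: %s:%s",
                               records$prey_chrom[bad[1]], records$prey_pos[bad[1]]))
    }
  }
  bins <- imap(as.list(sizes), function(sz, chr) {
    starts <- seq(0, sz - 1, by = bin_bp)
    tibble(chrom = chr, start = starts, end = pmin(starts + bin_bp, sz))
  }) |> list_rbind()
  bins$count <- 0
  if (nrow(records)) {
    key <- paste0(records$prey_chrom, ":", records$prey_pos %/% bin_bp)
    agg <- rowsum(cnt, key)
    bin_key <- paste0(bins$chrom, ":", bins$start %/% bin_bp)
    m <- match(rownames(agg), bin_key)
    bins$count[m] <- agg[, 1]
  }
  total <- sum(bins$count)
  if (total == 0) {
    warn("no interaction reads; all frequencies set to 0",
         class = "enhancerlink_empty_warning")
    bins$frequency <- 0
  } else {
    bins$frequency <- 1000 * bins$count / total
  }
  bins
}

#' Classify genome bins by domain activity
#'
#' Precedence rule: a bin overlapping at least one regulated region
#' (assigned enhancer or regulated gene) is `target`; otherwise a bin
#' overlapping a merged active domain is `active`; all remaining bins are
#' `inactive`. The partition is exhaustive and exclusive.
#'
#' @param bins Output of [bin_interactions()].
#' @param merged_domains Output of [merge_active_domains()].
#' @param target_regions Tibble of regulated regions (`chrom`, `start`,
#'   `end`).
#' @return `bins` with an added `bin_class` factor
#'   (levels inactive/active/target).
#' @export
classify_bins <- function(bins, merged_domains, target_regions) {
  overlaps_any <- function(x) {
    if (is.null(x) || nrow(x) == 0) return(logical(nrow(bins)))
    hits <- GenomicRanges::findOverlaps(intervals_to_gr(bins), intervals_to_gr(x),
                                        ignore.strand = TRUE)
    seq_len(nrow(bins)) %in% S4Vectors::queryHits(hits)
  }
  is_target <- overlaps_any(target_regions)
  is_active <- overlaps_any(merged_domains)
  bins |>
    mutate(bin_class = factor(
      case_when(is_target ~ "target", is_active ~ "active", TRUE ~ "inactive"),
      levels = c("inactive", "active", "target")
    ))
}

#' Compare interaction frequencies between bin classes
#'
#' Per-class summary (n, mean, SD of frequency) and an unpaired two-tailed
#' t-test for each class pair; Welch's unequal-variance form by default.
#' The bait's own chromosome can be excluded to isolate the
#' interchromosomal signal. Two identical constant groups get `t = 0`,
#' `p = 1`; a class with fewer than 2 bins skips its comparisons with a
#' warning.
#'
#' @param bins Output of [classify_bins()].
#' @param bait_chrom Chromosome of the bait (needed when
#'   `exclude_cis = TRUE`).
#' @param exclude_cis Drop bins on the bait chromosome.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list of class `contact_comparison`: `summary` (per class) and
#'   `tests` (per class pair: `t`, `df`, `p_value`).
#' @export
compare_classes <- function(bins, bait_chrom = NULL, exclude_cis = TRUE,
                            var_equal = FALSE) {
  if (exclude_cis) {
    if (is.null(bait_chrom)) abort_validation("exclude_cis = TRUE needs bait_chrom")
    bins <- bins |> filter(.data$chrom != bait_chrom)
  }
  summ <- bins |>
    group_by(.data$bin_class, .drop = FALSE) |>
    summarise(n = n(), mean = mean(.data$frequency), sd = sd(.data$frequency),
              .groups = "drop")
  pairs <- list(c("inactive", "active"), c("active", "target"),
                c("inactive", "target"))
  tests <- map(pairs, function(pr) {
    x <- bins$frequency[bins$bin_class == pr[1]]
    y <- bins$frequency[bins$bin_class == pr[2]]
    if (length(x) < 2 || length(y) < 2) {
      warn(paste0("class with < 2 bins; skipping ", pr[1], " vs ", pr[2]),
           class = "enhancerlink_skip_warning")
      return(tibble(group1 = pr[1], group2 = pr[2], t = NA_real_,
                    df = NA_real_, p_value = NA_real_))
    }
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      return(tibble(group1 = pr[1], group2 = pr[2], t = 0, df = NA_real_,
                    p_value = 1))
    }
    tt <- t.test(x, y, var.equal = var_equal)
    tibble(group1 = pr[1], group2 = pr[2], t = unname(tt$statistic),
           df = unname(tt$parameter), p_value = tt$p.value)
  }) |> list_rbind()
  structure(list(summary = summ, tests = tests), class = "contact_comparison")
}

#' @exportS3Method base::print
print.contact_comparison <- function(x, ...) {
  cat("<contact_comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.contact_comparison <- function(x, ...) x$tests

#' @exportS3Method generics::glance
glance.contact_comparison <- function(x, ...) {
  tibble(
    n_bins = sum(x$summary$n),
    mean_inactive = x$summary$mean[x$summary$bin_class == "inactive"],
    mean_active = x$summary$mean[x$summary$bin_class == "active"],
    mean_target = x$summary$mean[x$summary$bin_class == "target"],
    p_inactive_vs_target =
      x$tests$p_value[x$tests$group1 == "inactive" & x$tests$group2 == "target"]
  )
}
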