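#' Call CTCF/cohesin co-peak boundaries
#'
#' A boundary is an overlapping CTCF/RAD21 peak pair in which both caller
#' scores exceed `min_score` (strictly) and the larger score is less than
#' `ratio_limit` times the smaller (similar occupancy). A CTCF peak
#' overlapping several RAD21 peaks pairs with the largest-overlap one
#' (ties: leftmost). The boundary interval is the intersection of the two
#' peaks and its combined score the smaller of the two.
#'
#' @param ctcf_peaks,rad21_peaks Scored peak tibbles.
#' @param min_score Strict lower bound on both scores.
#' @param ratio_limit Strict upper bound on `max(score)/min(score)`.
#' @return Tibble of boundaries: `chrom`, `start`, `end`, `midpoint`,
#'   `ctcf_score`, `rad21_score`, `combined_score`, sorted by position.
#' @export
call_boundaries <- function(ctcf_peaks, rad21_peaks, min_score = 15, ratio_limit = 3) {
  check_intervals(ctcf_peaks, "CTCF peak"); check_intervals(rad21_peaks, "RAD21 peak")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  midpoint = double(), ctcf_score = double(),
                  rad21_score = double(), combined_score = double())
  if (!nrow(ctcf_peaks) || !nrow(rad21_peaks)) return(empty)
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(ctcf_peaks),
                                      intervals_to_gr(rad21_peaks),
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  ci <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  ov <- pmin(ctcf_peaks$end[ci], rad21_peaks$end[ri]) -
    pmax(ctcf_peaks$start[ci], rad21_peaks$start[ri])
  tibble(ci = ci, ri = ri, ov = ov, rstart = rad21_peaks$start[ri]) |>
    group_by(.data$ci) |>
    arrange(desc(.data$ov), .data$rstart, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(
      chrom = ctcf_peaks$chrom[.data$ci],
      start = pmax(ctcf_peaks$start[.data$ci], rad21_peaks$start[.data$ri]),
      end = pmin(ctcf_peaks$end[.data$ci], rad21_peaks$end[.data$ri]),
      ctcf_score = ctcf_peaks$score[.data$ci],
      rad21_score = rad21_peaks$score[.data$ri]
    ) |>
    filter(.data$ctcf_score > min_score, .data$rad21_score > min_score,
           pmax(.data$ctcf_score, .data$rad21_score) <
             ratio_limit * pmin(.data$ctcf_score, .data$rad21_score)) |>
    mutate(midpoint = (.data$start + .data$end) / 2,
           combined_score = pmin(.data$ctcf_score, .data$rad21_score)) |>
    select("chrom", "start", "end", "midpoint", "ctcf_score", "rad21_score",
           "combined_score") |>
    arrange(.data$chrom, .data$start)
}

#' Pair boundaries into functional domains
#'
#' Left-to-right greedy scan per chromosome: each unconsumed boundary is
#' paired with the nearest boundary to its right whose combined-score ratio
#' (larger/smaller) is below `ratio_limit`. Both partners are consumed;
#' boundaries skipped between partners stay unpaired (pairing them later
#' would create overlapping domains) and are reported via the
#' `unpaired` attribute. The domain interval runs between the two boundary
#' midpoints.
#'
#' @param boundaries Boundary tibble from [call_boundaries()].
#' @param ratio_limit Strict score-similarity bound for pairing.
#' @return Tibble of domains: `chrom`, `start`, `end`, `length`,
#'   `left_score`, `right_score`; attribute `unpaired` holds the row indices
#'   of unpaired boundaries.
#' @export
pair_domains <- function(boundaries, ratio_limit = 3) {
  out <- list(); unpaired <- integer()
  for (chr in unique(boundaries$chrom)) {
    idx <- which(boundaries$chrom == chr)
    b <- boundaries[idx, ]
    if (is.unsorted(b$midpoint)) {
      o <- order(b$midpoint); b <- b[o, ]; idx <- idx[o]
    }
    i <- 1
    consumed <- logical(nrow(b))
    while (i <= nrow(b)) {
      if (consumed[i]) { i <- i + 1; next }
      j <- i + 1
      found <- FALSE
      while (j <= nrow(b)) {
        s1 <- b$combined_score[i]; s2 <- b$combined_score[j]
        if (max(s1, s2) < ratio_limit * min(s1, s2)) { found <- TRUE; break }
        j <- j + 1
      }
      if (found) {
        if (j > i + 1) unpaired <- c(unpaired, idx[(i + 1):(j - 1)])
        consumed[i:j] <- TRUE
        out[[length(out) + 1]] <- tibble(
          chrom = chr, start = floor(b$midpoint[i]), end = ceiling(b$midpoint[j]),
          left_score = b$combined_score[i], right_score = b$combined_score[j]
        )
        i <- j + 1
      } else {
        unpaired <- c(unpaired, idx[i])
        consumed[i] <- TRUE
        i <- i + 1
      }
    }
  }
  domains <- if (length(out)) {
    list_rbind(out) |>
      mutate(length = .data$end - .data$start) |>
      arrange(.data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = double(), end = double(),
           left_score = double(), right_score = double(), length = double())
  }
  attr(domains, "unpaired") <- unpaired
  domains
}

#' Merge neighbouring domains into active domains
#'
#' Consecutive domains on a chromosome separated by strictly less than
#' `max_gap_bp` are merged transitively; the merged interval spans from the
#' first left boundary to the last right boundary. Merging is idempotent.
#'
#' @param domains Domain tibble from [pair_domains()].
#' @param max_gap_bp Strict gap threshold (default 100 kb).
#' @return Tibble of merged domains: `chrom`, `start`, `end`, `length`,
#'   `n_domains`.
#' @export
merge_active_domains <- function(domains, max_gap_bp = 100000) {
  if (!nrow(domains)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  length = double(), n_domains = integer()))
  }
  domains |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(c(TRUE, (.data$start[-1] - .data$end[-n()]) >= max_gap_bp))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_domains = n(), .groups = "drop") |>
    mutate(length = .data$end - .data$start) |>
    select("chrom", "start", "end", "length", "n_domains") |>
    arrange(.data$chrom, .data$start)
}

#' Length statistics of a domain set
#' @param domains Tibble with a `length` column.
#' @return One-row tibble: `n`, `median_length`, `mean_length`.
#' @export
domain_stats <- function(domains) {
  tibble(n = nrow(domains),
         median_length = median(domains$length),
         mean_length = mean(domains$length))
}

#' Place regulated genes and their enhancers within merged domains
#'
#' A gene resides inside the domain structure when its TSS and all of its
#' assigned regulatory regions fall within one and the same merged domain;
#' genes without assignments are judged by TSS membership alone.
#'
#' @param genes Gene tibble restricted to the genes of interest.
#' @param assignments [annotate_enhancers()] output (may be empty).
#' @param merged_domains Output of [merge_active_domains()].
#' @return A list: `per_gene` (tibble `gene_id`, `inside`, `domain_idx`) and
#'   `fraction_inside`.
#' @export
assign_to_domains <- function(genes, assignments, merged_domains) {
  domain_of_point <- function(chrom, pos) {
    hit <- which(merged_domains$chrom == chrom &
                   merged_domains$start <= pos & pos < merged_domains$end)
    if (length(hit)) hit[1] else NA_integer_
  }
  per_gene <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gd <- domain_of_point(g$chrom, g$tss)
    regions <- assignments[assignments$gene_id == g$gene_id, ]
    inside <- !is.na(gd)
    if (inside && nrow(regions)) {
      rd <- map_int(seq_len(nrow(regions)), function(k) {
        d <- which(merged_domains$chrom == regions$chrom[k] &
                     merged_domains$start <= regions$start[k] &
                     regions$end[k] <= merged_domains$end)
        if (length(d)) d[1] else NA_integer_
      })
      inside <- all(!is.na(rd)) && all(rd == gd)
    }
    tibble(gene_id = g$gene_id, inside = inside, domain_idx = gd)
  }) |> list_rbind()
  list(per_gene = per_gene,
       fraction_inside = if (nrow(genes)) mean(per_gene$inside) else NA_real_)
}
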