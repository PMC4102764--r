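#' Call transcript units from stranded coverage
#'
#' Per strand, maximal runs of nonzero coverage are taken as transcribed
#' segments, segments separated by at most `max_gap_bp` of zero signal are
#' merged, and merged units shorter than `min_length_bp` or below `min_rpkm`
#' are discarded. RPKM is `read_count / ((length/1000) * (library_size/1e6))`
#' where the read count is the summed per-base coverage. The 5' end is
#' `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param cov A [stranded_coverage()] object.
#' @param library_size Total mapped reads of the library (> 0). Default: the
#'   total signal mass of `cov`.
#' @param min_rpkm Expression floor; units below it are dropped. The default
#'   0.006 is the genome-wide transcription floor used for the transcribed
#'   fraction.
#' @param min_length_bp Minimum unit length in bp.
#' @param max_gap_bp Zero-coverage gaps up to this length are bridged.
#' @return Tibble of units: `chrom`, `start`, `end`, `strand`, `five_prime`,
#'   `read_count`, `rpkm`, sorted by chromosome and start.
#' @export
call_transcript_units <- function(cov, library_size = NULL, min_rpkm = 0.006,
                                  min_length_bp = 100, max_gap_bp = 50) {
  library_size <- library_size %||% coverage_total(cov)
  if (library_size <= 0) abort_validation("library_size must be > 0")
  one_strand <- function(v, chr, strand) {
    r <- rle(v > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths            # 0-based
    keep <- r$values
    s <- starts[keep]; e <- ends[keep]
    if (!length(s)) return(NULL)
    grp <- cumsum(c(TRUE, s[-1] - e[-length(e)] > max_gap_bp))
    s2 <- unname(vapply(split(s, grp), min, 0))
    e2 <- unname(vapply(split(e, grp), max, 0))
    cs <- cumsum(v)
    rc <- cs[e2] - ifelse(s2 > 0, cs[pmax(s2, 1)], 0)
    fp <- as.integer(if (strand == "+") s2 else e2 - 1)
    tibble(
      chrom = chr, start = as.integer(s2), end = as.integer(e2),
      strand = strand, five_prime = fp, read_count = rc
    )
  }
  units <- list_rbind(c(
    imap(cov$plus, function(v, chr) one_strand(v, chr, "+")),
    imap(cov$minus, function(v, chr) one_strand(v, chr, "-"))
  ))
  if (is.null(units) || nrow(units) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), five_prime = integer(),
                  read_count = double(), rpkm = double()))
  }
  units |>
    mutate(rpkm = .data$read_count /
             (((.data$end - .data$start) / 1000) * (library_size / 1e6))) |>
    filter(.data$end - .data$start >= min_length_bp, .data$rpkm >= min_rpkm) |>
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Fraction of the genome covered by transcript units
#'
#' Length of the union of unit intervals across both strands divided by the
#' total genome length.
#'
#' @param units Unit tibble from [call_transcript_units()].
#' @param chrom_sizes Chromosome sizes (tibble or named vector).
#' @return A fraction in `[0, 1]`.
#' @export
transcribed_fraction <- function(units, chrom_sizes) {
  sizes <- chrom_sizes_vec(chrom_sizes)
  if (nrow(units) == 0) return(0)
  check_within_genome(units, sizes, "unit")
  gr <- GenomicRanges::GRanges(units$chrom,
                               IRanges::IRanges(units$start + 1L, units$end))
  covered <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
  covered / sum(sizes)
}

#' Detect divergent initiation sites
#'
#' A divergent site pairs a minus-strand unit (transcribing leftward) with a
#' plus-strand unit (transcribing rightward) on the same chromosome whose 5'
#' ends point away from each other (`plus five_prime >= minus five_prime`)
#' and lie strictly closer than `max_gap_bp` apart, with the better-expressed
#' partner above `min_rpkm`. Each unit joins at most one site; pairs are
#' matched greedily by smallest gap with leftmost tie-break, which makes the
#' output independent of input order. The site interval spans the two 5'
#' ends (a 1-bp interval when they coincide).
#'
#' @param plus_units,minus_units Unit tibbles (strand `+` resp. `-`), sorted
#'   by chromosome and start as produced by [call_transcript_units()].
#' @param max_gap_bp Strict upper bound on the 5'-end distance.
#' @param min_rpkm Expression threshold applied to `max_rpkm` (strictly
#'   greater), or to both partners when `strict_both = TRUE`.
#' @param strict_both Require both partners above `min_rpkm`.
#' @return Tibble of sites: `chrom`, `start`, `end`, `gap`, `plus_five_prime`,
#'   `minus_five_prime`, member unit coordinates (`plus_start`, `plus_end`,
#'   `minus_start`, `minus_end`), `plus_rpkm`, `minus_rpkm`, `max_rpkm` and a
#'   site id, ordered by position.
#' @export
detect_divergent_sites <- function(plus_units, minus_units, max_gap_bp = 300,
                                   min_rpkm = 0.2, strict_both = FALSE) {
  for (u in list(plus_units, minus_units)) {
    if (nrow(u) > 1) {
      o <- order(u$chrom, u$start)
      if (!identical(o, seq_len(nrow(u)))) {
        abort_validation("unit lists must be sorted by chromosome and start")
      }
    }
  }
  if (nrow(plus_units) && any(plus_units$strand != "+")) {
    abort_validation("plus_units must all be on the + strand")
  }
  if (nrow(minus_units) && any(minus_units$strand != "-")) {
    abort_validation("minus_units must all be on the - strand")
  }
  empty <- tibble(
    site_id = character(), chrom = character(), start = integer(),
    end = integer(), gap = integer(), plus_five_prime = integer(),
    minus_five_prime = integer(), plus_start = integer(), plus_end = integer(),
    minus_start = integer(), minus_end = integer(),
    plus_rpkm = double(), minus_rpkm = double(), max_rpkm = double()
  )
  if (nrow(plus_units) == 0 || nrow(minus_units) == 0) return(empty)

  sites <- list()
  for (chr in intersect(unique(minus_units$chrom), unique(plus_units$chrom))) {
    mu <- minus_units[minus_units$chrom == chr, ]
    pu <- plus_units[plus_units$chrom == chr, ]
    p5 <- pu$five_prime
    # candidate pairs: plus 5' in [m5, m5 + max_gap - 1]
    ord_p <- order(p5)
    p5s <- p5[ord_p]
    lo <- findInterval(mu$five_prime - 1, p5s) + 1
    hi <- findInterval(mu$five_prime + max_gap_bp - 1, p5s)
    cand <- list_rbind(map(seq_len(nrow(mu)), function(i) {
      if (lo[i] > hi[i]) return(NULL)
      j <- ord_p[lo[i]:hi[i]]
      tibble(mi = i, pi = j, gap = p5[j] - mu$five_prime[i])
    }))
    if (is.null(cand) || nrow(cand) == 0) next
    ok <- if (strict_both) {
      mu$rpkm[cand$mi] > min_rpkm & pu$rpkm[cand$pi] > min_rpkm
    } else {
      pmax(mu$rpkm[cand$mi], pu$rpkm[cand$pi]) > min_rpkm
    }
    cand <- cand[ok, ]
    if (nrow(cand) == 0) next
    cand <- cand[order(cand$gap, mu$five_prime[cand$mi], pu$five_prime[cand$pi]), ]
    used_m <- logical(nrow(mu)); used_p <- logical(nrow(pu))
    for (k in seq_len(nrow(cand))) {
      mi <- cand$mi[k]; pi <- cand$pi[k]
      if (used_m[mi] || used_p[pi]) next
      used_m[mi] <- TRUE; used_p[pi] <- TRUE
      sites[[length(sites) + 1]] <- tibble(
        chrom = chr,
        start = mu$five_prime[mi],
        end = pu$five_prime[pi] + 1L,
        gap = cand$gap[k],
        plus_five_prime = pu$five_prime[pi],
        minus_five_prime = mu$five_prime[mi],
        plus_start = pu$start[pi], plus_end = pu$end[pi],
        minus_start = mu$start[mi], minus_end = mu$end[mi],
        plus_rpkm = pu$rpkm[pi], minus_rpkm = mu$rpkm[mi],
        max_rpkm = pmax(pu$rpkm[pi], mu$rpkm[mi])
      )
    }
  }
  if (!length(sites)) return(empty)
  list_rbind(sites) |>
    arrange(.data$chrom, .data$start) |>
    mutate(site_id = sprintf("site_%05d", row_number()), .before = 1)
}
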