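#' Construct a stranded coverage object
#'
#' Container for base-resolution, strand-specific nascent-transcription
#' signal of one library: a dense numeric vector per chromosome per strand.
#'
#' @param plus,minus Named lists of numeric vectors (one per chromosome),
#'   each of length equal to the chromosome size.
#' @param chrom_sizes Chromosome sizes (tibble or named vector).
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(plus, minus, chrom_sizes) {
  sizes <- chrom_sizes_vec(chrom_sizes)
  for (chr in names(sizes)) {
    if (is.null(plus[[chr]])) plus[[chr]] <- numeric(sizes[[chr]])
    if (is.null(minus[[chr]])) minus[[chr]] <- numeric(sizes[[chr]])
    if (length(plus[[chr]]) != sizes[[chr]] || length(minus[[chr]]) != sizes[[chr]]) {
      abort_validation(paste0("coverage vector length mismatch on ", chr))
    }
  }
  structure(
    list(plus = plus[names(sizes)], minus = minus[names(sizes)], chrom_sizes = sizes),
    class = "stranded_coverage"
  )
}

#' @exportS3Method base::print
print.stranded_coverage <- function(x, ...) {
  cat("<stranded_coverage> ", length(x$chrom_sizes), " chromosome(s), ",
      format(sum(x$chrom_sizes), big.mark = ","), " bp\n", sep = "")
  cat("  total signal: plus ", format(round(coverage_total(x, "plus"), 2)),
      ", minus ", format(round(coverage_total(x, "minus"), 2)), "\n", sep = "")
  invisible(x)
}

#' Total signal mass of a coverage object
#' @param cov A `stranded_coverage`.
#' @param strand `"both"`, `"plus"` or `"minus"`.
#' @return Sum of the per-base coverage.
#' @export
coverage_total <- function(cov, strand = "both") {
  p <- sum(vapply(cov$plus, sum, 0))
  m <- sum(vapply(cov$minus, sum, 0))
  switch(strand, both = p + m, plus = p, minus = m,
         abort_validation("strand must be both/plus/minus"))
}

# Dense per-base vector from bedGraph-style records; overlapping records sum.
dense_from_records <- function(chrom, start, end, value, size, warn_overlap = TRUE) {
  v <- numeric(size)
  if (!length(start)) return(v)
  if (any(start < 0) || any(end > size) || any(start >= end)) {
    bad <- which(start < 0 | end > size | start >= end)[1]
    abort_validation(sprintf(
      "bedGraph record beyond chromosome bounds or inverted: %s:%d-%d (size %d)",
      chrom, start[bad], end[bad], size
    ))
  }
  o <- order(start)
  if (warn_overlap && length(start) > 1) {
    if (any(start[o][-1] < cummax(end[o])[-length(o)])) {
      warn(paste0("overlapping bedGraph records on ", chrom, "; values summed"),
           class = "enhancerlink_overlap_warning")
    }
  }
  # interval-add via difference array
  d <- numeric(size + 1)
  agg <- rowsum(c(value, -value), c(start + 1, end + 1))
  idx <- as.integer(rownames(agg))
  keep <- idx <= size + 1
  d[idx[keep]] <- agg[keep]
  cumsum(d)[seq_len(size)]
}

read_bedgraph_one <- function(path, sizes) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(setNames(lapply(sizes, numeric), names(sizes)))
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", "value")),
    error = function(e) abort_parse(paste0("cannot parse bedGraph ", path, ": ", conditionMessage(e)))
  )
  out <- list()
  unknown <- setdiff(unique(dt$chrom), names(sizes))
  if (length(unknown)) abort_validation(paste0("bedGraph chromosome not in chrom_sizes: ", unknown[1]))
  for (chr in names(sizes)) {
    sub <- dt[dt$chrom == chr, ]
    out[[chr]] <- dense_from_records(chr, sub$start, sub$end, sub$value, sizes[[chr]])
  }
  out
}

#' Read a strand-specific bedGraph pair into dense coverage
#'
#' Reads one bedGraph per strand (0-based half-open records) and expands them
#' to dense per-base vectors. Bases not covered by any record are 0; the
#' total signal equals the sum of value x interval length over all records.
#' Overlapping records are summed with a warning.
#'
#' @param plus_path,minus_path Paths to the plus/minus-strand bedGraphs.
#' @param chrom_sizes Chromosome sizes (tibble or named vector).
#' @return A [stranded_coverage()] object.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes) {
  sizes <- chrom_sizes_vec(chrom_sizes)
  stranded_coverage(
    plus = read_bedgraph_one(plus_path, sizes),
    minus = read_bedgraph_one(minus_path, sizes),
    chrom_sizes = sizes
  )
}

write_bedgraph_one <- function(vectors, path) {
  pieces <- lapply(names(vectors), function(chr) {
    r <- rle(vectors[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    data.table::data.table(chrom = chr, start = starts[keep],
                           end = ends[keep], value = r$values[keep])
  })
  data.table::fwrite(data.table::rbindlist(pieces), path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a coverage object as a bedGraph pair
#' @param cov A `stranded_coverage`.
#' @param plus_path,minus_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(cov, plus_path, minus_path) {
  write_bedgraph_one(cov$plus, plus_path)
  write_bedgraph_one(cov$minus, minus_path)
  invisible(c(plus_path, minus_path))
}

#' Sum coverage within regions
#'
#' Read count of each region, defined as the sum of per-base coverage within
#' it, taken on the region's own strand (`strand_mode = "match"`) or on both
#' strands (`"both"`, used for divergent-site windows).
#'
#' @param regions Tibble with `chrom`, `start`, `end` and (for `"match"`)
#'   `strand` columns.
#' @param cov A `stranded_coverage`.
#' @param strand_mode `"match"` or `"both"`.
#' @return Numeric vector of per-region read counts.
#' @export
count_region_reads <- function(regions, cov, strand_mode = c("match", "both")) {
  strand_mode <- match.arg(strand_mode)
  check_intervals(regions, "region")
  check_within_genome(regions, cov$chrom_sizes, "region")
  if (strand_mode == "match" && !"strand" %in% names(regions)) {
    abort_validation("strand_mode='match' needs a strand column")
  }
  counts <- numeric(nrow(regions))
  for (chr in unique(regions$chrom)) {
    i <- which(regions$chrom == chr)
    csp <- cumsum(cov$plus[[chr]])
    csm <- cumsum(cov$minus[[chr]])
    seg <- function(cs, s, e) {
      out <- cs[e]
      out[e == 0] <- 0
      out - ifelse(s > 0, cs[pmax(s, 1)], 0)
    }
    s <- regions$start[i]; e <- regions$end[i]
    if (strand_mode == "both") {
      counts[i] <- seg(csp, s, e) + seg(csm, s, e)
    } else {
      st <- regions$strand[i]
      counts[i] <- ifelse(st == "+", seg(csp, s, e),
                   ifelse(st == "-", seg(csm, s, e),
                          seg(csp, s, e) + seg(csm, s, e)))
    }
  }
  counts
}

#' Add two coverage objects (e.g. pooling conditions)
#' @param a,b `stranded_coverage` objects over the same chromosomes.
#' @return A `stranded_coverage` with per-base sums.
#' @export
pool_coverage <- function(a, b) {
  if (!identical(names(a$chrom_sizes), names(b$chrom_sizes))) {
    abort_validation("coverage objects are over different chromosomes")
  }
  stranded_coverage(
    plus = map2(a$plus, b$plus, `+`),
    minus = map2(a$minus, b$minus, `+`),
    chrom_sizes = a$chrom_sizes
  )
}
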