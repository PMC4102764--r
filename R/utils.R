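# Internal helpers shared across modules. All coordinates in the package are
# 0-based half-open [start, end); GTF is converted at the reading boundary.

abort_validation <- function(msg, ...) {
  abort(msg, class = "enhancerlink_validation_error", ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = "enhancerlink_parse_error", ...)
}

#' Normalise a chromosome-size table to a named integer vector
#'
#' Accepts either a two-column data frame (`chrom`, `size`) or an already
#' named numeric vector.
#'
#' @param chrom_sizes Data frame with columns `chrom` and `size`, or a named
#'   numeric vector of chromosome lengths in bp.
#' @return Named numeric vector of chromosome lengths.
#' @keywords internal
chrom_sizes_vec <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    if (!all(c("chrom", "size") %in% names(chrom_sizes))) {
      abort_validation("chrom_sizes data frame needs columns 'chrom' and 'size'")
    }
    out <- setNames(as.numeric(chrom_sizes$size), chrom_sizes$chrom)
  } else if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    out <- chrom_sizes
  } else {
    abort_validation("chrom_sizes must be a named vector or a chrom/size data frame")
  }
  if (any(out <= 0) || anyNA(out)) abort_validation("chromosome sizes must be positive")
  out
}

check_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort_validation(paste0(what, " table needs columns chrom/start/end"))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s %d is invalid: start=%s end=%s (need 0 <= start < end)",
      what, bad[1], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

check_within_genome <- function(x, chrom_sizes, what = "interval") {
  sizes <- chrom_sizes_vec(chrom_sizes)
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown)) {
    abort_validation(paste0(what, " on unknown chromosome: ", unknown[1]))
  }
  bad <- which(x$end > sizes[x$chrom])
  if (length(bad)) {
    abort_validation(sprintf(
      "%s %d extends beyond chromosome end (%s:%s-%s)",
      what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed internally to Bioc).
intervals_to_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

midpoint0 <- function(start, end) floor((start + end) / 2)

#' Write a tibble as TSV with a single '#'-prefixed header line
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  writeLines(header, path)
  data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_commented <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE)
  if (nrow(dt) == 0) {
    return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
  }
  data.table::setnames(dt, cols)
  as_tibble(dt)
}
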