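#' Read a BED3/BED5 peak file
#'
#' Reads scored genomic intervals (ChIP peaks). Coordinates are kept 0-based
#' half-open exactly as in the file. A missing name column is filled with
#' `peak_<n>`, a missing score with 0, and a missing summit with the interval
#' midpoint. The optional 7th column carries the summit as an absolute
#' coordinate (BED thickStart slot); it is converted to an offset within the
#' interval.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `summit` (offset from `start`). Row order follows the file.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\te1\t25", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), summit = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort_parse(sprintf("BED line %d has %d fields; need at least 3",
                        which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  grab <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
  start <- suppressWarnings(as.integer(grab(2)))
  end <- suppressWarnings(as.integer(grab(3)))
  if (anyNA(start) || anyNA(end)) {
    abort_parse(sprintf("BED line %d: coordinates do not parse as integers",
                        which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    abort_validation(sprintf("BED line %d: invalid interval %d-%d",
                             bad[1], start[bad[1]], end[bad[1]]))
  }
  name <- grab(4)
  name[is.na(name) | name == "."] <- paste0("peak_", which(is.na(name) | name == "."))
  score <- suppressWarnings(as.numeric(grab(5)))
  score[is.na(score)] <- 0
  if (any(score < 0)) abort_validation("peak scores must be nonnegative")
  summit_abs <- suppressWarnings(as.numeric(grab(7)))
  summit <- ifelse(is.na(summit_abs), midpoint0(start, end) - start,
                   as.integer(summit_abs) - start)
  if (any(summit < 0 | summit >= end - start)) {
    abort_validation("summit falls outside its interval")
  }
  tibble(chrom = grab(1), start = start, end = end,
         name = name, score = score, summit = as.integer(summit))
}

#' Write peaks as BED5 plus a summit column
#'
#' Inverse of [read_bed()]: columns chrom, start, end, name, score and the
#' summit written back as an absolute coordinate in column 7 (column 6 holds
#' the strand, `.` when absent).
#'
#' @param peaks Peak tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  check_intervals(peaks, "peak")
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", nrow(peaks))
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name %||% paste0("peak_", seq_len(nrow(peaks))),
    score = peaks$score %||% 0,
    strand = strand,
    summit = peaks$start + (peaks$summit %||% (midpoint0(peaks$start, peaks$end) - peaks$start))
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path Path to a TSV with chromosome name and length.
#' @return Tibble with columns `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2) abort_parse("chrom.sizes needs two columns")
  out <- tibble(chrom = as.character(dt[[1]]), size = as.numeric(dt[[2]]))
  if (any(out$size <= 0)) abort_validation("chromosome sizes must be positive")
  out
}

#' Write a chrom.sizes file
#' @param chrom_sizes Tibble with `chrom`/`size` or named vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  v <- chrom_sizes_vec(chrom_sizes)
  data.table::fwrite(data.table::data.table(names(v), as.integer(v)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses a GTF (1-based closed coordinates) via `rtracklayer` and collapses
#' all records of a `gene_id` to a single gene model spanning their union.
#' Coordinates are converted to the package's 0-based half-open convention
#' and the TSS is derived from the strand (`start` for `+`, `end - 1` for
#' `-`). Transcripts must be stranded.
#'
#' @param path Path to a GTF file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) abort_parse("GTF records carry no gene_id attribute")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort_validation("gene records must be stranded '+' or '-'")
  }
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand
  ) |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = {
        if (length(unique(.data$chrom)) > 1)
          abort_validation(paste0("gene on multiple chromosomes: ", cur_group()$gene_id))
        .data$chrom[1]
      },
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], .groups = "drop"
    ) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    arrange(.data$chrom, .data$start)
}

#' Write gene models as GTF
#'
#' One `gene` record per gene model; coordinates converted back to 1-based
#' closed GTF convention.
#'
#' @param genes Gene tibble as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "enhancerlink") {
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$chrom, source, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}
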