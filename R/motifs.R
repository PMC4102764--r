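#' Scan a sequence for direct repeats of a nuclear-receptor half-site
#'
#' Targeted consensus scanning for direct repeats (DR0..DR5) of the
#' AGGTCA-type half-site: two copies of the half-site on the same strand
#' separated by a spacer of 0-5 bp, each copy allowed up to
#' `max_mismatch_per_half` mismatches. `N` never matches. Both strands are
#' scanned; coordinates are always reported on the forward strand, with
#' `strand` giving the strand of the repeat (the first half-site is the
#' 5'-most copy on that strand). Overlapping hits of different spacer
#' classes are all reported.
#'
#' @param sequence A character scalar or `Biostrings::DNAString` over
#'   `A,C,G,T,N`.
#' @param half_site Half-site consensus (default `"AGGTCA"`).
#' @param max_mismatch_per_half Mismatch budget per half-site copy.
#' @param spacers Integer vector of spacer lengths to scan.
#' @return Tibble of hits: `start` (0-based), `end`, `strand`,
#'   `repeat_class` (`"DR<k>"`), `spacer`, `mm1`, `mm2` (mismatches in the
#'   first/second half-site, 5'-to-3' on the hit strand), ordered by
#'   position.
#' @export
scan_dr_repeats <- function(sequence, half_site = "AGGTCA",
                            max_mismatch_per_half = 1, spacers = 0:5) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  s <- strsplit(toupper(sequence), "")[[1]]
  if (length(s) && !all(s %in% c("A", "C", "G", "T", "N"))) {
    abort_validation("sequence contains characters outside A/C/G/T/N")
  }
  half <- strsplit(toupper(half_site), "")[[1]]
  h <- length(half)
  rc_half <- rev(c(A = "T", C = "G", G = "C", T = "A")[half])
  mism <- function(pat) {
    L <- length(s) - h + 1
    if (L < 1) return(integer(0))
    mm <- integer(L)
    for (j in seq_len(h)) mm <- mm + (s[j:(L + j - 1)] != pat[j])
    mm
  }
  mmF <- mism(half)       # forward-strand half-site starts
  mmR <- mism(rc_half)    # reverse-complement half-site starts
  hits <- list()
  for (sp in spacers) {
    off <- h + sp
    L <- length(mmF) - off
    if (L < 1) next
    i <- seq_len(L)
    okF <- mmF[i] <= max_mismatch_per_half & mmF[i + off] <= max_mismatch_per_half
    okR <- mmR[i] <= max_mismatch_per_half & mmR[i + off] <= max_mismatch_per_half
    if (any(okF)) {
      w <- i[okF]
      hits[[length(hits) + 1]] <- tibble(
        start = w - 1L, end = w - 1L + 2L * h + sp, strand = "+",
        repeat_class = paste0("DR", sp), spacer = sp,
        mm1 = mmF[w], mm2 = mmF[w + off]
      )
    }
    if (any(okR)) {
      w <- i[okR]
      # on the minus strand the 5'-most half-site maps to the rightmost copy
      hits[[length(hits) + 1]] <- tibble(
        start = w - 1L, end = w - 1L + 2L * h + sp, strand = "-",
        repeat_class = paste0("DR", sp), spacer = sp,
        mm1 = mmR[w + off], mm2 = mmR[w]
      )
    }
  }
  if (!length(hits)) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  repeat_class = character(), spacer = integer(),
                  mm1 = integer(), mm2 = integer()))
  }
  list_rbind(hits) |> arrange(.data$start, .data$spacer, .data$strand)
}

#' Scan FASTA sequences for DR repeats
#'
#' Applies [scan_dr_repeats()] to every sequence of a FASTA file.
#'
#' @param path FASTA path (read with `Biostrings`).
#' @inheritParams scan_dr_repeats
#' @return Tibble of hits with a leading `chrom` column.
#' @export
scan_fasta_dr_repeats <- function(path, half_site = "AGGTCA",
                                  max_mismatch_per_half = 1, spacers = 0:5) {
  seqs <- Biostrings::readDNAStringSet(path)
  imap(as.list(as.character(seqs)), function(sq, nm) {
    scan_dr_repeats(sq, half_site, max_mismatch_per_half, spacers) |>
      mutate(chrom = nm, .before = 1)
  }) |> list_rbind()
}
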