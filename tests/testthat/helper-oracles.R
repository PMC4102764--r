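# Independent brute-force reference implementations used to cross-check the
# package. These deliberately avoid the code paths (and libraries) of the
# implementations they verify.

# reduced-scale synthetic genome for fast tests
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_chroms = 2, chrom_length = 1e6, n_genes = 24,
    n_enhancers = 36, n_silent_sites = 24, n_domains = 6,
    n_decoy_boundaries = 6, library_size = 2e5
  ), list(...))
  do.call(synthetic_spec, args)
}

rand_intervals <- function(n, chrom = "chr1", max_pos = 1e5, max_len = 2000) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom, start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    name = paste0("p", seq_len(n)), score = stats::runif(n, 0, 100)
  )
}

# all-pairs interval overlap
brute_overlap_pairs <- function(a, b, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) out[[length(out) + 1]] <- c(i, j, ov)
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}

# closest TSS by absolute midpoint distance, ties to smaller gene_id
brute_closest_tss <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(mid - g$tss)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, "")
}

# textbook BH step-up with monotone enforcement
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive window scan for direct repeats
brute_scan_dr <- function(seq, half = "AGGTCA", max_mm = 1, spacers = 0:5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s <- strsplit(toupper(seq), "")[[1]]
  h <- strsplit(half, "")[[1]]
  mm_at <- function(x, pat) sum(x != pat)
  out <- list()
  for (sp in spacers) {
    w <- 2 * length(h) + sp
    if (length(s) < w) next
    for (i in seq_len(length(s) - w + 1)) {
      win <- s[i:(i + w - 1)]
      m1 <- mm_at(win[seq_along(h)], h)
      m2 <- mm_at(win[(length(h) + sp + 1):w], h)
      if (m1 <= max_mm && m2 <= max_mm) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = i - 1L, spacer = sp, strand = "+", mm1 = m1, mm2 = m2)
      }
      rc <- rev(unname(comp[win]))
      r1 <- mm_at(rc[seq_along(h)], h)
      r2 <- mm_at(rc[(length(h) + sp + 1):w], h)
      if (r1 <= max_mm && r2 <= max_mm) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = i - 1L, spacer = sp, strand = "-", mm1 = r1, mm2 = r2)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), spacer = integer(),
                          strand = character(), mm1 = integer(), mm2 = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), start, spacer, strand)
}

# exhaustive divergent-site search: all eligible pairs, then the same
# smallest-gap greedy matching applied to the explicit pair list
brute_divergent <- function(plus_units, minus_units, max_gap = 300, min_rpkm = 0.2) {
  pairs <- list()
  for (i in seq_len(nrow(minus_units))) {
    for (j in seq_len(nrow(plus_units))) {
      if (minus_units$chrom[i] != plus_units$chrom[j]) next
      gap <- plus_units$five_prime[j] - minus_units$five_prime[i]
      if (gap < 0 || gap >= max_gap) next
      if (max(minus_units$rpkm[i], plus_units$rpkm[j]) <= min_rpkm) next
      pairs[[length(pairs) + 1]] <-
        c(i, j, gap, minus_units$five_prime[i], plus_units$five_prime[j])
    }
  }
  if (!length(pairs)) return(matrix(numeric(0), ncol = 5))
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 3], m[, 4], m[, 5]), , drop = FALSE]
  used_m <- c(); used_p <- c(); sel <- list()
  for (k in seq_len(nrow(m))) {
    if (m[k, 1] %in% used_m || m[k, 2] %in% used_p) next
    used_m <- c(used_m, m[k, 1]); used_p <- c(used_p, m[k, 2])
    sel[[length(sel) + 1]] <- m[k, ]
  }
  do.call(rbind, sel)
}

# per-base loop over a coverage vector
brute_region_count <- function(vec, start, end) {
  total <- 0
  for (b in (start + 1):end) total <- total + vec[b]
  total
}

# transitive-closure merge by repeated passes
brute_merge <- function(domains, max_gap) {
  d <- domains[order(domains$chrom, domains$start), ]
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(d)) {
      if (d$chrom[i] == d$chrom[i + 1] && d$start[i + 1] - d$end[i] < max_gap) {
        d$end[i] <- max(d$end[i], d$end[i + 1])
        d <- d[-(i + 1), ]
        merged_any <- TRUE
      } else i <- i + 1
    }
    if (!merged_any) break
  }
  d
}

# match called divergent sites to planted ones by midpoint proximity
site_recovery <- function(called, planted, tol = 100) {
  if (nrow(planted) == 0) return(c(recall = NA, precision = NA))
  cm <- floor((called$start + called$end) / 2)
  pm <- floor((planted$start + planted$end) / 2)
  matched_p <- logical(nrow(planted))
  matched_c <- logical(nrow(called))
  for (i in seq_len(nrow(called))) {
    j <- which(planted$chrom == called$chrom[i] & abs(pm - cm[i]) <= tol &
                 !matched_p)
    if (length(j)) { matched_p[j[1]] <- TRUE; matched_c[i] <- TRUE }
  }
  c(recall = mean(matched_p), precision = mean(matched_c))
}
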