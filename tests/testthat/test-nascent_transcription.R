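make_cov <- function(sizes, plus = list(), minus = list()) {
  pl <- lapply(sizes, numeric); names(pl) <- names(sizes)
  mi <- lapply(sizes, numeric); names(mi) <- names(sizes)
  for (r in plus) pl[[r$chrom]][(r$start + 1):r$end] <- r$depth
  for (r in minus) mi[[r$chrom]][(r$start + 1):r$end] <- r$depth
  stranded_coverage(pl, mi, sizes)
}

test_that("a uniform run yields the closed-form read count and RPKM", {
  cov <- make_cov(c(chr1 = 5000),
                  plus = list(list(chrom = "chr1", start = 1000, end = 2000, depth = 1)))
  u <- call_transcript_units(cov, library_size = 1e6, min_rpkm = 0)
  expect_equal(nrow(u), 1)
  expect_equal(u$read_count, 1000)
  expect_equal(u$rpkm, 1000)   # 1000 / ((1000/1000) * (1e6/1e6))
  expect_equal(u$five_prime, 1000L)
})

test_that("zero gaps up to max_gap_bp are bridged", {
  cov <- make_cov(c(chr1 = 2000),
                  plus = list(list(chrom = "chr1", start = 0, end = 500, depth = 1),
                              list(chrom = "chr1", start = 600, end = 1000, depth = 1)))
  u <- call_transcript_units(cov, 1e6, min_rpkm = 0, max_gap_bp = 200)
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end), c(0L, 1000L))
  u2 <- call_transcript_units(cov, 1e6, min_rpkm = 0, max_gap_bp = 50)
  expect_equal(nrow(u2), 2)
})

test_that("unit union matches a brute-force scan of the base vector", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- rpois(4000, 0.15)
    cov <- stranded_coverage(list(chr1 = v), list(chr1 = numeric(4000)),
                             c(chr1 = 4000))
    gapmax <- 30
    u <- call_transcript_units(cov, 1e6, min_rpkm = 0, min_length_bp = 1,
                               max_gap_bp = gapmax)
    # brute force: walk the vector, bridge zero runs <= gapmax
    nz <- which(v > 0)
    expect_equal(sum(u$read_count), sum(v))
    if (length(nz)) {
      brk <- which(diff(nz) > gapmax + 1)
      runs <- length(brk) + 1
      expect_equal(nrow(u), runs)
      union_len <- sum(u$end - u$start)
      lens <- diff(c(0, brk, length(nz)))
      starts <- nz[c(1, brk + 1)]
      ends <- nz[c(brk, length(nz))]
      expect_equal(union_len, sum(ends - starts + 1))
    }
  }
})

test_that("RPKM is invariant under joint doubling of coverage and library", {
  set.seed(2)
  v <- rpois(3000, 0.4)
  cov1 <- stranded_coverage(list(chr1 = v), list(chr1 = numeric(3000)), c(chr1 = 3000))
  cov2 <- stranded_coverage(list(chr1 = 2 * v), list(chr1 = numeric(3000)), c(chr1 = 3000))
  u1 <- call_transcript_units(cov1, 1e5, min_rpkm = 0, min_length_bp = 1)
  u2 <- call_transcript_units(cov2, 2e5, min_rpkm = 0, min_length_bp = 1)
  expect_equal(u1$rpkm, u2$rpkm)
})

test_that("transcribed_fraction is the genome-normalised unit union", {
  cov <- make_cov(c(chr1 = 1000),
                  plus = list(list(chrom = "chr1", start = 0, end = 500, depth = 1)))
  u <- call_transcript_units(cov, 1e6, min_rpkm = 0)
  expect_equal(transcribed_fraction(u, c(chr1 = 1000)), 0.5)
  expect_equal(transcribed_fraction(u[0, ], c(chr1 = 1000)), 0)
  # opposite-strand overlap is not double-counted
  cov2 <- make_cov(c(chr1 = 1000),
                   plus = list(list(chrom = "chr1", start = 0, end = 500, depth = 1)),
                   minus = list(list(chrom = "chr1", start = 250, end = 750, depth = 1)))
  u2 <- call_transcript_units(cov2, 1e6, min_rpkm = 0)
  expect_equal(transcribed_fraction(u2, c(chr1 = 1000)), 0.75)
})

unit_row <- function(chrom, start, end, strand, rpkm = 1) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = strand,
                 five_prime = as.integer(if (strand == "+") start else end - 1),
                 read_count = rpkm * (end - start), rpkm = rpkm)
}

test_that("divergent pairing applies the strict gap and orientation rules", {
  plus <- unit_row("chr1", 1000, 1400, "+")
  minus <- unit_row("chr1", 500, 901, "-")   # 5' at 900
  s <- detect_divergent_sites(plus, minus)
  expect_equal(nrow(s), 1)
  expect_equal(s$gap, 100)
  expect_equal(c(s$start, s$end), c(900L, 1001L))

  # gap exactly 300 is excluded (strict inequality)
  minus2 <- unit_row("chr1", 300, 701, "-")  # 5' at 700, gap 300
  expect_equal(nrow(detect_divergent_sites(plus, minus2)), 0)

  # convergent configuration (plus 5' left of minus 5') is never a site
  plus3 <- unit_row("chr1", 600, 900, "+")
  minus3 <- unit_row("chr1", 700, 1001, "-")
  expect_equal(nrow(detect_divergent_sites(plus3, minus3)), 0)

  # expression floor is strict and applies to the better partner
  weak_p <- unit_row("chr1", 1000, 1400, "+", rpkm = 0.2)
  weak_m <- unit_row("chr1", 500, 901, "-", rpkm = 0.1)
  expect_equal(nrow(detect_divergent_sites(weak_p, weak_m, min_rpkm = 0.2)), 0)
  ok_p <- unit_row("chr1", 1000, 1400, "+", rpkm = 0.21)
  expect_equal(nrow(detect_divergent_sites(ok_p, weak_m, min_rpkm = 0.2)), 1)
  expect_equal(nrow(detect_divergent_sites(ok_p, weak_m, min_rpkm = 0.2,
                                           strict_both = TRUE)), 0)
})

test_that("divergent matching equals the exhaustive all-pairs search", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 15
    p5 <- sort(sample.int(5e4, n)); m5 <- sort(sample.int(5e4, n))
    plus <- dplyr::bind_rows(lapply(p5, function(x) unit_row("chr1", x, x + 200, "+",
                                                             rpkm = runif(1, 0.1, 2))))
    minus <- dplyr::bind_rows(lapply(m5, function(x) unit_row("chr1", x - 200, x + 1, "-",
                                                              rpkm = runif(1, 0.1, 2))))
    got <- detect_divergent_sites(plus, minus)
    want <- brute_divergent(plus, minus)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      want <- want[order(want[, 4]), , drop = FALSE]
      expect_equal(got$minus_five_prime, as.integer(want[, 4]))
      expect_equal(got$plus_five_prime, as.integer(want[, 5]))
    }
    # a matching: no unit used twice
    expect_equal(anyDuplicated(got$plus_five_prime), 0)
    expect_equal(anyDuplicated(got$minus_five_prime), 0)
  }
})

test_that("unsorted unit input is rejected", {
  plus <- dplyr::bind_rows(unit_row("chr1", 2000, 2400, "+"),
                           unit_row("chr1", 100, 500, "+"))
  expect_error(detect_divergent_sites(plus, unit_row("chr1", 100, 500, "-")),
               class = "enhancerlink_validation_error")
})
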