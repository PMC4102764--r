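test_that("overlap_peaks follows half-open interval semantics", {
  a <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L, name = "a1")
  b <- tibble::tibble(chrom = "chr1", start = 150L, end = 250L, name = "b1")
  r <- overlap_peaks(a, b)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$overlap_bp, 50)
  # abutting intervals do not overlap
  b2 <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L, name = "b2")
  expect_equal(nrow(overlap_peaks(a, b2)$pairs), 0)
})

test_that("overlap pairs and Venn counts match the all-pairs oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    a <- rand_intervals(40); b <- rand_intervals(40)
    r <- overlap_peaks(a, b)
    want <- brute_overlap_pairs(a, b)
    got <- r$pairs[order(r$pairs$a_idx, r$pairs$b_idx), ]
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(got$a_idx, as.integer(want[, 1]))
      expect_equal(got$b_idx, as.integer(want[, 2]))
      expect_equal(got$overlap_bp, want[, 3])
    }
    expect_equal(unname(r$venn[["a_and_b"]]), length(unique(want[, 1])))
    expect_equal(unname(r$venn[["a_only"]]), nrow(a) - length(unique(want[, 1])))
    # pair existence is symmetric
    r2 <- overlap_peaks(b, a)
    expect_setequal(paste(r$pairs$a_idx, r$pairs$b_idx),
                    paste(r2$pairs$b_idx, r2$pairs$a_idx))
  }
})

test_that("GRO classification is an exhaustive, exclusive partition", {
  peaks <- rand_intervals(20)
  empty_sites <- tibble::tibble(site_id = character(), chrom = character(),
                                start = integer(), end = integer())
  cl <- classify_by_gro(peaks, empty_sites)
  expect_true(all(cl$gro_class == "negative"))

  sites <- tibble::tibble(site_id = "s1", chrom = "chr1",
                          start = peaks$start[1] + 5L, end = peaks$start[1] + 10L)
  cl2 <- classify_by_gro(peaks, sites)
  expect_equal(cl2$gro_class[1], "positive")   # peak contains the site
  expect_equal(cl2$site_id[1], "s1")
  for (seed in 1:10) {
    set.seed(seed)
    p <- rand_intervals(30); s <- rand_intervals(10) |>
      dplyr::mutate(site_id = paste0("s", dplyr::row_number()))
    cl <- classify_by_gro(p, s)
    expect_equal(sum(cl$gro_class == "positive") + sum(cl$gro_class == "negative"),
                 nrow(p))
    expect_true(all(is.na(cl$site_id[cl$gro_class == "negative"])))
    expect_true(all(!is.na(cl$site_id[cl$gro_class == "positive"])))
  }
})

test_that("summit profiles bin coverage around the summit", {
  sizes <- c(chr1 = 10000)
  v <- numeric(10000); v[5001] <- 7   # single covered base at position 5000
  cov <- stranded_coverage(list(chr1 = v), list(chr1 = numeric(10000)), sizes)
  peaks <- tibble::tibble(chrom = "chr1", start = 4900L, end = 5100L,
                          name = "p1", summit = 100L)
  pr <- summit_profile(peaks, cov, window_bp = 3000, bin_bp = 25)
  expect_equal(sum(pr$matrix > 0), 1)
  expect_equal(unname(pr$matrix[1, 61]), 7)   # central bin [summit, summit+25)

  cov1 <- stranded_coverage(list(chr1 = rep(1, 10000)),
                            list(chr1 = numeric(10000)), sizes)
  pr1 <- summit_profile(peaks, cov1, window_bp = 3000, bin_bp = 25)
  expect_true(all(pr1$matrix == 25))

  # row sums equal direct window counts
  set.seed(9)
  v2 <- rpois(10000, 0.5)
  cov2 <- stranded_coverage(list(chr1 = v2), list(chr1 = numeric(10000)), sizes)
  pr2 <- summit_profile(peaks, cov2, window_bp = 3000, bin_bp = 25)
  expect_equal(sum(pr2$matrix[1, ]),
               brute_region_count(v2, 5000 - 1500, 5000 + 1500))
  expect_error(summit_profile(peaks, cov, window_bp = 3000, bin_bp = 70),
               class = "enhancerlink_validation_error")
})

test_that("closest-TSS distances follow the gene-strand sign convention", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", start = c(50000L, 200000L),
    end = c(60000L, 210000L), strand = c("+", "-")
  ) |> dplyr::mutate(tss = ifelse(strand == "+", start, end - 1L))
  # peak midpoint exactly at a TSS
  at_tss <- tibble::tibble(chrom = "chr1", start = 49950L, end = 50050L, name = "x")
  expect_equal(tss_distance_stats(at_tss, genes)$distances$distance, 0)
  # 5 kb 5' of the minus-strand gene = 5 kb to its right, upstream => -5000
  up_m <- tibble::tibble(chrom = "chr1", start = 214949L, end = 215049L, name = "y")
  d <- tss_distance_stats(up_m, genes)$distances
  expect_equal(d$closest_gene, "gm")
  expect_equal(d$distance, -5000)
  expect_error(tss_distance_stats(at_tss, genes[0, ]),
               class = "enhancerlink_validation_error")
})

test_that("closest-TSS assignment matches the brute-force minimum", {
  for (seed in 1:8) {
    set.seed(seed)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15), chrom = sample(c("chr1", "chr2"), 15, TRUE),
      tss = sample.int(1e5, 15), strand = sample(c("+", "-"), 15, TRUE)
    )
    peaks <- rand_intervals(25, chrom = sample(c("chr1", "chr2"), 1))
    got <- tss_distance_stats(peaks, genes)$distances
    expect_equal(got$closest_gene, brute_closest_tss(peaks, genes))
    expect_equal(got$abs_distance,
                 abs(floor((peaks$start + peaks$end) / 2) -
                       genes$tss[match(got$closest_gene, genes$gene_id)]))
  }
})

test_that("DR-repeat scanning finds literal repeats and their classes", {
  h1 <- scan_dr_repeats("AGGTCATAGGTCA")
  expect_equal(nrow(h1), 1)
  expect_equal(h1$repeat_class, "DR1")
  expect_equal(h1$start, 0L)
  expect_equal(h1$mm1 + h1$mm2, 0L)
  h0 <- scan_dr_repeats("AGGTCAAGGTCA")
  expect_equal(h0$repeat_class, "DR0")
  # N never matches
  expect_equal(nrow(scan_dr_repeats("AGGTCNTAGGTCN",
                                    max_mismatch_per_half = 0)), 0)
  expect_error(scan_dr_repeats("AGGXCA"), class = "enhancerlink_validation_error")
})

test_that("DR scanning equals brute-force enumeration and mirrors on revcomp", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (seed in 1:6) {
    set.seed(seed)
    sq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    got <- scan_dr_repeats(sq)
    want <- brute_scan_dr(sq)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$spacer, want$spacer)
    expect_equal(got$mm1 + got$mm2, want$mm1 + want$mm2)
    # reverse complement mirrors coordinates and flips strands
    rc <- paste(rev(comp[strsplit(sq, "")[[1]]]), collapse = "")
    got_rc <- scan_dr_repeats(rc)
    expect_equal(nrow(got_rc), nrow(got))
    mirrored <- sort(nchar(sq) - got$end)
    expect_equal(sort(got_rc$start), mirrored)
  }
})
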