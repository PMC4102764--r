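peak_row <- function(start, end, score, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 name = paste0("p", start), score = score,
                 summit = as.integer((end - start) %/% 2))
}

test_that("boundary calling applies the strict score and ratio filters", {
  ctcf <- peak_row(1000, 1400, 20)
  expect_equal(nrow(call_boundaries(ctcf, peak_row(1000, 1400, 50))), 1)   # 2.5x
  expect_equal(nrow(call_boundaries(ctcf, peak_row(1000, 1400, 61))), 0)   # 3.05x
  expect_equal(nrow(call_boundaries(peak_row(1000, 1400, 15),
                                    peak_row(1000, 1400, 15))), 0)         # not > 15
  b <- call_boundaries(ctcf, peak_row(1200, 1600, 30))
  expect_equal(c(b$start, b$end), c(1200, 1400))   # intersection
  expect_equal(b$combined_score, 20)               # min of the two
})

test_that("a CTCF peak pairs with its largest-overlap RAD21 partner", {
  ctcf <- peak_row(1000, 2000, 30)
  rad <- dplyr::bind_rows(peak_row(900, 1200, 30), peak_row(1500, 2000, 40))
  b <- call_boundaries(ctcf, rad)
  expect_equal(nrow(b), 1)
  expect_equal(b$rad21_score, 40)
})

test_that("domain pairing is a greedy consume-once left-to-right scan", {
  b <- tibble::tibble(
    chrom = "chr1",
    start = c(9800, 89800), end = c(10200, 90200),
    midpoint = c(10000, 90000), combined_score = c(30, 40)
  )
  d <- pair_domains(b)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(10000, 90000))
  expect_equal(d$length, 80000)

  # dissimilar neighbour is skipped; the next similar one is taken
  b2 <- tibble::tibble(
    chrom = "chr1",
    start = c(10000, 50000, 90000), end = c(10400, 50400, 90400),
    midpoint = c(10200, 50200, 90200), combined_score = c(10, 100, 12)
  )
  d2 <- pair_domains(b2)
  expect_equal(nrow(d2), 1)
  expect_equal(c(d2$left_score, d2$right_score), c(10, 12))
  expect_equal(attr(d2, "unpaired"), 2L)   # the skipped score-100 boundary
  # each boundary consumed at most once
  expect_lte(2 * nrow(d2), nrow(b2))
})

test_that("domain merging is strict at the gap threshold and idempotent", {
  d <- tibble::tibble(chrom = "chr1",
                      start = c(0, 150000), end = c(100000, 250000),
                      length = 100000)
  m50 <- merge_active_domains(d, max_gap_bp = 100000)
  expect_equal(nrow(m50), 1)                    # 50-kb gap merges
  d2 <- tibble::tibble(chrom = "chr1",
                       start = c(0, 200000), end = c(100000, 300000),
                       length = 100000)
  expect_equal(nrow(merge_active_domains(d2, 100000)), 2)   # exactly 100 kb: no merge
  # idempotence
  m <- merge_active_domains(d, 100000)
  expect_equal(merge_active_domains(m, 100000) |> dplyr::select(chrom, start, end),
               m |> dplyr::select(chrom, start, end))
})

test_that("merging equals a brute-force transitive closure", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    start <- sort(sample.int(2e6, n))
    d <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        start = start, end = start + sample.int(8e4, n)) |>
      dplyr::arrange(chrom, start) |>
      dplyr::group_by(chrom) |>
      dplyr::filter(dplyr::row_number() == 1 | start > dplyr::lag(end, default = -1)) |>
      dplyr::ungroup() |>
      dplyr::mutate(length = end - start)
    got <- merge_active_domains(d, 5e4)
    want <- brute_merge(d, 5e4)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("gene-plus-enhancer domain residency follows the all-inside rule", {
  merged <- tibble::tibble(chrom = "chr1", start = c(0, 50000),
                           end = c(20000, 80000), length = c(20000, 30000),
                           n_domains = 1L)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000L, 52000L), end = c(3000L, 54000L),
                          strand = "+", tss = c(1000L, 52000L))
  asg <- tibble::tibble(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                        start = c(5000L, 8000L, 30000L),
                        end = c(5500L, 8500L, 30500L))
  r <- assign_to_domains(genes, asg, merged)
  expect_true(r$per_gene$inside[r$per_gene$gene_id == "g1"])    # all inside one
  expect_false(r$per_gene$inside[r$per_gene$gene_id == "g2"])   # enhancer outside
  expect_equal(r$fraction_inside, 0.5)
  # a gene without assignments is judged by its TSS alone
  r2 <- assign_to_domains(genes, asg[0, ], merged)
  expect_true(all(r2$per_gene$inside))
})

test_that("the planted domain structure is recovered exactly", {
  g <- simulate_genome(small_spec(seed = 31, noise = "none"))
  b <- call_boundaries(g$peaks$ctcf, g$peaks$rad21)
  expect_equal(nrow(b), 2 * nrow(g$domains))   # decoys all rejected
  d <- pair_domains(b)
  expect_equal(nrow(d), nrow(g$domains))
  expect_equal(d$start, g$domains$start)
  expect_equal(d$end, g$domains$end)
  expect_length(attr(d, "unpaired"), 0)
  # and all planted regulated genes land inside merged domains
  net <- run_enhancer_pipeline(as_pipeline_inputs(g))
  expect_equal(net$domain_residency$fraction_inside, 1)
})
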