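# hand-built minimal inputs for the annotation rules
mini_inputs <- function(site_fc = 2, gene_fc = c(gA = 2, gB = -2)) {
  classified <- tibble::tibble(
    chrom = "chr1", start = 10000L, end = 10500L, name = "peak1",
    score = 50, summit = 250L, gro_class = "positive", site_id = "s1"
  )
  site_records <- tibble::tibble(
    site_id = "s1", log2_fc = site_fc, q_value = 1e-4, p_value = 1e-5,
    status = factor(ifelse(site_fc > 0, "up", "down"),
                    levels = c("up", "down", "unchanged"))
  )
  gene_records <- tibble::tibble(
    gene_id = names(gene_fc), log2_fc = unname(gene_fc),
    q_value = c(1e-4, 1e-3), p_value = c(1e-5, 1e-4),
    status = factor(ifelse(gene_fc > 0, "up", "down"),
                    levels = c("up", "down", "unchanged"))
  )
  genes <- tibble::tibble(
    gene_id = names(gene_fc), chrom = "chr1",
    start = c(15000L, 60000L), end = c(20000L, 65000L),
    strand = c("+", "+")
  ) |> dplyr::mutate(tss = start)
  list(classified = classified, site_records = site_records,
       gene_records = gene_records, genes = genes)
}

test_that("sign concordance separates enhancers from silencers", {
  x <- mini_inputs(site_fc = 2)
  a <- annotate_enhancers(x$classified, x$site_records, x$gene_records, x$genes)
  expect_equal(nrow(a), 1)
  expect_equal(a$gene_id, "gA")      # closest changing gene
  expect_equal(a$reg_class, "enhancer")
  x2 <- mini_inputs(site_fc = -2)    # site down, nearest gene up -> silencer
  a2 <- annotate_enhancers(x2$classified, x2$site_records, x2$gene_records, x2$genes)
  expect_equal(a2$reg_class, "silencer")
})

test_that("distance cap drops remote regions and records the count", {
  x <- mini_inputs()
  a <- annotate_enhancers(x$classified, x$site_records, x$gene_records, x$genes,
                          max_distance_bp = 1000)
  expect_equal(nrow(a), 0)
  expect_equal(attr(a, "n_beyond_cap"), 1L)
})

test_that("a gro-positive region without a site record is an error", {
  x <- mini_inputs()
  expect_error(
    annotate_enhancers(x$classified, x$site_records[0, ], x$gene_records, x$genes),
    class = "enhancerlink_validation_error")
})

test_that("unchanged sites and genes never enter assignments", {
  x <- mini_inputs()
  x$site_records$status <- factor("unchanged", levels = levels(x$site_records$status))
  expect_equal(nrow(annotate_enhancers(x$classified, x$site_records,
                                       x$gene_records, x$genes)), 0)
  x <- mini_inputs()
  x$gene_records$status <- factor("unchanged", levels = levels(x$gene_records$status))
  expect_equal(nrow(annotate_enhancers(x$classified, x$site_records,
                                       x$gene_records, x$genes)), 0)
})

test_that("enhancers_per_gene conserves the assignment count", {
  a <- tibble::tibble(gene_id = c("g1", "g1", "g1", "g2"),
                      reg_class = "enhancer")
  h <- enhancers_per_gene(a)
  expect_equal(h$per_gene$n_regions[h$per_gene$gene_id == "g1"], 3)
  expect_equal(sum(h$histogram$n_regions * h$histogram$n_genes), nrow(a))
  empty <- enhancers_per_gene(a[0, ])
  expect_equal(nrow(empty$histogram), 0)
})

test_that("TSS-distance distribution applies the upstream sign convention", {
  a <- tibble::tibble(distance = c(-5000, 5000, -15000, 0))
  d <- tss_distance_distribution(a, breaks = seq(-2e4, 2e4, 5e3))
  expect_equal(sum(d$bins$fraction), 1)
  expect_equal(d$fraction_upstream_proximal, 0.5)   # -5000 and 0 qualify
  expect_error(tss_distance_distribution(a, breaks = c(0, -1)),
               class = "enhancerlink_validation_error")
})

test_that("network counts always satisfy the funnel identities", {
  set.seed(123)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:8), chrom = "chr1",
      tss = sort(sample.int(2e5, 8)), strand = sample(c("+", "-"), 8, TRUE)
    ) |> dplyr::mutate(start = tss, end = tss + 1000L)
    gene_records <- tibble::tibble(
      gene_id = genes$gene_id,
      log2_fc = runif(8, -3, 3), q_value = runif(8), p_value = runif(8),
      status = factor(sample(c("up", "down", "unchanged"), 8, TRUE),
                      levels = c("up", "down", "unchanged"))
    )
    sites <- tibble::tibble(site_id = sprintf("s%02d", 1:n))
    site_records <- sites |>
      dplyr::mutate(log2_fc = runif(n, -3, 3), q_value = runif(n),
                    p_value = runif(n),
                    status = factor(sample(c("up", "down", "unchanged"), n, TRUE),
                                    levels = c("up", "down", "unchanged")))
    classified <- tibble::tibble(
      chrom = "chr1", start = sample.int(2e5, n), name = sprintf("p%02d", 1:n),
      gro_class = sample(c("positive", "negative"), n, TRUE, prob = c(0.7, 0.3))
    ) |>
      dplyr::mutate(end = start + 400L,
                    site_id = ifelse(gro_class == "positive", sites$site_id, NA))
    a <- annotate_enhancers(classified, site_records, gene_records, genes)
    s <- network_summary(a, classified)
    expect_equal(s$n_gro_positive + s$n_gro_negative, s$n_peaks)
    expect_equal(s$n_enhancers + s$n_silencers, s$n_assigned)
    expect_true(all(a$gene_id %in%
                      gene_records$gene_id[gene_records$status != "unchanged"]))
    expect_true(all(a$site_id %in%
                      site_records$site_id[site_records$status != "unchanged"]))
    # permutation invariance of the input order
    perm <- sample(n)
    a2 <- annotate_enhancers(classified[perm, ], site_records[sample(n), ],
                             gene_records[sample(8), ], genes[sample(8), ])
    expect_equal(dplyr::arrange(a, name), dplyr::arrange(a2, name),
                 ignore_attr = TRUE)
  }
})

test_that("assignments recover the planted enhancer-target map without noise", {
  g <- simulate_genome(small_spec(seed = 21, noise = "none",
                                  fraction_ligand_induced = 0.4))
  net <- run_enhancer_pipeline(as_pipeline_inputs(g))
  truth <- g$enhancers |> dplyr::filter(changing)
  matched <- dplyr::inner_join(
    tidy(net) |> dplyr::select(name, gene_id),
    truth |> dplyr::select(enh_id, target = gene_id),
    by = c(name = "enh_id"))
  expect_equal(nrow(matched), nrow(truth))
  expect_gte(mean(matched$gene_id == matched$target), 0.95)
  # planted silencers come out sign-discordant
  sil_truth <- truth$enh_id[truth$reg_class == "silencer"]
  got_sil <- tidy(net)$name[tidy(net)$reg_class == "silencer"]
  expect_setequal(got_sil, sil_truth)
})
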