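#' Specification of a synthetic regulatory genome
#'
#' Parameters of the planted-ground-truth generator. The defaults are the
#' package's reference study conditions: a 10-Mb two-chromosome genome in
#' which 20% of the sequence is transcribed by a 1e6-read library (so the
#' average transcribed region sits near RPKM 500 — on a desk-scale genome
#' the RPKM denominators are tiny, which is why the basal RPKM defaults are
#' far above the thresholds used for real mammalian libraries), 120 genes,
#' 180 enhancers with outward-pointing divergent eRNA pairs whose 5' ends
#' are 150 bp apart, 120 silent (untranscribed) binding sites, 15% of genes
#' ligand-responsive at 4-fold, and 24 CTCF/RAD21-delimited domains whose
#' inter-domain gaps alternate between mergeable (< 100 kb) and extended
#' domain-free tracts.
#'
#' @param seed RNG seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes,n_enhancers,n_silent_sites Feature counts.
#' @param fraction_ligand_induced Fraction of genes responding to ligand.
#' @param fraction_repressed Fraction of responding genes that go down.
#' @param fraction_silencer Fraction of active enhancers whose eRNA change
#'   is discordant with the target gene (planted silencers).
#' @param gene_fold_change,erna_fold_change Planted fold changes (> 1).
#' @param basal_gene_rpkm,basal_erna_rpkm Vehicle-condition expression. The
#'   default (`NULL`) derives the flat self-consistent value
#'   `1e9 / transcribed_bp`, under which the expected vehicle read total
#'   equals `library_size` exactly; explicit overrides break that identity.
#' @param target_transcribed_fraction Fraction of the genome covered by
#'   planted transcripts.
#' @param divergent_gap_bp Distance between the two 5' ends of each planted
#'   divergent pair (< 300).
#' @param erna_length_range eRNA transcript length range (bp).
#' @param promoter_transcript_bp Length of the upstream divergent promoter
#'   transcript.
#' @param n_domains Number of functional domains (across the genome).
#' @param boundary_score_range Range for boundary peak scores; the two
#'   scores of a true boundary pair stay within 2.2-fold of each other.
#' @param n_decoy_boundaries CTCF/RAD21 co-peaks that must be rejected
#'   (score ratio >= 3 or score <= 15).
#' @param library_size Expected vehicle-condition read total.
#' @param noise `"poisson"` for per-base Poisson counts, `"none"` for exact
#'   expected coverage.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_chroms = 2, chrom_length = 5e6,
                           n_genes = 120, n_enhancers = 180,
                           n_silent_sites = 120,
                           fraction_ligand_induced = 0.15,
                           fraction_repressed = 0.15,
                           fraction_silencer = 0.07,
                           gene_fold_change = 4, erna_fold_change = 4,
                           basal_gene_rpkm = NULL, basal_erna_rpkm = NULL,
                           target_transcribed_fraction = 0.20,
                           divergent_gap_bp = 150,
                           erna_length_range = c(300, 500),
                           promoter_transcript_bp = 400,
                           n_domains = 24,
                           boundary_score_range = c(20, 100),
                           n_decoy_boundaries = 20,
                           library_size = 1e6,
                           noise = c("poisson", "none")) {
  spec <- list(
    seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
    n_genes = n_genes, n_enhancers = n_enhancers,
    n_silent_sites = n_silent_sites,
    fraction_ligand_induced = fraction_ligand_induced,
    fraction_repressed = fraction_repressed,
    fraction_silencer = fraction_silencer,
    gene_fold_change = gene_fold_change, erna_fold_change = erna_fold_change,
    basal_gene_rpkm = basal_gene_rpkm, basal_erna_rpkm = basal_erna_rpkm,
    target_transcribed_fraction = target_transcribed_fraction,
    divergent_gap_bp = divergent_gap_bp,
    erna_length_range = erna_length_range,
    promoter_transcript_bp = promoter_transcript_bp,
    n_domains = n_domains, boundary_score_range = boundary_score_range,
    n_decoy_boundaries = n_decoy_boundaries,
    library_size = library_size, noise = match.arg(noise)
  )
  # the self-consistent basal RPKM: with library_size reads over the planted
  # transcribed mass, RPKM r satisfies r * transcribed_bp = 1e9, which makes
  # the expected vehicle read total equal library_size at any genome scale
  flat_rpkm <- 1e9 / (target_transcribed_fraction * n_chroms * chrom_length)
  spec$basal_gene_rpkm <- basal_gene_rpkm %||% flat_rpkm
  spec$basal_erna_rpkm <- basal_erna_rpkm %||% flat_rpkm
  if (spec$basal_gene_rpkm <= 0 || spec$basal_erna_rpkm <= 0) {
    abort_validation("basal RPKM values must be positive")
  }
  with(spec, {
    if (n_chroms < 1 || n_genes < 1 || n_enhancers < 1 || n_domains < 2) {
      abort_validation("all feature counts must be >= 1 (n_domains >= 2)")
    }
    if (gene_fold_change <= 1 || erna_fold_change <= 1) {
      abort_validation("fold changes must be > 1")
    }
    if (divergent_gap_bp >= 300) abort_validation("divergent_gap_bp must be < 300")
    if (fraction_ligand_induced < 0 || fraction_ligand_induced > 1) {
      abort_validation("fraction_ligand_induced must lie in [0, 1]")
    }
  })
  structure(spec, class = "synthetic_spec")
}

# Per-chromosome domain/boundary/slot layout.
layout_chromosome <- function(chr, L, n_dom, n_genes_c, n_decoy_c, spec) {
  margin <- 5e4
  # alternate short (mergeable, < 100 kb) and long (domain-free tract)
  # inter-domain gaps so the genome has both active neighbourhoods and
  # extended inactive regions
  odd <- seq_len(n_dom - 1) %% 2 == 1
  gaps <- round(ifelse(odd, runif(n_dom - 1, 2e4, 9e4),
                       runif(n_dom - 1, 2.5e5, 4.5e5)))
  D <- round((L - 2 * margin - sum(gaps)) / n_dom)
  if (D < 4e4) {
    abort("domains do not fit the chromosome; reduce n_domains or feature density",
          class = "enhancerlink_placement_error")
  }
  left <- margin + cumsum(c(0, gaps + D))[seq_len(n_dom)]
  right <- left + D
  dom <- tibble(chrom = chr, d = seq_len(n_dom), start = left, end = right)
  # true boundary scores: the two boundaries of a domain stay within
  # 2.2-fold of each other so the pairing filter always accepts them
  lo <- spec$boundary_score_range[1]; hi <- spec$boundary_score_range[2]
  s_left <- runif(n_dom, lo, hi)
  s_right <- vapply(s_left, function(s) runif(1, max(lo, s / 2.2), min(hi, s * 2.2)), 0)
  boundaries <- tibble(
    chrom = chr,
    center = c(left, right),
    ctcf_score = c(s_left, s_right),
    rad21_score = c(s_left, s_right) * runif(2 * n_dom, 0.85, 1.18),
    kind = "boundary"
  ) |> arrange(.data$center)
  # decoys in inter-domain gaps: half violate the score ratio, half the floor
  decoys <- NULL
  decoy_gap <- integer(0)
  if (n_decoy_c > 0 && n_dom > 1) {
    decoy_gap <- rep(seq_len(n_dom - 1), length.out = n_decoy_c)
    mid <- round((right[decoy_gap] + left[decoy_gap + 1]) / 2)
    ratio_bad <- seq_len(n_decoy_c) %% 2 == 0
    cs <- ifelse(ratio_bad, runif(n_decoy_c, 18, 28), runif(n_decoy_c, 4, 13))
    rs <- ifelse(ratio_bad, cs * runif(n_decoy_c, 3.2, 4.5), cs * runif(n_decoy_c, 0.8, 1.2))
    decoys <- tibble(chrom = chr, center = mid, ctcf_score = cs,
                     rad21_score = rs, kind = "decoy")
  }
  # gene slots, round-robin over domains
  per_dom <- tabulate(rep(seq_len(n_dom), length.out = n_genes_c), n_dom)
  slots <- list_rbind(map(seq_len(n_dom), function(d) {
    k <- per_dom[d]
    if (k == 0) return(NULL)
    pad <- 8e3
    w <- floor((D - 2 * pad) / k)
    if (w < 2.6e4) {
      abort("gene slots too narrow; reduce n_genes or n_domains",
            class = "enhancerlink_placement_error")
    }
    tibble(chrom = chr, d = d,
           slot_start = left[d] + pad + (seq_len(k) - 1) * w,
           slot_end = left[d] + pad + seq_len(k) * w)
  }))
  # free spans for silent sites: gap interiors minus decoy neighbourhoods
  spans <- list()
  if (n_dom > 1) {
    for (g in seq_len(n_dom - 1)) {
      a <- right[g] + 1e3; b <- left[g + 1] - 1e3
      dec <- if (length(decoy_gap)) decoys$center[decoy_gap == g] else numeric(0)
      if (length(dec)) {
        cuts <- sort(dec)
        pts <- c(a, as.vector(rbind(cuts - 800, cuts + 800)), b)
        for (k in seq(1, length(pts) - 1, by = 2)) {
          if (pts[k + 1] - pts[k] > 4e3) spans[[length(spans) + 1]] <- c(pts[k], pts[k + 1])
        }
      } else if (b - a > 4e3) {
        spans[[length(spans) + 1]] <- c(a, b)
      }
    }
  }
  spans[[length(spans) + 1]] <- c(5e3, margin - 5e3)
  spans[[length(spans) + 1]] <- c(L - margin + 5e3, L - 5e3)
  list(domains = dom, boundaries = bind_rows(boundaries, decoys),
       slots = slots, free_spans = map(spans, ~ tibble(chrom = chr, a = .x[1], b = .x[2])) |> list_rbind())
}

#' Generate a synthetic regulatory genome with planted ground truth
#'
#' Builds a toy genome in which every downstream stage of the pipeline has a
#' known answer: gene-body transcripts with divergent promoter initiation,
#' enhancers emitting outward-pointing eRNA pairs, silent binding sites with
#' no transcription, ligand-induced fold changes at a subset of genes and
#' their enhancers, CTCF/RAD21 co-peak boundaries delimiting functional
#' domains (plus decoy co-peaks the boundary filter must reject), and
#' stranded per-base coverage for vehicle and ligand conditions with
#' optional Poisson read noise. Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional directory; when given, all standard-format files
#'   (bedGraph pairs, BED peak sets, GTF, chrom.sizes, ground-truth TSV) are
#'   written there.
#' @param write_fasta Also write a random genome FASTA with a literal DR1
#'   consensus planted at each enhancer centre.
#' @return A list of class `synthetic_genome`: `spec`, `chrom_sizes`,
#'   `genes`, `enhancers`, `truth` (one row per planted feature), `peaks`
#'   (rxr/pu1/p300/ctcf/rad21 tibbles), `domains` (planted domain
#'   intervals), `coverage_vehicle`, `coverage_ligand`.
#' @export
simulate_genome <- function(spec, out_dir = NULL, write_fasta = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  sizes <- setNames(rep(spec$chrom_length, spec$n_chroms), chroms)
  chrom_sizes <- tibble(chrom = chroms, size = as.numeric(sizes))

  n_dom_c <- tabulate(rep(seq_len(spec$n_chroms), length.out = spec$n_domains),
                      spec$n_chroms)
  n_gene_c <- tabulate(rep(seq_len(spec$n_chroms), length.out = spec$n_genes),
                       spec$n_chroms)
  n_decoy_c <- tabulate(rep(seq_len(spec$n_chroms), length.out = spec$n_decoy_boundaries),
                        spec$n_chroms)
  layouts <- map(seq_len(spec$n_chroms), function(i) {
    layout_chromosome(chroms[i], spec$chrom_length, n_dom_c[i], n_gene_c[i],
                      n_decoy_c[i], spec)
  })
  domains <- list_rbind(map(layouts, "domains")) |>
    mutate(domain_id = paste0("dom_", sprintf("%03d", row_number())))
  slots <- list_rbind(map(layouts, "slots")) |>
    left_join(domains |> select("chrom", "d", "domain_id"), by = c("chrom", "d")) |>
    select("chrom", "domain_id", "slot_start", "slot_end") |>
    arrange(.data$chrom, .data$slot_start)
  domains <- domains |> select(-"d")

  # ---- genes -------------------------------------------------------------
  n_genes <- spec$n_genes
  erna_len <- matrix(round(runif(2 * spec$n_enhancers, spec$erna_length_range[1],
                                 spec$erna_length_range[2])), ncol = 2)
  gene_budget <- spec$target_transcribed_fraction * sum(sizes) -
    sum(erna_len) - n_genes * spec$promoter_transcript_bp
  if (gene_budget < n_genes * 2000) {
    abort("transcribed-fraction budget too small for the requested gene count",
          class = "enhancerlink_placement_error")
  }
  raw <- runif(n_genes, 0.5, 1.5)
  glen <- round(raw / sum(raw) * gene_budget)
  gap <- spec$divergent_gap_bp
  pb <- spec$promoter_transcript_bp
  tss_off <- 11500

  n_changing <- round(spec$fraction_ligand_induced * n_genes)
  changing_idx <- sort(sample.int(n_genes, n_changing))
  dir_g <- integer(n_genes)
  dir_g[changing_idx] <- ifelse(
    runif(n_changing) < spec$fraction_repressed, -1L, 1L)

  genes <- map(seq_len(n_genes), function(i) {
    sl <- slots[i, ]
    jit <- sample.int(1000, 1)
    strand <- sample(c("+", "-"), 1)
    w <- sl$slot_end - sl$slot_start
    len <- min(glen[i], floor(w - tss_off - jit - 1000))
    if (strand == "+") {
      tss <- round(sl$slot_start + tss_off + jit)
      start <- tss; end <- tss + len
    } else {
      tss <- round(sl$slot_end - tss_off - jit)
      start <- tss - len + 1; end <- tss + 1
    }
    tibble(gene_id = sprintf("g%03d", i), chrom = sl$chrom,
           start = start, end = end, strand = strand, tss = tss,
           domain_id = sl$domain_id,
           direction = dir_g[i],
           true_fold = ifelse(dir_g[i] == 0, 1,
                              spec$gene_fold_change^dir_g[i]))
  }) |> list_rbind()

  # ---- enhancers ---------------------------------------------------------
  cap <- 5
  if (spec$n_enhancers > cap * n_genes) {
    abort("more enhancers requested than the gene layout can host",
          class = "enhancerlink_placement_error")
  }
  owner <- integer(spec$n_enhancers)
  load <- integer(n_genes)
  for (e in seq_len(spec$n_enhancers)) {
    repeat {
      g <- sample.int(n_genes, 1)
      if (load[g] < cap) break
    }
    load[g] <- load[g] + 1
    owner[e] <- g
  }
  enh_rank <- stats::ave(owner, owner, FUN = seq_along)
  enhancers <- map(seq_len(spec$n_enhancers), function(e) {
    g <- genes[owner[e], ]
    dist <- 3000 + (enh_rank[e] - 1) * 1600 + sample.int(300, 1)
    center <- if (g$strand == "+") g$tss - dist else g$tss + dist
    m5 <- center - floor(gap / 2)
    p5 <- m5 + gap
    gd <- dir_g[owner[e]]
    is_sil <- gd != 0 && runif(1) < spec$fraction_silencer
    ed <- if (gd == 0) 0L else if (is_sil) -gd else gd
    tibble(
      enh_id = sprintf("enh_%03d", e), gene_id = g$gene_id, chrom = g$chrom,
      center = center, minus_five_prime = m5, plus_five_prime = p5,
      minus_start = m5 - erna_len[e, 1] + 1, minus_end = m5 + 1,
      plus_start = p5, plus_end = p5 + erna_len[e, 2],
      domain_id = g$domain_id,
      direction = ed, changing = gd != 0,
      reg_class = if (gd == 0) NA_character_ else if (is_sil) "silencer" else "enhancer",
      true_fold = ifelse(ed == 0, 1, spec$erna_fold_change^ed)
    )
  }) |> list_rbind()

  # ---- silent sites ------------------------------------------------------
  spans <- list_rbind(map(layouts, "free_spans")) |>
    mutate(capacity = pmax(0, floor((.data$b - .data$a) / 1500)))
  if (sum(spans$capacity) < spec$n_silent_sites) {
    abort("not enough untranscribed space for silent sites; reduce n_silent_sites",
          class = "enhancerlink_placement_error")
  }
  silent <- list(); need <- spec$n_silent_sites
  for (i in seq_len(nrow(spans))) {
    if (need == 0) break
    k <- min(need, spans$capacity[i])
    if (k == 0) next
    pos <- round(spans$a[i] + (seq_len(k) - 0.5) * 1500)
    silent[[length(silent) + 1]] <- tibble(chrom = spans$chrom[i], center = pos)
    need <- need - k
  }
  silent <- list_rbind(silent) |>
    mutate(silent_id = sprintf("silent_%03d", row_number()))

  # ---- peak sets ---------------------------------------------------------
  mk_peaks <- function(chrom, center, half, names, scores) {
    tibble(chrom = chrom, start = as.integer(center - half),
           end = as.integer(center + half), name = names, score = scores,
           summit = as.integer(half))
  }
  rxr <- bind_rows(
    mk_peaks(enhancers$chrom, enhancers$center, 250, enhancers$enh_id,
             runif(nrow(enhancers), 20, 200)),
    mk_peaks(silent$chrom, silent$center, 250, silent$silent_id,
             runif(nrow(silent), 20, 200))
  ) |> arrange(.data$chrom, .data$start)
  with_pu1 <- runif(nrow(rxr)) < 0.8
  pu1 <- bind_rows(
    mk_peaks(rxr$chrom[with_pu1], (rxr$start + rxr$end)[with_pu1] / 2, 300,
             paste0("pu1_", seq_len(sum(with_pu1))),
             runif(sum(with_pu1), 20, 150)),
    mk_peaks(genes$chrom, genes$tss, 300,
             paste0("pu1_tss_", seq_len(nrow(genes))),
             runif(nrow(genes), 20, 150))
  ) |> arrange(.data$chrom, .data$start)
  active_enh <- enhancers |> filter(.data$changing)
  p300 <- bind_rows(
    mk_peaks(active_enh$chrom, active_enh$center, 250,
             paste0("p300_", active_enh$enh_id), runif(nrow(active_enh), 20, 150)),
    mk_peaks(genes$chrom[changing_idx], genes$tss[changing_idx], 250,
             paste0("p300_tss_", seq_along(changing_idx)),
             runif(length(changing_idx), 20, 150))
  ) |> arrange(.data$chrom, .data$start)
  all_bounds <- list_rbind(map(layouts, "boundaries"))
  ctcf <- mk_peaks(all_bounds$chrom, all_bounds$center, 200,
                   paste0("ctcf_", seq_len(nrow(all_bounds))), all_bounds$ctcf_score)
  rad21 <- mk_peaks(all_bounds$chrom, all_bounds$center, 200,
                    paste0("rad21_", seq_len(nrow(all_bounds))), all_bounds$rad21_score)

  # ---- coverage ----------------------------------------------------------
  lambda0 <- spec$library_size / 1e9   # depth per unit RPKM
  tx <- bind_rows(
    genes |> transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
                       strand = .data$strand,
                       r_veh = spec$basal_gene_rpkm,
                       r_lig = spec$basal_gene_rpkm * .data$true_fold),
    # divergent promoter transcript, opposite strand, 5' gap bp upstream
    genes |> transmute(
      chrom = .data$chrom,
      start = ifelse(.data$strand == "+",
                     .data$tss - gap - pb + 1, .data$tss + gap),
      end = ifelse(.data$strand == "+",
                   .data$tss - gap + 1, .data$tss + gap + pb),
      strand = ifelse(.data$strand == "+", "-", "+"),
      r_veh = spec$basal_erna_rpkm,
      r_lig = spec$basal_erna_rpkm * .data$true_fold),
    enhancers |> transmute(chrom = .data$chrom, start = .data$minus_start,
                           end = .data$minus_end, strand = "-",
                           r_veh = spec$basal_erna_rpkm,
                           r_lig = spec$basal_erna_rpkm * .data$true_fold),
    enhancers |> transmute(chrom = .data$chrom, start = .data$plus_start,
                           end = .data$plus_end, strand = "+",
                           r_veh = spec$basal_erna_rpkm,
                           r_lig = spec$basal_erna_rpkm * .data$true_fold)
  )
  build_cov <- function(rate_col) {
    plus <- map(as.list(sizes), numeric)
    minus <- map(as.list(sizes), numeric)
    for (i in seq_len(nrow(tx))) {
      chr <- tx$chrom[i]
      idx <- (tx$start[i] + 1):tx$end[i]
      lam <- tx[[rate_col]][i] * lambda0
      seg <- if (spec$noise == "poisson") rpois(length(idx), lam) else rep(lam, length(idx))
      if (tx$strand[i] == "+") plus[[chr]][idx] <- plus[[chr]][idx] + seg
      else minus[[chr]][idx] <- minus[[chr]][idx] + seg
    }
    stranded_coverage(plus, minus, sizes)
  }
  cov_veh <- build_cov("r_veh")
  cov_lig <- build_cov("r_lig")

  # ---- ground truth ------------------------------------------------------
  truth <- bind_rows(
    genes |> transmute(id = .data$gene_id, type = "gene", chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand, target_gene = .data$gene_id,
                       true_fold_change = .data$true_fold,
                       domain_id = .data$domain_id, reg_class = NA_character_,
                       changing = .data$direction != 0),
    genes |> transmute(id = paste0("prom_", .data$gene_id),
                       type = "promoter_site", chrom = .data$chrom,
                       start = pmin(.data$tss, ifelse(.data$strand == "+",
                                                      .data$tss - gap, .data$tss + gap)),
                       end = pmax(.data$tss, ifelse(.data$strand == "+",
                                                    .data$tss - gap, .data$tss + gap)) + 1,
                       strand = ".", target_gene = .data$gene_id,
                       true_fold_change = .data$true_fold,
                       domain_id = .data$domain_id, reg_class = NA_character_,
                       changing = .data$direction != 0),
    enhancers |> transmute(id = paste0("site_", .data$enh_id),
                           type = "enhancer_site", chrom = .data$chrom,
                           start = .data$minus_five_prime,
                           end = .data$plus_five_prime + 1, strand = ".",
                           target_gene = .data$gene_id,
                           true_fold_change = .data$true_fold,
                           domain_id = .data$domain_id,
                           reg_class = .data$reg_class,
                           changing = .data$changing),
    enhancers |> transmute(id = .data$enh_id, type = "enhancer",
                           chrom = .data$chrom, start = .data$center - 250,
                           end = .data$center + 250, strand = ".",
                           target_gene = .data$gene_id,
                           true_fold_change = .data$true_fold,
                           domain_id = .data$domain_id,
                           reg_class = .data$reg_class,
                           changing = .data$changing),
    silent |> transmute(id = .data$silent_id, type = "silent_site",
                        chrom = .data$chrom, start = .data$center - 250,
                        end = .data$center + 250, strand = ".",
                        target_gene = NA_character_, true_fold_change = 1,
                        domain_id = NA_character_, reg_class = NA_character_,
                        changing = FALSE),
    domains |> transmute(id = .data$domain_id, type = "domain",
                         chrom = .data$chrom, start = .data$start,
                         end = .data$end, strand = ".",
                         target_gene = NA_character_, true_fold_change = 1,
                         domain_id = .data$domain_id, reg_class = NA_character_,
                         changing = FALSE)
  )

  out <- structure(list(
    spec = spec, chrom_sizes = chrom_sizes,
    genes = genes |> select("gene_id", "chrom", "start", "end", "strand", "tss"),
    genes_truth = genes, enhancers = enhancers, silent_sites = silent,
    truth = truth, domains = domains,
    peaks = list(rxr = rxr, pu1 = pu1, p300 = p300, ctcf = ctcf, rad21 = rad21),
    coverage_vehicle = cov_veh, coverage_ligand = cov_lig
  ), class = "synthetic_genome")

  if (!is.null(out_dir)) write_genome_files(out, out_dir, write_fasta)
  out
}

#' @exportS3Method base::print
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", sum(x$chrom_sizes$size), "bp,",
      nrow(x$genes), "genes,", nrow(x$enhancers), "enhancers,",
      nrow(x$domains), "domains\n")
  invisible(x)
}

#' Write all standard-format files of a synthetic genome
#' @param genome A `synthetic_genome`.
#' @param out_dir Output directory (created if needed).
#' @param write_fasta Also write the genome FASTA (random sequence with a
#'   DR1 consensus planted at each enhancer centre).
#' @return `out_dir`, invisibly.
#' @export
write_genome_files <- function(genome, out_dir, write_fasta = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    abort(paste0("output directory not writable: ", out_dir),
          class = "enhancerlink_io_error")
  }
  p <- function(f) file.path(out_dir, f)
  write_chrom_sizes(genome$chrom_sizes, p("genome.chrom.sizes"))
  write_gtf(genome$genes, p("genes.gtf"))
  write_bedgraph_pair(genome$coverage_vehicle, p("vehicle_plus.bedgraph"),
                      p("vehicle_minus.bedgraph"))
  write_bedgraph_pair(genome$coverage_ligand, p("ligand_plus.bedgraph"),
                      p("ligand_minus.bedgraph"))
  for (nm in names(genome$peaks)) write_bed(genome$peaks[[nm]], p(paste0(nm, ".bed")))
  write_tsv_commented(genome$truth, p("ground_truth.tsv"))
  if (write_fasta) {
    seqs <- lapply(seq_len(nrow(genome$chrom_sizes)), function(i) {
      s <- sample(c("A", "C", "G", "T"), genome$chrom_sizes$size[i], replace = TRUE)
      enh <- genome$enhancers[genome$enhancers$chrom == genome$chrom_sizes$chrom[i], ]
      motif <- strsplit("AGGTCAAAGGTCA", "")[[1]]   # DR1 consensus
      for (cc in enh$center) s[(cc + 1):(cc + length(motif))] <- motif
      paste(s, collapse = "")
    })
    names(seqs) <- genome$chrom_sizes$chrom
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(seqs)), p("genome.fa"))
  }
  invisible(out_dir)
}

#' Simulate 3C-seq interaction read pairs for one bait
#'
#' Distributes interchromosomal reads over fixed genomic bins with planted
#' class enrichment (target > active > inactive, target at >= 3x the
#' inactive rate by default) plus a block of cis reads near the bait that
#' the comparison stage excludes. Bin classes are derived from the planted
#' truth: bins overlapping changing genes or active enhancers are target,
#' bins overlapping planted domains (merged at the 100-kb rule) are active,
#' the rest inactive.
#'
#' @param genome A `synthetic_genome`.
#' @param bait_id Enhancer id to use as bait (default: first planted active
#'   enhancer).
#' @param n_trans_reads Interchromosomal reads to distribute.
#' @param n_cis_reads Reads placed within 1 Mb of the bait.
#' @param rates Named relative per-bin rates for inactive/active/target.
#' @param bin_bp Bin size used for planting (the analysis may re-bin).
#' @return A list: `records` (tibble with bait/prey columns, one row per
#'   read) and `bin_classes` (the truth-derived class per bin).
#' @export
simulate_interactions <- function(genome, bait_id = NULL, n_trans_reads = 1000,
                                  n_cis_reads = 2000,
                                  rates = c(inactive = 1, active = 1.8, target = 3),
                                  bin_bp = 2e5) {
  active <- genome$enhancers |> filter(.data$changing)
  if (is.null(bait_id)) bait_id <- active$enh_id[1]
  bait <- genome$enhancers |> filter(.data$enh_id == !!bait_id)
  if (nrow(bait) != 1) abort_validation(paste0("unknown bait enhancer: ", bait_id))
  bins <- bin_interactions(tibble(prey_chrom = character(), prey_pos = double()),
                           genome$chrom_sizes, bin_bp = bin_bp) |>
    suppressWarnings() |>
    select("chrom", "start", "end")
  targets <- bind_rows(
    genome$truth |> filter(.data$type == "gene", .data$changing),
    genome$truth |> filter(.data$type == "enhancer", .data$changing)
  )
  merged <- merge_active_domains(genome$domains |>
                                   mutate(length = .data$end - .data$start))
  bins <- classify_bins(bins |> mutate(count = 0, frequency = 0),
                        merged, targets) |> select(-"count", -"frequency")
  trans <- bins |> filter(.data$chrom != bait$chrom)
  w <- rates[as.character(trans$bin_class)]
  counts <- as.vector(stats::rmultinom(1, n_trans_reads, w / sum(w)))
  trans_reads <- trans[rep(seq_len(nrow(trans)), counts), c("chrom", "start", "end")] |>
    mutate(prey_pos = floor(runif(n(), .data$start, .data$end))) |>
    select(prey_chrom = "chrom", "prey_pos")
  cis_pos <- round(bait$center + rnorm(n_cis_reads, 0, 3e5))
  cis_pos <- pmin(pmax(cis_pos, 0),
                  genome$chrom_sizes$size[match(bait$chrom, genome$chrom_sizes$chrom)] - 1)
  cis_reads <- tibble(prey_chrom = bait$chrom, prey_pos = cis_pos)
  records <- bind_rows(trans_reads, cis_reads) |>
    mutate(bait_id = bait$enh_id, bait_chrom = bait$chrom,
           bait_start = bait$center - 250, bait_end = bait$center + 250,
           count = 1L, .before = 1)
  list(records = records, bin_classes = bins)
}
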