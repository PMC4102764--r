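#' Pipeline configuration with the study's threshold defaults
#'
#' Collects every tunable threshold of the analysis with its default:
#' divergent-site 5'-gap 300 bp and RPKM 0.2; genome-wide transcription
#' floor 0.006 RPKM; more-than-twofold change at FDR < 0.1; boundary score
#' > 15 with score ratio < 3; 100-kb domain-merge gap; 1-Mb contact bins;
#' 3-kb summit-profile window. Unknown names are rejected.
#'
#' @param ... Named overrides of the defaults, including input `paths` (a
#'   named list) and `seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    site_gap_bp = 300, site_min_rpkm = 0.2,
    tx_min_rpkm = 0.006, tx_min_length_bp = 100, tx_max_gap_bp = 50,
    min_fold = 2, max_fdr = 0.1,
    normalization = "median_ratio",
    boundary_min_score = 15, score_ratio_limit = 3,
    domain_merge_gap_bp = 1e5,
    contact_bin_bp = 1e6,
    profile_window_bp = 3000, profile_bin_bp = 25,
    near_tss_bp = 1e4,
    seed = 1,
    paths = list()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort_validation(paste0("unknown configuration field: ", unknown[1]))
  }
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$normalization %in% c("library_size", "median_ratio")) {
    abort_validation("normalization must be 'library_size' or 'median_ratio'")
  }
  num <- setdiff(names(defaults), c("paths", "seed", "normalization"))
  bad <- num[vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, TRUE)]
  if (length(bad)) abort_validation(paste0("threshold must be positive: ", bad[1]))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged through the file.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; for the reader, the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Read all pipeline inputs from the paths in a configuration
#'
#' Required path fields: `chrom_sizes`, `vehicle_plus`, `vehicle_minus`,
#' `ligand_plus`, `ligand_minus`, `peaks`, `ctcf`, `rad21`, `genes`.
#' Optional: `interactions` (TSV with bait/prey columns).
#'
#' @param config A [pipeline_config()] whose `paths` entry is filled in.
#' @return An input list suitable for [run_enhancer_pipeline()].
#' @export
read_pipeline_inputs <- function(config) {
  need <- c("chrom_sizes", "vehicle_plus", "vehicle_minus", "ligand_plus",
            "ligand_minus", "peaks", "ctcf", "rad21", "genes")
  for (f in need) {
    if (is.null(config$paths[[f]])) {
      abort_validation(paste0("configuration is missing input path field '", f, "'"))
    }
  }
  for (f in need) {
    if (!file.exists(config$paths[[f]])) {
      abort_validation(paste0("input path for field '", f, "' does not exist: ",
                              config$paths[[f]]))
    }
  }
  cs <- read_chrom_sizes(config$paths$chrom_sizes)
  inputs <- list(
    chrom_sizes = cs,
    coverage_vehicle = read_bedgraph_pair(config$paths$vehicle_plus,
                                          config$paths$vehicle_minus, cs),
    coverage_ligand = read_bedgraph_pair(config$paths$ligand_plus,
                                         config$paths$ligand_minus, cs),
    peaks = read_bed(config$paths$peaks),
    ctcf = read_bed(config$paths$ctcf),
    rad21 = read_bed(config$paths$rad21),
    genes = read_gtf(config$paths$genes)
  )
  if (!is.null(config$paths$interactions)) {
    inputs$interactions <- read_tsv_commented(config$paths$interactions)
  }
  inputs
}

#' Turn a synthetic genome into pipeline inputs
#' @param genome A `synthetic_genome` from [simulate_genome()].
#' @param interactions Optional output of [simulate_interactions()].
#' @return Input list for [run_enhancer_pipeline()].
#' @export
as_pipeline_inputs <- function(genome, interactions = NULL) {
  list(
    chrom_sizes = genome$chrom_sizes,
    coverage_vehicle = genome$coverage_vehicle,
    coverage_ligand = genome$coverage_ligand,
    peaks = genome$peaks$rxr,
    ctcf = genome$peaks$ctcf,
    rad21 = genome$peaks$rad21,
    genes = genome$genes,
    interactions = interactions$records %||% NULL
  )
}

run_stage <- function(name, verbose, expr) {
  res <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "enhancerlink_stage_error", parent = e)
  })
  if (verbose) {
    n <- if (is.data.frame(res)) nrow(res) else NULL
    message("[", name, "] done", if (!is.null(n)) paste0(" (", n, " records)"))
  }
  res
}

#' Run the full enhancer-network analysis
#'
#' Orchestrates all stages in dependency order: transcript-unit calling on
#' the pooled coverage, divergent-site detection, GRO-positive/negative
#' classification of the binding sites, differential calling of gene-body
#' and site transcription (vehicle vs ligand), enhancer-to-gene annotation,
#' CTCF/RAD21 boundary and domain construction, domain residency of the
#' regulated genes, and (when interaction records are supplied) contact
#' binning with class comparisons. Stage-count identities (positive +
#' negative = total peaks; enhancers + silencers = assigned) are asserted at
#' the end.
#'
#' @param inputs List with `chrom_sizes`, `coverage_vehicle`,
#'   `coverage_ligand`, `peaks`, `ctcf`, `rad21`, `genes`, optionally
#'   `interactions` — see [read_pipeline_inputs()] / [as_pipeline_inputs()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for all stage outputs (TSVs plus a
#'   summary JSON).
#' @param verbose Log stage completion to the console.
#' @return A list of class `enhancer_network` with elements `units`,
#'   `sites`, `classified_peaks`, `site_records`, `gene_records`,
#'   `assignments`, `boundaries`, `domains`, `merged_domains`,
#'   `domain_residency`, `contacts` (or NULL), `summary` (one-row tibble)
#'   and `config`.
#' @export
run_enhancer_pipeline <- function(inputs, config = pipeline_config(),
                                  out_dir = NULL, verbose = FALSE) {
  cs <- inputs$chrom_sizes
  pooled <- run_stage("pool", verbose,
                      pool_coverage(inputs$coverage_vehicle, inputs$coverage_ligand))
  units <- run_stage("transcripts", verbose, call_transcript_units(
    pooled, library_size = coverage_total(pooled),
    min_rpkm = config$tx_min_rpkm, min_length_bp = config$tx_min_length_bp,
    max_gap_bp = config$tx_max_gap_bp))
  tx_fraction <- transcribed_fraction(units, cs)
  sites <- run_stage("divergent_sites", verbose, detect_divergent_sites(
    units |> filter(.data$strand == "+"),
    units |> filter(.data$strand == "-"),
    max_gap_bp = config$site_gap_bp, min_rpkm = config$site_min_rpkm))
  classified <- run_stage("classify", verbose, classify_by_gro(inputs$peaks, sites))

  lib_v <- coverage_total(inputs$coverage_vehicle)
  lib_l <- coverage_total(inputs$coverage_ligand)
  site_regions <- sites |>
    transmute(id = .data$site_id, chrom = .data$chrom,
              start = .data$minus_start, end = .data$plus_end)
  site_records <- run_stage("diff_sites", verbose, call_changes(
    site_regions |>
      mutate(count_vehicle = count_region_reads(site_regions, inputs$coverage_vehicle, "both"),
             count_ligand = count_region_reads(site_regions, inputs$coverage_ligand, "both")),
    lib_v, lib_l, min_fold = config$min_fold, max_fdr = config$max_fdr,
    normalization = config$normalization) |>
      rename(site_id = "id"))
  gene_records <- run_stage("diff_genes", verbose, call_changes(
    inputs$genes |>
      transmute(id = .data$gene_id, chrom = .data$chrom, start = .data$start,
                end = .data$end, strand = .data$strand) |>
      mutate(count_vehicle = count_region_reads(inputs$genes, inputs$coverage_vehicle, "match"),
             count_ligand = count_region_reads(inputs$genes, inputs$coverage_ligand, "match")),
    lib_v, lib_l, min_fold = config$min_fold, max_fdr = config$max_fdr,
    normalization = config$normalization) |>
      rename(gene_id = "id"))

  assignments <- run_stage("annotate", verbose, annotate_enhancers(
    classified, site_records, gene_records, inputs$genes))

  boundaries <- run_stage("boundaries", verbose, call_boundaries(
    inputs$ctcf, inputs$rad21, min_score = config$boundary_min_score,
    ratio_limit = config$score_ratio_limit))
  domains <- run_stage("domains", verbose,
                       pair_domains(boundaries, ratio_limit = config$score_ratio_limit))
  merged <- run_stage("merge_domains", verbose,
                      merge_active_domains(domains, max_gap_bp = config$domain_merge_gap_bp))
  regulated <- inputs$genes |> filter(.data$gene_id %in% assignments$gene_id)
  residency <- run_stage("domain_residency", verbose,
                         assign_to_domains(regulated, assignments, merged))

  contacts <- NULL
  if (!is.null(inputs$interactions) && nrow(inputs$interactions)) {
    contacts <- run_stage("contacts", verbose, {
      bins <- bin_interactions(inputs$interactions, cs, bin_bp = config$contact_bin_bp)
      target_regions <- bind_rows(
        regulated |> select("chrom", "start", "end"),
        assignments |> select("chrom", "start", "end")
      )
      bins <- classify_bins(bins, merged, target_regions)
      list(bins = bins,
           comparison = compare_classes(bins,
                                        bait_chrom = inputs$interactions$bait_chrom[1],
                                        exclude_cis = TRUE))
    })
  }

  summary <- network_summary(assignments, classified, upstream_bp = config$near_tss_bp) |>
    mutate(
      transcribed_fraction = tx_fraction,
      n_units = nrow(units), n_sites = nrow(sites),
      n_changing_sites = sum(site_records$status != "unchanged"),
      n_changing_genes = sum(gene_records$status != "unchanged"),
      n_boundaries = nrow(boundaries), n_domains = nrow(domains),
      median_domain_length = median(domains$length),
      mean_domain_length = mean(domains$length),
      n_merged_domains = nrow(merged),
      fraction_genes_in_domains = residency$fraction_inside
    )
  stopifnot(
    summary$n_gro_positive + summary$n_gro_negative == summary$n_peaks,
    summary$n_enhancers + summary$n_silencers == summary$n_assigned,
    all(assignments$gene_id %in% gene_records$gene_id[gene_records$status != "unchanged"])
  )
  res <- structure(list(
    units = units, sites = sites, classified_peaks = classified,
    site_records = site_records, gene_records = gene_records,
    assignments = assignments, boundaries = boundaries, domains = domains,
    merged_domains = merged, domain_residency = residency,
    contacts = contacts, summary = summary, config = config
  ), class = "enhancer_network")
  if (!is.null(out_dir)) write_network_outputs(res, out_dir)
  res
}

#' @exportS3Method base::print
print.enhancer_network <- function(x, ...) {
  s <- x$summary
  cat("<enhancer_network>\n")
  cat("  peaks:", s$n_peaks, "(", s$n_gro_positive, "GRO+,",
      s$n_gro_negative, "GRO- )\n")
  cat("  divergent sites:", s$n_sites, "| changing:", s$n_changing_sites, "\n")
  cat("  assigned regions:", s$n_assigned, "=", s$n_enhancers, "enhancers +",
      s$n_silencers, "silencers ->", s$n_regulated_genes, "genes\n")
  cat("  domains:", s$n_domains, "(median", round(s$median_domain_length / 1e3, 1),
      "kb ) merged:", s$n_merged_domains, "\n")
  cat(sprintf("  transcribed fraction: %.3f | active-enhancer fraction: %.3f\n",
              s$transcribed_fraction, s$active_enhancer_fraction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enhancer_network <- function(x, ...) as_tibble(x$assignments)

#' @exportS3Method generics::glance
glance.enhancer_network <- function(x, ...) x$summary

#' Write every stage output of a pipeline run
#' @param network An `enhancer_network`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_network_outputs <- function(network, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_commented(network$units, p("transcript_units.tsv"))
  write_tsv_commented(network$sites, p("divergent_sites.tsv"))
  write_tsv_commented(network$classified_peaks, p("classified_peaks.tsv"))
  write_tsv_commented(network$site_records, p("site_changes.tsv"))
  write_tsv_commented(network$gene_records, p("gene_changes.tsv"))
  write_tsv_commented(as_tibble(network$assignments), p("assignments.tsv"))
  write_tsv_commented(network$boundaries, p("boundaries.tsv"))
  write_tsv_commented(network$domains, p("domains.tsv"))
  write_tsv_commented(network$merged_domains, p("merged_domains.tsv"))
  if (!is.null(network$contacts)) {
    write_tsv_commented(network$contacts$bins, p("contact_bins.tsv"))
  }
  summary <- c(as.list(network$summary),
               list(config = unclass(network$config)))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' Derived network counts from stage totals
#'
#' Arithmetic identities among the funnel counts of the analysis: total
#' binding sites from the GRO-positive/negative split, assigned regions
#' from the enhancer/silencer split, the active-enhancer fraction
#' (enhancers over all binding sites) and the domain-residency fraction.
#'
#' @param n_gro_positive,n_gro_negative GRO-classification counts.
#' @param n_enhancers,n_silencers Assignment counts.
#' @param n_genes_in_domains,n_regulated_genes Domain-residency counts
#'   (optional).
#' @return One-row tibble with the derived quantities.
#' @export
summarize_network_counts <- function(n_gro_positive, n_gro_negative,
                                     n_enhancers, n_silencers,
                                     n_genes_in_domains = NA_real_,
                                     n_regulated_genes = NA_real_) {
  tibble(
    n_peaks = n_gro_positive + n_gro_negative,
    n_assigned = n_enhancers + n_silencers,
    active_enhancer_fraction = n_enhancers / (n_gro_positive + n_gro_negative),
    domain_residency = n_genes_in_domains / n_regulated_genes
  )
}

#' One-command synthetic demonstration run
#'
#' Simulates the reference synthetic genome (optionally with interaction
#' reads) and runs the full pipeline on it.
#'
#' @param seed RNG seed for the simulation.
#' @param spec Optional [synthetic_spec()] override.
#' @param with_interactions Also simulate 3C-style reads and run the
#'   contact stage (binned at 200 kb, the desk-scale analogue of 1-Mb
#'   mouse-genome bins).
#' @param ... Passed to [pipeline_config()].
#' @return A list: `genome`, `network`.
#' @export
run_demo <- function(seed = 1, spec = NULL, with_interactions = TRUE, ...) {
  spec <- spec %||% synthetic_spec(seed = seed)
  genome <- simulate_genome(spec)
  inter <- if (with_interactions) simulate_interactions(genome) else NULL
  cfg <- pipeline_config(seed = seed, ...)
  if (with_interactions) cfg$contact_bin_bp <- 2e5
  network <- run_enhancer_pipeline(as_pipeline_inputs(genome, inter), cfg)
  list(genome = genome, network = network)
}
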