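#' Link changing enhancers to the closest gene with changing expression
#'
#' Implements the enhancer-to-gene annotation step: eligible regions are
#' GRO-positive binding sites whose matched divergent site changes upon
#' ligand treatment; each is assigned to the closest changing gene on the
#' same chromosome by `|peak midpoint - TSS|` (optionally capped). A region
#' whose site change agrees in sign with its gene's change is an
#' `enhancer`; a sign-discordant one is a `silencer`. Distance ties are
#' broken toward the more significant gene (smaller q then p), then the
#' lexicographically smaller `gene_id`.
#'
#' @param classified_peaks Output of [classify_by_gro()].
#' @param site_records [call_changes()] output for divergent sites, with a
#'   `site_id` column.
#' @param gene_records [call_changes()] output for genes, with a `gene_id`
#'   column.
#' @param genes Gene tibble (for TSS/strand).
#' @param max_distance_bp Optional cap on `|midpoint - TSS|`; regions beyond
#'   it are dropped and counted in the `n_beyond_cap` attribute.
#' @return Tibble of class `enhancer_assignments`: one row per assigned
#'   region with `name`, peak coordinates, `site_id`, `site_log2_fc`,
#'   `gene_id`, `gene_log2_fc`, `reg_class`, `distance` (signed,
#'   gene-strand-oriented; negative = upstream).
#' @export
annotate_enhancers <- function(classified_peaks, site_records, gene_records,
                               genes, max_distance_bp = NULL) {
  if (nrow(genes) == 0) abort_validation("gene list is empty")
  pos <- classified_peaks |> filter(.data$gro_class == "positive")
  missing_site <- setdiff(pos$site_id, site_records$site_id)
  if (length(missing_site)) {
    abort_validation(paste0("no differential record for site ", missing_site[1]))
  }
  sr <- site_records |> select("site_id", site_status = "status",
                               site_log2_fc = "log2_fc", site_q = "q_value")
  eligible <- pos |>
    inner_join(sr, by = "site_id") |>
    filter(.data$site_status != "unchanged")
  changing_genes <- gene_records |>
    filter(.data$status != "unchanged") |>
    select("gene_id", gene_status = "status", gene_log2_fc = "log2_fc",
           gene_q = "q_value", gene_p = "p_value") |>
    inner_join(genes |> select("gene_id", gene_chrom = "chrom", "tss",
                               gene_strand = "strand"), by = "gene_id")
  empty <- tibble(
    name = character(), chrom = character(), start = integer(), end = integer(),
    midpoint = integer(), site_id = character(), site_log2_fc = double(),
    gene_id = character(), gene_log2_fc = double(), reg_class = character(),
    distance = double()
  )
  n_beyond <- 0L
  if (nrow(eligible) == 0 || nrow(changing_genes) == 0) {
    out <- empty
  } else {
    rows <- map(seq_len(nrow(eligible)), function(i) {
      g <- changing_genes[changing_genes$gene_chrom == eligible$chrom[i], ]
      if (nrow(g) == 0) return(NULL)
      mid <- midpoint0(eligible$start[i], eligible$end[i])
      d <- abs(mid - g$tss)
      g <- g[order(d, g$gene_q, g$gene_p, g$gene_id), ]
      d <- sort(d)
      if (!is.null(max_distance_bp) && d[1] > max_distance_bp) {
        n_beyond <<- n_beyond + 1L
        return(NULL)
      }
      raw <- mid - g$tss[1]
      tibble(
        name = eligible$name[i], chrom = eligible$chrom[i],
        start = eligible$start[i], end = eligible$end[i], midpoint = mid,
        site_id = eligible$site_id[i], site_log2_fc = eligible$site_log2_fc[i],
        gene_id = g$gene_id[1], gene_log2_fc = g$gene_log2_fc[1],
        reg_class = if (sign(eligible$site_log2_fc[i]) == sign(g$gene_log2_fc[1]))
          "enhancer" else "silencer",
        distance = if (g$gene_strand[1] == "-") -raw else raw
      )
    })
    out <- list_rbind(keep(rows, ~ !is.null(.x)))
    if (is.null(out) || nrow(out) == 0) out <- empty
  }
  attr(out, "n_beyond_cap") <- n_beyond
  class(out) <- c("enhancer_assignments", class(out))
  out
}

#' Number of assigned regulatory regions per gene
#'
#' @param assignments Output of [annotate_enhancers()].
#' @return A list: `per_gene` (tibble `gene_id`, `n_regions`) and
#'   `histogram` (tibble `n_regions`, `n_genes`).
#' @export
enhancers_per_gene <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(list(per_gene = tibble(gene_id = character(), n_regions = integer()),
                histogram = tibble(n_regions = integer(), n_genes = integer())))
  }
  per_gene <- assignments |> count(.data$gene_id, name = "n_regions")
  list(per_gene = per_gene,
       histogram = per_gene |> count(.data$n_regions, name = "n_genes"))
}

#' Distance distribution of assignments relative to target TSSs
#'
#' Signed, gene-strand-oriented distances binned over `breaks`; "within
#' 10 kb upstream" means distance in `(-upstream_bp, 0]`.
#'
#' @param assignments Output of [annotate_enhancers()].
#' @param breaks Monotone bin breaks (bp).
#' @param upstream_bp Width of the proximal-upstream window.
#' @return A list: `bins` (tibble `bin`, `n`, `fraction`) and
#'   `fraction_upstream_proximal`.
#' @export
tss_distance_distribution <- function(assignments,
                                      breaks = seq(-100000, 100000, by = 10000),
                                      upstream_bp = 10000) {
  if (is.unsorted(breaks, strictly = TRUE)) abort_validation("breaks must be increasing")
  d <- assignments$distance
  cuts <- cut(pmin(pmax(d, min(breaks)), max(breaks)), breaks,
              include.lowest = TRUE, right = TRUE)
  bins <- tibble(bin = levels(cuts)) |>
    left_join(tibble(bin = as.character(cuts)) |> count(.data$bin), by = "bin") |>
    mutate(n = coalesce(.data$n, 0L),
           fraction = if (length(d)) .data$n / length(d) else 0)
  list(
    bins = bins,
    fraction_upstream_proximal =
      if (length(d)) mean(d > -upstream_bp & d <= 0) else NA_real_
  )
}

#' Summary counts of an annotated enhancer network
#'
#' Aggregates the stage counts of the analysis: how many binding sites are
#' transcriptionally active, how many were assigned, the enhancer/silencer
#' split, the regulated genes, and the active-enhancer fraction (assigned
#' enhancers over all binding sites).
#'
#' @param assignments Output of [annotate_enhancers()].
#' @param classified_peaks Output of [classify_by_gro()] (for totals).
#' @param upstream_bp Window for the upstream-proximal fraction.
#' @return One-row tibble of network counts.
#' @export
network_summary <- function(assignments, classified_peaks, upstream_bp = 10000) {
  n_enh <- sum(assignments$reg_class == "enhancer")
  n_sil <- sum(assignments$reg_class == "silencer")
  stopifnot(n_enh + n_sil == nrow(assignments))
  tibble(
    n_peaks = nrow(classified_peaks),
    n_gro_positive = sum(classified_peaks$gro_class == "positive"),
    n_gro_negative = sum(classified_peaks$gro_class == "negative"),
    n_assigned = nrow(assignments),
    n_enhancers = n_enh,
    n_silencers = n_sil,
    n_regulated_genes = length(unique(assignments$gene_id)),
    active_enhancer_fraction = if (nrow(classified_peaks)) n_enh / nrow(classified_peaks) else NA_real_,
    fraction_upstream_proximal =
      tss_distance_distribution(assignments, upstream_bp = upstream_bp)$fraction_upstream_proximal
  )
}
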