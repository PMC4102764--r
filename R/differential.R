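#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' `stats::p.adjust`), with input validation and order preservation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# Vectorised exact two-sided binomial test of x successes out of n at p0.
binom_p_two_sided <- function(x, n, p0) {
  map_dbl(seq_along(x), function(i) {
    if (n[i] == 0) return(1)
    d_all <- dbinom(0:n[i], n[i], p0)
    min(1, sum(d_all[d_all <= d_all[x[i] + 1] * (1 + 1e-7)]))
  })
}

#' Call ligand-induced changes from two count libraries
#'
#' Per-region two-sided binomial test of the ligand count against the
#' vehicle + ligand total, with success probability
#' `lib_ligand / (lib_vehicle + lib_ligand)` (the conditional-Poisson test
#' for two libraries). P-values are BH-adjusted across all tested regions.
#' Fold changes are computed on per-million-normalised counts with a
#' pseudocount of 1 read in each condition (applied to the fold change only,
#' not the test). A region is `up` when its fold change exceeds `min_fold`
#' (strictly) and `q_value < max_fdr`; `down` symmetrically; otherwise
#' `unchanged`. Regions with zero total count get `p = 1` by convention.
#'
#' @param counts Tibble with an `id` column plus `count_vehicle` and
#'   `count_ligand`; any other columns are carried through.
#' @param lib_vehicle,lib_ligand Library sizes (> 0).
#' @param min_fold Strict fold-change threshold (default 2: "more than
#'   twofold").
#' @param max_fdr FDR threshold (default 0.1).
#' @param normalization `"library_size"` uses the supplied library sizes
#'   directly; `"median_ratio"` rescales the ligand library by the median
#'   per-region cpm ratio (the median-of-ratios idea), which protects the
#'   fold-change scale against composition bias when strong inductions make
#'   one library systematically deeper.
#' @return The input with added `cpm_vehicle`, `cpm_ligand`, `log2_fc`,
#'   `p_value`, `q_value`, `status` (factor up/down/unchanged); class
#'   `diff_calls`.
#' @export
call_changes <- function(counts, lib_vehicle, lib_ligand,
                         min_fold = 2, max_fdr = 0.1,
                         normalization = c("library_size", "median_ratio")) {
  normalization <- match.arg(normalization)
  if (lib_vehicle <= 0 || lib_ligand <= 0) abort_validation("library sizes must be > 0")
  if (!all(c("count_vehicle", "count_ligand") %in% names(counts))) {
    abort_validation("counts needs columns count_vehicle and count_ligand")
  }
  if (any(counts$count_vehicle < 0 | counts$count_ligand < 0)) {
    abort_validation("counts must be nonnegative")
  }
  if (normalization == "median_ratio") {
    pos <- counts$count_vehicle > 0 & counts$count_ligand > 0
    if (any(pos)) {
      m <- median((counts$count_ligand[pos] / lib_ligand) /
                    (counts$count_vehicle[pos] / lib_vehicle))
      if (is.finite(m) && m > 0) lib_ligand <- lib_ligand * m
    }
  }
  cv <- round(counts$count_vehicle); cl <- round(counts$count_ligand)
  p0 <- lib_ligand / (lib_vehicle + lib_ligand)
  pvals <- binom_p_two_sided(cl, cv + cl, p0)
  out <- counts |>
    mutate(
      cpm_vehicle = .data$count_vehicle / lib_vehicle * 1e6,
      cpm_ligand = .data$count_ligand / lib_ligand * 1e6,
      log2_fc = log2(((.data$count_ligand + 1) / lib_ligand) /
                       ((.data$count_vehicle + 1) / lib_vehicle)),
      p_value = pvals,
      q_value = benjamini_hochberg(pvals),
      status = factor(
        case_when(
          .data$q_value < max_fdr & .data$log2_fc > log2(min_fold) ~ "up",
          .data$q_value < max_fdr & .data$log2_fc < -log2(min_fold) ~ "down",
          TRUE ~ "unchanged"
        ),
        levels = c("up", "down", "unchanged")
      )
    )
  class(out) <- c("diff_calls", class(out))
  out
}

#' @exportS3Method generics::glance
glance.diff_calls <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_changing = sum(x$status != "unchanged")
  )
}

#' Call changes across a treatment time course
#'
#' Tests each post-treatment timepoint against the baseline (first element)
#' with [call_changes()]. A region is changing when any timepoint passes;
#' its sign is taken from its most significant timepoint.
#'
#' @param counts Tibble with `id` and one count column per timepoint.
#' @param count_cols Names of the count columns, baseline first.
#' @param lib_sizes Library sizes, parallel to `count_cols`.
#' @inheritParams call_changes
#' @return Tibble with `id`, `best_timepoint`, `p_value`, `q_value`,
#'   `log2_fc` (at the best timepoint) and overall `status`.
#' @export
call_changes_series <- function(counts, count_cols, lib_sizes,
                                min_fold = 2, max_fdr = 0.1) {
  if (length(count_cols) < 2 || length(count_cols) != length(lib_sizes)) {
    abort_validation("need >= 2 timepoints with matching library sizes")
  }
  base <- count_cols[1]
  per_tp <- map(count_cols[-1], function(tp) {
    call_changes(
      tibble(id = counts$id,
             count_vehicle = counts[[base]],
             count_ligand = counts[[tp]]),
      lib_vehicle = lib_sizes[1],
      lib_ligand = lib_sizes[match(tp, count_cols)],
      min_fold = min_fold, max_fdr = max_fdr
    ) |> mutate(timepoint = tp)
  }) |> list_rbind()
  per_tp |>
    group_by(.data$id) |>
    arrange(.data$p_value, .by_group = TRUE) |>
    summarise(
      best_timepoint = .data$timepoint[1],
      p_value = .data$p_value[1],
      q_value = .data$q_value[1],
      log2_fc = .data$log2_fc[1],
      status = if (any(.data$status != "unchanged")) {
        as.character(.data$status[.data$status != "unchanged"][1])
      } else "unchanged",
      .groups = "drop"
    )
}
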