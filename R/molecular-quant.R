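# Ct-based copy-number and expression arithmetic, and loading-normalized
# densitometry.

# Mean Ct per (sample, gene) within each analysis repeat; technical
# replicates are combined by the arithmetic mean of Ct.
mean_ct <- function(ct_table) {
  check_columns(ct_table, c("sample", "gene", "ct"), "Ct table")
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  if (!"analysis" %in% names(ct_table)) ct_table$analysis <- 1L
  ct_table |>
    group_by(.data$sample, .data$gene, .data$analysis) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
}

#' Copy number from Ct values against a diploid reference
#'
#' Implements the standard delta-Ct chain: technical replicates are
#' averaged to one Ct per (sample, gene, analysis); then per sample
#' `dCt = Ct_target - Ct_reference_gene`, the relative copy number
#' `n_rel = 2^-dCt` (assuming exponential, 2-fold-per-cycle amplification),
#' and the absolute copy number
#' `n_abs = n_rel / n_rel(diploid reference sample) * 2`. With several
#' analysis repeats the chain is applied per analysis and `n_abs`
#' summarized as mean +/- SEM; the diploid reference sample evaluates to
#' exactly 2 in every analysis.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct`, and
#'   optionally `analysis` (independent repeats) and `replicate`
#'   (technical replicates).
#' @param target_gene,reference_gene Assayed gene and internal reference
#'   gene.
#' @param diploid_reference_sample Sample used as the diploid (copy number
#'   2) calibrator.
#'
#' @return Tibble with one row per sample: `sample`, `delta_ct`, `n_rel`,
#'   `n_abs` (means over analyses), `n_abs_sem`, `n_analyses`.
#' @export
cnv_from_ct <- function(ct_table, target_gene = "RRM1",
                        reference_gene = "RNaseP",
                        diploid_reference_sample) {
  ct <- mean_ct(ct_table)
  for (g in c(target_gene, reference_gene)) {
    if (!g %in% ct$gene) abort(sprintf("Gene `%s` has no rows in the Ct table.", g))
  }
  if (!diploid_reference_sample %in% ct$sample) {
    abort(sprintf("Diploid reference sample `%s` not found.", diploid_reference_sample))
  }
  wide <- ct |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (any(!complete.cases(wide))) {
    abort("Every sample needs both target and reference gene Ct values in every analysis.")
  }
  per_analysis <- wide |>
    mutate(delta_ct = .data[[target_gene]] - .data[[reference_gene]],
           n_rel = 2^(-.data$delta_ct)) |>
    group_by(.data$analysis) |>
    mutate(n_abs = .data$n_rel /
             .data$n_rel[.data$sample == diploid_reference_sample] * 2) |>
    ungroup()
  per_analysis |>
    group_by(.data$sample) |>
    summarise(
      delta_ct = mean(.data$delta_ct),
      n_rel = mean(.data$n_rel),
      n_abs = mean(.data$n_abs),
      n_abs_sem = sem(.data$n_abs),
      n_analyses = n(),
      .groups = "drop"
    )
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change relative to a calibrator sample:
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_target - Ct_housekeeping)_sample -
#'         (Ct_target - Ct_housekeeping)_calibrator`.
#' Technical replicates are averaged (arithmetic mean of Ct) per analysis;
#' with several analyses the fold change is summarized as mean +/- SEM.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct`, and
#'   optionally `analysis`, `replicate`.
#' @param target_gene Gene of interest.
#' @param housekeeping_gene Housekeeping/normalizer gene (e.g. GAPDH).
#' @param calibrator_sample Sample defining fold change 1.
#'
#' @return Tibble with one row per sample: `sample`, `delta_delta_ct`,
#'   `fold_change`, `fold_change_sem`, `n_analyses`.
#' @export
ddct_expression <- function(ct_table, target_gene,
                            housekeeping_gene = "GAPDH",
                            calibrator_sample) {
  ct <- mean_ct(ct_table)
  for (g in c(target_gene, housekeeping_gene)) {
    if (!g %in% ct$gene) abort(sprintf("Gene `%s` has no rows in the Ct table.", g))
  }
  if (!calibrator_sample %in% ct$sample) {
    abort(sprintf("Calibrator sample `%s` not found.", calibrator_sample))
  }
  wide <- ct |>
    filter(.data$gene %in% c(target_gene, housekeeping_gene)) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (any(!complete.cases(wide))) {
    abort("Every sample needs both target and housekeeping Ct values in every analysis.")
  }
  per_analysis <- wide |>
    mutate(delta_ct = .data[[target_gene]] - .data[[housekeeping_gene]]) |>
    group_by(.data$analysis) |>
    mutate(delta_delta_ct = .data$delta_ct -
             .data$delta_ct[.data$sample == calibrator_sample],
           fold_change = 2^(-.data$delta_delta_ct)) |>
    ungroup()
  per_analysis |>
    group_by(.data$sample) |>
    summarise(
      delta_delta_ct = mean(.data$delta_delta_ct),
      fold_change = mean(.data$fold_change),
      fold_change_sem = sem(.data$fold_change),
      n_analyses = n(),
      .groups = "drop"
    )
}

#' Loading-normalized densitometry abundance
#'
#' Relative protein abundance from immunoblot band intensities, normalized
#' to the total protein loaded per lane and to a control sample:
#' `abundance = (intensity / load) / (intensity_control / load_control)`.
#'
#' @param data Data frame with columns `sample`, `intensity`, `load_ug`
#'   (protein loaded per lane, micrograms, > 0).
#' @param control_sample Sample defining abundance 1.
#'
#' @return Tibble with columns `sample`, `relative_abundance`.
#' @export
densitometry_abundance <- function(data, control_sample) {
  check_columns(data, c("sample", "intensity", "load_ug"), "densitometry table")
  if (any(data$load_ug <= 0)) abort("Protein loads must be strictly positive.")
  if (!control_sample %in% data$sample) {
    abort(sprintf("Control sample `%s` not found.", control_sample))
  }
  per_lane <- data |>
    group_by(.data$sample) |>
    summarise(signal = mean(.data$intensity / .data$load_ug), .groups = "drop")
  ctrl <- per_lane$signal[per_lane$sample == control_sample]
  if (ctrl <= 0) abort("Control sample has non-positive loading-normalized signal.")
  per_lane |>
    mutate(relative_abundance = .data$signal / ctrl) |>
    select("sample", "relative_abundance")
}
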