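# Chemoprotection: observed vs expected mixed-culture viability.

#' Expected viability of a mixed culture
#'
#' The ratio-weighted linear combination of the component mono-culture
#' viabilities at one dose: for a 3:1 culture,
#' `(3 * V_1 + V_2) / 4`. Weights are normalized internally to sum to 1.
#'
#' @param viabilities Numeric vector, one viability per component.
#' @param weights Positive weights matching `viabilities` (e.g. `c(3, 1)`).
#' @return The weighted mean viability.
#' @export
expected_viability <- function(viabilities, weights) {
  if (length(viabilities) != length(weights)) {
    abort("`viabilities` and `weights` must have the same length.")
  }
  if (any(weights <= 0) || any(!is.finite(weights))) {
    abort("`weights` must be positive and finite.")
  }
  sum(weights * viabilities) / sum(weights)
}

#' Chemoprotection coefficient
#'
#' The ratio of observed to expected mixed-culture viability, `C_O/E`.
#' Values above 1 indicate population-level protection of the sensitive
#' component. Undefined (returned as `NA` with a warning) where the
#' expected viability is not positive.
#'
#' @param observed,expected Viabilities (vectorized).
#' @return `observed / expected`, `NA` where `expected <= 0`.
#' @export
protection_coefficient <- function(observed, expected) {
  out <- observed / expected
  bad <- !is.finite(expected) | expected <= 0
  if (any(bad)) {
    warn(sprintf(
      "Chemoprotection coefficient undefined for %d dose(s) with expected viability <= 0.",
      sum(bad)
    ))
    out[bad] <- NA_real_
  }
  out
}

#' Per-dose chemoprotection profile of a co-culture
#'
#' Computes the expected co-culture viability at each dose as the
#' ratio-weighted combination of the mono-culture mean viabilities, the
#' observed viability from the co-culture table (per experimental replicate,
#' then mean +/- SEM), and the chemoprotection coefficient
#' `C_O/E = observed / expected`. The SEM of `C_O/E` is propagated from the
#' observed and expected SEMs by the first-order delta method. Doses where
#' the expected viability falls below `min_expected`, or is within 3 SEM of
#' zero, are retained but flagged `unstable`: the ratio is ill-conditioned
#' there and its delta-method SEM unreliable.
#'
#' @param mono Long table of mono-culture viabilities: columns `condition`,
#'   `dose_M`, `replicate`, `value`, with one condition per mixture
#'   component.
#' @param co Long table of co-culture viabilities, same columns.
#' @param ratio Named positive weights, one per mono-culture condition,
#'   e.g. `c(sensitive = 3, resistant = 1)`.
#' @param context Free-text culture context tag (e.g. `"2D"` or
#'   `"spheroid"`).
#' @param min_expected Stability threshold on the expected viability
#'   (default 0.02, i.e. 2% of the untreated signal).
#'
#' @return An object of class `protection_profile`: a tibble with one row
#'   per dose and columns `dose_M`, `observed`, `observed_sem`, `expected`,
#'   `expected_sem`, `c_oe`, `c_oe_sem`, `n`, `unstable`, plus attributes
#'   `ratio` and `context`.
#' @export
protection_profile <- function(mono, co, ratio, context = "2D",
                               min_expected = 0.02) {
  check_columns(mono, c("condition", "dose_M", "replicate", "value"), "mono-culture table")
  check_columns(co, c("condition", "dose_M", "replicate", "value"), "co-culture table")
  comps <- names(ratio)
  if (is.null(comps) || any(!nzchar(comps))) {
    abort("`ratio` must be a named vector of positive weights (one per mono-culture condition).")
  }
  if (any(ratio <= 0)) abort("`ratio` weights must be positive.")
  missing_comp <- setdiff(comps, unique(mono$condition))
  if (length(missing_comp) > 0) {
    abort(sprintf(
      "Mono-culture table has no rows for component(s): %s.",
      paste(missing_comp, collapse = ", ")
    ))
  }
  dose_sets <- c(
    lapply(comps, function(cc) sort(unique(mono$dose_M[mono$condition == cc]))),
    list(sort(unique(co$dose_M)))
  )
  ref_doses <- dose_sets[[length(dose_sets)]]
  agree <- vapply(dose_sets, function(d) isTRUE(all.equal(d, ref_doses)), logical(1))
  if (!all(agree)) {
    abort(sprintf(
      "Dose grids disagree between mono- and co-culture tables; co-culture doses: %s.",
      paste(signif(ref_doses, 3), collapse = ", ")
    ))
  }

  mono_means <- mono |>
    filter(.data$condition %in% comps) |>
    group_by(.data$condition, .data$dose_M) |>
    summarise(mean_v = mean(.data$value), sem_v = sem(.data$value), .groups = "drop")
  w <- ratio / sum(ratio)
  expected <- mono_means |>
    group_by(.data$dose_M) |>
    summarise(
      expected = sum(w[.data$condition] * .data$mean_v),
      expected_sem = sqrt(sum((w[.data$condition] * .data$sem_v)^2)),
      .groups = "drop"
    )
  observed <- co |>
    group_by(.data$dose_M) |>
    summarise(
      observed = mean(.data$value),
      observed_sem = sem(.data$value),
      n = dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    )
  prof <- left_join(observed, expected, by = "dose_M") |>
    mutate(
      c_oe = protection_coefficient(.data$observed, .data$expected),
      # first-order (delta-method) propagation of the ratio's SEM
      c_oe_sem = .data$c_oe * sqrt(
        ifelse(is.na(.data$observed_sem), 0, (.data$observed_sem / .data$observed)^2) +
          ifelse(is.na(.data$expected_sem) | .data$expected_sem == 0, 0,
                 (.data$expected_sem / .data$expected)^2)
      ),
      unstable = .data$expected < min_expected |
        .data$expected < 3 * dplyr::coalesce(.data$expected_sem, 0)
    ) |>
    arrange(.data$dose_M) |>
    select("dose_M", "observed", "observed_sem", "expected", "expected_sem",
           "c_oe", "c_oe_sem", "n", "unstable")
  structure(prof, class = c("protection_profile", class(prof)),
            ratio = ratio, context = context)
}

#' @export
print.protection_profile <- function(x, ...) {
  ratio <- attr(x, "ratio")
  cat(sprintf(
    "<protection_profile> %s culture, mixture %s\n",
    attr(x, "context"), paste(names(ratio), ratio, sep = " = ", collapse = " : ")
  ))
  NextMethod()
}
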