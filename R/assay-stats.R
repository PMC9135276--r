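# Plate-level normalization and curve fitting.

#' Normalize raw MTT absorbances to relative viability
#'
#' Computes per-well net absorbance `A560 - A690`, subtracts the mean blank
#' net absorbance, divides by the mean untreated net absorbance (within each
#' experimental replicate), and averages technical replicates within each
#' (condition, dose, experimental replicate).
#'
#' @param data Data frame with one row per well and columns `well`,
#'   `condition`, `dose_M`, `replicate` (experimental replicate), `a560`,
#'   `a690`. Blank (media-only) wells carry `condition == blank_condition`;
#'   untreated wells carry `dose_M == 0`.
#' @param blank_condition Condition label of media-only wells (default
#'   `"blank"`); if absent, no blank subtraction is applied.
#'
#' @return A tibble (one row per condition, dose and experimental
#'   replicate) with columns `condition`, `dose_M`, `replicate`,
#'   `viability`, `n_tech` — a dose-response dataset ready for
#'   [fit_dose_response()]. Untreated rows (`dose_M == 0`) are retained with
#'   viability on the same scale (mean 1 within each replicate).
#' @export
normalize_mtt <- function(data, blank_condition = "blank") {
  check_columns(data, c("well", "condition", "dose_M", "replicate", "a560", "a690"),
                "MTT plate table")
  data <- mutate(data, net = .data$a560 - .data$a690)
  blanks <- filter(data, .data$condition == blank_condition)
  blank_net <- if (nrow(blanks) > 0) mean(blanks$net) else 0
  wells <- filter(data, .data$condition != blank_condition) |>
    mutate(net = .data$net - blank_net)
  untreated <- filter(wells, .data$dose_M == 0)
  if (nrow(untreated) == 0) abort("No untreated wells (`dose_M == 0`) found.")
  ref <- untreated |>
    group_by(.data$condition, .data$replicate) |>
    summarise(untreated_net = mean(.data$net), .groups = "drop")
  if (any(ref$untreated_net <= 0)) {
    abort("Mean untreated net absorbance is <= 0; normalization undefined.")
  }
  wells |>
    left_join(ref, by = c("condition", "replicate")) |>
    group_by(.data$condition, .data$dose_M, .data$replicate) |>
    summarise(
      viability = mean(.data$net / .data$untreated_net),
      n_tech = n(),
      .groups = "drop"
    ) |>
    arrange(.data$condition, .data$replicate, .data$dose_M)
}

# Three-parameter inhibition fit for one replicate, in log-dose space with
# IC50 parameterized as log(ic50).
fit_one_dose_response <- function(dose, viability) {
  keep <- dose > 0 & is.finite(viability)
  dose <- dose[keep]; viability <- viability[keep]
  out <- list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
              converged = FALSE, extrapolated = NA, rss = NA_real_)
  if (length(unique(dose)) < 4) return(out)
  if (diff(range(viability)) < 1e-6) return(out)  # flat response
  x <- log(dose)
  top0 <- max(viability); bot0 <- min(viability)
  half <- (top0 + bot0) / 2
  lic0 <- x[which.min(abs(viability - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + exp(x - lic50)),
      start = list(top = top0, bottom = bot0, lic50 = lic0),
      lower = c(-Inf, -Inf, min(x) - log(1e4)),
      upper = c(Inf, Inf, max(x) + log(1e4)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  p <- coef(fit)
  if (p[["bottom"]] > p[["top"]]) {  # reparameterize so bottom <= top
    p[c("top", "bottom")] <- p[c("bottom", "top")]
  }
  ic50 <- exp(p[["lic50"]])
  list(
    top = p[["top"]], bottom = p[["bottom"]], ic50 = ic50,
    converged = TRUE,
    extrapolated = ic50 < min(dose) || ic50 > max(dose),
    rss = sum(stats::residuals(fit)^2)
  )
}

#' Fit three-parameter dose-response curves and extract IC50s
#'
#' Fits the inhibition model `V(c) = bottom + (top - bottom) / (1 + c/IC50)`
#' (unit Hill slope) by least squares to each experimental replicate
#' independently, in log-dose space with the IC50 parameterized on the log
#' scale for conditioning. Per-replicate IC50s are summarized as
#' mean +/- SEM. Flat or non-convergent replicates are flagged and excluded
#' from the summary; IC50s outside the tested dose range are flagged
#' `extrapolated`.
#'
#' @param data A dose-response dataset: data frame with columns `condition`,
#'   `dose_M`, `replicate`, `viability` (e.g. from [normalize_mtt()]), at
#'   least 4 distinct positive doses. Untreated rows (`dose_M == 0`) are
#'   ignored by the fit.
#'
#' @return An object of class `dose_response_fit`: a list with
#'   `replicates` (per-replicate parameter tibble), `summary` (per-condition
#'   `ic50_mean`, `ic50_sem`, `n`), and `data`. Use [tidy()] /
#'   [glance()] / [autoplot()] to inspect it.
#' @export
fit_dose_response <- function(data) {
  check_columns(data, c("condition", "dose_M", "replicate", "viability"),
                "dose-response dataset")
  treated <- filter(data, .data$dose_M > 0)
  if (length(unique(treated$dose_M)) < 4) {
    abort("At least 4 distinct positive doses are required for a 3-parameter fit.")
  }
  reps <- treated |>
    group_by(.data$condition, .data$replicate) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(fit = purrr::map(data, ~ fit_one_dose_response(.x$dose_M, .x$viability))) |>
    mutate(fit = purrr::map(.data$fit, as_tibble)) |>
    select(-data) |>
    tidyr::unnest("fit")
  summary <- reps |>
    filter(.data$converged) |>
    group_by(.data$condition) |>
    summarise(
      ic50_mean = mean(.data$ic50),
      ic50_sem = sem(.data$ic50),
      n = n(),
      .groups = "drop"
    )
  if (any(!reps$converged)) {
    bad <- filter(reps, !.data$converged)
    warn(sprintf(
      "%d replicate fit(s) did not converge (flat or degenerate response): %s.",
      nrow(bad), paste(unique(bad$condition), collapse = ", ")
    ))
  }
  structure(
    list(replicates = reps, summary = summary, data = as_tibble(data)),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> 3-parameter inhibition model, unit Hill slope\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) x$replicates

#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) x$summary

#' Evaluate a fitted dose-response curve
#'
#' @param object A `dose_response_fit`.
#' @param doses Doses (molar) to evaluate at; defaults to a log grid over
#'   the fitted range.
#' @param ... Unused.
#' @return Tibble of per-condition mean fitted curves (`condition`,
#'   `dose_M`, `viability`).
#' @export
predict.dose_response_fit <- function(object, doses = NULL, ...) {
  rng <- range(object$data$dose_M[object$data$dose_M > 0])
  doses <- doses %||% exp(seq(log(rng[1]), log(rng[2]), length.out = 100))
  object$replicates |>
    filter(.data$converged) |>
    group_by(.data$condition) |>
    summarise(top = mean(.data$top), bottom = mean(.data$bottom),
              ic50 = exp(mean(log(.data$ic50))), .groups = "drop") |>
    tidyr::expand_grid(dose_M = doses) |>
    mutate(viability = .data$bottom +
             (.data$top - .data$bottom) / (1 + .data$dose_M / .data$ic50)) |>
    select("condition", "dose_M", "viability")
}

#' Fold-resistance between two IC50s
#'
#' The ratio of a query IC50 to a reference IC50, e.g. a resistant
#' subclone's IC50 over the parental line's, or a spheroid-culture IC50
#' over the 2D IC50 of the same line.
#'
#' @param ic50_query,ic50_reference Positive IC50s in the same units.
#' @return `ic50_query / ic50_reference`.
#' @export
fold_resistance <- function(ic50_query, ic50_reference) {
  if (any(!is.finite(ic50_query)) || any(!is.finite(ic50_reference)) ||
      any(ic50_query <= 0) || any(ic50_reference <= 0)) {
    abort("IC50 values must be positive and finite.")
  }
  ic50_query / ic50_reference
}

#' Normalize cytotoxicity (dead-cell area) readouts to matched viability
#'
#' Relative death per well is the red-positive area divided by the matched
#' viability, then divided by the mean of that same quantity over untreated
#' control wells (`dose_M == 0`). Wells with viability <= 0 are excluded
#' with a warning.
#'
#' @param data Data frame with columns `condition`, `dose_M`, `replicate`,
#'   `red_area`, `viability` (matched, e.g. joined from [normalize_mtt()]
#'   output).
#' @return Tibble with columns `condition`, `dose_M`, `replicate`,
#'   `relative_death`.
#' @export
normalize_cytotox <- function(data) {
  check_columns(data, c("condition", "dose_M", "replicate", "red_area", "viability"),
                "cytotoxicity table")
  bad <- data$viability <= 0 | !is.finite(data$viability)
  if (any(bad)) {
    warn(sprintf("Excluding %d well(s) with viability <= 0.", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  data <- mutate(data, death = .data$red_area / .data$viability)
  ctrl <- data |>
    filter(.data$dose_M == 0) |>
    group_by(.data$condition) |>
    summarise(ctrl_death = mean(.data$death), .groups = "drop")
  if (nrow(ctrl) == 0 || any(ctrl$ctrl_death <= 0)) {
    abort("Untreated control death signal missing or non-positive.")
  }
  data |>
    left_join(ctrl, by = "condition") |>
    mutate(relative_death = .data$death / .data$ctrl_death) |>
    select("condition", "dose_M", "replicate", "relative_death")
}

#' Fit a logistic growth curve to a confluency time course
#'
#' Fits `confluency(t) = K / (1 + exp(-r (t - t0)))` by least squares and
#' reports the exponential-phase doubling time `log(2) / r`. Constant or
#' decreasing series are flagged non-convergent.
#'
#' @param data Data frame with columns `time_h` and `confluency` (percent),
#'   at least 6 time points.
#'
#' @return An object of class `growth_fit` with elements `K`, `r`, `t0`,
#'   `doubling_time_h`, `converged`, `rss`, `data`. Use [tidy()],
#'   [glance()] and [autoplot()] to inspect it.
#' @export
fit_logistic_growth <- function(data) {
  check_columns(data, c("time_h", "confluency"), "confluency time course")
  data <- as_tibble(data)
  t <- data$time_h; y <- data$confluency
  out <- structure(
    list(K = NA_real_, r = NA_real_, t0 = NA_real_, doubling_time_h = NA_real_,
         converged = FALSE, rss = NA_real_, data = data),
    class = "growth_fit"
  )
  if (length(t) < 6) abort("At least 6 time points are required.")
  trend <- suppressWarnings(stats::cor(t, y))  # NA for constant series
  if (diff(range(y)) < 1e-8 || !is.finite(trend) || trend <= 0) {
    warn("Constant or decreasing confluency series; growth fit flagged non-convergent.")
    return(out)
  }
  K0 <- max(y) * 1.02
  t00 <- t[which.min(abs(y - K0 / 2))]
  r0 <- 4 * max(diff(y) / diff(t), na.rm = TRUE) / K0
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.05
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + exp(-r * (t - t0))),
      start = list(K = K0, r = r0, t0 = t00),
      lower = c(1e-6, 1e-6, -Inf), upper = c(100, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("Logistic growth fit did not converge.")
    return(out)
  }
  p <- coef(fit)
  out$K <- p[["K"]]; out$r <- p[["r"]]; out$t0 <- p[["t0"]]
  out$doubling_time_h <- log(2) / p[["r"]]
  out$converged <- TRUE
  out$rss <- sum(stats::residuals(fit)^2)
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<growth_fit> K = %.1f%%, r = %.4f /h, t0 = %.1f h, doubling time = %.2f h\n",
      x$K, x$r, x$t0, x$doubling_time_h
    ))
  } else {
    cat("<growth_fit> non-convergent\n")
  }
  invisible(x)
}

#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("K", "r", "t0"),
    estimate = c(x$K, x$r, x$t0)
  )
}

#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    K = x$K, r = x$r, t0 = x$t0,
    doubling_time_h = x$doubling_time_h,
    converged = x$converged, rss = x$rss, n = nrow(x$data)
  )
}
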