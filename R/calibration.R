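#' Coefficient of variation of replicate k' values
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) standard
#' deviation, the replicate-precision summary reported per standard.
#'
#' @param values Numeric vector of at least two replicate measurements.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(0.9, 1.0, 1.1)) # 10
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    abort("CV needs at least two replicate values.",
          class = "taqase_domain_error")
  }
  m <- mean(values)
  if (!is.finite(m) || m == 0) {
    abort("CV undefined for zero or non-finite mean.",
          class = "taqase_domain_error")
  }
  100 * sd(values) / m
}

#' Average replicate CV over all standards (Intra-CV)
#'
#' Unweighted arithmetic mean of the per-standard CVs, including the pure
#' (x = 0 and x = 1) standards even though those are excluded from the
#' regression itself.
#'
#' @param points Either a numeric vector of CV percentages or a data frame
#'   with a `cv_percent` column (e.g. from [standard_points()] or
#'   [reference_standards()]).
#' @return Mean CV in percent.
#' @export
intra_cv <- function(points) {
  cvs <- if (is.data.frame(points)) points$cv_percent else points
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0) {
    abort("No CV values available.", class = "taqase_domain_error")
  }
  mean(cvs)
}

#' Aggregate per-well k' values into standard points
#'
#' Joins the per-well k' table with the sample sheet, keeps STANDARD wells,
#' and summarises replicates per predefined mixture fraction: replicate k'
#' values, their mean, and the replicate CV.
#'
#' @param kprime Tibble from [kprime_table()].
#' @param sample_sheet Tibble with at least `well`, `role`, `x_true`,
#'   `replicate` (see [read_sample_sheet()]).
#' @return Tibble with columns `x_true`, `n_replicates`, `k_values`
#'   (list-column), `k_mean`, `cv_percent` (`NA` with a warning when a
#'   standard has a single usable replicate).
#' @export
standard_points <- function(kprime, sample_sheet) {
  joined <- left_join(kprime, sample_sheet, by = "well")
  std <- filter(joined, .data$role == "STANDARD", !is.na(.data$k_prime))
  if (nrow(std) == 0) {
    abort("No usable STANDARD wells.", class = "taqase_calibration_error")
  }
  out <- std |>
    group_by(.data$x_true) |>
    summarise(n_replicates = dplyr::n(),
              k_values = list(.data$k_prime),
              k_mean = mean(.data$k_prime),
              cv_percent = if (dplyr::n() >= 2) {
                coefficient_of_variation(.data$k_prime)
              } else {
                NA_real_
              },
              .groups = "drop") |>
    arrange(.data$x_true)
  if (anyNA(out$cv_percent)) {
    warn("Some standards have a single replicate; CV undefined there.")
  }
  out
}

#' Build the k' standard curve
#'
#' Ordinary least squares of the replicate-averaged k' on the predefined
#' mixture fraction `x_true` (fraction of the VIC-detected allele). The pure
#' standards (x = 0 and x = 1) are excluded by default: measured pure
#' plasmids behave aberrantly and do not sit on the line through the mixed
#' standards, and the biological samples of interest are heterozygous anyway.
#' The slope sign is unconstrained; calibration works for either orientation
#' of k' in x.
#'
#' @param points Data frame with columns `x_true` and `k_mean` (e.g. from
#'   [standard_points()] or [reference_standards()]). Alternatively replicate-
#'   level rows with columns `x_true` and `k_prime`, which are averaged first.
#' @param exclude_pure Drop x = 0 and x = 1 before fitting (default `TRUE`).
#' @param assay Label stored with the curve (`"cDNA"`, `"gDNA"`, ...).
#' @return A `standard_curve` object with elements `slope`, `intercept`,
#'   `r_squared`, `n_points`, `excluded_pure`, `assay`, the fitted `model`
#'   and the included `points`.
#' @export
#' @examples
#' pts <- tibble::tibble(x_true = c(0.2, 0.4, 0.6, 0.8),
#'                       k_mean = 0.4 + 0.3 * c(0.2, 0.4, 0.6, 0.8))
#' build_standard_curve(pts, assay = "cDNA")
build_standard_curve <- function(points, exclude_pure = TRUE,
                                 assay = "cDNA") {
  stopifnot(is.data.frame(points))
  if (!"k_mean" %in% names(points)) {
    if (!"k_prime" %in% names(points)) {
      abort("`points` needs a `k_mean` (or replicate `k_prime`) column.",
            class = "taqase_calibration_error")
    }
    points <- points |>
      group_by(.data$x_true) |>
      summarise(k_mean = mean(.data$k_prime), .groups = "drop")
  }
  pts <- filter(points, is.finite(.data$x_true), is.finite(.data$k_mean))
  if (exclude_pure) {
    pts <- filter(pts, .data$x_true > 0, .data$x_true < 1)
  }
  if (nrow(pts) < 3 || length(unique(pts$x_true)) < 3) {
    abort("Underdetermined calibration: need >= 3 distinct standards.",
          class = "taqase_calibration_error")
  }
  model <- lm(k_mean ~ x_true, data = pts)
  structure(
    list(slope = unname(coef(model)[2]),
         intercept = unname(coef(model)[1]),
         r_squared = suppressWarnings(summary(model)$r.squared),
         n_points = nrow(pts),
         excluded_pure = exclude_pure,
         assay = assay,
         model = model,
         points = as_tibble(pts)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s assay, %d points%s\n", x$assay,
              x$n_points,
              if (x$excluded_pure) " (pure standards excluded)" else ""))
  cat(sprintf("k' = %.4f + %.4f * x,  R^2 = %.4f\n", x$intercept, x$slope,
              x$r_squared))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_points = x$n_points,
         excluded_pure = x$excluded_pure, assay = x$assay)
}

#' Invert the standard curve for one sample
#'
#' Averages the replicate k' values and maps them through the inverse of the
#' calibration line, `x_hat = (mean(k) - intercept) / slope`. Estimates
#' falling outside [0, 1] are clamped with an explicit flag (raw inversions
#' can leave the calibrated range, as the aberrant pure plasmids show).
#' Per-replicate inversions are also returned so replicate spread survives to
#' the tissue level.
#'
#' @param k_values Numeric vector of replicate k' values for one sample.
#' @param curve A [build_standard_curve()] object.
#' @param sample_id,tissue Labels carried through to the output.
#' @return One-row tibble: `sample_id`, `tissue`, `n_replicates`, `k_mean`,
#'   `x_hat`, `x_hat_sd` (sd of per-replicate inversions; `NA` for a single
#'   replicate), `clamped`.
#' @export
#' @examples
#' pts <- tibble::tibble(x_true = c(0.2, 0.5, 0.8),
#'                       k_mean = 0.4 + 0.3 * c(0.2, 0.5, 0.8))
#' curve <- build_standard_curve(pts)
#' estimate_frequency(0.55, curve, sample_id = "s1", tissue = "ovary")
estimate_frequency <- function(k_values, curve, sample_id = NA_character_,
                               tissue = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"))
  k_values <- k_values[!is.na(k_values)]
  if (length(k_values) == 0) {
    abort("No k' values to invert.", class = "taqase_domain_error")
  }
  if (abs(curve$slope) < 1e-10) {
    abort("Non-informative calibration: slope is (numerically) zero.",
          class = "taqase_calibration_error")
  }
  invert <- function(k) (k - curve$intercept) / curve$slope
  raw <- invert(mean(k_values))
  per_rep <- invert(k_values)
  tibble(sample_id = sample_id, tissue = tissue,
         n_replicates = length(k_values),
         k_mean = mean(k_values),
         x_hat = min(1, max(0, raw)),
         x_hat_sd = if (length(k_values) >= 2) sd(per_rep) else NA_real_,
         clamped = raw < 0 || raw > 1)
}

#' Allele-frequency estimates for all unknown samples on a plate
#'
#' Groups UNKNOWN wells by sample and tissue, pools technical replicates, and
#' inverts each sample's mean k' through the standard curve.
#'
#' @inheritParams standard_points
#' @param curve A [build_standard_curve()] object.
#' @return Tibble with one row per (sample_id, tissue):
#'   see [estimate_frequency()].
#' @export
estimate_frequencies <- function(kprime, sample_sheet, curve) {
  joined <- left_join(kprime, sample_sheet, by = "well")
  unk <- filter(joined, .data$role == "UNKNOWN", !is.na(.data$k_prime))
  if (nrow(unk) == 0) {
    abort("No usable UNKNOWN wells.", class = "taqase_domain_error")
  }
  unk |>
    group_by(.data$sample_id, .data$tissue) |>
    dplyr::group_map(~ estimate_frequency(.x$k_prime, curve,
                                          sample_id = .y$sample_id,
                                          tissue = .y$tissue)) |>
    list_rbind() |>
    arrange(.data$tissue, .data$sample_id)
}
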