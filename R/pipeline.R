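#' Run the full ASE quantification pipeline on one plate
#'
#' Chains every stage: two-step sigmoid fitting of each channel curve, the
#' per-well transformed fluorescence ratio k', replicate aggregation of the
#' standards, the OLS standard curve (pure standards excluded by default),
#' inversion of each unknown sample's mean k' to an allele-frequency
#' estimate, per-tissue summaries with tests against a 1:1 ratio, and — when
#' at least two tissues have at least two biological samples — a one-way
#' ANOVA with post-hoc contrasts.
#'
#' A per-well log records the branch taken, convergence, truncation cycle
#' and any failure note, so every downstream number can be traced.
#'
#' @param fluorescence Long-format readings: tibble or CSV path (see
#'   [read_fluorescence_csv()]).
#' @param sample_sheet Plate annotation: tibble or CSV path (see
#'   [read_sample_sheet()]).
#' @param assay Label for the standard curve (`"cDNA"` or `"gDNA"`).
#' @param exclude_pure Exclude x = 0 / x = 1 standards from the calibration.
#' @param alpha Significance level for the per-tissue 1:1 test.
#' @param posthoc Post-hoc method, see [anova_across_tissues()].
#' @inheritParams fit_amplification
#' @return An `ase_pipeline` object: `fits`, `kprime`, `standard_points`,
#'   `standard_curve`, `estimates`, `tissues`, `anova` (or `NULL`), `log`.
#' @export
#' @examples
#' plate <- simulate_plate(
#'   plate_design(standard_fractions = c(0.2, 0.4, 0.6, 0.8), replicates = 2,
#'                unknowns = tibble::tibble(sample_id = c("s1", "s2"),
#'                                          tissue = "ovary",
#'                                          true_x = c(0.7, 0.75))),
#'   seed = 11)
#' res <- run_ase_pipeline(plate$fluorescence, plate$sample_sheet)
#' res$estimates
run_ase_pipeline <- function(fluorescence, sample_sheet, assay = "cDNA",
                             exclude_pure = TRUE, alpha = 0.05,
                             posthoc = "tukey", two_step = TRUE,
                             tol = 1e-10, max_iter = 500, plateau_mult = 3) {
  if (is.character(fluorescence)) {
    fluorescence <- read_fluorescence_csv(fluorescence)
  } else {
    fluorescence <- validate_fluorescence(fluorescence)
  }
  if (is.character(sample_sheet)) {
    sample_sheet <- read_sample_sheet(sample_sheet)
  } else {
    sample_sheet <- validate_sample_sheet(sample_sheet)
  }
  orphan <- setdiff(sample_sheet$well, unique(fluorescence$well))
  if (length(orphan) > 0) {
    abort(sprintf("Sample sheet references wells absent from fluorescence data: %s.",
                  paste(head(orphan, 3), collapse = ", ")),
          class = "taqase_parse_error")
  }
  extra <- setdiff(unique(fluorescence$well), sample_sheet$well)
  if (length(extra) > 0) {
    warn(sprintf("%d well(s) in fluorescence data have no sample-sheet entry and are ignored.",
                 length(extra)))
    fluorescence <- filter(fluorescence, .data$well %in% sample_sheet$well)
  }
  if (!any(sample_sheet$role == "STANDARD")) {
    abort("Cannot calibrate: no STANDARD wells on the plate.",
          class = "taqase_calibration_error")
  }
  fits <- fit_amplification(fluorescence, two_step = two_step, tol = tol,
                            max_iter = max_iter,
                            plateau_mult = plateau_mult)
  kp <- kprime_table(fits)
  pts <- standard_points(kp, sample_sheet)
  curve <- build_standard_curve(pts, exclude_pure = exclude_pure,
                                assay = assay)
  has_unknowns <- any(sample_sheet$role == "UNKNOWN" & sample_sheet$well
                      %in% kp$well[!is.na(kp$k_prime)])
  estimates <- if (has_unknowns) {
    estimate_frequencies(kp, sample_sheet, curve)
  } else {
    NULL
  }
  tissues <- NULL
  anova <- NULL
  if (!is.null(estimates)) {
    tissues <- tissue_summary(estimates, alpha = alpha)
    enough <- sum(table(estimates$tissue) >= 2) >= 2 &&
      all(table(estimates$tissue) >= 2)
    if (enough) {
      anova <- anova_across_tissues(estimates, posthoc = posthoc)
    }
  }
  log <- fits |>
    select("well", "channel", "converged", "truncation_cycle",
           "step2_fallback", "note") |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("converged", "truncation_cycle",
                                       "step2_fallback", "note")) |>
    left_join(select(kp, "well", "branch", "k_prime",
                     kprime_note = "note"),
              by = "well")
  if (!is.null(estimates) && any(estimates$clamped)) {
    warn(sprintf("%d sample estimate(s) fell outside [0, 1] and were clamped.",
                 sum(estimates$clamped)))
  }
  structure(
    list(fits = fits, kprime = kp, standard_points = pts,
         standard_curve = curve, estimates = estimates, tissues = tissues,
         anova = anova, log = log),
    class = "ase_pipeline"
  )
}

#' @export
print.ase_pipeline <- function(x, ...) {
  cat("<ase_pipeline>\n")
  print(x$standard_curve)
  n_fail <- sum(!x$fits$converged)
  cat(sprintf("%d wells, %d channel fits (%d failed)\n",
              length(unique(x$fits$well)), nrow(x$fits), n_fail))
  if (!is.null(x$estimates)) {
    cat(sprintf("%d sample estimates in %d tissue(s)\n", nrow(x$estimates),
                length(unique(x$estimates$tissue))))
  }
  if (!is.null(x$anova)) {
    print(x$anova)
  }
  invisible(x)
}

#' @export
glance.ase_pipeline <- function(x, ...) {
  tibble(assay = x$standard_curve$assay,
         r_squared = x$standard_curve$r_squared,
         n_standards = x$standard_curve$n_points,
         n_samples = if (is.null(x$estimates)) 0L else nrow(x$estimates),
         n_failed_fits = sum(!x$fits$converged))
}

#' @export
tidy.ase_pipeline <- function(x, ...) {
  if (is.null(x$estimates)) {
    abort("Pipeline has no unknown-sample estimates to tidy.")
  }
  x$estimates
}

#' Write pipeline results to disk
#'
#' Serialises the results bundle: `kprime.tsv` (per-well k' with branch and
#' fit parameters), `standards.tsv`, `estimates.tsv`, `log.tsv`, and
#' `report.json` (standard curve, tissue summaries and ANOVA at full
#' precision; frequencies as fractions).
#'
#' @param pipeline An [run_ase_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ase_results <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "ase_pipeline"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  readr::write_tsv(pipeline$kprime, file.path(dir, "kprime.tsv"))
  readr::write_tsv(select(pipeline$standard_points, -"k_values"),
                   file.path(dir, "standards.tsv"))
  if (!is.null(pipeline$estimates)) {
    readr::write_tsv(pipeline$estimates, file.path(dir, "estimates.tsv"))
  }
  readr::write_tsv(pipeline$log, file.path(dir, "log.tsv"))
  report <- list(
    standard_curve = as.list(glance(pipeline$standard_curve)),
    coefficients = list(slope = pipeline$standard_curve$slope,
                        intercept = pipeline$standard_curve$intercept),
    tissues = pipeline$tissues,
    anova = if (!is.null(pipeline$anova)) {
      list(overall = as.list(glance(pipeline$anova)),
           posthoc = pipeline$anova$posthoc)
    }
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
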