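#' Conditional fluorescence ratio R' of a dual-channel reaction
#'
#' Combines the fitted sigmoid parameters of the FAM and VIC channels of one
#' reaction into the branch-conditional ratio R'. Which branch applies depends
#' on which channel reached its maximum amplification speed (inflection cycle
#' `b`) first:
#'
#' * `b_fam < b_vic`:  `R' = 0.5 (a_fam / a_vic) (1 + exp(-(b_fam - b_vic) / c_vic))`
#' * `b_fam > b_vic`:  `R' = 2 (a_fam / a_vic) / (1 + exp(-(b_vic - b_fam) / c_fam))`
#' * `b_fam = b_vic` (within `tie_tol` cycles): both expressions coincide at
#'   `a_fam / a_vic`.
#'
#' R' is continuous in `b_fam - b_vic` across the branch switch.
#'
#' @param fam_fit,vic_fit `sigmoid_fit` objects (or lists with elements `a`,
#'   `b`, `c` and optionally `converged`) for the FAM and VIC channels.
#' @param tie_tol Absolute tolerance (cycles) under which the two inflection
#'   cycles are treated as equal.
#' @return A list with `r_prime` (positive scalar) and `branch` (one of
#'   `"EQ1"`, `"EQ2"`, `"TIE"`).
#' @export
#' @examples
#' fam <- list(a = 2, b = 10, c = 2, converged = TRUE)
#' vic <- list(a = 1, b = 12, c = 2, converged = TRUE)
#' compute_r_prime(fam, vic) # 1 + e
compute_r_prime <- function(fam_fit, vic_fit, tie_tol = 1e-9) {
  for (f in list(fam_fit, vic_fit)) {
    if (!is.null(f$converged) && !isTRUE(f$converged)) {
      abort("Unfit curve: channel fit did not converge.",
            class = "taqase_unfit_curve")
    }
    if (!all(is.finite(c(f$a, f$b, f$c)))) {
      abort("Unfit curve: non-finite parameters.",
            class = "taqase_unfit_curve")
    }
  }
  if (vic_fit$a <= 0) {
    abort("Degenerate VIC channel: plateau amplitude must be positive.",
          class = "taqase_degenerate_channel")
  }
  if (fam_fit$a <= 0) {
    abort("Degenerate FAM channel: plateau amplitude must be positive.",
          class = "taqase_degenerate_channel")
  }
  if (fam_fit$c <= 0 || vic_fit$c <= 0) {
    abort("Slope scales must be positive.", class = "taqase_degenerate_channel")
  }
  amp_ratio <- fam_fit$a / vic_fit$a
  db <- fam_fit$b - vic_fit$b
  if (abs(db) <= tie_tol) {
    list(r_prime = amp_ratio, branch = "TIE")
  } else if (db < 0) {
    list(r_prime = 0.5 * amp_ratio * (1 + exp(-db / vic_fit$c)),
         branch = "EQ1")
  } else {
    list(r_prime = 2 * amp_ratio / (1 + exp(db / fam_fit$c)),
         branch = "EQ2")
  }
}

#' Transformed fluorescence ratio k'
#'
#' Maps the ratio R' into the unit interval: `k' = R' / (R' + 1)`, a strictly
#' increasing bijection from (0, Inf) to (0, 1) with `k'(1) = 0.5` (balanced
#' channels). k' is the per-reaction statistic that is calibrated against
#' plasmid mixtures of known allele composition.
#'
#' @param r_prime Positive finite ratio (vectorised).
#' @return k' in (0, 1).
#' @export
#' @examples
#' compute_k_prime(1)            # 0.5
#' compute_k_prime(exp(1) + 1)   # the EQ1 example of compute_r_prime()
compute_k_prime <- function(r_prime) {
  if (!all(is.finite(r_prime)) || any(r_prime <= 0)) {
    abort("`r_prime` must be positive and finite.",
          class = "taqase_domain_error")
  }
  r_prime / (r_prime + 1)
}

#' k' for a single dual-channel reaction
#'
#' Fits both channel curves with the two-step sigmoid procedure, then applies
#' the branch-conditional ratio and its transform.
#'
#' @param fam_curve,vic_curve Data frames with columns `cycle` and
#'   `fluorescence` (and optionally `channel`, which is then checked to be
#'   `"FAM"` / `"VIC"` respectively).
#' @inheritParams fit_sigmoid_two_step
#' @param two_step Use the two-step plateau-robust fit (default) or a single
#'   full-curve fit.
#' @return One-row tibble: `branch`, `r_prime`, `k_prime`, and the fitted
#'   parameters of both channels (`a_fam` ... `c_vic`).
#' @export
k_prime_for_reaction <- function(fam_curve, vic_curve, two_step = TRUE,
                                 tol = 1e-10, max_iter = 500,
                                 plateau_mult = 3) {
  check_channel_label <- function(curve, expected) {
    if (!is.null(curve$channel) &&
        !all(toupper(as.character(curve$channel)) == expected)) {
      abort(sprintf("Expected a %s curve.", expected),
            class = "taqase_channel_mismatch")
    }
  }
  check_channel_label(fam_curve, "FAM")
  check_channel_label(vic_curve, "VIC")
  fitter <- if (two_step) fit_sigmoid_two_step else fit_sigmoid_single
  fam <- fitter(fam_curve$cycle, fam_curve$fluorescence, tol, max_iter)
  vic <- fitter(vic_curve$cycle, vic_curve$fluorescence, tol, max_iter)
  rp <- compute_r_prime(fam, vic)
  tibble(branch = rp$branch, r_prime = rp$r_prime,
         k_prime = compute_k_prime(rp$r_prime),
         a_fam = fam$a, b_fam = fam$b, c_fam = fam$c,
         a_vic = vic$a, b_vic = vic$b, c_vic = vic$c)
}

#' Per-well k' table from fitted channel parameters
#'
#' Pairs the FAM and VIC fits of each well (output of [fit_amplification()])
#' and computes R' and k'. Wells with a missing channel or a failed fit are
#' kept with `NA` values and a `note`, so nothing silently disappears from
#' the plate.
#'
#' @param fits Tibble from [fit_amplification()].
#' @return Tibble with one row per well: `well`, `branch`, `r_prime`,
#'   `k_prime`, the six channel parameters, and `note`.
#' @export
kprime_table <- function(fits) {
  stopifnot(is.data.frame(fits))
  wells <- unique(fits$well)
  rows <- map(wells, function(w) {
    sub <- filter(fits, .data$well == w)
    fam <- filter(sub, .data$channel == "FAM")
    vic <- filter(sub, .data$channel == "VIC")
    out <- tibble(well = w, branch = NA_character_, r_prime = NA_real_,
                  k_prime = NA_real_, a_fam = NA_real_, b_fam = NA_real_,
                  c_fam = NA_real_, a_vic = NA_real_, b_vic = NA_real_,
                  c_vic = NA_real_, note = NA_character_)
    if (nrow(fam) != 1 || nrow(vic) != 1) {
      out$note <- "missing_channel"
      return(out)
    }
    if (!fam$converged || !vic$converged) {
      out$note <- paste(na.omit(c(fam$note, vic$note, "unfit_channel"))[1])
      return(out)
    }
    rp <- tryCatch(
      compute_r_prime(list(a = fam$a, b = fam$b, c = fam$c),
                      list(a = vic$a, b = vic$b, c = vic$c)),
      error = function(e) NULL
    )
    if (is.null(rp)) {
      out$note <- "degenerate_channel"
      return(out)
    }
    out$branch <- rp$branch
    out$r_prime <- rp$r_prime
    out$k_prime <- compute_k_prime(rp$r_prime)
    out$a_fam <- fam$a; out$b_fam <- fam$b; out$c_fam <- fam$c
    out$a_vic <- vic$a; out$b_vic <- vic$b; out$c_vic <- vic$c
    out
  })
  list_rbind(rows)
}
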