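#' Four-parameter sigmoid model of an amplification curve
#'
#' Evaluates `y0 + a / (1 + exp(-(t - b) / c))`: baseline fluorescence `y0`,
#' plateau amplitude `a` above baseline, inflection cycle `b` and slope scale
#' `c` (cycles). This is the model fitted to each raw single-channel TaqMan
#' amplification curve.
#'
#' @param t Cycle number (numeric vector).
#' @param y0,a,b,c Model parameters.
#' @return Fluorescence at each cycle.
#' @export
#' @examples
#' sigmoid4(1:46, y0 = 0.1, a = 3, b = 20, c = 1.5)
sigmoid4 <- function(t, y0, a, b, c) {
  y0 + a / (1 + exp(-(t - b) / c))
}

# Validate a single-channel curve: consecutive integer cycles, finite
# fluorescence, at least 8 cycles (4 parameters need slack).
check_curve <- function(cycle, fluorescence, call = caller_env()) {
  if (length(cycle) != length(fluorescence)) {
    abort("`cycle` and `fluorescence` must have equal length.",
          class = "taqase_invalid_curve", call = call)
  }
  if (length(cycle) < 8) {
    abort("An amplification curve needs at least 8 cycles.",
          class = "taqase_invalid_curve", call = call)
  }
  if (!all(is.finite(cycle)) || !all(is.finite(fluorescence))) {
    abort("Curve contains non-finite values.",
          class = "taqase_invalid_curve", call = call)
  }
  d <- diff(cycle)
  if (any(d != 1)) {
    abort("Cycles must be strictly increasing consecutive integers.",
          class = "taqase_invalid_curve", call = call)
  }
  invisible(TRUE)
}

#' Seed values for the four-parameter sigmoid fit
#'
#' Heuristic starting values: `y0` is the curve minimum, `a` the observed
#' range, `b` the midpoint of the steepest single-cycle rise (median of tied
#' positions, so a featureless ramp seeds near mid-curve), and `c` the cycle
#' span over which fluorescence crosses from 25% to 75% of its range, divided
#' by `2 * log(3)` (the exact crossing width of a logistic), floored at 0.5.
#'
#' @param cycle Integer cycle numbers (consecutive).
#' @param fluorescence Raw fluorescence, same length.
#' @return Named list with components `y0`, `a`, `b`, `c`.
#' @export
initial_guess <- function(cycle, fluorescence) {
  check_curve(cycle, fluorescence)
  rng <- max(fluorescence) - min(fluorescence)
  if (rng <= 1e-10 * max(1, max(abs(fluorescence)))) {
    abort("Flat curve: no amplification detected.",
          class = "taqase_no_amplification")
  }
  d <- diff(fluorescence)
  steepest <- which(d == max(d))
  b0 <- median(cycle[steepest]) + 0.5
  lo <- min(fluorescence) + 0.25 * rng
  hi <- min(fluorescence) + 0.75 * rng
  mid <- cycle[fluorescence >= lo & fluorescence <= hi]
  c0 <- if (length(mid) >= 2) {
    max(0.5, (max(mid) - min(mid)) / (2 * log(3)))
  } else {
    0.5
  }
  list(y0 = min(fluorescence), a = rng, b = b0, c = c0)
}

new_sigmoid_fit <- function(y0, a, b, c, rss, converged, n_cycles,
                            truncation_cycle = NA_integer_,
                            step2_fallback = FALSE) {
  structure(
    list(y0 = y0, a = a, b = b, c = c, rss = rss, converged = converged,
         n_cycles = n_cycles, truncation_cycle = truncation_cycle,
         step2_fallback = step2_fallback),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>",
      sprintf("y0 = %.4g, a = %.4g, b = %.4g, c = %.4g", x$y0, x$a, x$b, x$c),
      sprintf("rss = %.4g over %d cycles; converged: %s", x$rss, x$n_cycles,
              x$converged),
      sep = "\n")
  if (!is.na(x$truncation_cycle)) {
    cat(sprintf("plateau truncated at cycle %d\n", x$truncation_cycle))
  }
  invisible(x)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("y0", "a", "b", "c"),
         estimate = c(x$y0, x$a, x$b, x$c))
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n_cycles = x$n_cycles,
         truncation_cycle = x$truncation_cycle,
         step2_fallback = x$step2_fallback)
}

# Deterministic multi-start jitter factors (rows = restarts; columns a, b, c).
# Fixed internal seed so repeated fits are bit-identical.
jitter_factors <- function(n_starts = 5) {
  withr::with_seed(24601, matrix(runif(n_starts * 3, 0.7, 1.3), n_starts, 3))
}

nls_attempt <- function(cycle, fluorescence, start, lower, upper, tol,
                        max_iter) {
  df <- data.frame(t = cycle, y = fluorescence)
  fit <- minpack.lm::nlsLM(
    y ~ y0 + a / (1 + exp(-(t - b) / c)),
    data = df, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                         maxiter = max_iter)
  )
  p <- coef(fit)
  list(par = as.list(p), rss = sum(residuals(fit)^2),
       converged = fit$convInfo$isConv %||% TRUE)
}

#' Fit the four-parameter sigmoid to one amplification curve
#'
#' Bounded Levenberg-Marquardt least squares over all cycles, seeded by
#' [initial_guess()]. If the first attempt fails, up to five deterministic
#' restarts jitter the `a`, `b`, `c` seeds by up to 30%. If no attempt
#' converges the best attempt's parameters are retained with
#' `converged = FALSE`.
#'
#' Parameter bounds keep the model identifiable on an amplifying curve:
#' `y0` in `[min - range, max]`, `a` in `(0, 10 range]`, `b` in
#' `[0, 2 n_cycles]`, `c` in `[0.05, n_cycles]` (so the slope scale stays
#' positive and the downstream branch logic of the fluorescence ratio is
#' well defined).
#'
#' @param cycle,fluorescence The curve (consecutive integer cycles, raw
#'   fluorescence; no baseline subtraction is applied).
#' @param tol Convergence tolerance passed to the optimizer.
#' @param max_iter Maximum optimizer iterations per attempt.
#' @return A `sigmoid_fit` object: parameters `y0`, `a`, `b`, `c`, residual
#'   sum of squares `rss`, `converged`, and `truncation_cycle` (`NA` here;
#'   set by [fit_sigmoid_two_step()]).
#' @seealso [fit_sigmoid_two_step()] for the plateau-robust refinement used
#'   by the pipeline.
#' @export
#' @examples
#' y <- sigmoid4(1:46, 0.2, 2.5, 22, 1.8)
#' fit_sigmoid_single(1:46, y)
fit_sigmoid_single <- function(cycle, fluorescence, tol = 1e-10,
                               max_iter = 500) {
  g <- initial_guess(cycle, fluorescence)
  rng <- max(fluorescence) - min(fluorescence)
  n <- length(cycle)
  lower <- c(y0 = min(fluorescence) - rng, a = 1e-8 * rng, b = 0, c = 0.05)
  upper <- c(y0 = max(fluorescence), a = 10 * rng, b = 2 * max(cycle),
             c = max(cycle))
  starts <- list(g)
  jf <- jitter_factors()
  for (i in seq_len(nrow(jf))) {
    s <- list(y0 = g$y0, a = g$a * jf[i, 1], b = g$b * jf[i, 2],
              c = g$c * jf[i, 3])
    starts[[i + 1]] <- s
  }
  best <- NULL
  for (s in starts) {
    s <- as.list(pmin(pmax(unlist(s), lower + 1e-12), upper - 1e-12))
    res <- tryCatch(
      nls_attempt(cycle, fluorescence, s, lower, upper, tol, max_iter),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$rss < best$rss) best <- res
    if (res$converged) break
  }
  if (is.null(best)) {
    return(new_sigmoid_fit(g$y0, g$a, g$b, g$c,
                           rss = sum((fluorescence -
                                        sigmoid4(cycle, g$y0, g$a, g$b,
                                                 g$c))^2),
                           converged = FALSE, n_cycles = n))
  }
  new_sigmoid_fit(best$par$y0, best$par$a, best$par$b, best$par$c,
                  rss = best$rss, converged = isTRUE(best$converged),
                  n_cycles = n)
}

#' Two-step plateau-robust sigmoid fit
#'
#' The number of plateau-phase cycles varies between reactions and biases the
#' single-pass fit. Step 1 fits the full curve; step 2 refits using only
#' cycles up to a truncation point placed just past the inflection
#' (`ceiling(b + plateau_mult * c)`, clamped to `[b + 2, n_cycles]`), so that
#' plateau drift contributes little to the refined parameters. If truncation
#' would remove fewer than 2 cycles the step-1 fit is returned unchanged; if
#' the step-2 fit fails, the step-1 fit is returned with `step2_fallback`
#' set.
#'
#' @inheritParams fit_sigmoid_single
#' @param plateau_mult Multiples of the slope scale `c` beyond the inflection
#'   cycle retained in step 2. The default 3 keeps cycles up to roughly 95%
#'   of plateau height.
#' @return A `sigmoid_fit`; `truncation_cycle` records the last cycle used in
#'   step 2 (`NA` when no truncation was applied).
#' @export
fit_sigmoid_two_step <- function(cycle, fluorescence, tol = 1e-10,
                                 max_iter = 500, plateau_mult = 3) {
  step1 <- fit_sigmoid_single(cycle, fluorescence, tol, max_iter)
  if (!step1$converged) {
    return(step1)
  }
  trunc_at <- ceiling(max(step1$b + plateau_mult * step1$c, step1$b + 2))
  trunc_at <- min(trunc_at, max(cycle))
  if (max(cycle) - trunc_at < 2) {
    return(step1)
  }
  keep <- cycle <= trunc_at
  if (sum(keep) < 8) {
    return(step1)
  }
  step2 <- tryCatch(
    fit_sigmoid_single(cycle[keep], fluorescence[keep], tol, max_iter),
    error = function(e) NULL
  )
  if (is.null(step2) || !step2$converged) {
    step1$step2_fallback <- TRUE
    return(step1)
  }
  step2$truncation_cycle <- as.integer(trunc_at)
  step2$n_cycles <- length(cycle)
  step2
}

#' Fit amplification curves for a whole plate
#'
#' Data-frame-first wrapper: takes long-format fluorescence readings and
#' returns one row of fitted sigmoid parameters per well and channel. Wells
#' whose curve is flat (no amplification) or whose fit does not converge are
#' retained with `converged = FALSE` and an explanatory `note`, so that
#' downstream steps can log and skip them.
#'
#' @param data Data frame with columns `well`, `channel` (`"FAM"`/`"VIC"`),
#'   `cycle`, `fluorescence`.
#' @param two_step Use the plateau-robust two-step refinement (default) or
#'   the single full-curve fit.
#' @inheritParams fit_sigmoid_two_step
#' @return A tibble with columns `well`, `channel`, `y0`, `a`, `b`, `c`,
#'   `rss`, `converged`, `truncation_cycle`, `step2_fallback`, `note`.
#' @export
#' @examples
#' plate <- simulate_plate(plate_design(standard_fractions = c(0.3, 0.5, 0.7),
#'                                      replicates = 1))
#' fit_amplification(plate$fluorescence)
fit_amplification <- function(data, two_step = TRUE, tol = 1e-10,
                              max_iter = 500, plateau_mult = 3) {
  data <- validate_fluorescence(data)
  grp <- dplyr::group_split(group_by(data, .data$well, .data$channel))
  rows <- map(grp, function(g) {
    g <- arrange(g, .data$cycle)
    out <- tibble(well = g$well[1], channel = g$channel[1],
                  y0 = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
                  rss = NA_real_, converged = FALSE,
                  truncation_cycle = NA_integer_, step2_fallback = FALSE,
                  note = NA_character_)
    fit <- tryCatch(
      if (two_step) {
        fit_sigmoid_two_step(g$cycle, g$fluorescence, tol, max_iter,
                             plateau_mult)
      } else {
        fit_sigmoid_single(g$cycle, g$fluorescence, tol, max_iter)
      },
      taqase_no_amplification = function(e) NULL
    )
    if (is.null(fit)) {
      out$note <- "no_amplification"
      return(out)
    }
    out$y0 <- fit$y0; out$a <- fit$a; out$b <- fit$b; out$c <- fit$c
    out$rss <- fit$rss; out$converged <- fit$converged
    out$truncation_cycle <- fit$truncation_cycle
    out$step2_fallback <- fit$step2_fallback
    if (!fit$converged) out$note <- "fit_not_converged"
    out
  })
  list_rbind(rows)
}
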