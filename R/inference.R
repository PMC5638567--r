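#' Per-tissue ASE summary with a test against balanced expression
#'
#' Summarises per-sample allele-frequency estimates tissue by tissue (one
#' value per biological specimen, never technical replicates) and tests each
#' tissue's mean against 0.5 — a 1:1 allelic ratio — with a two-sided
#' one-sample t-test.
#'
#' Degenerate inputs are kept explicit rather than erroring: tissues with a
#' single sample get no test (`degenerate = TRUE`); zero-variance tissues get
#' `p = 1` when the mean is exactly 0.5 and an infinite-t flag otherwise.
#'
#' @param estimates Data frame with columns `tissue` and `x_hat`, one row per
#'   biological sample (e.g. from [estimate_frequencies()]).
#' @param alpha Significance level for the `significant_vs_half` flag.
#' @return Tibble with one row per tissue: `tissue`, `n_samples`, `mean_x`,
#'   `sd_x`, `t_vs_half`, `p_vs_half`, `significant_vs_half`, `degenerate`.
#' @export
#' @examples
#' est <- tibble::tibble(tissue = rep(c("ovary", "brain"), each = 4),
#'                       x_hat = c(0.77, 0.75, 0.79, 0.77,
#'                                 0.48, 0.52, 0.46, 0.50))
#' tissue_summary(est)
tissue_summary <- function(estimates, alpha = 0.05) {
  stopifnot(is.data.frame(estimates),
            all(c("tissue", "x_hat") %in% names(estimates)))
  one <- function(x) {
    n <- length(x)
    m <- mean(x)
    s <- if (n >= 2) sd(x) else NA_real_
    if (n < 2) {
      return(tibble(n_samples = n, mean_x = m, sd_x = s,
                    t_vs_half = NA_real_, p_vs_half = NA_real_,
                    significant_vs_half = NA, degenerate = TRUE))
    }
    if (s == 0) {
      if (m == 0.5) {
        return(tibble(n_samples = n, mean_x = m, sd_x = s, t_vs_half = 0,
                      p_vs_half = 1, significant_vs_half = FALSE,
                      degenerate = TRUE))
      }
      return(tibble(n_samples = n, mean_x = m, sd_x = s,
                    t_vs_half = sign(m - 0.5) * Inf, p_vs_half = 0,
                    significant_vs_half = TRUE, degenerate = TRUE))
    }
    tt <- t.test(x, mu = 0.5)
    tibble(n_samples = n, mean_x = m, sd_x = s,
           t_vs_half = unname(tt$statistic), p_vs_half = tt$p.value,
           significant_vs_half = tt$p.value < alpha, degenerate = FALSE)
  }
  estimates |>
    group_by(.data$tissue) |>
    dplyr::group_map(~ mutate(one(.x$x_hat), tissue = .y$tissue,
                              .before = 1)) |>
    list_rbind()
}

#' One-way ANOVA of allele-frequency estimates across tissues
#'
#' Fixed-effects one-way ANOVA of per-sample `x_hat` on tissue, with
#' family-wise-adjusted pairwise post-hoc comparisons (Tukey HSD by default,
#' Bonferroni-adjusted pairwise t-tests as an alternative).
#'
#' @inheritParams tissue_summary
#' @param posthoc `"tukey"` (default) or `"bonferroni"`.
#' @return An `ase_anova` object: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, a `posthoc` tibble (`tissue_a`, `tissue_b`, `diff`,
#'   `p_adjusted`), and the underlying `aov` fit.
#' @export
#' @examples
#' est <- tibble::tibble(tissue = rep(c("a", "b", "c"), each = 3),
#'                       x_hat = c(1, 2, 3, 2, 3, 4, 3, 4, 5) / 10)
#' anova_across_tissues(est)
anova_across_tissues <- function(estimates, posthoc = c("tukey",
                                                        "bonferroni")) {
  posthoc <- arg_match(posthoc)
  stopifnot(is.data.frame(estimates),
            all(c("tissue", "x_hat") %in% names(estimates)))
  counts <- table(estimates$tissue)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("ANOVA needs >= 2 groups with >= 2 values each.",
          class = "taqase_domain_error")
  }
  df <- data.frame(tissue = factor(estimates$tissue), x = estimates$x_hat)
  k <- nlevels(df$tissue)
  n_tot <- nrow(df)
  pairs_tbl <- function(names_ab, diff, p) {
    ab <- do.call(rbind, strsplit(names_ab, "-", fixed = TRUE))
    tibble(tissue_a = ab[, 1], tissue_b = ab[, 2], diff = diff,
           p_adjusted = p)
  }
  if (stats::var(df$x) == 0) {
    lev <- levels(df$tissue)
    combos <- utils::combn(lev, 2)
    return(structure(
      list(f_stat = 0, df_between = k - 1L, df_within = n_tot - k,
           p_value = 1,
           posthoc = tibble(tissue_a = combos[2, ], tissue_b = combos[1, ],
                            diff = 0, p_adjusted = 1),
           model = NULL, method = posthoc),
      class = "ase_anova"
    ))
  }
  fit <- aov(x ~ tissue, data = df)
  tab <- summary(fit)[[1]]
  ph <- if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$tissue
    pairs_tbl(rownames(tk), tk[, "diff"], tk[, "p adj"])
  } else {
    pw <- pairwise.t.test(df$x, df$tissue, p.adjust.method = "bonferroni")
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    tibble(tissue_a = rownames(m)[idx[, 1]],
           tissue_b = colnames(m)[idx[, 2]],
           diff = NA_real_, p_adjusted = m[idx])
  }
  structure(
    list(f_stat = tab[1, "F value"], df_between = tab[1, "Df"],
         df_within = tab[2, "Df"], p_value = tab[1, "Pr(>F)"],
         posthoc = ph, model = fit, method = posthoc),
    class = "ase_anova"
  )
}

#' @export
print.ase_anova <- function(x, ...) {
  cat(sprintf("<ase_anova> F(%d, %d) = %.3f, p = %.3g\n", x$df_between,
              x$df_within, x$f_stat, x$p_value))
  cat(sprintf("post-hoc (%s):\n", x$method))
  print(x$posthoc)
  invisible(x)
}

#' @export
tidy.ase_anova <- function(x, ...) {
  x$posthoc
}

#' @export
glance.ase_anova <- function(x, ...) {
  tibble(f_stat = x$f_stat, df_between = x$df_between,
         df_within = x$df_within, p_value = x$p_value, method = x$method)
}
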