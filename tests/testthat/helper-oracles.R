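# Independent oracles used across test files.

# Noiseless logistic curve on consecutive cycles.
make_curve <- function(y0, a, b, c, n_cycles = 46) {
  t <- seq_len(n_cycles)
  list(cycle = t, fluorescence = sigmoid4(t, y0, a, b, c))
}

# Global alignment optimum by memoised top-down recursion over all moves —
# structurally independent of the package's bottom-up matrix fill.
nw_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  memo <- array(NA_real_, dim = c(length(av) + 1, length(bv) + 1))
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    res <- if (i == 0 && j == 0) {
      0
    } else {
      cand <- -Inf
      if (i > 0 && j > 0) {
        cand <- max(cand, rec(i - 1, j - 1) +
                      if (av[i] == bv[j]) match else mismatch)
      }
      if (i > 0) cand <- max(cand, rec(i - 1, j) + gap)
      if (j > 0) cand <- max(cand, rec(i, j - 1) + gap)
      cand
    }
    memo[i + 1, j + 1] <<- res
    res
  }
  rec(length(av), length(bv))
}

# Naive CpG-island caller: per-window stats counted with table(), qualifying
# windows unioned through a coverage vector, region stats recounted.
cpg_oracle <- function(seq, window = 200, gc_min = 0.5, oe_min = 0.6,
                       min_len = 200) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < window) return(NULL)
  win_ok <- function(sub) {
    non_n <- sum(sub != "N")
    gc <- sum(sub %in% c("C", "G")) / non_n
    nc <- sum(sub == "C"); ng <- sum(sub == "G")
    ncpg <- sum(sub[-length(sub)] == "C" & sub[-1] == "G")
    oe <- if (nc * ng > 0) ncpg * non_n / (nc * ng) else 0
    is.finite(gc) && gc > gc_min && oe > oe_min
  }
  covered <- logical(n)
  for (st in 1:(n - window + 1)) {
    if (win_ok(s[st:(st + window - 1)])) {
      covered[st:(st + window - 1)] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- NULL
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    sub <- s[starts[k]:ends[k]]
    non_n <- sum(sub != "N")
    gc <- sum(sub %in% c("C", "G")) / non_n
    nc <- sum(sub == "C"); ng <- sum(sub == "G")
    ncpg <- sum(sub[-length(sub)] == "C" & sub[-1] == "G")
    oe <- if (nc * ng > 0) ncpg * non_n / (nc * ng) else 0
    if (length(sub) >= min_len && gc > gc_min && oe > oe_min) {
      out <- rbind(out, data.frame(start = starts[k], end = ends[k],
                                   gc_fraction = gc, obs_exp_cpg = oe))
    }
  }
  out
}

# Random DNA string.
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Simulate standards + unknowns and run the full pipeline once; returns the
# calibration R^2 and per-sample estimation errors.
recovery_run <- function(seed, unknown_x = c(0.2, 0.5, 0.77),
                         noise_sd = 0.005) {
  unknowns <- tibble::tibble(sample_id = sprintf("u%d", seq_along(unknown_x)),
                             tissue = "sample", true_x = unknown_x)
  plate <- simulate_plate(plate_design(unknowns = unknowns),
                          base_config = reaction_config(noise_sd = noise_sd),
                          seed = seed)
  res <- suppressWarnings(
    run_ase_pipeline(plate$fluorescence, plate$sample_sheet)
  )
  est <- res$estimates[order(res$estimates$sample_id), ]
  list(r_squared = res$standard_curve$r_squared,
       errors = abs(est$x_hat - unknown_x[order(unknowns$sample_id)]))
}
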