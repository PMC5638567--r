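fitlike <- function(a, b, c) list(a = a, b = b, c = c, converged = TRUE)

test_that("branch selection and ratio values match symbolic evaluation", {
  # symmetric reaction: both branches coincide at the amplitude ratio
  sym <- compute_r_prime(fitlike(1.5, 20, 2), fitlike(1.5, 20, 2))
  expect_identical(sym$branch, "TIE")
  expect_equal(sym$r_prime, 1)
  # FAM inflects first
  eq1 <- compute_r_prime(fitlike(2, 10, 5), fitlike(1, 12, 2))
  expect_identical(eq1$branch, "EQ1")
  expect_equal(eq1$r_prime, 1 + exp(1), tolerance = 1e-12)
  # VIC inflects first
  eq2 <- compute_r_prime(fitlike(1, 14, 2), fitlike(2, 12, 5))
  expect_identical(eq2$branch, "EQ2")
  expect_equal(eq2$r_prime, 1 / (1 + exp(1)), tolerance = 1e-12)
})

test_that("invalid channel fits are refused", {
  bad <- list(a = 1, b = 20, c = 2, converged = FALSE)
  expect_error(compute_r_prime(bad, fitlike(1, 20, 2)),
               class = "taqase_unfit_curve")
  expect_error(compute_r_prime(fitlike(1, 20, 2), fitlike(-1, 20, 2)),
               class = "taqase_degenerate_channel")
})

test_that("k' transform is the expected bijection onto (0, 1)", {
  expect_identical(compute_k_prime(1), 0.5)
  expect_lt(compute_k_prime(1e-9), 1e-8)
  expect_gt(compute_k_prime(1e9), 1 - 1e-8)
  r <- exp(seq(-6, 6, length.out = 50))
  k <- compute_k_prime(r)
  expect_true(all(k > 0 & k < 1))
  expect_true(all(diff(k) > 0))
  # inverse map recovers the published balanced-standard ratio
  k_mid <- 0.522
  expect_equal(k_mid / (1 - k_mid), 1.0921, tolerance = 1e-4)
  expect_equal(compute_k_prime(k_mid / (1 - k_mid)), k_mid)
  expect_error(compute_k_prime(-1), class = "taqase_domain_error")
  expect_error(compute_k_prime(Inf), class = "taqase_domain_error")
})

test_that("the two branch formulas agree at equal inflection cycles", {
  withr::with_seed(42, {
    for (i in 1:100) {
      a_f <- runif(1, 0.2, 5)
      a_v <- runif(1, 0.2, 5)
      b <- runif(1, 10, 35)
      c_f <- runif(1, 0.5, 4)
      c_v <- runif(1, 0.5, 4)
      eq1 <- 0.5 * (a_f / a_v) * (1 + exp(-(b - b) / c_v))
      eq2 <- 2 * (a_f / a_v) / (1 + exp(-(b - b) / c_f))
      expect_lt(abs(eq1 - eq2), 1e-12)
      tie <- compute_r_prime(fitlike(a_f, b, c_f), fitlike(a_v, b, c_v))
      expect_identical(tie$branch, "TIE")
      expect_equal(tie$r_prime, eq1, tolerance = 1e-12)
    }
  })
})

test_that("R' is continuous across the branch switch", {
  withr::with_seed(43, {
    for (i in 1:25) {
      a_f <- runif(1, 0.2, 5)
      a_v <- runif(1, 0.2, 5)
      b_v <- runif(1, 15, 30)
      c_f <- runif(1, 0.5, 4)
      c_v <- runif(1, 0.5, 4)
      eps <- 1e-7
      left <- compute_r_prime(fitlike(a_f, b_v - eps, c_f),
                              fitlike(a_v, b_v, c_v))
      right <- compute_r_prime(fitlike(a_f, b_v + eps, c_f),
                               fitlike(a_v, b_v, c_v))
      expect_identical(left$branch, "EQ1")
      expect_identical(right$branch, "EQ2")
      expect_equal(left$r_prime, a_f / a_v, tolerance = 1e-5)
      expect_equal(right$r_prime, a_f / a_v, tolerance = 1e-5)
    }
  })
})

test_that("swapping the channels maps k' to 1 - k'", {
  withr::with_seed(44, {
    for (i in 1:20) {
      fam <- fitlike(runif(1, 0.2, 5), runif(1, 10, 35), runif(1, 0.5, 4))
      vic <- fitlike(runif(1, 0.2, 5), runif(1, 10, 35), runif(1, 0.5, 4))
      r <- compute_r_prime(fam, vic)$r_prime
      r_swapped <- compute_r_prime(vic, fam)$r_prime
      # the swapped ratio is the exact reciprocal, so k' maps to 1 - k'
      expect_equal(r * r_swapped, 1, tolerance = 1e-12)
      k <- compute_k_prime(r)
      k_swapped <- compute_k_prime(r_swapped)
      expect_equal(k_swapped, 1 - k, tolerance = 1e-9)
    }
  })
})

test_that("k' for a whole reaction reflects the template composition", {
  cfg <- function(x, seed) {
    reaction_config(true_x = x, efficiency = 0.9, seed = seed)
  }
  curves_of <- function(x, seed) {
    cv <- simulate_reaction(cfg(x, seed))
    split(cv, cv$channel)
  }
  bal <- curves_of(0.5, 21)
  res_bal <- k_prime_for_reaction(bal$FAM, bal$VIC)
  expect_lt(abs(res_bal$k_prime - 0.5), 0.02)
  # FAM template 4x the VIC template
  skew <- curves_of(0.2, 22)
  res_skew <- k_prime_for_reaction(skew$FAM, skew$VIC)
  expect_gt(res_skew$k_prime, res_bal$k_prime)
  # channel mismatch and flat channels are refused
  expect_error(k_prime_for_reaction(bal$FAM, bal$FAM),
               class = "taqase_channel_mismatch")
  flat <- bal$VIC
  flat$fluorescence <- rep(0.1, nrow(flat))
  expect_error(k_prime_for_reaction(bal$FAM, flat),
               class = "taqase_no_amplification")
})

test_that("kprime_table pairs channels per well and keeps failures", {
  plate <- simulate_plate(
    plate_design(standard_fractions = c(0.3, 0.7, 1), replicates = 1),
    seed = 9
  )
  kp <- kprime_table(fit_amplification(plate$fluorescence))
  expect_equal(nrow(kp), 3)
  good <- kp[!is.na(kp$k_prime), ]
  expect_true(all(good$k_prime > 0 & good$k_prime < 1))
  expect_true(all(good$branch %in% c("EQ1", "EQ2", "TIE")))
})
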