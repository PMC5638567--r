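test_that("reactions are deterministic given a seed", {
  cfg <- reaction_config(true_x = 0.3, seed = 99)
  expect_identical(simulate_reaction(cfg), simulate_reaction(cfg))
  plate_a <- simulate_plate(seed = 17)
  plate_b <- simulate_plate(seed = 17)
  expect_identical(plate_a$fluorescence, plate_b$fluorescence)
  expect_false(identical(plate_a$fluorescence,
                         simulate_plate(seed = 18)$fluorescence))
  pair_a <- simulate_promoter_pair(seed = 5)
  pair_b <- simulate_promoter_pair(seed = 5)
  expect_identical(pair_a$seq_a, pair_b$seq_a)
})

test_that("a balanced noiseless reaction is channel symmetric", {
  cfg <- reaction_config(true_x = 0.5, efficiency = 0.9, noise_sd = 0)
  cv <- simulate_reaction(cfg)
  fam <- cv$fluorescence[cv$channel == "FAM"]
  vic <- cv$fluorescence[cv$channel == "VIC"]
  expect_equal(fam, vic, tolerance = 1e-12)
})

test_that("more VIC template makes the VIC channel inflect earlier", {
  b_of <- function(x) {
    cv <- simulate_reaction(reaction_config(true_x = x, noise_sd = 0))
    vic <- cv[cv$channel == "VIC", ]
    fit_sigmoid_two_step(vic$cycle, vic$fluorescence)$b
  }
  expect_lt(b_of(0.8), b_of(0.5))
})

test_that("amplicons never exceed the shared carrying capacity", {
  cfg <- reaction_config(true_x = 0.3, noise_sd = 0,
                         carrying_capacity = 1e10)
  cv <- simulate_reaction(cfg)
  total <- (cv$fluorescence[cv$channel == "FAM"] - 0.1) / 3e-12 +
    (cv$fluorescence[cv$channel == "VIC"] - 0.1) / 3e-12
  expect_true(all(total <= 1e10 * (1 + 1e-9)))
})

test_that("noiseless pipeline k' is strictly monotone in the true fraction", {
  xs <- seq(0.05, 0.95, by = 0.1)
  ks <- vapply(xs, function(x) {
    cv <- simulate_reaction(reaction_config(true_x = x, noise_sd = 0))
    sp <- split(cv, cv$channel)
    k_prime_for_reaction(sp$FAM, sp$VIC)$k_prime
  }, numeric(1))
  expect_true(all(diff(ks) < 0) || all(diff(ks) > 0))
})

test_that("the fitted sigmoid reproduces a noiseless simulated curve", {
  cv <- simulate_reaction(reaction_config(true_x = 0.4, noise_sd = 0))
  fam <- cv[cv$channel == "FAM", ]
  fit2 <- fit_sigmoid_two_step(fam$cycle, fam$fluorescence)
  fit1 <- fit_sigmoid_single(fam$cycle, fam$fluorescence)
  expect_true(fit2$converged)
  # the discrete per-cycle recursion is close to, but not exactly, a
  # continuous logistic: the structural lack of fit is ~1.3e-3 of the
  # squared plateau (computed once and frozen here), and plateau
  # truncation must not make it worse than the full-curve fit
  expect_lt(fit2$rss, 2e-3 * fit2$a^2)
  expect_lt(fit2$rss, fit1$rss)
})

test_that("plate layout matches the design and round-trips through IO", {
  unknowns <- tibble::tibble(sample_id = c("u1", "u2"),
                             tissue = c("ovary", "brain"),
                             true_x = c(0.7, 0.5))
  plate <- simulate_plate(plate_design(unknowns = unknowns), seed = 2)
  expect_equal(nrow(plate$sample_sheet), 13 * 3 + 2 * 3)
  expect_equal(sum(plate$sample_sheet$role == "STANDARD"), 39)
  expect_equal(dplyr::n_distinct(plate$fluorescence$well),
               nrow(plate$sample_sheet))
  expect_equal(nrow(plate$fluorescence), nrow(plate$sample_sheet) * 2 * 46)
  fl <- withr::local_tempfile(fileext = ".csv")
  sh <- withr::local_tempfile(fileext = ".csv")
  write_fluorescence_csv(plate$fluorescence, fl)
  write_sample_sheet(plate$sample_sheet, sh)
  expect_equal(as.data.frame(read_fluorescence_csv(fl)),
               as.data.frame(dplyr::arrange(plate$fluorescence, well,
                                            channel, cycle)))
  sheet_back <- read_sample_sheet(sh)
  expect_equal(sheet_back$x_true, plate$sample_sheet$x_true)
  expect_equal(sheet_back$tissue, plate$sample_sheet$tissue)
})

test_that("single-replicate plates still calibrate, with a warning", {
  plate <- simulate_plate(plate_design(replicates = 1), seed = 4)
  fits <- fit_amplification(plate$fluorescence)
  kp <- kprime_table(fits)
  expect_warning(pts <- standard_points(kp, plate$sample_sheet),
                 "single replicate")
  curve <- build_standard_curve(pts)
  expect_gt(curve$r_squared, 0.9)
})

test_that("planted promoter features respect their constraints", {
  pair <- simulate_promoter_pair(seed = 31)
  expect_equal(nchar(pair$seq_a), 670)
  expect_equal(nchar(pair$seq_b), 669)
  a <- strsplit(pair$seq_a, "")[[1]]
  b <- strsplit(pair$seq_b, "")[[1]]
  expect_false(a[77] == b[77])
  # deleted base differs from both neighbours (unambiguous gap placement)
  expect_false(a[231] == a[230])
  expect_false(a[231] == a[232])
  expect_error(simulate_promoter_pair(snp_pos = 231, indel_pos = 231),
               class = "taqase_domain_error")
  expect_error(simulate_promoter_pair(snp_pos = 1),
               class = "taqase_domain_error")
  none <- simulate_promoter_pair(snp_pos = NULL, indel_pos = NULL,
                                 island_span = NULL, seed = 8)
  expect_equal(none$seq_a, none$seq_b)
  expect_equal(nrow(find_variants(align_pair(none$seq_a, none$seq_b))), 0)
})

test_that("tissue study draws biology once per specimen", {
  study <- simulate_tissue_study(n_samples = 3, replicates = 2, seed = 41)
  expect_equal(nrow(study$biology), 9)
  expect_equal(sum(study$sample_sheet$role == "UNKNOWN"), 18)
  expect_true(all(study$biology$true_x >= 0.02 &
                    study$biology$true_x <= 0.98))
  ovary <- study$biology$true_x[study$biology$tissue == "ovary"]
  expect_true(all(abs(ovary - 0.77) < 0.15))
})
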