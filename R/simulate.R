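#' Configuration of one simulated dual-channel TaqMan reaction
#'
#' Mechanistic stand-in for a competitive dual-probe amplification: both
#' amplicons grow by a discrete logistic recursion against a *shared*
#' carrying capacity (the two alleles are amplified by the same primer pair
#' and compete for the same reagents), and each channel's fluorescence is a
#' linear readout of its amplicon count plus a baseline and iid Gaussian read
#' noise.
#'
#' Defaults describe a realistic plate: 1e5 template copies, per-cycle
#' efficiencies 0.90 (FAM) / 0.905 (VIC) — a slight allelic asymmetry of the
#' kind real dual-probe assays show, small enough that the k' link stays
#' nearly linear in the allele fraction — carrying capacity 1e12 copies, probe
#' gain 3e-12 fluorescence units per copy (plateau amplitude about 3 units),
#' baseline 0.1, read noise sd 0.005, and 46 cycles matching the qPCR
#' protocol the pipeline targets. These values put inflection cycles in the
#' low-to-mid 20s of 46 cycles, as in typical runs.
#'
#' @param true_x True fraction of the VIC-detected allele in \[0, 1\]
#'   (the FAM-detected allele has fraction `1 - true_x`).
#' @param total_template Total template copies across both alleles.
#' @param efficiency Per-cycle amplification efficiency in (0, 1]; scalar or
#'   named vector `c(FAM = , VIC = )`.
#' @param carrying_capacity Shared saturation copy number.
#' @param probe_gain Fluorescence units per amplicon copy; scalar or named
#'   vector.
#' @param baseline Baseline fluorescence per channel; scalar or named vector.
#' @param noise_sd Gaussian read-noise sd (fluorescence units).
#' @param n_cycles Number of PCR cycles.
#' @param seed Integer seed making the reaction reproducible.
#' @return A `reaction_config` list.
#' @export
reaction_config <- function(true_x = 0.5, total_template = 1e5,
                            efficiency = c(FAM = 0.90, VIC = 0.905),
                            carrying_capacity = 1e12,
                            probe_gain = c(FAM = 3e-12, VIC = 3e-12),
                            baseline = c(FAM = 0.1, VIC = 0.1),
                            noise_sd = 0.005, n_cycles = 46L, seed = 1L) {
  per_channel <- function(x, nm) {
    if (length(x) == 1) {
      x <- c(FAM = unname(x), VIC = unname(x))
    }
    if (!all(c("FAM", "VIC") %in% names(x))) {
      abort(sprintf("`%s` must be a scalar or named c(FAM=, VIC=).", nm))
    }
    x[c("FAM", "VIC")]
  }
  stopifnot(is.numeric(true_x), length(true_x) == 1, true_x >= 0,
            true_x <= 1, total_template > 0, carrying_capacity > 0,
            noise_sd >= 0, n_cycles >= 8)
  efficiency <- per_channel(efficiency, "efficiency")
  stopifnot(all(efficiency > 0), all(efficiency <= 1))
  structure(
    list(true_x = true_x, total_template = total_template,
         efficiency = efficiency,
         carrying_capacity = carrying_capacity,
         probe_gain = per_channel(probe_gain, "probe_gain"),
         baseline = per_channel(baseline, "baseline"),
         noise_sd = noise_sd, n_cycles = as.integer(n_cycles),
         seed = as.integer(seed)),
    class = "reaction_config"
  )
}

#' Simulate one dual-channel amplification reaction
#'
#' Runs the competitive logistic recursion of [reaction_config()]:
#' `N_ch(c+1) = N_ch(c) + eff_ch * N_ch(c) * (1 - (N_FAM + N_VIC) / K)`,
#' starting from `total_template * (1 - true_x)` FAM-allele and
#' `total_template * true_x` VIC-allele copies, and reads each channel out as
#' `baseline + gain * N + noise`. A channel with zero template stays at
#' baseline + noise (downstream fitting flags it as no amplification), which
#' is how pure standards acquire their aberrant behaviour.
#'
#' @param config A [reaction_config()].
#' @return Tibble with columns `channel`, `cycle`, `fluorescence`
#'   (deterministic given `config$seed`).
#' @export
#' @examples
#' curves <- simulate_reaction(reaction_config(true_x = 0.8, seed = 42))
#' head(curves)
simulate_reaction <- function(config = reaction_config()) {
  stopifnot(inherits(config, "reaction_config"))
  n_fam <- config$total_template * (1 - config$true_x)
  n_vic <- config$total_template * config$true_x
  nc <- config$n_cycles
  f_fam <- numeric(nc)
  f_vic <- numeric(nc)
  for (cyc in seq_len(nc)) {
    lim <- max(0, 1 - (n_fam + n_vic) / config$carrying_capacity)
    n_fam <- n_fam + config$efficiency[["FAM"]] * n_fam * lim
    n_vic <- n_vic + config$efficiency[["VIC"]] * n_vic * lim
    f_fam[cyc] <- config$baseline[["FAM"]] + config$probe_gain[["FAM"]] * n_fam
    f_vic[cyc] <- config$baseline[["VIC"]] + config$probe_gain[["VIC"]] * n_vic
  }
  if (config$noise_sd > 0) {
    noise <- withr::with_seed(config$seed, rnorm(2 * nc, 0, config$noise_sd))
    f_fam <- f_fam + noise[seq_len(nc)]
    f_vic <- f_vic + noise[nc + seq_len(nc)]
  }
  bind_rows(
    tibble(channel = "FAM", cycle = seq_len(nc), fluorescence = f_fam),
    tibble(channel = "VIC", cycle = seq_len(nc), fluorescence = f_vic)
  )
}

#' Plate layout for a simulated calibration experiment
#'
#' @param standard_fractions VIC-allele fractions of the plasmid standards;
#'   the default is the 13-point series 1.0, 0.95, 0.9, 0.8, ..., 0.2, 0.1,
#'   0.05, 0.0.
#' @param replicates Technical replicates per standard and per unknown.
#' @param unknowns `NULL` or a tibble with columns `sample_id`, `tissue`,
#'   `true_x` (one row per biological sample).
#' @return A `plate_design` list.
#' @export
plate_design <- function(standard_fractions = c(1, 0.95, 0.9, 0.8, 0.7, 0.6,
                                                0.5, 0.4, 0.3, 0.2, 0.1,
                                                0.05, 0),
                         replicates = 3L, unknowns = NULL) {
  stopifnot(all(standard_fractions >= 0), all(standard_fractions <= 1),
            replicates >= 1)
  if (!is.null(unknowns)) {
    stopifnot(is.data.frame(unknowns),
              all(c("sample_id", "tissue", "true_x") %in% names(unknowns)),
              all(unknowns$true_x >= 0), all(unknowns$true_x <= 1))
    unknowns <- as_tibble(unknowns)
  }
  structure(
    list(standard_fractions = standard_fractions,
         replicates = as.integer(replicates), unknowns = unknowns),
    class = "plate_design"
  )
}

# Deterministic per-well seed: exact integer arithmetic in doubles,
# reduced mod 2^31 - 1 so it stays a valid 32-bit seed.
well_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 1000003 + index) %% 2147483647)
}

#' Simulate a full calibration plate
#'
#' One dual-channel reaction per standard x replicate and per unknown x
#' replicate. Each well's noise stream is seeded by a fixed hash of the
#' master seed and the well index (`(seed * 1000003 + index) mod 2^31 - 1`),
#' so a plate is bit-reproducible and individual wells are independent.
#'
#' @param design A [plate_design()].
#' @param base_config A [reaction_config()]; its `true_x` and `seed` are
#'   overridden per well.
#' @param seed Master seed for the plate.
#' @return List of class `ase_plate`: `fluorescence` (long tibble: `well`,
#'   `cycle`, `channel`, `fluorescence`), `sample_sheet` (tibble: `well`,
#'   `role`, `x_true`, `sample_id`, `tissue`, `replicate`), and `truth`
#'   (per-well true fractions).
#' @export
#' @examples
#' plate <- simulate_plate(seed = 7)
#' dplyr::count(plate$sample_sheet, role)
simulate_plate <- function(design = plate_design(),
                           base_config = reaction_config(), seed = 1L) {
  stopifnot(inherits(design, "plate_design"),
            inherits(base_config, "reaction_config"))
  layout <- bind_rows(
    tidyr::expand_grid(x = design$standard_fractions,
                       replicate = seq_len(design$replicates)) |>
      mutate(role = "STANDARD", sample_id = NA_character_,
             tissue = NA_character_),
    if (!is.null(design$unknowns)) {
      tidyr::expand_grid(design$unknowns,
                         replicate = seq_len(design$replicates)) |>
        rename(x = "true_x") |>
        mutate(role = "UNKNOWN")
    }
  )
  layout <- mutate(layout, well = sprintf("W%03d", row_number()))
  fluor <- pmap(list(layout$x, layout$well, seq_len(nrow(layout))),
                function(x, w, idx) {
    cfg <- base_config
    cfg$true_x <- x
    cfg$seed <- well_seed(seed, idx)
    mutate(simulate_reaction(cfg), well = w, .before = 1)
  }) |>
    list_rbind() |>
    select("well", "cycle", "channel", "fluorescence")
  sheet <- layout |>
    mutate(x_true = ifelse(.data$role == "STANDARD", .data$x, NA_real_)) |>
    select("well", "role", "x_true", "sample_id", "tissue", "replicate")
  structure(
    list(fluorescence = fluor, sample_sheet = sheet,
         truth = select(layout, "well", "role", true_x = "x")),
    class = "ase_plate"
  )
}

#' Simulate a multi-tissue ASE study
#'
#' Draws per-specimen true allele fractions for each tissue from a Gaussian
#' with tissue-specific mean and biological sd (truncated to \[0.02, 0.98\])
#' and lays them out on a standard calibration plate. The default means and
#' sds describe the ovary-biased / brain- and gill-balanced expression
#' pattern of the hybrid-fish study system this package models, with its
#' reported between-specimen spreads.
#'
#' @param tissue_means,tissue_sds Named numeric vectors (same names): mean
#'   and biological sd of the true VIC-allele expression fraction per tissue.
#' @param n_samples Biological specimens per tissue.
#' @param replicates Technical replicates per specimen.
#' @param base_config A [reaction_config()].
#' @param seed Master seed (biological draws and plate noise).
#' @return As [simulate_plate()], plus a `biology` tibble of per-specimen
#'   true fractions.
#' @export
simulate_tissue_study <- function(tissue_means = c(ovary = 0.770,
                                                   brain = 0.462,
                                                   gill = 0.407),
                                  tissue_sds = c(ovary = 0.02, brain = 0.04,
                                                 gill = 0.09),
                                  n_samples = 4L, replicates = 3L,
                                  base_config = reaction_config(),
                                  seed = 1L) {
  stopifnot(identical(names(tissue_means), names(tissue_sds)),
            n_samples >= 2)
  biology <- withr::with_seed(seed, {
    imap(tissue_means, function(m, tis) {
      x <- rnorm(n_samples, m, tissue_sds[[tis]])
      tibble(sample_id = sprintf("%s_%02d", tis, seq_len(n_samples)),
             tissue = tis, true_x = pmin(0.98, pmax(0.02, x)))
    }) |>
      list_rbind()
  })
  plate <- simulate_plate(
    plate_design(replicates = replicates, unknowns = biology),
    base_config = base_config, seed = seed
  )
  plate$biology <- biology
  plate
}

#' Simulate a pair of promoter alleles with planted features
#'
#' Sequence A is drawn base by base from an AT-rich background (default GC
#' 30%), with an optional GC-rich block (default GC about 67%, bases drawn
#' independently so the observed/expected CpG ratio is near 1) planted over
#' `island_span`. Sequence B equals A except for a planted substitution at
#' `snp_pos` and a planted 1 bp deletion at `indel_pos`; the deleted base is
#' forced to differ from both neighbours so the alignment position of the
#' indel is unambiguous.
#'
#' @param length Sequence length (bp) of allele A.
#' @param snp_pos,indel_pos 1-based positions on allele A of the planted SNP
#'   and deletion; either may be `NULL` to plant nothing.
#' @param gc_background Background GC fraction.
#' @param island_span `NULL` or `c(start, end)` of the planted GC-rich block.
#' @param island_gc GC fraction inside the planted block.
#' @param seed Integer seed.
#' @return List of class `promoter_pair`: `seq_a`, `seq_b`, and `truth`
#'   (the planted positions and span).
#' @export
#' @examples
#' pair <- simulate_promoter_pair(seed = 7)
#' find_variants(align_pair(pair$seq_a, pair$seq_b))
simulate_promoter_pair <- function(length = 670L, snp_pos = 77L,
                                   indel_pos = 231L, gc_background = 0.3,
                                   island_span = c(200L, 520L),
                                   island_gc = 0.67, seed = 1L) {
  stopifnot(length >= 10)
  if (!is.null(snp_pos) && !is.null(indel_pos) &&
      abs(snp_pos - indel_pos) < 2) {
    abort("Planted SNP and indel positions overlap.",
          class = "taqase_domain_error")
  }
  for (p in c(snp_pos, indel_pos)) {
    if (!is.null(p) && (p < 2 || p > length - 1)) {
      abort("Planted positions must lie strictly inside the sequence.",
            class = "taqase_domain_error")
    }
  }
  if (!is.null(island_span)) {
    stopifnot(length(island_span) == 2, island_span[1] >= 1,
              island_span[2] <= length, island_span[1] < island_span[2])
  }
  base_probs <- function(gc) {
    c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  }
  seq_a <- withr::with_seed(seed, {
    p_bg <- base_probs(gc_background)
    s <- sample(names(p_bg), length, replace = TRUE, prob = p_bg)
    if (!is.null(island_span)) {
      span <- island_span[1]:island_span[2]
      p_is <- base_probs(island_gc)
      s[span] <- sample(names(p_is), length(span), replace = TRUE,
                        prob = p_is)
    }
    s
  })
  transversion <- c(A = "C", C = "A", G = "T", T = "G")
  if (!is.null(indel_pos)) {
    # force the deleted base to differ from both neighbours so the gap
    # placement is unique under the alignment scoring
    nbrs <- seq_a[c(indel_pos - 1, indel_pos + 1)]
    if (seq_a[indel_pos] %in% nbrs) {
      seq_a[indel_pos] <- setdiff(c("A", "C", "G", "T"), nbrs)[1]
    }
  }
  seq_b <- seq_a
  if (!is.null(snp_pos)) {
    seq_b[snp_pos] <- transversion[[seq_a[snp_pos]]]
  }
  if (!is.null(indel_pos)) {
    seq_b <- seq_b[-indel_pos]
  }
  structure(
    list(seq_a = paste(seq_a, collapse = ""),
         seq_b = paste(seq_b, collapse = ""),
         truth = list(snp_pos = snp_pos, indel_pos = indel_pos,
                      island_span = island_span)),
    class = "promoter_pair"
  )
}
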