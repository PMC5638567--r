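parse_error <- function(msg, call = caller_env()) {
  abort(msg, class = "taqase_parse_error", call = call)
}

validate_fluorescence <- function(data, call = caller_env()) {
  needed <- c("well", "cycle", "channel", "fluorescence")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    parse_error(paste0("Fluorescence data is missing column(s): ",
                       paste(missing_cols, collapse = ", ")), call = call)
  }
  data <- as_tibble(data)
  data$channel <- toupper(as.character(data$channel))
  bad_chan <- which(!data$channel %in% c("FAM", "VIC"))
  if (length(bad_chan) > 0) {
    parse_error(sprintf("Unknown channel label in row %d (expected FAM/VIC).",
                        bad_chan[1]), call = call)
  }
  fl <- suppressWarnings(as.numeric(data$fluorescence))
  if (anyNA(fl)) {
    parse_error(sprintf("Non-numeric fluorescence in row %d.",
                        which(is.na(fl))[1]), call = call)
  }
  data$fluorescence <- fl
  cyc <- suppressWarnings(as.integer(data$cycle))
  if (anyNA(cyc)) {
    parse_error(sprintf("Non-integer cycle in row %d.",
                        which(is.na(cyc))[1]), call = call)
  }
  data$cycle <- cyc
  dup <- duplicated(data[c("well", "channel", "cycle")])
  if (any(dup)) {
    parse_error(sprintf("Duplicated (well, channel, cycle) row: %d.",
                        which(dup)[1]), call = call)
  }
  data
}

#' Read long-format raw fluorescence readings
#'
#' Expects a CSV with header `well,cycle,channel,fluorescence`; channel
#' labels FAM / VIC (case-insensitive). Readings are validated (no duplicate
#' well/channel/cycle rows, numeric fluorescence) and sorted by cycle within
#' each curve.
#'
#' @param path CSV file path.
#' @return Validated tibble with columns `well`, `cycle`, `channel`,
#'   `fluorescence`.
#' @export
read_fluorescence_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  data <- validate_fluorescence(data)
  arrange(data, .data$well, .data$channel, .data$cycle)
}

#' Write long-format fluorescence readings
#'
#' @param data Tibble with columns `well`, `cycle`, `channel`,
#'   `fluorescence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fluorescence_csv <- function(data, path) {
  readr::write_csv(validate_fluorescence(data)[
    c("well", "cycle", "channel", "fluorescence")], path)
  invisible(path)
}

validate_sample_sheet <- function(sheet, call = caller_env()) {
  needed <- c("well", "role")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0) {
    parse_error(paste0("Sample sheet is missing column(s): ",
                       paste(missing_cols, collapse = ", ")), call = call)
  }
  sheet <- as_tibble(sheet)
  for (col in c("x_true", "sample_id", "tissue", "replicate")) {
    if (!col %in% names(sheet)) {
      sheet[[col]] <- NA
    }
  }
  sheet$role <- toupper(as.character(sheet$role))
  bad_role <- which(!sheet$role %in% c("STANDARD", "UNKNOWN"))
  if (length(bad_role) > 0) {
    parse_error(sprintf("Unknown role in row %d (expected STANDARD/UNKNOWN).",
                        bad_role[1]), call = call)
  }
  sheet$x_true <- suppressWarnings(as.numeric(sheet$x_true))
  sheet$replicate <- suppressWarnings(as.integer(sheet$replicate))
  if (any(duplicated(sheet$well))) {
    parse_error(sprintf("Duplicated well in sample sheet: %s.",
                        sheet$well[duplicated(sheet$well)][1]), call = call)
  }
  std <- sheet$role == "STANDARD"
  bad_std <- std & (is.na(sheet$x_true) | sheet$x_true < 0 | sheet$x_true > 1)
  if (any(bad_std)) {
    parse_error(sprintf(
      "STANDARD well %s needs x_true in [0, 1].",
      sheet$well[bad_std][1]), call = call)
  }
  unk <- !std
  bad_unk <- unk & (is.na(sheet$sample_id) | is.na(sheet$tissue))
  if (any(bad_unk)) {
    parse_error(sprintf("UNKNOWN well %s needs sample_id and tissue.",
                        sheet$well[bad_unk][1]), call = call)
  }
  sheet
}

#' Read a plate sample sheet
#'
#' CSV mapping wells to roles. STANDARD wells must carry `x_true` (known
#' VIC-allele fraction in \[0, 1\]); UNKNOWN wells must carry `sample_id`
#' and `tissue`. Wells must be unique.
#'
#' @param path CSV file with header
#'   `well,role,x_true,sample_id,tissue,replicate`.
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_sample_sheet(sheet)
}

#' Write a plate sample sheet
#'
#' @param sheet Sample-sheet tibble (see [read_sample_sheet()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(validate_sample_sheet(sheet)[
    c("well", "role", "x_true", "sample_id", "tissue", "replicate")], path)
  invisible(path)
}

#' Reference k' calibration measurements
#'
#' The packaged reference calibration dataset: replicate-averaged transformed
#' fluorescence ratios (k') and replicate CVs for the 13 plasmid-mixture
#' standards (VIC-allele fractions 0, 0.05, 0.1, 0.2, ..., 0.9, 0.95, 1),
#' measured once on cDNA-assay primers and once on gDNA-assay primers in the
#' published dual-probe ASE experiment this package reimplements the analysis
#' of.
#'
#' @param assay `"cDNA"`, `"gDNA"`, or `"both"` (default).
#' @return Tibble with columns `assay`, `x_true` (fraction), `k_mean`,
#'   `cv_percent`.
#' @export
#' @examples
#' intra_cv(reference_standards("cDNA")) # 0.70
reference_standards <- function(assay = c("both", "cDNA", "gDNA")) {
  assay <- arg_match(assay)
  path <- system.file("extdata", "reference_standards.tsv",
                      package = "taqase", mustWork = TRUE)
  out <- readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(x_true = .data$x_true_percent / 100) |>
    select("assay", "x_true", "k_mean", "cv_percent")
  if (assay != "both") {
    out <- filter(out, .data$assay == .env$assay)
  }
  out
}

#' Calibrate directly from tabulated k' values
#'
#' Builds a standard curve from a table of known mixture fractions and k'
#' values, skipping curve fitting — for instruments or published tables where
#' only per-standard k' is available.
#'
#' @param data Data frame (or TSV path) with columns `x_true` and `k_mean`,
#'   or replicate-level `x_true` and `k_prime`.
#' @inheritParams build_standard_curve
#' @return A `standard_curve`.
#' @export
#' @examples
#' calibrate_from_kprime(reference_standards("cDNA"), assay = "cDNA")
calibrate_from_kprime <- function(data, exclude_pure = TRUE,
                                  assay = "cDNA") {
  if (is.character(data) && length(data) == 1) {
    data <- readr::read_tsv(data, show_col_types = FALSE)
  }
  build_standard_curve(data, exclude_pure = exclude_pure, assay = assay)
}
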