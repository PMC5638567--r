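norm_dna <- function(x, arg = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(sprintf("`%s` must be a single non-empty DNA string.", arg),
          class = "taqase_invalid_sequence")
  }
  if (grepl("[^ACGTN]", x)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T,N}.", arg),
          class = "taqase_invalid_sequence")
  }
  x
}

#' Global pairwise alignment of two promoter alleles
#'
#' Needleman-Wunsch global alignment with linear gap penalty (defaults:
#' match +1, mismatch -1, gap -2). Traceback ties are broken
#' deterministically, preferring diagonal (substitution) over up (gap in the
#' second sequence) over left (gap in the first sequence), so identical
#' inputs always give identical alignments. A linear penalty suffices here:
#' the promoter alleles this was built for differ by a single 1 bp indel.
#'
#' @param seq_a,seq_b DNA strings (characters A, C, G, T, N;
#'   case-insensitive).
#' @param match,mismatch,gap Scoring scheme.
#' @return A `pairwise_alignment` object: `aligned_a`, `aligned_b` (equal
#'   length gapped strings), and `score`.
#' @export
#' @examples
#' align_pair("ACGTA", "ACTA")
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(norm_dna(seq_a, "seq_a"), "")[[1]]
  b <- strsplit(norm_dna(seq_b, "seq_b"), "")[[1]]
  n <- length(a)
  m <- length(b)
  score <- matrix(0, n + 1, m + 1)
  # traceback codes: 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  trace <- matrix(0L, n + 1, m + 1)
  score[, 1] <- gap * 0:n
  score[1, ] <- gap * 0:m
  trace[-1, 1] <- 2L
  trace[1, -1] <- 3L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    prev <- score[i, ]
    cur <- score[i + 1, ]
    for (j in seq_len(m)) {
      d <- prev[j] + sub[j]
      u <- prev[j + 1] + gap
      l <- cur[j] + gap
      if (d >= u && d >= l) {
        cur[j + 1] <- d
        trace[i + 1, j + 1] <- 1L
      } else if (u >= l) {
        cur[j + 1] <- u
        trace[i + 1, j + 1] <- 2L
      } else {
        cur[j + 1] <- l
        trace[i + 1, j + 1] <- 3L
      }
    }
    score[i + 1, ] <- cur
  }
  out_a <- character(0)
  out_b <- character(0)
  i <- n + 1
  j <- m + 1
  while (i > 1 || j > 1) {
    tr <- trace[i, j]
    if (tr == 1L) {
      out_a <- c(a[i - 1], out_a)
      out_b <- c(b[j - 1], out_b)
      i <- i - 1
      j <- j - 1
    } else if (tr == 2L) {
      out_a <- c(a[i - 1], out_a)
      out_b <- c("-", out_b)
      i <- i - 1
    } else {
      out_a <- c("-", out_a)
      out_b <- c(b[j - 1], out_b)
      j <- j - 1
    }
  }
  structure(
    list(aligned_a = paste(out_a, collapse = ""),
         aligned_b = paste(out_b, collapse = ""),
         score = score[n + 1, m + 1]),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score:", x$score, "\n")
  cat(x$aligned_a, "\n")
  cat(x$aligned_b, "\n")
  invisible(x)
}

#' Inter-allele variants from a global alignment
#'
#' Scans the alignment column by column. Mismatched bases become SNPs;
#' runs of adjacent gap columns are merged into single indel events
#' (DELETION = bases present in sequence A only, INSERTION = bases present in
#' sequence B only). Positions are 1-based coordinates on sequence A; an
#' insertion is anchored at the A position immediately 5' of the inserted
#' bases (0 when the insertion precedes the first base).
#'
#' @param alignment An [align_pair()] result.
#' @return Tibble with columns `position`, `kind` (`"SNP"`, `"INSERTION"`,
#'   `"DELETION"`), `allele_a`, `allele_b`. Empty when the sequences are
#'   identical.
#' @export
#' @examples
#' find_variants(align_pair("ACGT", "ACTT"))
find_variants <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  pos_a <- cumsum(a != "-") # A-coordinate of each column (0 before first base)
  state <- dplyr::case_when(a == "-" ~ "ins", b == "-" ~ "del",
                            a != b ~ "snp", TRUE ~ "match")
  rows <- list()
  i <- 1
  while (i <= length(a)) {
    s <- state[i]
    if (s == "match") {
      i <- i + 1
      next
    }
    if (s == "snp") {
      rows[[length(rows) + 1]] <- tibble(position = pos_a[i], kind = "SNP",
                                         allele_a = a[i], allele_b = b[i])
      i <- i + 1
      next
    }
    j <- i
    while (j < length(a) && state[j + 1] == s) j <- j + 1
    if (s == "del") {
      rows[[length(rows) + 1]] <- tibble(
        position = pos_a[i], kind = "DELETION",
        allele_a = paste(a[i:j], collapse = ""), allele_b = "")
    } else {
      rows[[length(rows) + 1]] <- tibble(
        position = pos_a[i], kind = "INSERTION", allele_a = "",
        allele_b = paste(b[i:j], collapse = ""))
    }
    i <- j + 1
  }
  if (length(rows) == 0) {
    return(tibble(position = integer(0), kind = character(0),
                  allele_a = character(0), allele_b = character(0)))
  }
  list_rbind(rows)
}

#' GC fraction of a DNA string
#'
#' Fraction of G + C among non-N bases (N bases are excluded from numerator
#' and denominator).
#'
#' @param seq DNA string.
#' @return Fraction in \[0, 1\] (`NaN` for an all-N sequence).
#' @export
gc_fraction <- function(seq) {
  s <- strsplit(norm_dna(seq), "")[[1]]
  non_n <- sum(s != "N")
  sum(s %in% c("G", "C")) / non_n
}

#' Observed / expected CpG ratio
#'
#' `(N_CpG * L) / (N_C * N_G)` with `L` the number of non-N bases; defined as
#' 0 when either base count is 0. Values near 1 indicate CpG dinucleotides
#' occur as often as base composition predicts; bulk genomic DNA is CpG
#' depleted, CpG islands are not.
#'
#' @param seq DNA string.
#' @return Non-negative ratio.
#' @export
obs_exp_cpg <- function(seq) {
  s <- strsplit(norm_dna(seq), "")[[1]]
  n_c <- sum(s == "C")
  n_g <- sum(s == "G")
  if (n_c == 0 || n_g == 0) {
    return(0)
  }
  n_cpg <- sum(s[-length(s)] == "C" & s[-1] == "G")
  n_cpg * sum(s != "N") / (n_c * n_g)
}

#' Predict CpG islands with sliding-window criteria
#'
#' Slides a window (default 200 bp, step 1) across the sequence; a window
#' qualifies when its GC fraction strictly exceeds `gc_min` and its
#' observed/expected CpG ratio strictly exceeds `oe_min` (the classical
#' >50% / >60% island criteria). Overlapping qualifying windows are merged;
#' merged regions are reported with whole-region statistics, recomputed on
#' the merged interval, and must themselves satisfy the length and threshold
#' criteria.
#'
#' @param seq DNA string.
#' @param window Window width in bp.
#' @param gc_min,oe_min Strict lower thresholds for GC fraction and O/E CpG.
#' @param min_len Minimum merged-region length in bp.
#' @return Tibble with columns `start`, `end` (1-based inclusive), `length`,
#'   `gc_fraction`, `obs_exp_cpg`. Empty (with a warning) when the sequence
#'   is shorter than the window.
#' @export
#' @examples
#' predict_cpg_islands(strrep("CG", 300))
predict_cpg_islands <- function(seq, window = 200, gc_min = 0.5,
                                oe_min = 0.6, min_len = 200) {
  s <- strsplit(norm_dna(seq), "")[[1]]
  empty <- tibble(start = integer(0), end = integer(0), length = integer(0),
                  gc_fraction = numeric(0), obs_exp_cpg = numeric(0))
  n <- length(s)
  if (n < window) {
    warn("Sequence shorter than the window; no islands predicted.")
    return(empty)
  }
  cum_c <- c(0, cumsum(s == "C"))
  cum_g <- c(0, cumsum(s == "G"))
  cum_n <- c(0, cumsum(s == "N"))
  is_cpg <- c(s[-n] == "C" & s[-1] == "G", FALSE)
  cum_cpg <- c(0, cumsum(is_cpg))
  win_sum <- function(cum, start, end) {
    cum[end + 1] - cum[start]
  }
  starts <- seq_len(n - window + 1)
  ends <- starts + window - 1
  nc <- win_sum(cum_c, starts, ends)
  ng <- win_sum(cum_g, starts, ends)
  nn <- win_sum(cum_n, starts, ends)
  len_eff <- window - nn
  # CpG counted when both bases lie inside the window
  ncpg <- win_sum(cum_cpg, starts, pmax(starts, ends - 1))
  gc <- (nc + ng) / len_eff
  oe <- ifelse(nc * ng > 0, ncpg * len_eff / (nc * ng), 0)
  ok <- is.finite(gc) & gc > gc_min & oe > oe_min
  if (!any(ok)) {
    return(empty)
  }
  # merge overlapping qualifying windows
  qs <- starts[ok]
  qe <- ends[ok]
  breaks <- which(qs[-1] > head(qe, -1) + 1)
  grp <- rep(seq_len(length(breaks) + 1),
             diff(c(0, breaks, length(qs))))
  regions <- tibble(start = tapply(qs, grp, min)[unique(grp)],
                    end = tapply(qe, grp, max)[unique(grp)])
  stats <- map2(regions$start, regions$end, function(st, en) {
    sub <- paste(s[st:en], collapse = "")
    tibble(start = as.integer(st), end = as.integer(en),
           length = as.integer(en - st + 1),
           gc_fraction = gc_fraction(sub), obs_exp_cpg = obs_exp_cpg(sub))
  })
  out <- list_rbind(stats)
  filter(out, .data$length >= min_len, .data$gc_fraction > gc_min,
         .data$obs_exp_cpg > oe_min)
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA file (uncompressed or gzip).
#' @return Tibble with columns `id` (first word of the header) and
#'   `sequence` (upper-case).
#' @export
read_promoter_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(set)),
         sequence = unname(toupper(as.character(set))))
}

#' Write promoter sequences to a FASTA file
#'
#' @param sequences Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  set <- Biostrings::DNAStringSet(setNames(sequences$sequence, sequences$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
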