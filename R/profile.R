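# Homeodomain profile search: build a log-odds profile from a gapless seed
# alignment, scan assembly contigs in all six reading frames, convert scores
# to an empirically calibrated E-value analogue, and collapse redundant hits.

#' Build a log-odds protein profile from a gapless seed alignment
#'
#' Column scores are `ln((freq + pseudocount * bg) / (1 + pseudocount) / bg)`,
#' i.e. log odds of a pseudocount-smoothed column frequency against the
#' background. As `pseudocount` grows the profile flattens towards zero
#' (pure background).
#'
#' @param seed_alignment gapless aligned protein sequences (character vector
#'   or [Biostrings::AAStringSet]), all the same length (60 for a
#'   homeodomain).
#' @param pseudocount smoothing pseudocount (> 0, default 0.5).
#' @param background named vector of 20 residue frequencies summing to 1;
#'   default uniform.
#' @return An object of class `protein_profile`: list with `length`,
#'   `log_odds` (20 x L matrix, rows `ACDEFGHIKLMNPQRSTVWY`), `background`,
#'   `pseudocount` and (after calibration) `calibration`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 0.5, background = NULL) {
  seqs <- as_seq_character(seed_alignment)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("ragged seed alignment: unequal lengths")
  if (any(grepl("-", seqs, fixed = TRUE))) stop("seed alignment must be gapless")
  stopifnot(pseudocount > 0)
  L <- lens[1]
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(abs(sum(background) - 1) < 1e-8, all(AA_ALPHABET %in% names(background)))
  background <- background[AA_ALPHABET]

  mat <- do.call(rbind, strsplit(seqs, ""))
  log_odds <- matrix(NA_real_, 20, L, dimnames = list(AA_ALPHABET, NULL))
  n <- nrow(mat)
  for (j in seq_len(L)) {
    cnt <- table(factor(mat[, j], levels = AA_ALPHABET))
    freq <- as.numeric(cnt) / n
    log_odds[, j] <- log((freq + pseudocount * background) /
                           (1 + pseudocount) / background)
  }
  structure(list(length = L, log_odds = log_odds, background = background,
                 pseudocount = pseudocount, n_sequences = n, calibration = NULL),
            class = "protein_profile")
}

#' Score a peptide against a profile
#' @param profile a [build_profile()] result.
#' @param peptide amino-acid string of the profile's length; `NA` if it
#'   contains residues outside the 20-letter alphabet.
#' @return Numeric score (sum of per-column log odds, nats).
#' @export
score_peptide <- function(profile, peptide) {
  stopifnot(inherits(profile, "protein_profile"),
            nchar(peptide) == profile$length)
  aa <- strsplit(peptide, "")[[1]]
  if (!all(aa %in% AA_ALPHABET)) return(NA_real_)
  sum(profile$log_odds[cbind(match(aa, AA_ALPHABET), seq_along(aa))])
}

#' Calibrate a profile's score-to-E-value mapping
#'
#' Scores `n` random peptides drawn i.i.d. from the profile background and
#' fits a Gumbel distribution to the null scores by the method of moments.
#' The tail probability of a window score s is then
#' `p(s) = 1 - exp(-exp(-(s - mu) / beta))`, and a scan reporting `W`
#' windows assigns each hit the E-value analogue `W * p(s)`. The calibration
#' is deterministic (fixed internal seed) and stored on the profile.
#'
#' @param profile a [build_profile()] result.
#' @param n number of null windows (default 1000).
#' @param seed seed of the null sample (fixed default so every calibration
#'   of the same profile is identical).
#' @return The profile with a `calibration` field (`mu`, `beta`, `n`).
#' @export
calibrate_profile <- function(profile, n = 1000L, seed = 990917L) {
  stopifnot(inherits(profile, "protein_profile"))
  scores <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pep <- sample(AA_ALPHABET, profile$length, replace = TRUE,
                    prob = profile$background)
      sum(profile$log_odds[cbind(match(pep, AA_ALPHABET), seq_along(pep))])
    }, numeric(1))
  })
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.57721566490153286 * beta
  profile$calibration <- list(mu = mu, beta = beta, n = n)
  profile
}

gumbel_tail_p <- function(s, mu, beta) {
  # upper tail of the fitted null distribution; stable for large (s-mu)/beta
  z <- (s - mu) / beta
  ifelse(z > 20, exp(-z), 1 - exp(-exp(-z)))
}

# score cutoff such that n_windows * p(score) <= evalue
score_cutoff_for_evalue <- function(calibration, evalue, n_windows) {
  p <- min(1 - 1e-12, evalue / max(n_windows, 1))
  if (p >= 1) return(-Inf)
  calibration$mu - calibration$beta * log(-log(1 - p))
}

#' Scan contigs for profile matches in all six reading frames
#'
#' Slides a gapless window of the profile's length over the six conceptual
#' translations of each contig (both strands, three frames). Windows
#' containing a stop codon or an untranslatable residue are voided. Window
#' scores are converted to an E-value analogue via the profile's Gumbel
#' calibration (run automatically if absent), and windows at or below
#' `threshold_evalue` are reported as hits, sorted by score.
#'
#' Coordinates are 0-based half-open on the forward strand; for every hit
#' `end - start` equals three times the profile length, and `peptide` is the
#' translation of the strand-adjusted slice.
#'
#' @param contigs contig sequences (character vector,
#'   [Biostrings::DNAStringSet], or a FASTA file path).
#' @param profile a (calibrated) [build_profile()] result.
#' @param threshold_evalue E-value analogue cutoff (default 1e-6).
#' @return A data.frame of class `profile_hits` with columns `contig`,
#'   `start`, `end`, `strand`, `frame`, `score`, `evalue`, `peptide`.
#' @export
scan_contigs <- function(contigs, profile, threshold_evalue = 1e-6) {
  stopifnot(inherits(profile, "protein_profile"))
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  seqs <- as_seq_character(contigs)
  if (length(seqs) == 0) stop("no contigs supplied")
  L <- profile$length
  short <- nchar(seqs) < 3L * L
  if (any(short)) {
    message(sum(short), " contig(s) shorter than ", 3L * L, " nt skipped")
    seqs <- seqs[!short]
  }
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(), score = numeric(),
                      evalue = numeric(), peptide = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("profile_hits", "data.frame")
  if (length(seqs) == 0) return(empty)

  if (is.null(profile$calibration)) profile <- calibrate_profile(profile)
  cal <- profile$calibration

  # nominal window count (stop-voided windows included: a conservative,
  # deterministic scan-size constant for the E-value analogue)
  n_windows <- sum(vapply(nchar(seqs), function(len) {
    aa <- (len - 0:2) %/% 3L
    2 * sum(pmax(0L, aa - L + 1L))
  }, numeric(1)))
  s_min <- score_cutoff_for_evalue(cal, threshold_evalue, n_windows)

  res <- scan_profile_cpp(unname(seqs), profile$log_odds,
                          paste(AA_ALPHABET, collapse = ""), s_min)
  if (length(res$score) == 0) return(empty)

  len <- nchar(seqs)[res$contig]
  aa_start_nt <- res$frame + 3L * res$aa_offset         # on scanned strand
  aa_end_nt <- aa_start_nt + 3L * L
  start <- ifelse(res$strand == "+", aa_start_nt, len - aa_end_nt)
  end <- start + 3L * L
  hits <- data.frame(contig = names(seqs)[res$contig],
                     start = as.integer(start), end = as.integer(end),
                     strand = res$strand, frame = res$frame,
                     score = res$score,
                     evalue = n_windows * gumbel_tail_p(res$score, cal$mu, cal$beta),
                     peptide = res$peptide, stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= threshold_evalue, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("profile_hits", "data.frame")
  hits
}

#' Collapse redundant overlapping hits
#'
#' Greedy best-first selection: hits are visited in decreasing score order
#' and a hit is dropped when it overlaps an already kept hit on the same
#' contig by at least `min_overlap` of the shorter interval.
#'
#' @param hits a [scan_contigs()] result (must be sorted by score
#'   descending, as returned).
#' @param min_overlap overlap fraction at which two hits are considered
#'   redundant (default 0.5).
#' @return The surviving hits, same columns, score-descending.
#' @export
dedupe_hits <- function(hits, min_overlap = 0.5) {
  if (nrow(hits) <= 1) return(hits)
  if (is.unsorted(-hits$score)) hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$contig[i] != hits$contig[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      wmin <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov > 0 && ov / wmin >= min_overlap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits as BED6 plus a detailed TSV
#'
#' BED scores are the scan scores rescaled linearly to 0-1000 over the
#' reported hits.
#'
#' @param hits a [scan_contigs()] result.
#' @param bed_path,tsv_path output paths (`NULL` to skip either).
#' @return Invisibly, the written paths.
#' @export
write_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    rng <- range(hits$score)
    scaled <- if (diff(rng) == 0) rep(1000L, nrow(hits)) else
      as.integer(round(1000 * (hits$score - rng[1]) / diff(rng)))
    bed <- data.frame(hits$contig, hits$start, hits$end,
                      paste0("hit", seq_len(nrow(hits))), scaled, hits$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(hits, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
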