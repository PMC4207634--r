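# k-mer spectrum genome profiling: count k-mers in reads, locate the
# coverage peak of the multiplicity histogram, convert k-mer coverage to
# base coverage via Ck = C * (L - k + 1) / L, and estimate genome size as
# total_bases / C.

#' Count k-mers in sequencing reads
#'
#' Builds the k-mer spectrum: a histogram of how many distinct k-mers occur
#' at each multiplicity. With `canonical = TRUE` (the default; shotgun reads
#' sample both strands) a k-mer and its reverse complement are pooled.
#' k-mers spanning a non-ACGT base are skipped. Counting is exact
#' (hash-based), so `k` is limited to 31.
#'
#' @param reads a character vector, [Biostrings::DNAStringSet], or a vector
#'   of FASTQ/FASTA file paths (optionally gzipped; format inferred from the
#'   extension).
#' @param k odd k-mer size between 1 and 31 (default 17).
#' @param canonical pool reverse-complement k-mers (default `TRUE`).
#' @return An object of class `kmer_spectrum`: list with `k`, `histogram`
#'   (data.frame `multiplicity`, `count`), `total_kmers`, `distinct_kmers`,
#'   `total_bases` (sum of read lengths) and `canonical`.
#' @export
count_kmers <- function(reads, k = 17L, canonical = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 1, k <= 31)
  if (k %% 2L == 0L) warning("even k cannot distinguish palindromic k-mers; odd k recommended")
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads))) {
    sets <- lapply(reads, function(f) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE)) "fastq" else "fasta"
      Biostrings::readDNAStringSet(f, format = fmt)
    })
    reads <- as.character(do.call(c, sets))
  } else {
    reads <- as_seq_character(reads)
  }
  total_bases <- sum(nchar(reads))
  if (all(nchar(reads) < k)) {
    warning("k exceeds every read length; empty spectrum")
    hist <- data.frame(multiplicity = integer(), count = numeric())
    return(structure(list(k = k, histogram = hist, total_kmers = 0,
                          distinct_kmers = 0, total_bases = total_bases,
                          canonical = canonical),
                     class = "kmer_spectrum"))
  }
  res <- kmer_histogram_cpp(reads, k, canonical)
  hist <- data.frame(multiplicity = res$multiplicity, count = res$count)
  structure(list(k = k, histogram = hist, total_kmers = res$total_kmers,
                 distinct_kmers = res$distinct_kmers, total_bases = total_bases,
                 canonical = canonical),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum: k =", x$k,
      if (x$canonical) "(canonical)" else "(stranded)", "\n")
  cat("  total k-mers:", format(x$total_kmers, big.mark = ","),
      " distinct:", format(x$distinct_kmers, big.mark = ","), "\n")
  invisible(x)
}

#' Locate the k-mer coverage peak of a spectrum
#'
#' Finds the multiplicity with the highest distinct-k-mer count among local
#' maxima at multiplicity `>= min_multiplicity` (the low-multiplicity ramp
#' of error k-mers is excluded by the threshold), then refines it by
#' three-point quadratic interpolation over the immediate neighbours to give
#' sub-integer resolution.
#'
#' @param spectrum a [count_kmers()] result.
#' @param min_multiplicity smallest multiplicity eligible as a peak
#'   (default 4).
#' @return The k-mer coverage `ck` (numeric scalar).
#' @export
find_peak <- function(spectrum, min_multiplicity = 4L) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  h <- spectrum$histogram
  if (nrow(h) == 0) stop("empty spectrum: no k-mers counted")
  mmax <- max(h$multiplicity)
  counts <- numeric(mmax + 2L)  # dense, with zero-padding above
  counts[h$multiplicity] <- h$count
  eligible <- seq.int(max(min_multiplicity, 2L), mmax)
  if (length(eligible) == 0) stop("no multiplicities at or above min_multiplicity")
  is_local_max <- vapply(eligible, function(m)
    counts[m] > 0 && counts[m] >= counts[m - 1L] && counts[m] >= counts[m + 1L],
    logical(1))
  if (!any(is_local_max))
    stop("no coverage peak above the error ramp: spectrum uninterpretable ",
         "(coverage too low or min_multiplicity too high)")
  cand <- eligible[is_local_max]
  m0 <- cand[which.max(counts[cand])]
  y0 <- counts[m0]; ym <- counts[m0 - 1L]; yp <- counts[m0 + 1L]
  denom <- ym - 2 * y0 + yp
  offset <- if (denom < 0) 0.5 * (ym - yp) / denom else 0
  m0 + offset
}

#' Convert k-mer coverage to base coverage
#'
#' A read of length `L` contains `L - k + 1` k-mers, so k-mer coverage
#' understates base coverage: `Ck = C * (L - k + 1) / L`, hence
#' `C = Ck * L / (L - k + 1)`.
#'
#' @param ck k-mer coverage (fold).
#' @param L read length in bp.
#' @param k k-mer size (`L > k >= 1`).
#' @return Base coverage `C` (fold).
#' @export
kmer_to_base_coverage <- function(ck, L, k) {
  stopifnot(k >= 1)
  if (L <= k) stop("read length L must exceed k")
  ck * L / (L - k + 1)
}

#' Estimate genome size from total sequenced bases and coverage
#'
#' @param total_bases total sequenced bases (post-trim, as provided).
#' @param c base coverage (fold, > 0).
#' @return Estimated genome size in bp.
#' @export
estimate_genome_size <- function(total_bases, c) {
  if (c <= 0) stop("coverage must be positive")
  total_bases / c
}

#' Full k-mer-spectrum genome profile of a read set
#'
#' Runs the whole chain: count k-mers, locate the coverage peak, convert
#' k-mer coverage to base coverage, and estimate genome size from the total
#' sequenced bases.
#'
#' Sequencing errors shunt k-mer mass out of the coverage peak into the
#' low-multiplicity error ramp, which would inflate the genome size if the
#' raw base total were divided by the peak coverage. With
#' `exclude_error_ramp = TRUE` (default) the base total is therefore scaled
#' by the fraction of k-mer mass at multiplicities at or above
#' `min_multiplicity` - the same cutoff that excludes the ramp from peak
#' finding - before the division, so numerator and denominator describe the
#' same (error-free) k-mer population.
#'
#' @inheritParams count_kmers
#' @inheritParams find_peak
#' @param read_length read length `L` used in the coverage conversion;
#'   `NULL` (default) uses the modal read length of the input.
#' @param exclude_error_ramp discount the sequenced-base total by the
#'   error-ramp k-mer mass (default `TRUE`).
#' @return An object of class `kmer_profile_report`: list with `k`, `ck`,
#'   `c`, `read_length`, `total_bases` (raw), `effective_bases` (after the
#'   error-ramp discount) and `genome_size`, plus the `spectrum` itself.
#' @export
kmer_profile <- function(reads, k = 17L, canonical = TRUE,
                         min_multiplicity = 4L, read_length = NULL,
                         exclude_error_ramp = TRUE) {
  spectrum <- count_kmers(reads, k = k, canonical = canonical)
  if (is.null(read_length)) {
    lens <- if (is.character(reads) && all(file.exists(reads))) NULL else
      nchar(as_seq_character(reads))
    if (is.null(lens)) {
      # files were streamed through count_kmers; recover L from bases/kmers:
      # total_kmers = n_reads * (L - k + 1) is unavailable without n_reads,
      # so require explicit read_length for file input
      stop("read_length must be given when reads are supplied as files")
    }
    tab <- table(lens)
    read_length <- as.integer(names(tab)[which.max(tab)])
  }
  ck <- find_peak(spectrum, min_multiplicity = min_multiplicity)
  c <- kmer_to_base_coverage(ck, read_length, spectrum$k)
  eff_bases <- spectrum$total_bases
  if (exclude_error_ramp && spectrum$total_kmers > 0) {
    h <- spectrum$histogram
    mass <- h$multiplicity * h$count
    kept <- sum(mass[h$multiplicity >= min_multiplicity]) / sum(mass)
    eff_bases <- spectrum$total_bases * kept
  }
  gs <- estimate_genome_size(eff_bases, c)
  structure(list(k = spectrum$k, ck = ck, c = c, read_length = read_length,
                 total_bases = spectrum$total_bases, effective_bases = eff_bases,
                 genome_size = gs, spectrum = spectrum),
            class = "kmer_profile_report")
}

#' @export
print.kmer_profile_report <- function(x, ...) {
  cat("k-mer genome profile (k =", x$k, ")\n")
  cat(sprintf("  k-mer coverage Ck : %.3f\n", x$ck))
  cat(sprintf("  base coverage C   : %.3f  (L = %d)\n", x$c, x$read_length))
  cat(sprintf("  total bases       : %s\n", format(x$total_bases, big.mark = ",")))
  cat(sprintf("  genome size       : %.3f Mb\n", x$genome_size / 1e6))
  invisible(x)
}

#' Write a k-mer spectrum as TSV
#' @param spectrum a [count_kmers()] result.
#' @param path output path; columns `multiplicity`, `count`.
#' @return Invisibly, `path`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  write.table(spectrum$histogram, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a k-mer profile report as JSON
#' @param report a [kmer_profile()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_kmer_report <- function(report, path) {
  stopifnot(inherits(report, "kmer_profile_report"))
  jsonlite::write_json(report[c("k", "ck", "c", "read_length", "total_bases",
                                "genome_size")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
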