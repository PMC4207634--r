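# Synthetic genomes with planted homeobox-containing genes, and a paired-end
# shotgun read simulator. These stand in for real sequencing data so that the
# k-mer and homeobox-search stages can be validated against known truth.

#' Specify a synthetic genome
#'
#' Describes a random genome of a given length and GC content into which
#' protein-coding segments (typically 60-residue homeodomains) are planted at
#' known positions, on either strand. The planted coordinates form the ground
#' truth used to validate homeobox searches.
#'
#' @param length genome length in bp.
#' @param gc_fraction GC content in `[0, 1]`. Default 0.35, typical of
#'   lepidopteran genomes.
#' @param planted_genes `NULL` or a data.frame with columns `name`, `protein`
#'   (amino-acid string to reverse-translate), `position` (0-based insertion
#'   offset in bp) and `strand` (`"+"` or `"-"`).
#' @param seed integer seed controlling both the background sequence and the
#'   synonymous codon choices of the back-translation.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(length, gc_fraction = 0.35, planted_genes = NULL, seed = 1L) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(planted_genes)) {
    stopifnot(is.data.frame(planted_genes),
              all(c("name", "protein", "position", "strand") %in% names(planted_genes)))
    stopifnot(all(planted_genes$strand %in% c("+", "-")))
    w <- 3L * nchar(planted_genes$protein)
    if (any(planted_genes$position < 0) || any(planted_genes$position + w > length))
      stop("planted gene outside [0, length)")
    o <- order(planted_genes$position)
    p <- planted_genes[o, , drop = FALSE]
    ends <- p$position + 3L * nchar(p$protein)
    if (nrow(p) > 1 && any(p$position[-1] < ends[-nrow(p)]))
      stop("planted gene insertions overlap")
  }
  structure(list(length = as.integer(length), gc_fraction = gc_fraction,
                 planted_genes = planted_genes, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome with planted genes
#'
#' Draws a random background sequence and overwrites it at the requested
#' positions with uniform-synonymous-codon back-translations of the planted
#' proteins (reverse-complemented for minus-strand genes). Identical specs
#' yield byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @return A list with `contigs` (a named [Biostrings::DNAStringSet] of one
#'   record) and `truth`, a data.frame of 0-based half-open planted-gene
#'   coordinates with the realised CDS for each gene.
#' @export
gen_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    g <- random_dna(spec$length, spec$gc_fraction)
    pg <- spec$planted_genes
    if (is.null(pg) || nrow(pg) == 0) {
      truth <- data.frame(name = character(), start = integer(), end = integer(),
                          strand = character(), cds = character(),
                          stringsAsFactors = FALSE)
    } else {
      cds <- character(nrow(pg))
      for (i in seq_len(nrow(pg))) {
        cds[i] <- reverse_translate(pg$protein[i])
        ins <- if (pg$strand[i] == "-") revcomp(cds[i]) else cds[i]
        substr(g, pg$position[i] + 1L, pg$position[i] + nchar(ins)) <- ins
      }
      truth <- data.frame(name = pg$name, start = as.integer(pg$position),
                          end = as.integer(pg$position + 3L * nchar(pg$protein)),
                          strand = pg$strand, cds = cds, stringsAsFactors = FALSE)
    }
    contigs <- Biostrings::DNAStringSet(stats::setNames(g, "synthetic_genome"))
    list(contigs = contigs, truth = truth)
  })
}

#' Specify a paired-end read simulation
#'
#' Models Illumina-style paired-end shotgun sequencing: fixed read length,
#' a target fold coverage, Gaussian insert sizes, and uniform per-base
#' substitution errors (no indels). Defaults follow a typical 101-bp HiSeq
#' run at moderate coverage.
#'
#' @param read_length read length in bp (default 101).
#' @param coverage target fold coverage (> 0, default 15).
#' @param insert_mean,insert_sd insert size mean and SD in bp.
#' @param error_rate per-base substitution probability in `[0, 0.1)`.
#' @param seed integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length = 101L, coverage = 15, insert_mean = 300,
                          insert_sd = 30, error_rate = 0.005, seed = 1L) {
  stopifnot(read_length >= 1, coverage > 0, insert_mean >= 2 * read_length,
            error_rate >= 0, error_rate < 0.1)
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate paired-end shotgun reads from a genome
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragment pairs
#' uniformly from the genome, reads `read_length` bases inward from each
#' fragment end (read 2 reverse-complemented), and applies independent
#' substitution errors. Base qualities are a constant placeholder (`I`).
#'
#' @param genome a [Biostrings::DNAStringSet], [Biostrings::DNAString], or
#'   character vector of contig sequences (fragments are drawn from contigs
#'   proportionally to length).
#' @param spec a [read_sim_spec()].
#' @return A list with `fwd` and `rev` ([Biostrings::DNAStringSet] of read 1
#'   and read 2 sequences), `true_total_bases` (sum of read lengths) and
#'   `n_pairs`.
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (methods::is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  seqs <- as_seq_character(genome)
  glens <- nchar(seqs)
  gtot <- sum(glens)
  if (gtot <= spec$insert_mean) stop("genome shorter than mean insert size")
  rl <- spec$read_length
  n_pairs <- as.integer(round(spec$coverage * gtot / (2 * rl)))
  if (n_pairs < 1) stop("coverage too low: zero read pairs requested")

  with_seed(spec$seed, {
    ctg <- if (length(seqs) == 1L) rep.int(1L, n_pairs) else
      sample.int(length(seqs), n_pairs, replace = TRUE, prob = glens)
    ins <- pmax(2 * rl, round(rnorm(n_pairs, spec$insert_mean, spec$insert_sd)))
    ins <- pmin(ins, glens[ctg])
    start <- floor(runif(n_pairs) * (glens[ctg] - ins + 1)) + 1L

    r1 <- character(n_pairs)
    r2 <- character(n_pairs)
    for (ci in unique(ctg)) {
      idx <- which(ctg == ci)
      s <- seqs[[ci]]
      r1[idx] <- substring(s, start[idx], start[idx] + rl - 1L)
      frag_end <- start[idx] + ins[idx] - 1L
      r2raw <- substring(s, frag_end - rl + 1L, frag_end)
      r2[idx] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r2raw)))
    }

    if (spec$error_rate > 0) {
      r1 <- add_substitution_errors(r1, spec$error_rate)
      r2 <- add_substitution_errors(r2, spec$error_rate)
    }

    nm <- sprintf("pair%07d", seq_len(n_pairs))
    list(fwd = Biostrings::DNAStringSet(stats::setNames(r1, paste0(nm, "/1"))),
         rev = Biostrings::DNAStringSet(stats::setNames(r2, paste0(nm, "/2"))),
         true_total_bases = as.numeric(2 * n_pairs) * rl,
         n_pairs = n_pairs)
  })
}

# independent per-base substitutions; every error changes the base.
# operates on the concatenation of all reads so the per-base work is
# vectorised (reads must share one length, as simulate_reads guarantees)
add_substitution_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  n <- length(reads)
  total <- n * rl
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(total, n_err)
  chars <- strsplit(paste(reads, collapse = ""), "")[[1]]
  old <- chars[pos]
  new <- sample(DNA_BASES, n_err, replace = TRUE)
  while (any(same <- new == old))
    new[same] <- sample(DNA_BASES, sum(same), replace = TRUE)
  chars[pos] <- new
  cat <- paste(chars, collapse = "")
  substring(cat, (seq_len(n) - 1L) * rl + 1L, seq_len(n) * rl)
}

#' Write simulated reads as paired FASTQ files
#'
#' @param reads result of [simulate_reads()].
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written with constant `I` base qualities.
#' @return Invisibly, the two file paths.
#' @export
write_paired_fastq <- function(reads, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads$fwd)))
  q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads$rev)))
  Biostrings::writeXStringSet(reads$fwd, f1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(reads$rev, f2, format = "fastq", qualities = q2)
  invisible(c(f1, f2))
}
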