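# Shared low-level helpers: alphabets, seeded evaluation, translation.

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded generators do not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# named character vector codon -> amino acid (standard code, '*' = stop)
genetic_code <- function() {
  gc <- .lepihox_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    .lepihox_cache$genetic_code <- gc
  }
  gc
}

# list amino acid -> character vector of codons (stop under "*")
codons_by_aa <- function() {
  tab <- .lepihox_cache$codons_by_aa
  if (is.null(tab)) {
    gc <- genetic_code()
    tab <- split(names(gc), unname(gc))
    .lepihox_cache$codons_by_aa <- tab
  }
  tab
}

# translate an in-frame nucleotide string (character scalar) to protein
translate_nt <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# reverse complement of a character scalar
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# back-translate a protein with uniform random synonymous codon choice;
# caller controls the RNG state
reverse_translate <- function(protein, stop_codon = FALSE) {
  aas <- strsplit(protein, "")[[1]]
  tab <- codons_by_aa()
  bad <- setdiff(unique(aas), names(tab))
  if (length(bad)) stop("cannot back-translate residue(s): ", paste(bad, collapse = ","))
  codons <- vapply(aas, function(a) {
    cs <- tab[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  out <- paste(codons, collapse = "")
  if (stop_codon) out <- paste0(out, sample(c("TAA", "TAG", "TGA"), 1L))
  out
}

# sample a random DNA string with a given GC fraction
random_dna <- function(n, gc_fraction = 0.5) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# coerce sequences (character vector / DNAStringSet / AAStringSet) to a
# named character vector
as_seq_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a character vector or an XStringSet")
  }
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}
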