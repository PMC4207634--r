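# In silico evolution of preferred DNA binding sites: repeated cycles of
# single-base mutation and greedy selection against an energy model, run
# from each of the four homopolymer starts, with every evaluated complex
# archived. Consensus matrices summarise the lowest-energy archive members.

#' DNA core sequence
#'
#' The mutable DNA segment presented to a homeodomain. The inner window -
#' the centred `length - 2` positions (9 for the default 11-bp core) - is
#' sampled more heavily during mutation, mirroring the stronger protein
#' contacts at the centre of the binding site.
#'
#' @param sequence DNA string over ACGT.
#' @return An object of class `dna_core` with fields `sequence`,
#'   `core_length` and `inner` (inner-window positions).
#' @export
dna_core <- function(sequence) {
  stopifnot(grepl("^[ACGT]+$", sequence))
  n <- nchar(sequence)
  inner <- if (n > 2) 2:(n - 1) else seq_len(n)
  structure(list(sequence = sequence, core_length = n, inner = inner),
            class = "dna_core")
}

as_core_string <- function(dna) {
  if (inherits(dna, "dna_core")) dna$sequence else dna
}

#' Configuration of an in silico evolution run
#'
#' @param cycles mutation/selection cycles per start (default 1000).
#' @param core_length DNA core length (default 11).
#' @param inner_weight relative sampling weight of the inner window versus
#'   the two flanking positions (default 3; `Inf` restricts mutation to the
#'   inner window).
#' @param archive_top_n number of lowest-energy archived sequences pooled
#'   into the consensus (default 50).
#' @param seed integer master seed; each homopolymer start uses
#'   `seed + 0:3` (A, C, G, T order).
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(cycles = 1000L, core_length = 11L,
                             inner_weight = 3, archive_top_n = 50L, seed = 1L) {
  stopifnot(cycles >= 1, core_length >= 1, inner_weight >= 1, archive_top_n >= 1)
  structure(list(cycles = as.integer(cycles), core_length = as.integer(core_length),
                 inner_weight = inner_weight, archive_top_n = as.integer(archive_top_n),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

#' Propose a single-base mutation of a DNA core
#'
#' Changes exactly one position per call. The position is drawn with weight
#' `inner_weight` for inner-window positions and 1 for the two flanks; the
#' new base is uniform over the three alternatives. Uses the current RNG
#' state (seed control belongs to the caller).
#'
#' @param dna a [dna_core()] or DNA string.
#' @param inner_weight inner-window sampling weight (default 3).
#' @return A `dna_core` differing from the input at exactly one position.
#' @export
mutate_core <- function(dna, inner_weight = 3) {
  if (!inherits(dna, "dna_core")) dna <- dna_core(dna)
  n <- dna$core_length
  w <- rep(1, n)
  w[dna$inner] <- inner_weight
  if (is.infinite(inner_weight)) {
    pos <- dna$inner[sample.int(length(dna$inner), 1L)]
  } else {
    pos <- sample.int(n, 1L, prob = w)
  }
  old <- substr(dna$sequence, pos, pos)
  alt <- setdiff(DNA_BASES, old)
  s <- dna$sequence
  substr(s, pos, pos) <- alt[sample.int(3L, 1L)]
  dna_core(s)
}

#' Evolve preferred DNA binding sites for a homeodomain
#'
#' From each homopolymer start (poly-A, -C, -G, -T) runs `cycles` rounds of
#' single-base mutation followed by greedy selection: the proposal is scored
#' under the energy model and accepted iff its energy does not exceed the
#' current template's. Every evaluated (sequence, energy) pair is archived,
#' so low-energy states are retained even when a later proposal is rejected.
#'
#' @param protein homeodomain amino-acid string.
#' @param model an energy model (see [energy_score()]).
#' @param config an [evolution_config()].
#' @return An object of class `evolution_result`: a list of four
#'   `evolution_trace` objects (one per start), each holding `start_base`,
#'   `trace` (cycle, proposed sequence, energy, accepted), `best_energy_path`
#'   (template energy after each cycle, non-increasing), `final` and
#'   `archive` (distinct sequences with their best energies).
#' @export
evolve_binding_site <- function(protein, model, config = evolution_config()) {
  stopifnot(inherits(config, "evolution_config"))
  traces <- lapply(seq_along(DNA_BASES), function(i) {
    start <- strrep(DNA_BASES[i], config$core_length)
    with_seed(config$seed + i - 1L,
              evolve_one_start(protein, model, start, config))
  })
  names(traces) <- DNA_BASES
  structure(list(traces = traces, config = config,
                 descriptor = model_descriptor(model)),
            class = "evolution_result")
}

evolve_one_start <- function(protein, model, start, config) {
  check_energy <- function(e, s) {
    if (!is.finite(e))
      stop("non-finite energy for '", s, "' from model ", model_descriptor(model))
    e
  }
  cur <- dna_core(start)
  e_cur <- check_energy(energy_score(model, protein, cur), start)
  arch <- new.env(parent = emptyenv())
  arch[[start]] <- e_cur
  n <- config$cycles
  prop_seq <- character(n); prop_e <- numeric(n)
  accepted <- logical(n); path <- numeric(n)
  for (cy in seq_len(n)) {
    prop <- mutate_core(cur, config$inner_weight)
    e <- check_energy(energy_score(model, protein, prop), prop$sequence)
    old <- arch[[prop$sequence]]
    if (is.null(old) || e < old) arch[[prop$sequence]] <- e
    acc <- e <= e_cur
    if (acc) { cur <- prop; e_cur <- e }
    prop_seq[cy] <- prop$sequence; prop_e[cy] <- e
    accepted[cy] <- acc; path[cy] <- e_cur
  }
  seqs <- ls(arch)
  structure(list(start_base = substr(start, 1, 1),
                 trace = data.frame(cycle = seq_len(n), sequence = prop_seq,
                                    energy = prop_e, accepted = accepted,
                                    stringsAsFactors = FALSE),
                 best_energy_path = path,
                 final = cur$sequence,
                 archive = data.frame(sequence = seqs,
                                      energy = vapply(seqs, function(s) arch[[s]],
                                                      numeric(1)),
                                      stringsAsFactors = FALSE)),
            class = "evolution_trace")
}

#' Consensus matrix from the lowest-energy archived complexes
#'
#' Pools the archives of all runs (by default the four homopolymer starts),
#' deduplicates sequences keeping each sequence's best energy, takes the
#' `top_n` lowest-energy distinct sequences (ties broken lexicographically
#' for determinism) and tabulates per-position base frequencies. Information
#' content per position is `2 + sum(p * log2(p))` bits.
#'
#' @param result an [evolve_binding_site()] result, a list of
#'   `evolution_trace` objects, or a data.frame with `sequence` and `energy`.
#' @param top_n number of lowest-energy sequences to pool (default 50).
#' @return An object of class `consensus_matrix`: list with `prob`
#'   (core_length x 4 matrix, rows sum to 1), `ic` (bits per position),
#'   `consensus` (per-position argmax string), `source_count` and `sequences`.
#' @export
consensus_from_archives <- function(result, top_n = 50L) {
  pool <- pool_archive(result)
  agg <- stats::aggregate(energy ~ sequence, data = pool, FUN = min)
  agg <- agg[order(agg$energy, agg$sequence), , drop = FALSE]
  if (nrow(agg) < top_n) {
    warning("only ", nrow(agg), " distinct sequences available; using all")
    top_n <- nrow(agg)
  }
  top <- agg[seq_len(top_n), , drop = FALSE]
  mat <- do.call(rbind, strsplit(top$sequence, ""))
  L <- ncol(mat)
  prob <- t(apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = DNA_BASES))
    as.numeric(tab) / length(col)
  }))
  colnames(prob) <- DNA_BASES
  rownames(prob) <- seq_len(L)
  ic <- apply(prob, 1, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  consensus <- paste(DNA_BASES[apply(prob, 1, which.max)], collapse = "")
  structure(list(prob = prob, ic = ic, consensus = consensus,
                 source_count = top_n, sequences = top),
            class = "consensus_matrix")
}

pool_archive <- function(result) {
  if (is.data.frame(result)) return(result[c("sequence", "energy")])
  traces <- if (inherits(result, "evolution_result")) result$traces else result
  do.call(rbind, lapply(traces, function(tr) tr$archive[c("sequence", "energy")]))
}

#' Exhaustive substitution scan of a DNA core
#'
#' For each core position, scores all four bases with every other position
#' fixed at the start sequence. Under an additive energy model (such as the
#' built-in contact potential) the position-wise argmin equals the global
#' optimum, which makes the scan a start-independent control for bias
#' introduced by homopolymer starting points in the evolutionary search.
#'
#' @param protein homeodomain amino-acid string.
#' @param model an energy model.
#' @param start a [dna_core()] or DNA string.
#' @return A list with `energy` (4 x core_length matrix, rows A,C,G,T) and
#'   `argmin` (string of the per-position lowest-energy base; ties resolved
#'   in A,C,G,T order).
#' @export
substitution_scan <- function(protein, model, start) {
  start <- as_core_string(start)
  L <- nchar(start)
  E <- matrix(NA_real_, 4, L, dimnames = list(DNA_BASES, seq_len(L)))
  for (p in seq_len(L)) {
    for (b in seq_along(DNA_BASES)) {
      s <- start
      substr(s, p, p) <- DNA_BASES[b]
      E[b, p] <- energy_score(model, protein, s)
    }
  }
  argmin <- paste(DNA_BASES[apply(E, 2, which.min)], collapse = "")
  list(energy = E, argmin = argmin)
}

#' Export a consensus matrix as a MEME-format motif file
#'
#' Writes a minimal MEME motif text file (letter-probability matrix plus an
#' information-content comment block) consumable by standard sequence-logo
#' renderers.
#'
#' @param cm a [consensus_from_archives()] result.
#' @param path output file path.
#' @param name motif name written into the file.
#' @return Invisibly, `path`.
#' @export
logo_export <- function(cm, path, name = "consensus") {
  stopifnot(inherits(cm, "consensus_matrix"))
  L <- nrow(cm$prob)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            L, cm$source_count),
    vapply(seq_len(L), function(i)
      paste(sprintf("%.9f", cm$prob[i, ]), collapse = " "), character(1)),
    "",
    paste("# IC_bits:", paste(sprintf("%.6f", cm$ic), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a MEME-format letter-probability matrix
#'
#' @param path file written by [logo_export()] (or any minimal MEME motif
#'   file with a single DNA motif).
#' @return A list with `prob` (L x 4 matrix, columns A,C,G,T) and `ic`
#'   (recomputed information content in bits).
#' @export
read_meme_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix:", lines)
  stopifnot(length(hdr) >= 1)
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr[1]]))
  rows <- lines[(hdr[1] + 1):(hdr[1] + w)]
  prob <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  colnames(prob) <- DNA_BASES
  ic <- apply(prob, 1, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  list(prob = prob, ic = ic)
}
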