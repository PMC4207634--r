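# Synthetic multi-species protein alignments with planted conserved motifs,
# the ground truth for validating the lineage-aware motif rule.

#' Default species panel and lineage partition
#'
#' Seven lepidopteran species spanning basal moths and butterflies, with the
#' divergent-lineage partition used for motif calling (one basal-moth group,
#' one butterfly group; the seventh species belongs to neither group and
#' counts only towards the half-of-species majority).
#'
#' @return A list with `species` (7 names) and `lineage_partition` (list of
#'   two character vectors).
#' @export
default_species_panel <- function() {
  list(species = c("Hepialus", "Cameraria", "Plutella",
                   "Heliconius", "Polygonia", "Pararge", "Callimorpha"),
       lineage_partition = list(c("Hepialus", "Cameraria", "Plutella"),
                                c("Heliconius", "Polygonia", "Pararge")))
}

#' Specify a synthetic motif-bearing alignment
#'
#' @param species species names.
#' @param lineage_partition list of two disjoint species groups.
#' @param motifs `NULL`, or a list of motifs, each a list with `start`
#'   (0-based column), `residues` (string, length >= 3) and `carriers`
#'   (character vector of species). Every motif must be carried by at least
#'   half the species including at least one from each lineage group, and
#'   motifs must not overlap.
#' @param n_columns alignment width (default 80).
#' @param background_rate probability that a planted motif residue in a
#'   carrier is substituted by a random residue (default 0; background
#'   columns are always fully random per species).
#' @param seed integer seed.
#' @param strict with the default `TRUE`, a motif violating the carrier
#'   invariants (fewer than half the species, or carriers confined to one
#'   lineage group) is rejected with an error; with `FALSE` it is still
#'   planted in the sequences but omitted from the truth table, since it is
#'   not a conserved motif under the rule.
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(species = default_species_panel()$species,
                       lineage_partition = default_species_panel()$lineage_partition,
                       motifs = NULL, n_columns = 80L,
                       background_rate = 0, seed = 1L, strict = TRUE) {
  stopifnot(length(species) >= 2, n_columns >= 1,
            background_rate >= 0, background_rate < 1)
  g1 <- lineage_partition[[1]]; g2 <- lineage_partition[[2]]
  stopifnot(length(intersect(g1, g2)) == 0, all(c(g1, g2) %in% species))
  need <- ceiling(length(species) / 2)
  if (!is.null(motifs)) {
    occupied <- integer()
    for (i in seq_along(motifs)) {
      m <- motifs[[i]]
      stopifnot(all(c("start", "residues", "carriers") %in% names(m)))
      if (nchar(m$residues) < 3) stop("motif shorter than 3 residues")
      if (!all(m$carriers %in% species)) stop("unknown carrier species")
      qualifies <- length(m$carriers) >= need &&
        any(m$carriers %in% g1) && any(m$carriers %in% g2)
      if (!qualifies && strict)
        stop("motif violates carrier invariants (needs >= half the species ",
             "and both lineage groups); use strict = FALSE to plant it anyway")
      motifs[[i]]$qualifies <- qualifies
      cols <- m$start + seq_len(nchar(m$residues))
      if (m$start < 0 || max(cols) > n_columns) stop("motif outside alignment")
      if (any(cols %in% occupied)) stop("motifs overlap")
      occupied <- c(occupied, cols)
    }
  }
  structure(list(species = species, lineage_partition = lineage_partition,
                 motifs = motifs, n_columns = as.integer(n_columns),
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "motif_spec")
}

#' Generate an alignment with planted conserved motifs
#'
#' Background cells are drawn independently and uniformly over the 20
#' residues for every species. For each planted motif, the motif residues
#' are copied into the carrier species (each copied residue independently
#' corrupted with probability `background_rate`); non-carriers keep their
#' random background at those columns.
#'
#' @param spec a [motif_spec()].
#' @return A list with `msa` (an [msa_block()] with the spec's partition)
#'   and `truth`, a data.frame of planted motifs (`start` 0-based, `length`,
#'   `consensus`, `carriers`).
#' @export
gen_msa_with_motifs <- function(spec) {
  stopifnot(inherits(spec, "motif_spec"))
  ns <- length(spec$species)
  with_seed(spec$seed, {
    m <- matrix(sample(AA_ALPHABET, ns * spec$n_columns, replace = TRUE),
                nrow = ns, dimnames = list(spec$species, NULL))
    truth <- list()
    for (mo in spec$motifs) {
      res <- strsplit(mo$residues, "")[[1]]
      cols <- mo$start + seq_along(res)
      for (sp in mo$carriers) {
        planted <- res
        if (spec$background_rate > 0) {
          corrupt <- runif(length(res)) < spec$background_rate
          planted[corrupt] <- sample(AA_ALPHABET, sum(corrupt), replace = TRUE)
        }
        m[sp, cols] <- planted
      }
      if (isTRUE(mo$qualifies))
        truth[[length(truth) + 1L]] <- data.frame(
          start = mo$start, length = nchar(mo$residues),
          consensus = mo$residues,
          carriers = paste(sort(mo$carriers), collapse = ","),
          stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(start = integer(), length = integer(), consensus = character(),
                 carriers = character(), stringsAsFactors = FALSE)
    msa <- msa_block(spec$species, apply(m, 1, paste, collapse = ""),
                     spec$lineage_partition)
    list(msa = msa, truth = truth[order(truth$start), , drop = FALSE])
  })
}
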