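# Hit classification by nearest labelled reference homeodomain and
# diagnostic residues, a neighbor-joining helper for orthology assignment,
# and a synthetic labelled reference set with realistic class structure.

HOX_CLASSES <- c("lab", "pb", "zen/Shx", "Dfd", "Scr", "ftz", "Antp",
                 "Ubx", "abdA", "AbdB")

#' Synthetic labelled homeodomain reference set
#'
#' Generates a fully synthetic stand-in for a curated panel of labelled
#' 60-residue homeodomains covering the ten classes searched for in insect
#' genomes (`lab, pb, zen/Shx, Dfd, Scr, ftz, Antp, Ubx, abdA, AbdB`). A
#' common scaffold sequence is mutated at a fixed number of class-diagnostic
#' positions per class (default 12, i.e. 20% - comparable to between-class
#' homeodomain divergence), and each class carries `n_per_class` orthologue
#' variants differing at a few positions (within-class divergence). Position
#' 10 is serine in the `zen/Shx` class and non-serine elsewhere, so the
#' classic Hox3 S10 diagnostic holds by construction.
#'
#' These are synthetic sequences for pipeline validation, not curated
#' natural homeodomains.
#'
#' @param seed integer seed.
#' @param n_per_class orthologue variants per class (default 3).
#' @param class_divergence positions mutated per class prototype (default 12).
#' @param species_divergence positions mutated per within-class variant
#'   (default 2).
#' @return A data.frame with columns `id`, `class`, `sequence` (60-aa).
#' @export
synthetic_reference_set <- function(seed = 20140101L, n_per_class = 3L,
                                    class_divergence = 12L,
                                    species_divergence = 2L) {
  with_seed(seed, {
    scaffold <- sample(AA_ALPHABET, 60, replace = TRUE)
    scaffold[10] <- "A"  # non-serine baseline; zen/Shx overrides below
    mutate_at <- function(x, pos) {
      for (p in pos) x[p] <- sample(setdiff(AA_ALPHABET, x[p]), 1L)
      x
    }
    out <- list()
    for (cl in HOX_CLASSES) {
      proto <- mutate_at(scaffold, sample(setdiff(1:60, 10), class_divergence))
      proto[10] <- if (cl == "zen/Shx") "S" else {
        if (proto[10] == "S") "A" else proto[10]
      }
      for (v in seq_len(n_per_class)) {
        var <- mutate_at(proto, sample(setdiff(1:60, 10), species_divergence))
        out[[length(out) + 1L]] <- data.frame(
          id = sprintf("%s_sp%d", gsub("/", "", cl), v),
          class = cl, sequence = paste(var, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' p-distance between two equal-length peptides
#'
#' Mismatch fraction over positions where both sequences carry a standard
#' residue (pairwise deletion of gaps/ambiguity).
#'
#' @param a,b amino-acid strings of equal length.
#' @return Numeric distance in `[0, 1]`, `NA` if no comparable positions.
#' @keywords internal
p_distance <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  ok <- va %in% AA_ALPHABET & vb %in% AA_ALPHABET
  if (!any(ok)) return(NA_real_)
  mean(va[ok] != vb[ok])
}

#' Classify homeodomain hits by nearest labelled reference
#'
#' Assigns each hit peptide the class of its nearest reference by p-distance
#' on the 60-residue homeodomain, evaluates diagnostic residue flags (serine
#' at homeodomain position 10, the classic Hox3/zen marker), and reports
#' `unknown` when the nearest distance exceeds `max_distance` or when more
#' than 10% of the peptide is ambiguous. Distance ties are broken towards
#' the class with more reference members, then lexicographically.
#'
#' @param hits a [scan_contigs()] result, or a character vector of peptides.
#' @param reference_set data.frame with columns `id`, `class`, `sequence`
#'   covering all ten classes (see [synthetic_reference_set()]).
#' @param max_distance distance ceiling above which a hit is `unknown`
#'   (default 0.6).
#' @return A data.frame with one row per hit: `peptide`, `assigned_class`,
#'   `nearest_id`, `distance`, `s10` (diagnostic serine flag), plus the hit
#'   coordinate columns when `hits` was a scan result.
#' @export
classify_hits <- function(hits, reference_set, max_distance = 0.6) {
  stopifnot(all(c("id", "class", "sequence") %in% names(reference_set)))
  missing_cls <- setdiff(HOX_CLASSES, reference_set$class)
  if (length(missing_cls))
    stop("reference set lacks class(es): ", paste(missing_cls, collapse = ", "))
  peptides <- if (is.data.frame(hits)) hits$peptide else hits
  class_size <- table(reference_set$class)

  rows <- lapply(peptides, function(pep) {
    aa <- strsplit(pep, "")[[1]]
    ambig <- mean(!aa %in% AA_ALPHABET)
    s10 <- identical(aa[10], "S")
    if (ambig > 0.1) {
      return(data.frame(peptide = pep, assigned_class = "unknown",
                        nearest_id = NA_character_, distance = NA_real_,
                        s10 = s10, stringsAsFactors = FALSE))
    }
    d <- vapply(reference_set$sequence, p_distance, numeric(1), a = pep,
                USE.NAMES = FALSE)
    dmin <- min(d, na.rm = TRUE)
    if (!is.finite(dmin) || dmin > max_distance) {
      return(data.frame(peptide = pep, assigned_class = "unknown",
                        nearest_id = NA_character_, distance = dmin,
                        s10 = s10, stringsAsFactors = FALSE))
    }
    tied <- which(abs(d - dmin) < 1e-12)
    if (length(tied) > 1L) {
      cls <- reference_set$class[tied]
      pref <- order(-as.numeric(class_size[cls]), cls)
      tied <- tied[pref[1]]
    } else tied <- tied[1]
    data.frame(peptide = pep, assigned_class = reference_set$class[tied],
               nearest_id = reference_set$id[tied], distance = dmin,
               s10 = s10, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.data.frame(hits))
    out <- cbind(hits[setdiff(names(hits), "peptide")], out)
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Validates the matrix (symmetric, zero diagonal, finite, at least three
#' taxa) and runs standard neighbor joining (via [ape::nj()]) to produce an
#' unrooted tree used for orthology assignment of candidate homeodomains.
#'
#' @param dm a symmetric numeric matrix with taxon labels as dimnames.
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distances must be finite")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  ape::nj(stats::as.dist(dm))
}

#' Six-frame homeobox hunt across an assembly
#'
#' The full search stage: builds one log-odds profile per reference class
#' (each from that class's orthologue variants), scans the contigs with
#' every profile at the given E-value analogue threshold, pools the hits,
#' collapses redundant overlapping hits (best score wins), and classifies
#' the survivors by nearest reference.
#'
#' @param contigs assembly sequences (character vector,
#'   [Biostrings::DNAStringSet], or FASTA path).
#' @param reference_set labelled homeodomain panel (data.frame `id`,
#'   `class`, `sequence`).
#' @param threshold_evalue per-scan E-value analogue cutoff (default 1e-6).
#' @param pseudocount profile pseudocount (default 0.5).
#' @return A classified hit table (see [classify_hits()]), score-descending.
#' @export
hunt_homeoboxes <- function(contigs, reference_set, threshold_evalue = 1e-6,
                            pseudocount = 0.5) {
  stopifnot(all(c("id", "class", "sequence") %in% names(reference_set)))
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  hit_list <- lapply(split(reference_set, reference_set$class), function(refs) {
    prof <- calibrate_profile(build_profile(refs$sequence, pseudocount = pseudocount))
    scan_contigs(contigs, prof, threshold_evalue = threshold_evalue)
  })
  hits <- do.call(rbind, hit_list)
  rownames(hits) <- NULL
  if (nrow(hits) == 0) {
    return(cbind(hits, data.frame(assigned_class = character(),
                                  nearest_id = character(), distance = numeric(),
                                  s10 = logical())))
  }
  hits <- dedupe_hits(hits[order(-hits$score), , drop = FALSE])
  classify_hits(hits, reference_set)
}

#' Read / write a labelled reference set as FASTA
#'
#' Headers follow `id|class`; [read_reference_fasta()] parses them back.
#'
#' @param reference_set data.frame `id`, `class`, `sequence`.
#' @param path FASTA path.
#' @return `write_reference_fasta`: invisibly `path`;
#'   `read_reference_fasta`: the data.frame.
#' @export
write_reference_fasta <- function(reference_set, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(
    reference_set$sequence, paste(reference_set$id, reference_set$class, sep = "|")))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 1),
             class = vapply(parts, `[`, character(1), 2),
             sequence = as.character(aa), stringsAsFactors = FALSE,
             row.names = NULL)
}
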