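# Alignment post-processing and lineage-aware conservation statistics:
# missing-data column filtering, the conserved-motif rule (runs of >= 3
# columns whose majority residue is shared between divergent lineages),
# invariant-site percentages, and pairwise divergence matrices.

#' Aligned protein block with a lineage partition
#'
#' @param species character vector of species names (one per row).
#' @param rows aligned protein strings of equal length; gaps `-`, missing
#'   data `X`.
#' @param lineage_partition `NULL`, or a list of two disjoint character
#'   vectors of species names marking divergent lineages (each a subset of
#'   `species`), e.g. basal moths versus butterflies.
#' @return An object of class `msa_block`.
#' @export
msa_block <- function(species, rows, lineage_partition = NULL) {
  rows <- as_seq_character(rows)
  stopifnot(length(species) == length(rows), length(rows) >= 1)
  if (length(unique(nchar(rows))) != 1L) stop("rows have unequal lengths")
  if (!is.null(lineage_partition)) {
    stopifnot(is.list(lineage_partition), length(lineage_partition) == 2L)
    g1 <- lineage_partition[[1]]; g2 <- lineage_partition[[2]]
    if (length(g1) == 0 || length(g2) == 0)
      stop("both lineage groups must be non-empty")
    if (length(intersect(g1, g2)) > 0) stop("lineage groups must be disjoint")
    if (!all(c(g1, g2) %in% species)) stop("partition members must be species")
  }
  structure(list(species = as.character(species), rows = unname(rows),
                 n_columns = nchar(rows[1]),
                 lineage_partition = lineage_partition),
            class = "msa_block")
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(m) <- msa$species
  m
}

#' Remove alignment columns with excessive missing data
#'
#' Drops every column where the fraction of gap (`-`) plus missing (`X`)
#' characters exceeds `max_missing_fraction` (strictly greater than; a
#' column at exactly the threshold is kept).
#'
#' @param msa an [msa_block()].
#' @param max_missing_fraction missing-data ceiling (default 0.5).
#' @return The filtered `msa_block`, with attribute `column_map` giving the
#'   original 1-based index of each retained column. An empty result is
#'   returned with a warning if every column is removed.
#' @export
filter_columns <- function(msa, max_missing_fraction = 0.5) {
  stopifnot(inherits(msa, "msa_block"))
  m <- msa_matrix(msa)
  missing_frac <- colMeans(m == "-" | m == "X")
  keep <- which(missing_frac <= max_missing_fraction)
  if (length(keep) == 0) warning("all columns removed by missing-data filter")
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (length(keep) == 0) rows <- rep("", length(msa$species))
  out <- msa_block(msa$species, rows, msa$lineage_partition)
  attr(out, "column_map") <- keep
  out
}

# does a single column satisfy the conservation rule? returns the qualifying
# residue (most frequent qualifying state, ties lexicographic) or NA
column_conserved_state <- function(col, species, g1, g2) {
  real <- col %in% AA_ALPHABET
  need <- ceiling(length(species) / 2)
  states <- unique(col[real])
  best <- NA_character_; best_n <- -1L
  for (s in states) {
    carriers <- species[real & col == s]
    if (length(carriers) < need) next
    if (!any(carriers %in% g1) || !any(carriers %in% g2)) next
    if (length(carriers) > best_n ||
        (length(carriers) == best_n && s < best)) {
      best <- s; best_n <- length(carriers)
    }
  }
  best
}

#' Find lineage-shared conserved motifs in an alignment
#'
#' A column qualifies when some residue state is carried by at least half
#' the species (ceiling at odd counts; gapped species stay in the
#' denominator) *and* by at least one species of each lineage group.
#' Maximal runs of three or more consecutive qualifying columns are
#' reported as conserved motifs.
#'
#' @param msa an [msa_block()] with a lineage partition.
#' @param min_length minimum motif length in columns (default 3).
#' @return A data.frame with one row per motif: `start` (0-based column),
#'   `length`, `consensus` (qualifying residue per column) and `support`
#'   (comma-separated per-column carrier counts).
#' @export
find_conserved_motifs <- function(msa, min_length = 3L) {
  stopifnot(inherits(msa, "msa_block"))
  if (is.null(msa$lineage_partition))
    stop("a lineage partition is required for motif detection")
  g1 <- msa$lineage_partition[[1]]; g2 <- msa$lineage_partition[[2]]
  m <- msa_matrix(msa)
  state <- vapply(seq_len(ncol(m)), function(j)
    column_conserved_state(m[, j], msa$species, g1, g2), character(1))
  qual <- !is.na(state)

  res <- list()
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_length) next
    idx <- starts[i]:ends[i]
    support <- vapply(idx, function(j) {
      col <- m[, j]
      sum(col == state[j] & col %in% AA_ALPHABET)
    }, integer(1))
    res[[length(res) + 1L]] <- data.frame(
      start = starts[i] - 1L, length = r$lengths[i],
      consensus = paste(state[idx], collapse = ""),
      support = paste(support, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(start = integer(), length = integer(),
                      consensus = character(), support = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Invariant-site percentage of a gapless alignment block
#'
#' The percentage of columns with a single residue state across all rows,
#' reported rounded to the nearest integer (matching the conventional
#' presentation of homeodomain conservation figures).
#'
#' @param msa an [msa_block()], or a character vector of equal-length
#'   gapless sequences.
#' @param name optional group label carried into the report.
#' @return An object of class `invariant_report`: list with `name`,
#'   `n_columns`, `n_invariant`, `percent_invariant` (integer 0-100) and
#'   `percent_exact` (unrounded).
#' @export
invariant_fraction <- function(msa, name = NA_character_) {
  if (!inherits(msa, "msa_block")) msa <- msa_block(seq_along(msa), msa)
  if (length(msa$rows) < 2) stop("at least 2 sequences are required")
  m <- msa_matrix(msa)
  if (any(m == "-" | m == "X"))
    stop("invariant_fraction expects a gapless, complete block")
  inv <- apply(m, 2, function(col) length(unique(col)) == 1L)
  pct <- 100 * sum(inv) / ncol(m)
  structure(list(name = name, n_columns = ncol(m), n_invariant = sum(inv),
                 percent_invariant = as.integer(round(pct)),
                 percent_exact = pct),
            class = "invariant_report")
}

#' @export
print.invariant_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d invariant sites (%d%%)\n",
              ifelse(is.na(x$name), "block", x$name),
              x$n_invariant, x$n_columns, x$percent_invariant))
  invisible(x)
}

#' Pairwise divergence matrix for aligned proteins
#'
#' Distances under pairwise deletion of gap/missing sites:
#' `p` is the mismatch fraction, `poisson` is `-ln(1 - p)` (infinite, with a
#' warning, at p = 1), and `jtt_ml` is the maximum-likelihood distance under
#' the empirical JTT amino-acid replacement model, found by bounded
#' one-dimensional likelihood optimisation per pair.
#'
#' @param seqs equal-length aligned protein sequences (character vector or
#'   [Biostrings::AAStringSet]).
#' @param model one of `"p"`, `"poisson"`, `"jtt_ml"`.
#' @param max_t upper bound of the ML distance search (default 20
#'   substitutions/site).
#' @return A symmetric matrix with zero diagonal and taxon dimnames.
#' @export
pairwise_distance_matrix <- function(seqs, model = c("p", "poisson", "jtt_ml"),
                                     max_t = 20) {
  model <- match.arg(model)
  seqs <- as_seq_character(seqs)
  stopifnot(length(unique(nchar(seqs))) == 1L, length(seqs) >= 2)
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a %in% AA_ALPHABET & b %in% AA_ALPHABET
    if (!any(ok)) { D[i, j] <- D[j, i] <- NA_real_; next }
    a <- a[ok]; b <- b[ok]
    d <- switch(model,
      p = mean(a != b),
      poisson = {
        p <- mean(a != b)
        if (p >= 1) { warning("saturated pair (p = 1): infinite distance"); Inf }
        else -log(1 - p)
      },
      jtt_ml = jtt_ml_distance(a, b, max_t = max_t))
    D[i, j] <- D[j, i] <- d
  }
  D
}

# eigendecomposition of the JTT rate matrix (scaled to unit expected rate),
# built from the empirical model shipped with phangorn; cached
jtt_eigen <- function() {
  je <- .lepihox_cache$jtt_eigen
  if (!is.null(je)) return(je)
  getAA <- get("getModelAA", envir = asNamespace("phangorn"))
  fetch <- function() {
    Q <- NULL; bf <- NULL
    getAA("JTT", bf = TRUE, Q = TRUE)  # assigns Q and bf into this frame
    list(Q = Q, bf = bf)
  }
  md <- fetch()
  s <- md$Q          # 190 lower-triangle exchangeabilities
  bf <- as.numeric(md$bf)
  aa_order <- toupper(names(md$bf))
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- s
  S <- S + t(S)
  Q <- S * rep(bf, each = 20)      # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q <- Q / mu
  # symmetrise for a stable eigendecomposition: B = D^{1/2} Q D^{-1/2}
  d <- sqrt(bf)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  je <- list(values = e$values,
             left = e$vectors * rep(1 / d, times = 20),   # D^{-1/2} U
             right = t(e$vectors) * rep(d, each = 20),    # U' D^{1/2}
             bf = bf, aa = aa_order)
  .lepihox_cache$jtt_eigen <- je
  je
}

jtt_pmatrix <- function(t) {
  je <- jtt_eigen()
  P <- je$left %*% (exp(je$values * t) * je$right)
  P[P < 1e-300] <- 1e-300
  P
}

jtt_ml_distance <- function(a, b, max_t = 20, tol = 1e-6) {
  je <- jtt_eigen()
  ia <- match(a, je$aa); ib <- match(b, je$aa)
  pat <- table(paste(ia, ib))
  key <- strsplit(names(pat), " ")
  i_idx <- as.integer(vapply(key, `[`, character(1), 1))
  j_idx <- as.integer(vapply(key, `[`, character(1), 2))
  w <- as.numeric(pat)
  if (all(i_idx == j_idx)) return(0)
  nll <- function(t) {
    P <- jtt_pmatrix(t)
    -sum(w * log(je$bf[i_idx] * P[cbind(i_idx, j_idx)]))
  }
  optimize(nll, c(1e-8, max_t), tol = tol)$minimum
}

#' Write conserved motifs as a GFF-like TSV
#' @param motifs a [find_conserved_motifs()] result.
#' @param path output path (0-based `start` column preserved).
#' @return Invisibly, `path`.
#' @export
write_motifs_tsv <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
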