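# Codon-alignment simulator under a GY94-style model: Markov substitution
# over the 61 sense codons with transition/transversion ratio kappa and a
# per-branch nonsynonymous/synonymous rate ratio omega. Used as ground truth
# for the counting dN/dS estimator.

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# symmetric GY94 generator pieces, cached: per-codon-pair difference info
codon_pair_info <- function() {
  info <- .lepihox_cache$codon_pair_info
  if (!is.null(info)) return(info)
  cod <- sense_codons()
  n <- length(cod)
  gc <- genetic_code()
  aa <- gc[cod]
  mat <- do.call(rbind, strsplit(cod, ""))
  one_diff <- matrix(FALSE, n, n)
  is_transition <- matrix(FALSE, n, n)
  is_nonsyn <- matrix(FALSE, n, n)
  ti_pairs <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- which(mat[i, ] != mat[j, ])
    if (length(d) == 1L) {
      one_diff[i, j] <- one_diff[j, i] <- TRUE
      pair <- paste0(mat[i, d], mat[j, d])
      ti <- isTRUE(ti_pairs[pair])
      is_transition[i, j] <- is_transition[j, i] <- ti
      is_nonsyn[i, j] <- is_nonsyn[j, i] <- (aa[i] != aa[j])
    }
  }
  info <- list(codons = cod, one_diff = one_diff,
               is_transition = is_transition, is_nonsyn = is_nonsyn)
  .lepihox_cache$codon_pair_info <- info
  info
}

# 61x61 transition probability matrix exp(Q t) for given omega/kappa; Q is
# scaled to one expected substitution per codon per unit branch length and is
# symmetric under uniform codon frequencies, so eigen() is exact.
codon_pmatrix <- function(t, omega, kappa = 2) {
  info <- codon_pair_info()
  n <- length(info$codons)
  Q <- matrix(0, n, n)
  Q[info$one_diff] <- 1
  Q[info$one_diff & info$is_transition] <- kappa
  Q[info$one_diff & info$is_nonsyn] <- Q[info$one_diff & info$is_nonsyn] * omega
  Q <- Q / n  # uniform stationary frequencies
  diag(Q) <- -rowSums(Q)
  mu <- -sum(diag(Q)) / n
  if (mu <= 0) return(diag(n))  # omega = 0 with kappa = 0 edge case
  Q <- Q / mu
  e <- eigen(Q, symmetric = TRUE)
  P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Specify a synthetic codon alignment
#'
#' @param tree an [ape::phylo] rooted binary tree with branch lengths in
#'   expected substitutions per codon.
#' @param omega nonsynonymous/synonymous rate ratio: a single value applied to
#'   every branch, or a vector with one value per row of `tree$edge`.
#' @param codon_count number of codon sites to simulate.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param seed integer seed.
#' @return An object of class `codon_spec`.
#' @export
codon_spec <- function(tree, omega, codon_count, kappa = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ne <- nrow(tree$edge)
  if (length(omega) == 1L) omega <- rep(omega, ne)
  stopifnot(length(omega) == ne, all(omega >= 0), codon_count >= 1, kappa >= 0)
  structure(list(tree = tree, omega = omega, codon_count = as.integer(codon_count),
                 kappa = kappa, seed = as.integer(seed)),
            class = "codon_spec")
}

#' Simulate a codon alignment on a tree
#'
#' Evolves `codon_count` sites independently along the tree under the
#' GY94-style model of [codon_spec()], starting from a uniform-random root
#' sequence over the 61 sense codons. Stop codons are never emitted.
#'
#' @param spec a [codon_spec()].
#' @return A list with `alignment` (named character vector of in-frame
#'   nucleotide strings, one per tip), `root` (root nucleotide string),
#'   `omega` (true per-branch values) and `tree`.
#' @export
gen_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "codon_spec"))
  info <- codon_pair_info()
  cod <- info$codons
  n_state <- length(cod)
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  edge_omega <- spec$omega[match(paste(tree$edge[, 1], tree$edge[, 2]),
                                 paste(spec$tree$edge[, 1], spec$tree$edge[, 2]))]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  with_seed(spec$seed, {
    states <- matrix(NA_integer_, nnode, spec$codon_count)
    states[root, ] <- sample.int(n_state, spec$codon_count, replace = TRUE)
    pcache <- new.env(parent = emptyenv())
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]; w <- edge_omega[e]
      key <- paste(signif(t_e, 12), signif(w, 12))
      P <- pcache[[key]]
      if (is.null(P)) {
        P <- if (t_e == 0) diag(n_state) else codon_pmatrix(t_e, w, spec$kappa)
        pcache[[key]] <- P
      }
      ps <- states[par, ]
      cs <- integer(spec$codon_count)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(n_state, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[child, ] <- cs
    }
    aln <- vapply(seq_len(ntip), function(i)
      paste(cod[states[i, ]], collapse = ""), character(1))
    names(aln) <- tree$tip.label
    list(alignment = aln,
         root = paste(cod[states[root, ]], collapse = ""),
         omega = spec$omega, tree = spec$tree)
  })
}
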