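# Counting-based dN/dS: the Nei-Gojobori (1986) pathway estimator with
# Jukes-Cantor correction, pairwise and with count pooling across taxon
# groups, plus a codon-column bootstrap for group-level confidence
# intervals. Chosen over ML codon models for transparency: every number is
# reproducible by explicit enumeration.

all_codons <- function() {
  cache <- .lepihox_cache$all_codons
  if (is.null(cache)) {
    cache <- names(genetic_code())
    .lepihox_cache$all_codons <- cache
  }
  cache
}

# expected synonymous site count per codon: at each position, the fraction
# of the three possible changes that are synonymous; changes to stop codons
# count as nonsynonymous so that syn + nonsyn sites = 3 per codon
ng86_site_table <- function() {
  tab <- .lepihox_cache$ng86_sites
  if (!is.null(tab)) return(tab)
  gc <- genetic_code()
  cods <- all_codons()
  syn <- numeric(64)
  for (ci in seq_len(64)) {
    cod <- strsplit(cods[ci], "")[[1]]
    aa <- gc[cods[ci]]
    s <- 0
    for (p in 1:3) for (b in setdiff(DNA_BASES, cod[p])) {
      alt <- cod; alt[p] <- b
      alt_aa <- gc[paste(alt, collapse = "")]
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
    syn[ci] <- s
  }
  tab <- list(syn = syn, nonsyn = 3 - syn)
  .lepihox_cache$ng86_sites <- tab
  tab
}

# observed synonymous/nonsynonymous differences for every codon pair,
# averaged with equal weights over all shortest mutational pathways;
# pathways through stop codons are excluded (all-pathway fallback, with
# stop-involving steps counted nonsynonymous, if every pathway is blocked)
ng86_pathway_tables <- function() {
  tabs <- .lepihox_cache$ng86_paths
  if (!is.null(tabs)) return(tabs)
  gc <- genetic_code()
  cods <- all_codons()
  ND <- matrix(0, 64, 64)
  SD <- matrix(0, 64, 64)
  split_cods <- strsplit(cods, "")
  for (i in seq_len(64)) for (j in seq_len(64)) {
    if (i == j) next
    a <- split_cods[[i]]; b <- split_cods[[j]]
    diffpos <- which(a != b)
    paths <- enumerate_pathways(a, b, diffpos, gc)
    ND[i, j] <- paths$nd
    SD[i, j] <- paths$sd
  }
  tabs <- list(ND = ND, SD = SD)
  .lepihox_cache$ng86_paths <- tabs
  tabs
}

enumerate_pathways <- function(a, b, diffpos, gc) {
  orders <- perms(diffpos)
  step_counts <- function(ord, allow_stops) {
    cur <- a; nd <- 0; sd <- 0
    for (p in ord) {
      prev <- cur
      cur[p] <- b[p]
      aa1 <- gc[paste(prev, collapse = "")]
      aa2 <- gc[paste(cur, collapse = "")]
      if (aa1 == "*" || aa2 == "*") {
        if (!allow_stops) return(NULL)
        nd <- nd + 1          # stop-involving step counted nonsynonymous
      } else if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd, sd)
  }
  res <- lapply(orders, step_counts, allow_stops = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) res <- lapply(orders, step_counts, allow_stops = TRUE)
  m <- do.call(rbind, res)
  list(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Validate an in-frame codon alignment
#'
#' Checks that every row's length is divisible by three, trims terminal
#' stop codons, replaces partially gapped or ambiguous codons with the gap
#' codon `---`, and rejects rows containing internal stop codons.
#'
#' @param aln named character vector of nucleotide strings (or a
#'   [Biostrings::DNAStringSet] / alignment file content coerced to one).
#' @return An object of class `codon_alignment`: named character vector of
#'   cleaned rows with attribute `n_codons`.
#' @export
validate_codon_alignment <- function(aln) {
  rows <- as_seq_character(aln)
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("rows have unequal lengths")
  if (lens[1] %% 3L != 0L) stop("alignment length not divisible by 3")
  nc <- unname(lens[1] %/% 3L)
  gc <- genetic_code()
  for (r in seq_along(rows)) {
    codons <- substring(rows[r], seq(1L, lens[1], 3L), seq(3L, lens[1], 3L))
    clean <- !grepl("[^ACGT]", codons)
    partial_gap <- grepl("-", codons) & codons != "---"
    if (any(partial_gap | (!clean & codons != "---")))
      warning("row '", names(rows)[r],
              "': partially gapped/ambiguous codon(s) replaced by ---")
    codons[!clean] <- "---"
    aa <- ifelse(codons == "---", "-", unname(gc[codons]))
    stops <- which(aa == "*")
    if (length(stops)) {
      if (max(stops) == nc && length(stops) == 1L) {
        codons[nc] <- "---"  # terminal stop trimmed
      } else {
        stop("internal stop codon in row '", names(rows)[r],
             "' at codon ", stops[1])
      }
    }
    rows[r] <- paste(codons, collapse = "")
  }
  structure(rows, n_codons = nc, class = "codon_alignment")
}

# per-codon NG86 contributions for one pair of rows; NA-safe via
# comparability mask. Returns vectors over codon positions.
ng86_percodon <- function(ia, ib) {
  st <- ng86_site_table()
  pt <- ng86_pathway_tables()
  ok <- !is.na(ia) & !is.na(ib)
  n <- length(ia)
  out <- list(nd = numeric(n), sd = numeric(n),
              nsites = numeric(n), ssites = numeric(n), compared = ok)
  if (any(ok)) {
    out$nd[ok] <- pt$ND[cbind(ia[ok], ib[ok])]
    out$sd[ok] <- pt$SD[cbind(ia[ok], ib[ok])]
    out$ssites[ok] <- (st$syn[ia[ok]] + st$syn[ib[ok]]) / 2
    out$nsites[ok] <- (st$nonsyn[ia[ok]] + st$nonsyn[ib[ok]]) / 2
  }
  out
}

codon_indices <- function(row) {
  n <- nchar(row)
  codons <- substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
  idx <- match(codons, all_codons())
  gc <- genetic_code()
  idx[!is.na(idx) & gc[codons] == "*"] <- NA_integer_
  idx
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (4 * p / 3 >= 1) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

summarise_counts <- function(Nd, Sd, Nsites, Ssites) {
  pN <- if (Nsites > 0) Nd / Nsites else NA_real_
  pS <- if (Ssites > 0) Sd / Ssites else NA_real_
  dN <- jc_correct(pN); dS <- jc_correct(pS)
  saturated <- (!is.na(pN) && 4 * pN / 3 >= 1) || (!is.na(pS) && 4 * pS / 3 >= 1)
  undefined <- is.na(dS) || dS == 0
  omega <- if (!undefined && !is.na(dN)) dN / dS else NA_real_
  list(N_sites = Nsites, S_sites = Ssites, Nd = Nd, Sd = Sd,
       pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
       undefined = undefined, saturated = saturated)
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts expected synonymous and nonsynonymous sites (averaged over the
#' pair), apportions observed differences over all shortest mutational
#' pathways with equal weights (pathways through stop codons excluded), and
#' applies the Jukes-Cantor correction `d = -3/4 ln(1 - 4p/3)` to the
#' proportions. Gap and ambiguous codons are pairwise-deleted.
#'
#' @param row_i,row_j in-frame nucleotide strings of equal length, or a
#'   `codon_alignment` plus two taxon names.
#' @return An object of class `omega_estimate`: list with `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`,
#'   `undefined` (dS is zero or unestimable) and `saturated` flags.
#' @export
ng86_pairwise <- function(row_i, row_j) {
  if (nchar(row_i) != nchar(row_j)) stop("rows have unequal lengths")
  ia <- codon_indices(toupper(row_i))
  ib <- codon_indices(toupper(row_j))
  pc <- ng86_percodon(ia, ib)
  out <- summarise_counts(sum(pc$nd), sum(pc$sd), sum(pc$nsites), sum(pc$ssites))
  out$n_codons_compared <- sum(pc$compared)
  structure(out, class = "omega_estimate")
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat(sprintf("NG86: dN = %.4f  dS = %.4f  omega = %s  (N = %.1f, S = %.1f)\n",
              x$dN, x$dS,
              if (x$undefined) "undefined" else sprintf("%.4f", x$omega),
              x$N_sites, x$S_sites))
  invisible(x)
}

#' Group-wise pooled dN/dS with bootstrap confidence intervals
#'
#' For each taxon group, sums NG86 site and difference counts over all
#' within-group pairs before taking ratios (count pooling), applies the
#' Jukes-Cantor correction, and attaches a percentile bootstrap confidence
#' interval obtained by resampling codon columns (preserving codon
#' structure).
#'
#' @param aln a [validate_codon_alignment()] result or named character
#'   vector of in-frame rows.
#' @param scheme named list of character vectors of taxon names; groups
#'   must be disjoint and have at least two taxa each.
#' @param boot bootstrap replicates (default 200); 0 disables the CI.
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return A data.frame with one row per group: `group`, `n_taxa`, `Nd`,
#'   `Sd`, `N_sites`, `S_sites`, `dN`, `dS`, `omega`, `omega_lo`,
#'   `omega_hi`, `undefined`.
#' @export
group_omega <- function(aln, scheme, boot = 200L, seed = 1L, conf = 0.95) {
  if (!inherits(aln, "codon_alignment")) aln <- validate_codon_alignment(aln)
  stopifnot(is.list(scheme), length(names(scheme)) == length(scheme))
  all_members <- unlist(scheme)
  if (anyDuplicated(all_members)) stop("groups must be disjoint")
  if (!all(all_members %in% names(aln)))
    stop("scheme names missing from alignment: ",
         paste(setdiff(all_members, names(aln)), collapse = ", "))
  idx_cache <- lapply(aln, codon_indices)

  res <- lapply(names(scheme), function(gname) {
    taxa <- scheme[[gname]]
    if (length(taxa) < 2) stop("group '", gname, "' has fewer than 2 taxa")
    nc <- attr(aln, "n_codons")
    nd_c <- sd_c <- ns_c <- ss_c <- numeric(nc)
    prs <- utils::combn(taxa, 2, simplify = FALSE)
    for (pr in prs) {
      pc <- ng86_percodon(idx_cache[[pr[1]]], idx_cache[[pr[2]]])
      nd_c <- nd_c + pc$nd; sd_c <- sd_c + pc$sd
      ns_c <- ns_c + pc$nsites; ss_c <- ss_c + pc$ssites
    }
    s <- summarise_counts(sum(nd_c), sum(sd_c), sum(ns_c), sum(ss_c))
    ci <- c(NA_real_, NA_real_)
    if (boot > 0) {
      om <- with_seed(seed, vapply(seq_len(boot), function(b) {
        cols <- sample.int(nc, nc, replace = TRUE)
        sb <- summarise_counts(sum(nd_c[cols]), sum(sd_c[cols]),
                               sum(ns_c[cols]), sum(ss_c[cols]))
        if (isTRUE(sb$undefined)) NA_real_ else sb$omega
      }, numeric(1)))
      if (any(!is.na(om)))
        ci <- unname(quantile(om, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              na.rm = TRUE))
    }
    data.frame(group = gname, n_taxa = length(taxa),
               Nd = s$Nd, Sd = s$Sd, N_sites = s$N_sites, S_sites = s$S_sites,
               dN = s$dN, dS = s$dS, omega = s$omega,
               omega_lo = ci[1], omega_hi = ci[2],
               undefined = s$undefined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
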