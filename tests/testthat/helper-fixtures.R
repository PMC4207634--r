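# Shared fixtures and independent oracles used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
BASES <- c("A", "C", "G", "T")

# one representative 60-aa reference per class, planted-gene table builder
planted_gene_table <- function(refs, positions, strands) {
  picks <- do.call(rbind, lapply(split(refs, refs$class), function(d) d[1, ]))
  stopifnot(length(positions) == nrow(picks), length(strands) == nrow(picks))
  data.frame(name = picks$id, protein = picks$sequence,
             position = positions, strand = strands,
             stringsAsFactors = FALSE)
}

# independent brute-force NG86 oracle: recomputes site counts and pathway
# averages from first principles, without the package's cached tables
oracle_ng86 <- function(c1, c2) {
  gcode <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(gcode[cod])
  site_syn <- function(cod) {
    v <- strsplit(cod, "")[[1]]
    aa <- translate1(cod)
    s <- 0
    for (p in 1:3) for (b in setdiff(BASES, v[p])) {
      alt <- v; alt[p] <- b
      alt_aa <- translate1(paste(alt, collapse = ""))
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
    s
  }
  perms_of <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (r in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], r)
    out
  }
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (length(dpos) == 0) {
    nd <- 0; sd <- 0
  } else {
    walk <- function(ord, allow) {
      cur <- a; nd <- 0; sd <- 0
      for (p in ord) {
        prev <- paste(cur, collapse = ""); cur[p] <- b[p]
        aa1 <- translate1(prev); aa2 <- translate1(paste(cur, collapse = ""))
        if (aa1 == "*" || aa2 == "*") {
          if (!allow) return(NULL)
          nd <- nd + 1
        } else if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      }
      c(nd, sd)
    }
    res <- Filter(Negate(is.null), lapply(perms_of(dpos), walk, allow = FALSE))
    if (length(res) == 0) res <- lapply(perms_of(dpos), walk, allow = TRUE)
    m <- do.call(rbind, res)
    nd <- mean(m[, 1]); sd <- mean(m[, 2])
  }
  s_sites <- (site_syn(c1) + site_syn(c2)) / 2
  list(Nd = nd, Sd = sd, S_sites = s_sites, N_sites = 3 - s_sites)
}

# independent column-wise validator of the conserved-motif rule
oracle_column_qualifies <- function(col, species, g1, g2) {
  need <- ceiling(length(species) / 2)
  for (s in unique(col[col %in% AA20])) {
    carriers <- species[col == s & col %in% AA20]
    if (length(carriers) >= need && any(carriers %in% g1) && any(carriers %in% g2))
      return(TRUE)
  }
  FALSE
}

oracle_motif_intervals <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(m) <- msa$species
  g1 <- msa$lineage_partition[[1]]; g2 <- msa$lineage_partition[[2]]
  q <- vapply(seq_len(ncol(m)), function(j)
    oracle_column_qualifies(m[, j], msa$species, g1, g2), logical(1))
  r <- rle(q)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= 3)
  data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
}

# exhaustive enumeration of all DNA sequences of length L (L small)
all_dna <- function(L) {
  g <- do.call(expand.grid, rep(list(BASES), L))
  apply(g[, L:1, drop = FALSE], 1, paste, collapse = "")
}
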