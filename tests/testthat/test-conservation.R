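# Column filtering, the lineage-aware motif rule, invariant sites,
# divergence matrices.

panel_msa <- function(rows, partition = NULL) {
  sp <- paste0("sp", seq_along(rows))
  if (is.null(partition)) partition <- list(sp[1:2], sp[3:length(rows)])
  msa_block(sp, rows, partition)
}

test_that("filter_columns removes only columns above the missing threshold", {
  # gapless alignment unchanged
  m0 <- panel_msa(c("ABCD", "ABCD", "ABCD", "ABCD"))
  f0 <- filter_columns(m0)
  expect_equal(f0$rows, m0$rows)
  expect_equal(attr(f0, "column_map"), 1:4)

  # 4 species: 3 gaps (0.75 > 0.5) removed, 2 gaps (0.5, not >) kept
  m <- panel_msa(c("A-CD", "A-CD", "A-CD", "AACD"))
  f <- filter_columns(m)
  expect_equal(attr(f, "column_map"), c(1, 3, 4))
  m2 <- panel_msa(c("A-CD", "A-CD", "AACD", "AACD"))
  f2 <- filter_columns(m2)
  expect_equal(attr(f2, "column_map"), 1:4)

  # X counts as missing too
  mx <- panel_msa(c("AXCD", "AXCD", "A-CD", "AACD"))
  expect_equal(attr(filter_columns(mx), "column_map"), c(1, 3, 4))

  expect_warning(filter_columns(panel_msa(c("--", "--", "--", "AA"))), "removed")
})

test_that("motif rule enforces run length, majority and lineage sharing", {
  sp <- default_species_panel()
  # planted YSP in all species: exactly one motif recovered
  out <- gen_msa_with_motifs(motif_spec(
    motifs = list(list(start = 20, residues = "YSP", carriers = sp$species)),
    seed = 5))
  got <- find_conserved_motifs(out$msa)
  expect_equal(got$start, 20)
  expect_equal(got$consensus, "YSP")

  # run of exactly 2 qualifying columns is not a motif
  rows <- c("AAQW", "AAQW", "AAQW", "AAQW", "CCQW", "GGQW", "HHQW")
  msa2 <- msa_block(sp$species, rows, sp$lineage_partition)
  # columns 3-4 qualify in all species, columns 1-2 only in 4/7 species
  # (>= ceil(7/2) = 4) -> run of 4... make columns 1-2 non-qualifying:
  rows <- c("ADQW", "DAQW", "ADQW", "DAQW", "CCQW", "GGQW", "HHQW")
  msa2 <- msa_block(sp$species, rows, sp$lineage_partition)
  expect_equal(nrow(find_conserved_motifs(msa2)), 0)

  # motif carried by exactly half the species incl. one per lineage counts
  half <- c("Hepialus", "Cameraria", "Plutella", "Heliconius")  # 4 of 7
  outh <- gen_msa_with_motifs(motif_spec(
    motifs = list(list(start = 10, residues = "WWWW", carriers = half)),
    seed = 6))
  expect_equal(nrow(outh$truth), 1)
  goth <- find_conserved_motifs(outh$msa)
  expect_true(any(goth$start <= 10 & goth$start + goth$length >= 14))

  # motif confined to one lineage group is excluded from truth and must
  # not be detected
  onelin <- c("Heliconius", "Polygonia", "Pararge", "Callimorpha")
  expect_error(motif_spec(
    motifs = list(list(start = 10, residues = "WWWW", carriers = onelin)),
    seed = 7), "lineage")
  outo <- gen_msa_with_motifs(motif_spec(
    motifs = list(list(start = 10, residues = "WWWW", carriers = onelin)),
    seed = 7, strict = FALSE))
  expect_equal(nrow(outo$truth), 0)
  goto <- find_conserved_motifs(outo$msa)
  expect_false(any(goto$start <= 13 & goto$start + goto$length > 10))
})

test_that("motif detection is invariant to row order and partition swap", {
  sp <- default_species_panel()
  out <- gen_msa_with_motifs(motif_spec(
    motifs = list(list(start = 30, residues = "PNG", carriers = sp$species[c(1, 3, 5, 6)])),
    seed = 8))
  base <- find_conserved_motifs(out$msa)

  perm <- sample(length(out$msa$species))
  shuffled <- msa_block(out$msa$species[perm], out$msa$rows[perm],
                        out$msa$lineage_partition)
  expect_equal(find_conserved_motifs(shuffled), base)

  swapped <- msa_block(out$msa$species, out$msa$rows,
                       rev(out$msa$lineage_partition))
  expect_equal(find_conserved_motifs(swapped), base)
})

test_that("planted motifs are recovered with perfect precision and recall", {
  sp <- default_species_panel()
  for (s in 1:50) {
    set.seed(s)
    n_m <- sample(1:3, 1)
    starts <- sort(sample(seq(0, 70, by = 12), n_m))
    motifs <- lapply(starts, function(st) {
      len <- sample(3:5, 1)
      carriers <- unique(c(sample(sp$lineage_partition[[1]], 1),
                           sample(sp$lineage_partition[[2]], 1),
                           sample(sp$species, 3)))
      list(start = st, residues = paste(sample(AA20, len, replace = TRUE),
                                        collapse = ""),
           carriers = if (length(carriers) >= 4) carriers else
             unique(c(carriers, sp$species[1:2], sp$species[4])))
    })
    out <- gen_msa_with_motifs(motif_spec(motifs = motifs, seed = 100 + s))
    got <- find_conserved_motifs(out$msa)
    orc <- oracle_motif_intervals(out$msa)
    # detector agrees with the independent column-wise oracle exactly
    expect_equal(got$start, orc$start)
    expect_equal(got$length, orc$length)
    # every planted motif interval is covered by a detected motif
    for (i in seq_len(nrow(out$truth))) {
      tr <- out$truth[i, ]
      expect_true(any(got$start <= tr$start &
                        got$start + got$length >= tr$start + tr$length),
                  info = paste("seed", s))
    }
    # every detected column really qualifies (precision at column level)
    m <- do.call(rbind, strsplit(out$msa$rows, ""))
    rownames(m) <- out$msa$species
    for (i in seq_len(nrow(got))) {
      for (j in (got$start[i] + 1):(got$start[i] + got$length[i])) {
        expect_true(oracle_column_qualifies(m[, j], out$msa$species,
                                            out$msa$lineage_partition[[1]],
                                            out$msa$lineage_partition[[2]]))
      }
    }
  }
})

test_that("invariant fractions and their rounding match direct arithmetic", {
  expect_equal(invariant_fraction(c("AAAA", "AAAA"))$percent_invariant, 100L)
  # 60 columns, 50 invariant -> 83%
  set.seed(3)
  base <- sample(AA20, 60, replace = TRUE)
  v <- base
  pos <- sample(60, 10)
  for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
  rep <- invariant_fraction(c(paste(base, collapse = ""), paste(v, collapse = "")))
  expect_equal(rep$n_invariant, 50)
  expect_equal(rep$percent_invariant, 83L)
  expect_error(invariant_fraction("AAAA"), "2 sequences")
  expect_error(invariant_fraction(c("A-AA", "AAAA")), "gapless")
})

test_that("distance models: identity, poisson formula, JTT recovery", {
  seqs <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  for (m in c("p", "poisson", "jtt_ml"))
    expect_equal(unname(pairwise_distance_matrix(seqs, m)[1, 2]), 0)

  # p = 0.1 -> poisson distance -ln(0.9) = 0.10536
  set.seed(4)
  s1 <- sample(AA20, 200, replace = TRUE)
  s2 <- s1; idx <- sample(200, 20)
  for (p in idx) s2[p] <- sample(setdiff(AA20, s1[p]), 1)
  pair <- c(a = paste(s1, collapse = ""), b = paste(s2, collapse = ""))
  expect_equal(unname(pairwise_distance_matrix(pair, "p")[1, 2]), 0.1)
  expect_equal(unname(pairwise_distance_matrix(pair, "poisson")[1, 2]),
               -log(0.9), tolerance = 1e-9)

  # saturation under poisson
  sat <- c(a = strrep("A", 5), b = strrep("C", 5))
  expect_warning(d <- pairwise_distance_matrix(sat, "poisson"), "saturated")
  expect_true(is.infinite(d[1, 2]))

  # gaps are pairwise-deleted
  gap <- c(a = "AC-EF", b = "ACDEF")
  expect_equal(unname(pairwise_distance_matrix(gap, "p")[1, 2]), 0)
})

test_that("JTT ML distance recovers simulated divergence and matches phangorn", {
  # simulate a pair at distance 0.5 under the JTT chain itself
  je <- lepihox:::jtt_eigen()
  P <- lepihox:::jtt_pmatrix(0.5)
  set.seed(19)
  n <- 10000
  anc <- sample.int(20, n, replace = TRUE, prob = je$bf)
  der <- vapply(anc, function(i) sample.int(20, 1, prob = P[i, ]), integer(1))
  pair <- c(a = paste(je$aa[anc], collapse = ""),
            b = paste(je$aa[der], collapse = ""))
  d <- pairwise_distance_matrix(pair, "jtt_ml")[1, 2]
  expect_lt(abs(d - 0.5), 0.05)

  # independent implementation agreement
  pd <- phangorn::phyDat(do.call(rbind, strsplit(unname(pair), "")), type = "AA")
  ph <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
  expect_equal(unname(d), unname(ph), tolerance = 1e-3)
})

test_that("filtering then invariant scoring commutes with dropping all-gap rows", {
  rows <- c("AAC-A", "AAC-A", "AACCA", "-----")
  sp <- paste0("s", 1:4)
  msa <- msa_block(sp, rows, list(sp[1:2], sp[3]))
  with_gap_row <- filter_columns(msa)
  kept <- msa_block(sp[1:3], rows[1:3], list(sp[1:2], sp[3]))
  without <- filter_columns(kept)
  a <- invariant_fraction(msa_block(sp[1:3], with_gap_row$rows[1:3]))
  b <- invariant_fraction(without)
  expect_equal(a$percent_invariant, b$percent_invariant)
})
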