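# Codon simulator and the NG86 counting estimator.

test_that("codon simulator respects degenerate settings", {
  # zero branch lengths: leaves identical to root
  tr <- ape::read.tree(text = "(a:0,b:0);")
  sim <- gen_codon_alignment(codon_spec(tr, omega = 1, codon_count = 50, seed = 2))
  expect_identical(sim$alignment[["a"]], sim$root)
  expect_identical(sim$alignment[["b"]], sim$root)

  # omega = 0 on long branches: every substitution event is synonymous,
  # so each leaf translates to exactly the root protein (NG86's pathway
  # averaging can still apportion fractional nonsynonymous steps to
  # multi-hit codons, so the clean invariant is at the protein level)
  tr2 <- ape::read.tree(text = "(a:1.5,b:1.5);")
  sim2 <- gen_codon_alignment(codon_spec(tr2, omega = 0, codon_count = 300, seed = 3))
  root_prot <- lepihox:::translate_nt(sim2$root)
  expect_identical(lepihox:::translate_nt(sim2$alignment[["a"]]), root_prot)
  expect_identical(lepihox:::translate_nt(sim2$alignment[["b"]]), root_prot)
  est <- ng86_pairwise(sim2$alignment[["a"]], sim2$alignment[["b"]])
  expect_gt(est$Sd, 0)
  # synonymous divergence dominates (dS itself saturates at these branch
  # lengths, so compare raw proportions)
  expect_lt(est$pN, est$pS / 5)

  # no stop codons ever
  gc <- Biostrings::GENETIC_CODE
  for (row in sim2$alignment) {
    codons <- substring(row, seq(1, nchar(row), 3), seq(3, nchar(row), 3))
    expect_false(any(gc[codons] == "*"))
  }

  expect_error(codon_spec(tr2, omega = -1, codon_count = 10), "omega")
  expect_error(codon_spec(tr2, omega = 1, codon_count = 0), "codon_count")
})

test_that("NG86 is consistent for neutral evolution at large n", {
  # kappa = 1 so the generating model matches NG86's equal-rate site
  # counting; estimator should recover omega = 1 within 0.1
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  sim <- gen_codon_alignment(codon_spec(tr, omega = 1, codon_count = 10000,
                                        kappa = 1, seed = 10))
  est <- ng86_pairwise(sim$alignment[["a"]], sim$alignment[["b"]])
  expect_lt(abs(est$omega - 1), 0.1)
})

test_that("NG86 pairwise equals brute-force pathway enumeration", {
  # every codon pair with <= 2 differences, checked against the
  # independent oracle in helper-fixtures.R
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(6)
  pairs <- expand.grid(a = sense, b = sense, stringsAsFactors = FALSE)
  ndiff <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), pairs$a, pairs$b)
  pairs <- pairs[ndiff >= 1 & ndiff <= 2, ]
  # exhaustive over all (hundreds of) such pairs
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    est <- ng86_pairwise(a, b)
    orc <- oracle_ng86(a, b)
    expect_equal(est$Nd, orc$Nd, info = paste(a, b))
    expect_equal(est$Sd, orc$Sd, info = paste(a, b))
    expect_equal(est$N_sites, orc$N_sites, info = paste(a, b))
    expect_equal(est$S_sites, orc$S_sites, info = paste(a, b))
  }
})

test_that("NG86 basics: identity, single changes, symmetry, conservation", {
  x <- strrep("ATGGCT", 50)
  est <- ng86_pairwise(x, x)
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  expect_true(est$undefined)

  # one synonymous third-position change over 100 codons
  y <- x
  substr(y, 6, 6) <- "C"   # GCT -> GCC, both Ala
  est2 <- ng86_pairwise(x, y)
  expect_equal(est2$Sd, 1)
  expect_equal(est2$Nd, 0)
  expect_equal(est2$dN, 0)

  # the classic two-difference pair TTT <-> GTA averaged over 2 orderings
  est3 <- ng86_pairwise("TTT", "GTA")
  orc3 <- oracle_ng86("TTT", "GTA")
  expect_equal(est3$Nd, orc3$Nd)
  expect_equal(est3$Sd, orc3$Sd)

  # symmetry and site conservation on random sense-codon strings
  set.seed(8)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (r in 1:5) {
    a <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    ab <- ng86_pairwise(a, b); ba <- ng86_pairwise(b, a)
    expect_equal(ab$Nd, ba$Nd)
    expect_equal(ab$Sd, ba$Sd)
    expect_equal(ab$N_sites + ab$S_sites, 3 * 30)
  }
})

test_that("codon alignment validation trims terminal stops and flags frame errors", {
  v <- validate_codon_alignment(c(r1 = "ATGAAATAA"))
  expect_equal(unname(unclass(v)[1]), "ATGAAA---")
  expect_error(validate_codon_alignment(c(r1 = "ATGTAAAAA")), "internal stop")
  expect_error(validate_codon_alignment(c(r1 = "ATGAAAA")), "divisible")
  # gap-only codon columns preserved
  v2 <- validate_codon_alignment(c(r1 = "ATG---AAA", r2 = "ATG---AAA"))
  expect_equal(attr(v2, "n_codons"), 3L)
})

test_that("group pooling matches single pairs and conserves counts", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  sim <- gen_codon_alignment(codon_spec(tr, omega = 0.5, codon_count = 400, seed = 9))
  aln <- sim$alignment

  # two-taxon group equals the plain pairwise estimate
  go <- group_omega(aln, list(ab = c("a", "b")), boot = 0)
  pw <- ng86_pairwise(aln[["a"]], aln[["b"]])
  expect_equal(go$dN, pw$dN)
  expect_equal(go$dS, pw$dS)
  expect_equal(go$omega, pw$omega)

  # pooled counts are conserved across grouping schemes
  g1 <- group_omega(aln, list(all = c("a", "b", "c", "d")), boot = 0)
  g2 <- group_omega(aln, list(p1 = c("a", "b"), p2 = c("c", "d")), boot = 0)
  cross <- combn(c("a", "b", "c", "d"), 2, simplify = FALSE)
  in_g2 <- list(c("a", "b"), c("c", "d"))
  cross_nd <- sum(vapply(cross, function(p) {
    e <- ng86_pairwise(aln[[p[1]]], aln[[p[2]]]); e$Nd
  }, numeric(1)))
  pair_nd <- sum(vapply(in_g2, function(p) {
    e <- ng86_pairwise(aln[[p[1]]], aln[[p[2]]]); e$Nd
  }, numeric(1)))
  expect_equal(g1$Nd, cross_nd)
  expect_equal(sum(g2$Nd), pair_nd)

  # all-identical group: omega undefined
  same <- c(x = strrep("ATGGCT", 20), y = strrep("ATGGCT", 20))
  gu <- group_omega(same, list(g = c("x", "y")), boot = 0)
  expect_true(gu$undefined)
})

test_that("purifying and relaxed groups are ordered correctly", {
  tr <- ape::read.tree(text = "((a:0.15,b:0.15):0.05,(c:0.15,d:0.15):0.05);")
  ok <- 0
  for (s in 1:20) {
    pur <- gen_codon_alignment(codon_spec(tr, omega = 0.02, codon_count = 500,
                                          seed = 1000 + s))
    rel <- gen_codon_alignment(codon_spec(tr, omega = 1.0, codon_count = 500,
                                          seed = 2000 + s))
    op <- group_omega(pur$alignment, list(g = c("a", "b", "c", "d")), boot = 0)
    or <- group_omega(rel$alignment, list(g = c("a", "b", "c", "d")), boot = 0)
    if (!op$undefined && !or$undefined && op$omega < or$omega) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
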