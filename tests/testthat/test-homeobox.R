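# Profile construction, six-frame scanning, redundancy removal,
# classification and the NJ helper.

test_that("profile scores have the log-odds structure", {
  set.seed(31)
  seqs <- replicate(4, paste(sample(AA20, 60, replace = TRUE), collapse = ""))
  prof <- build_profile(seqs, pseudocount = 0.5)
  expect_equal(dim(prof$log_odds), c(20, 60))

  # large pseudocount flattens every score towards zero (background limit)
  flat <- build_profile(seqs, pseudocount = 1e6)
  expect_lt(max(abs(flat$log_odds)), 1e-3)

  # a conserved rare residue scores positive, an absent one negative
  wcol <- build_profile(strrep("W", 60), pseudocount = 0.1,
                        background = setNames(c(rep(0.99 / 19, 19), 0.01),
                                              c(setdiff(AA20, "W"), "W")))
  expect_gt(wcol$log_odds["W", 1], 0)
  expect_lt(wcol$log_odds["A", 1], 0)

  # ragged and gapped seed alignments are rejected
  expect_error(build_profile(c("AAA", "AAAA")), "ragged")
  expect_error(build_profile(c("AA-A", "AAAA")), "gapless")
})

test_that("a member sequence outscores its shuffled permutations", {
  set.seed(77)
  seqs <- replicate(5, paste(sample(AA20, 60, replace = TRUE,
                                    prob = c(rep(1, 10), rep(3, 10))), collapse = ""))
  prof <- build_profile(seqs)
  member <- seqs[1]
  s_member <- score_peptide(prof, member)
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
    expect_gte(s_member, score_peptide(prof, shuf))
  }
})

test_that("scan finds planted homeoboxes on both strands at exact coordinates", {
  refs <- synthetic_reference_set()
  zen <- refs$sequence[refs$class == "zen/Shx"][1]
  prof <- calibrate_profile(build_profile(refs$sequence[refs$class == "zen/Shx"]))

  pg <- data.frame(name = "z", protein = zen, position = 300, strand = "+")
  g <- gen_genome(genome_spec(2000, planted_genes = pg, seed = 4))
  hits <- scan_contigs(g$contigs, prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 300)
  expect_equal(hits$end, 480)
  expect_equal(hits$strand, "+")
  expect_equal(hits$end - hits$start, 3 * 60)
  expect_equal(hits$peptide, zen)

  # same gene planted on the reverse strand: minus-strand hit, same
  # forward-strand coordinates
  pgm <- data.frame(name = "z", protein = zen, position = 300, strand = "-")
  gm <- gen_genome(genome_spec(2000, planted_genes = pgm, seed = 4))
  hm <- scan_contigs(gm$contigs, prof)
  expect_equal(hm$start, 300)
  expect_equal(hm$end, 480)
  expect_equal(hm$strand, "-")
  expect_equal(hm$peptide, zen)
})

test_that("scanning a contig and its reverse complement gives mirrored hits", {
  refs <- synthetic_reference_set()
  prof <- calibrate_profile(build_profile(refs$sequence[refs$class == "Antp"]))
  pg <- data.frame(name = "a", protein = refs$sequence[refs$class == "Antp"][1],
                   position = 501, strand = "+")
  g <- gen_genome(genome_spec(1500, planted_genes = pg, seed = 6))
  fwd <- scan_contigs(g$contigs, prof)
  rc <- Biostrings::reverseComplement(g$contigs)
  names(rc) <- names(g$contigs)
  rev <- scan_contigs(rc, prof)
  expect_equal(nrow(fwd), nrow(rev))
  # forward coordinates mirror: start' = len - end
  expect_setequal(1500 - rev$end, fwd$start)
  expect_setequal(sort(fwd$peptide), sort(rev$peptide))
})

test_that("dedupe keeps the best of overlapping hits and matches brute force", {
  mk <- function(contig, start, score)
    data.frame(contig = contig, start = start, end = start + 180,
               strand = "+", frame = 0, score = score, evalue = 1e-9,
               peptide = "X", stringsAsFactors = FALSE)
  # identical intervals: best survives
  h <- rbind(mk("c1", 100, 50), mk("c1", 100, 40))
  expect_equal(dedupe_hits(h)$score, 50)
  # disjoint: both kept
  h2 <- rbind(mk("c1", 100, 50), mk("c1", 500, 40))
  expect_equal(nrow(dedupe_hits(h2)), 2)

  # staggered chains: greedy best-first vs exhaustive independent-set search
  set.seed(90)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    h3 <- do.call(rbind, lapply(seq_len(n), function(i)
      mk("c1", sample(0:400, 1), runif(1, 10, 60))))
    got <- dedupe_hits(h3)
    # brute force: greedy is defined as best-first acceptance; verify the
    # surviving set is conflict-free and no rejected hit is conflict-free
    # with respect to the survivors
    conflict <- function(a, b) {
      ov <- min(a$end, b$end) - max(a$start, b$start)
      ov > 0 && ov / 180 >= 0.5
    }
    for (i in seq_len(nrow(got))) for (j in seq_len(nrow(got)))
      if (i < j) expect_false(conflict(got[i, ], got[j, ]))
    rejected <- h3[!paste(h3$start, h3$score) %in% paste(got$start, got$score), ]
    for (i in seq_len(nrow(rejected))) {
      clash <- any(vapply(seq_len(nrow(got)), function(j)
        conflict(rejected[i, ], got[j, ]) && got$score[j] >= rejected$score[i],
        logical(1)))
      expect_true(clash)
    }
  }
})

test_that("classification recovers the class of mutated references", {
  refs <- synthetic_reference_set()
  # identical to a zen reference: distance 0, S10 flag on
  zen <- refs[refs$class == "zen/Shx", ][1, ]
  cl <- classify_hits(zen$sequence, refs)
  expect_equal(cl$assigned_class, "zen/Shx")
  expect_equal(cl$distance, 0)
  expect_true(cl$s10)

  # far from everything: unknown
  far <- strrep("W", 60)
  expect_equal(classify_hits(far, refs)$assigned_class, "unknown")

  # heavy ambiguity: unknown
  ambig <- paste0(strrep("X", 10), substr(zen$sequence, 11, 60))
  expect_equal(classify_hits(ambig, refs)$assigned_class, "unknown")

  # 10% mutation recovery, >= 95% correct over 100 replicates
  set.seed(12)
  correct <- 0; total <- 0
  for (r in 1:100) {
    row <- refs[sample(nrow(refs), 1), ]
    v <- strsplit(row$sequence, "")[[1]]
    pos <- sample(60, 6)
    for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
    got <- classify_hits(paste(v, collapse = ""), refs)$assigned_class
    total <- total + 1
    correct <- correct + (got == row$class)
  }
  expect_gte(correct / total, 0.95)
})

test_that("neighbor joining recovers additive and ultrametric topologies", {
  # 3 taxa: branch lengths solve the three-point equations exactly
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))

  # additive 4-taxon matrix: NJ recovers the generating topology
  tree4 <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  dm4 <- ape::cophenetic.phylo(tree4)
  tr4 <- ape::unroot(nj_tree(dm4))
  expect_equal(ape::dist.topo(tr4, ape::unroot(tree4))[1], 0)

  # ultrametric 5-taxon matrix
  tree5 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:2,e:2):1);")
  dm5 <- ape::cophenetic.phylo(tree5)
  tr5 <- ape::unroot(nj_tree(dm5))
  expect_equal(ape::dist.topo(tr5, ape::unroot(tree5))[1], 0)

  # invalid matrices rejected
  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
})
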