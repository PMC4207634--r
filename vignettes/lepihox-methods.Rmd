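---
title: "Methods: homeobox discovery and molecular evolution with lepihox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeobox discovery and molecular evolution with lepihox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lepihox` re-implements, as one tested toolkit, the chain of computations
used to discover and characterise fast-evolving homeobox genes (the Shx
family of ditrysian Lepidoptera being the motivating case) in low-coverage
draft genome data: genome profiling from raw reads, homeodomain hunting in
contigs, conservation and divergence statistics for the resulting protein
families, counting-based selection contrasts, and an in silico evolution
engine for preferred DNA binding sites. Every stage can be driven by the
built-in synthetic-data generators, which produce inputs with known ground
truth at desk scale.

This vignette explains the models and procedures, the tunable parameters
and their defaults, the numerical choices, and what the synthetic
validation does and does not establish about real data.

# Genome profiling from the k-mer spectrum

A shotgun read set of total length `B` sequenced from a genome of size `G`
covers each base about `C = B/G` times. Each read of length `L` contains
`L - k + 1` k-mers, so the coverage of any particular genomic k-mer is
lower than the base coverage:

$$C_k = C \cdot \frac{L - k + 1}{L}.$$

`count_kmers()` builds the spectrum (distinct k-mers per multiplicity)
exactly, with a hash-based counter limited to `k <= 31`; `find_peak()`
reads off the main peak; `kmer_to_base_coverage()` inverts the relation
above; and `estimate_genome_size()` divides total bases by coverage.
`kmer_profile()` chains the four steps.

Parameter choices:

* `k = 17` (default): long enough that random 17-mer collisions are
  negligible in genomes up to tens of Gb, short enough that an error-free
  101-bp read still contributes 85 counted k-mers.
* `canonical = TRUE`: shotgun reads sample both strands, so a k-mer and
  its reverse complement are pooled.
* `min_multiplicity = 4`: multiplicities below this form the error ramp -
  k-mers created by sequencing errors are mostly unique - and are excluded
  from peak finding.

Two systematic effects matter at the few-percent level and are handled
explicitly rather than hidden:

1. **Error thinning.** A k-mer survives error-free with probability
   `(1 - e)^k` (about 0.92 at `e = 0.005`, `k = 17`), so the observed peak
   sits at `C_k (1-e)^k`, not `C_k`. Dividing the *raw* base total by the
   peak-derived coverage would therefore inflate the genome size by
   `~(1-e)^{-k}`. `kmer_profile()` instead scales the base total by the
   fraction of k-mer mass at or above `min_multiplicity`, so numerator and
   denominator describe the same error-free k-mer population. This is the
   usual way spectra are integrated; it is exposed as
   `exclude_error_ramp = TRUE`.
2. **Mode versus mean.** The three-point quadratic refinement of the peak
   estimates the *mode* of the multiplicity distribution, which for the
   Poisson-like spectra at moderate coverage sits roughly half a unit
   below the mean. This leaves a residual upward genome-size bias of
   3-4% at 12-15x coverage; the synthetic recovery tests run with this
   bias included, and median relative error stays within 5%. A mixture
   fit would remove it, at the cost of a model the peak-reading procedure
   deliberately avoids.

The synthetic read simulator (`simulate_reads()`) models uniform fragment
sampling, Gaussian insert sizes and substitution errors only. Real
datasets add coverage biases, repeats and heterozygosity, which broaden or
split the peak; passing the synthetic tests shows the chain's arithmetic
and peak logic are right, not that every real spectrum is interpretable.
Defaults (101-bp reads, 15x coverage, 300 +/- 30 bp inserts, 0.5% error,
GC 0.35) mirror a typical HiSeq run on a lepidopteran genome.

# Homeodomain hunting in contigs

The search stage replaces an external translated-BLAST dependency with an
ungapped sliding-profile scan, preserving its detection semantics. The
homeodomain is modelled as a single gapless 60-column block - homeobox
hits in draft assemblies are single-exon at this scale - so spliced
homeoboxes are out of scope and flagged as such.

`build_profile()` turns a gapless seed alignment into per-column
log-odds scores `ln((f + c \pi) / (1 + c) / \pi)` with pseudocount
`c = 0.5` against a background `\pi` (uniform by default).
`scan_contigs()` translates all six frames and scores every 60-residue
window; windows containing stop codons are voided. Because the profile
score is not a BLAST score, the familiar E-value threshold is preserved
through an *E-value analogue*: 1000 windows drawn from the background are
scored once per profile (fixed internal seed, so calibration is
deterministic), a Gumbel distribution is fitted by moments, and each
window's expected count of equal-or-better random hits in a scan of `W`
windows is `W \cdot p(s)`. The default cutoff `1e-6` then means "fewer
than one-in-a-million random windows this good are expected per scan".
The mapping is an extrapolated tail fit, so the analogue's absolute scale
is approximate; only its ordering/threshold semantics are relied on, and
the false-positive rate is verified empirically on random sequence.

Searching is performed with one profile per reference class (mirroring
query-per-family translated searches) via `hunt_homeoboxes()`;
overlapping hits from different class profiles are collapsed by
`dedupe_hits()` (greedy best-first, redundancy at >= 50% overlap of the
shorter interval). Classification (`classify_hits()`) is
nearest-reference by p-distance on the homeodomain with a distance
ceiling of 0.6 (beyond which `unknown` is reported), plus diagnostic
residue flags - serine at homeodomain position 10, the classic marker of
Hox3-derived (zen/Shx) proteins. `nj_tree()` provides a
neighbor-joining tree from any distance matrix for orthology assignment;
full phylogenetic inference is deliberately out of scope.

The bundled reference panel (`synthetic_reference_set()`) is synthetic:
ten classes derived from a common scaffold at 20% between-class
divergence, three orthologues per class at ~3% divergence, with S10
planted only in zen/Shx. It exists so that detection, redundancy
removal and classification can be validated against known truth; analyses
of real assemblies should supply a curated panel via
`read_reference_fasta()`.

# Conservation statistics

`filter_columns()` removes alignment columns whose fraction of gap (`-`)
or missing (`X`) characters *exceeds* 0.5 (a column at exactly one half
is kept). `invariant_fraction()` reports the percentage of single-state
columns, rounded to the nearest integer as such figures are conventionally
printed.

`find_conserved_motifs()` implements a lineage-aware rule: a column
qualifies when some residue is carried by at least half the species
(ceiling at odd counts; species with a gap in the column do not count as
carriers but stay in the denominator) *and* by at least one species on
each side of a divergent-lineage partition; maximal runs of three or more
qualifying columns are motifs. Two readings of the sharing rule are
possible - per column or per whole motif; the per-column reading is
implemented because it is the stricter one and composes cleanly into
runs. The qualifying residue reported per column is the most frequent
qualifying state, ties broken alphabetically.

`pairwise_distance_matrix()` offers p-distance, Poisson distance
`-ln(1-p)`, and a maximum-likelihood distance under the empirical JTT
amino-acid replacement model, optimised per pair by bounded 1-D search
(tolerance 1e-6, search interval up to 20 substitutions/site) on the
likelihood `\sum \ln \pi_i P_{ij}(t)` with pairwise deletion of gap
sites. Saturated pairs (p = 1 under Poisson) return infinity with a
warning.

# Counting-based selection contrasts

Selection on coding sequence is summarised by `\omega = d_N/d_S`. The
package uses the Nei-Gojobori (1986) counting estimator rather than ML
codon models: expected synonymous/nonsynonymous site counts per codon
(averaged over the compared pair), observed differences apportioned
equally over all shortest mutational pathways (pathways through stop
codons excluded; in the rare case that every pathway is blocked, all
pathways are used with stop-involving steps counted nonsynonymous), and
the Jukes-Cantor correction `d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)`.
Changes that would create a stop codon are counted as nonsynonymous in
the site totals so that synonymous plus nonsynonymous sites always sum to
three per codon. Groups are compared by pooling counts over all
within-group pairs before taking ratios (`group_omega()`), with a
percentile bootstrap over codon columns (200 replicates, seeded) for
interval estimates; `dS = 0` yields an explicit `undefined` flag rather
than an infinite ratio.

A counting estimator is transparent and exactly checkable against
enumeration, but it is *not* an ML branch-model estimate: with
transition/transversion bias it mis-weights site opportunities, and at
high divergence pathway averaging assigns fractional nonsynonymous steps
even to purely synonymous histories. Printed ML `\omega` values from
branch models are therefore not comparable in absolute terms; only the
purifying-versus-relaxed *ordering* is asserted, and the simulation tests
confirm that ordering is recovered in >= 95% of seeded runs at 500
codons for `\omega` 0.02 versus 1.0.

The companion simulator (`gen_codon_alignment()`) evolves codons on a
tree under a GY94-style model (61 sense codons, transition/transversion
ratio `kappa = 2` by default, per-branch `\omega`, uniform codon
frequencies, rate matrix scaled to one expected substitution per codon
per unit branch length). Stop codons are excluded from the state space,
so they are never emitted. Transition probabilities are computed by exact
eigendecomposition (the generator is symmetric under uniform
frequencies).

# In silico evolution of binding sites

The engine evolves the DNA core presented to a homeodomain against a
pluggable energy model. The contract (`energy_score()`) is minimal:
deterministic, finite, lower-is-more-stable. Three implementations ship:

* `contact_potential_model()` - a coarse additive statistical potential:
  a contact map linking recognition-helix positions (47, 50, 51, 54) and
  N-terminal-arm positions (3, 5) to core positions, and a 20 x 4
  residue-base compatibility table encoding canonical preferences
  (Asn-A, Gln-A/T, Arg/Lys-G, hydrophobics-T). It is a test-bed
  potential: additive by construction, so exhaustive optima are
  computable, and not a predictor of in vivo sites.
* `planted_energy_model()` - Hamming distance to a known target, the
  exact oracle for engine validation.
* `function_energy_model()` - an adapter wrapping any function, including
  subprocess calls into atomic modelling/scoring backends. Structure-based
  scoring itself is out of scope; with such a backend plugged in, the
  engine runs unchanged.

One run: from each homopolymer start (poly-A/C/G/T over an 11-bp core by
default), 1000 cycles of propose-one-mutation / score / greedy accept
(accept iff the proposal's energy does not exceed the current
template's; a proposal counts as a cycle whether or not it is accepted).
Mutation changes exactly one position per cycle, drawn with weight 3 for
the nine central positions versus 1 for the two flanks - "elevated
sampling" of the inner core, quantified here as 3:1 since no ratio is
canonical. Every evaluated (sequence, energy) pair is archived, so good
states rejected by the greedy rule still reach the consensus stage. A
Metropolis temperature would be a one-line extension of the acceptance
rule; greedy (temperature zero) is the default because the archive
already preserves diversity.

`consensus_from_archives()` pools the four starts' archives,
deduplicates sequences keeping best energies, takes the 50 lowest
(lexicographic tie-break for determinism), and tabulates per-position
base probabilities with information content `2 + \sum p \log_2 p` bits.
Pooling across starts (rather than 50 per start) is the default reading;
per-start consensus is available by calling the function on a single
trace. `substitution_scan()` is the no-evolution control: each position's
four bases scored with the rest fixed; under an additive model its
position-wise argmin *is* the global optimum, which makes it a
start-bias control. `logo_export()` writes a MEME-format matrix for logo
renderers.

The template geometry follows the co-crystal convention of an 11-bp
mutable core within fixed flanks; the engine takes the core length as a
parameter (tests use length 8 so that the 4^8 space can be enumerated
exactly).

# Validation scale and limitations

The shipped tests run the whole pipeline at sizes chosen to finish in
minutes on one CPU while keeping estimator noise well below the asserted
tolerances: 1 Mb genomes at 15x coverage over 10 seeds for genome-size
recovery; 100-kb planted assemblies plus twenty 1-Mb random controls for
the homeobox hunt; 50 seeded motif alignments; 100 seeded 500-codon
alignments for the selection contrast; and 100 evolution runs at core
length 8. These sizes are the package's validation conditions, stated
here so they can be reproduced or scaled up.

Known limitations, restated: k-mer genome sizing carries the mode-bias
described above and does not decompose heterozygosity or repeats; the
homeobox scan is ungapped and single-exon; the E-value analogue's
absolute scale is an extrapolation; NG86 `\omega` is not comparable to ML
branch-model values; the built-in contact potential is a validation
surrogate for atomic scoring; and none of the synthetic generators model
real error profiles, indels, or alignment uncertainty.
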