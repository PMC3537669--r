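---
title: "Allele-specific network perturbation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific network perturbation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical model behind `aspnet`, the
assumptions it rests on, the parameters that matter, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## The setting and its assumptions

The package models a two-parent haploid cross: every strain carries, at
every marker, one of exactly two parental alleles (coded 0/1; there are
no heterozygotes anywhere in the data model). Three assumptions do real
work:

1. **Biallelic haploid genetics.** Every linkage test is a two-group
   comparison; every allele-specific quantity is conditioned on a binary
   split of the strains. Nothing in the package generalizes to diploid or
   multi-allelic data.
2. **A static typed interactome as scaffold.** Protein–protein (PPI) and
   enzyme–enzyme (EEI) edges are undirected; protein–DNA (PDI,
   regulator → target) and kinase–substrate (KPI) edges are directed. The
   network itself is held fixed; what varies with genotype is the
   transcriptional program *on* it.
3. **Exchangeability under the null.** All significance comes from
   permutations of strain labels, valid when strains are exchangeable
   under the null hypothesis — reasonable for a randomized cross, not for
   structured populations.

## Linkage statistics

`linkage_t()` / `t_stat_matrix()` use the equal-variance pooled Student
t (Welch by flag), signed as mean(allele 1) − mean(allele 0). Two-sided
tests on |t| are used throughout. Degenerate inputs are signalled rather
than propagated: a monomorphic marker gives `NA`; zero pooled variance
gives t = 0 when the means agree and a large finite guard (±10⁶, with a
warning) when they differ, so that noise-free simulations rank sensibly
instead of overflowing.

`map_qtls()` assesses significance by permutation. The permutation
formula counts with a weak inequality, p = #{|t\*| ≥ |t|}/pool size, and
by default allows p = 0 (the plain-frequency convention); the
conservative (+1)/(B+1) variant is a flag. **Design choice — null
pooling:** the null pool for a trait aggregates permuted |t\*| across all
of that trait's markers (genome-wide permutation tradition; gives usable
resolution at moderate B), with a per-pair mode available. A practical
corollary of plain-frequency p-values: Monte-Carlo resolution must
exceed the demands of the test family, so B should be large relative to
the number of traits when calibrated FDR matters; the calibration test
in the suite uses B = 400 for 8 traits on this ground.

Heritability is H² = (σ²_seg − σ²_parents)/σ²_seg with the pooled
parental variance taken as the df-weighted average of the two
within-parent replicate variances (the standard meaning of "pooled
variance"). Its permutation test pools all segregant and parental values
and reassigns them to null groups of the original sizes. σ²_seg = 0
flags the record as undefined instead of raising.

Cis/trans classification uses an inclusive 10 kb rule on 1-based bp
coordinates: cis iff same chromosome and the marker point lies within
10,000 bp of the gene interval (a marker at 10,001 bp is trans).
Adjacent markers with identical genotype profiles are merged to their
first marker before mapping; the merge map inverts the operation, and
consumers that need original marker ids should expand through it.
Missing expression entries are imputed by K = 15 nearest gene rows
(root-mean-square distance on co-observed columns, donors restricted to
rows observed in the target column).

## ASCP and ASDP

ASCP is set logic: one record per (marker, edge) where both edge
endpoints are significant targets of the marker. ASDP is the
differential-correlation statistic Dys = |r⁰ − r¹| between allele
groups, tested against random reassignments of strains to two groups of
the original sizes. Two deliberate asymmetries with the linkage test:

- the ASDP tail is **strict** (p = #{Dys\* > Dys}/B) while the linkage
  tail is weak — each follows its own stated formula;
- significance keeps records with q **below** the FDR level.

**Design choice — candidate universe.** By default a (marker, edge) pair
is tested only when the marker is an eQTL of at least one edge endpoint;
a full marker × edge scan exists behind a flag but is quadratic and
changes the multiplicity burden. **Numerical guards:** correlations are
only computed for allele groups of ≥ 3 strains with nonzero variance in
both genes; degenerate pairs are skipped with a logged reason, not
silently dropped. Within one call, the random group reassignments are
drawn once per marker and shared across that marker's candidate edges —
a vectorisation that leaves each pair's marginal p-value untouched (the
null-calibration test in the suite checks exactly this).

## Blocks and sub-networks

**Design choice — block rule.** Classical haplotype-block callers target
diploid outbred data and confidence intervals on D′. For a haploid
biallelic cross a simpler contiguous rule fits: a block grows while the
candidate marker's minimum pairwise r² with every member is at least the
threshold (default 0.8). Blocks partition the markers. An external
marker→block file can override the rule, so externally defined blocks
remain usable.

**Design choice — "minimal component".** A block's sub-network is the
induced subgraph on the endpoint genes of its perturbed edges — not a
Steiner tree over the interactome. The induced reading guarantees, by
construction, that every perturbed edge is contained; connector genes
are never invented. Blocks are kept when they perturb at least
`min_edges = 3` distinct interactions.

## Topology against degree-preserving nulls

Three statistics per sub-network, all on the undirected simple-graph
view (parallel typed edges between the same pair count once; directed
edges lose direction — the density/path definitions are undirected-style):

- **characteristic path length**: mean shortest-path distance over gene
  pairs measured in the *full* integrated network, not inside the
  induced subgraph. Rationale: distances between module genes through
  the whole interactome are what a "shorter than random" claim is about,
  and scattered random gene sets then score long paths as they should.
  Pairs in different components are excluded, with the excluded fraction
  reported; an induced-subgraph mode exists by flag.
- **density**: 2E/(N(N−1));
- **in-degree ratio**: within-edges over boundary-edges; a set with no
  boundary edges returns a flagged infinity rather than a number.

The null rewires each interaction-type layer by degree-preserving
double-edge swaps, preserving in/out-degrees for directed layers and
rejecting self-loops and duplicates. The rewiring engine performs
`swaps_per_edge × E` rewiring *trials* per layer (the package's own
accounting; mixing is verified empirically by an edge-overlap test
rather than by counting accepted swaps). Z = (obs − null mean)/null SD;
the empirical p counts null values ≥ obs for density and in-degree
ratio and ≤ obs for path length, which modular sets are expected to
shorten. A null SD of zero leaves Z undefined rather than infinite.
**Design choice — two nulls:** the edge-swap null is the default; a
same-size gene-set resampling null is also exposed, since the two answer
different questions ("is this wiring special given degrees?" versus "is
this gene set special given the network?").

CSR is the Jaccard index of two blocks' module gene sets. The group
contrast between same- and different-chromosome block pairs uses the
two-sided Wilcoxon rank-sum test; ranks are invariant under monotone
transforms, so the log transform conventionally applied to CSR values
cannot change the p-value, and zeros are therefore handled by testing on
the raw scale.

## Enrichment

The drug-target test is the hypergeometric upper tail with a **strict**
inequality, p = P(X > x) = 1 − F(x; m, n, k). The strictness is not a
stylistic choice: with m = 1 known target and x = 1 observed, only the
strict tail yields exactly 0, which pins the convention against the
reference table the acceptance suite reproduces. The conventional
inclusive tail P(X ≥ x) is available by flag. The background defaults to
all interactome genes in the pipeline and is configurable. Candidate
drug targets are non-target genes counted by *distinct* known targets
reached through perturbed edges, pooled across compounds, thresholded at
`min_links = 3`.

## SMP bridging

Each compound × condition growth trait is an independent phenotype,
mapped like an expression trait and thresholded at |t| strictly greater
than 3.28; markers are unioned per compound. **Design choice — block
resolution bridging:** a compound's QTL recruits every perturbed
interaction whose eQTL marker shares an LD block with the QTL marker.
Within a block, association cannot be resolved further by design, so
block resolution is the honest default; exact-marker bridging exists by
flag for tighter, sparser sub-networks.

## The synthetic generator: what it emulates, what it does not

Defaults mirror the scale of the classical yeast cross this design comes
from: 112 segregants, 2,956 markers on 16 chromosomes, a 6,064-gene
interactome with layer sizes 25,301/12,681/28,785/3,486
(PPI/PDI/KPI/EEI), and a 100-compound screen with several conditions per
compound. Choices where no reference value exists, made once:

- `recomb_prob = 0.02` per adjacent marker pair — at ~4 kb spacing this
  matches the order of magnitude of yeast's high recombination rate
  (roughly 0.3–0.4 cM/kb) while leaving clear LD structure;
- `effect_size = 2` residual SD for planted eQTLs, a strong but
  realistic expression QTL;
- `dys_delta = 0.9`: planted ASDP pairs get correlation `r0 = 0.9` in
  one allele group via a shared latent factor and independence in the
  other, giving an analytically controlled contrast;
- `n_parent_reps = 4` parental replicates — enough for a df-weighted
  pooled variance, deliberately small like real parental panels;
- genes sit at marker positions round-robin with 1 kb spans so cis
  relationships (≤ 10 kb) are constructible;
- planted ASDP/ASCP edges are chosen with endpoints untouched by other
  planted effects, so the planted correlation structure is not diluted,
  and each planted ASDP marker also receives an eQTL effect on one
  endpoint so the default candidate universe contains the planted pair;
- planted SMP QTLs sit on markers that already carry perturbations, and
  each compound's known-target set contains the endpoint genes of those
  perturbations plus random padding — making target enrichment
  recoverable by construction.

The generator does **not** emulate: realistic recombination maps or
hotspots, sequence-level variation, epistasis, correlated measurement
error across genes (beyond the planted pairs), batch structure, or
missing-data patterns (missingness must be injected by the caller).
Passing tests on synthetic data therefore demonstrate the machinery's
correctness and calibration under clean assumptions, not performance on
real expression data, where pervasive co-expression, hotspot trans-bands
and measurement artefacts make multiplicity and LD structure harsher.

## Problem sizes in the test suite

The suite favours many small, sharply targeted instances over few large
ones: null-calibration at 112 strains over 120 interacting pairs with
B = 1000; planted-recovery at 112 strains over 100 replicates (eQTL
effect 2 SD, q < 0.05; planted Dys 0.9); the FDR harness over 100 null
panels at B = 400; the randomization contract over 1000 draws of a
four-layer network and a planted 12-clique scored against 200 nulls; the
end-to-end pipeline at 50 strains, 100 markers, 150 genes. These sizes
are the package's own choices for tight, deterministic checks under
fixed seeds.

## Known limitations

- Permutation p-values inherit Monte-Carlo granularity; q-values near
  the FDR boundary move with B.
- The LD-block rule is greedy and order-dependent by construction
  (left-to-right extension); it does not revisit block boundaries.
- ASCP inherits every thresholding decision of the upstream eQTL scan;
  it has no significance of its own beyond that.
- Directed-edge information is used in the randomization null but
  ignored by the topology statistics.
- The pipeline's heritability filter is only as powerful as the
  parental replication allows; with few replicates it passes few traits,
  and it deliberately falls back to keeping all traits rather than
  continuing with fewer than two.
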