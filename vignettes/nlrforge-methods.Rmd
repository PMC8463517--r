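---
title: "Methods and design of the nlrforge pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the nlrforge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models
behind each stage, the parameters that matter, the choices we made where
the design was genuinely open, and what the synthetic-data validation
does and does not demonstrate about real data.

## The annotation problem

Plant NLR receptors share a conserved nucleotide-binding core (NB-ARC,
the domain family shared with the animal Apaf-1 protein, which therefore
serves as a natural phylogenetic outgroup) flanked by a variable
N-terminal domain — coiled-coil (CC), Toll/interleukin-1-receptor (TIR)
or RPW8 — and a C-terminal leucine-rich-repeat (LRR) region. Annotating
them from de novo transcriptomes is hard for two reasons: assembly
fragments truncate architectures (so most expressed-NLR records are
partial), and the gene family is too diverse for any single detector.
The pipeline therefore combines three detection routes and takes their
union: motif scanning, a profile HMM of the NB core, and an iterative
PSSM homology search that can walk through intermediates to remote
family members. Any candidate carrying at least one recognisable domain
enters the record set as a partial gene; this replaces interactive
curation with a deterministic rule.

## Motif stage

Motifs are learned from a reference NB-domain set by EM over the OOPS
model (exactly one occurrence per sequence). Each of the `n_motifs = 5`
motifs (width 12 by default; the original workflow's motif count is not
prescribed anywhere, so these are package defaults) is fit with 10
seeded restarts, keeping the best final log-likelihood; occurrences of
each accepted motif are masked before the next is fit, which is what
forces motif 2 to explain different signal than motif 1. The M-step adds
a total pseudocount mass of 0.01 per column, small enough that a fully
conserved column still exceeds probability 0.99 with ten training
sequences.

Scanning follows the MAST recipe. The null distribution of a motif's
integer-rounded score (0.1-bit granularity) is computed exactly by
convolving per-position score distributions under the background; the
best window's position p-value is corrected for the number of windows
scanned, `p_seq = 1 - (1 - p_pos)^m`, and per-motif p-values combine by
the QFAST product formula before conversion to an E-value against the
database size. Two numerical details matter in practice. First, without
the window correction the best-of-m selection bias makes every random
sequence look significant. Second, residues outside the 20-letter
alphabet (stops and X from six-frame translation) score the
background-expected column score rather than zero: the typical random
window scores far below zero under an informative PWM, so a zero-scoring
stop-rich window would otherwise sit in the extreme upper tail and flood
the scan with false positives. With both in place, combined p-values are
super-uniform on random sequences (verified by a one-sided
Kolmogorov–Smirnov test in the suite).

## Profile-HMM stage

The domain model is a deliberately small profile HMM rather than a full
Plan7: single-hit, match/insert/delete states, no I–D or D–I
transitions, insert states emitting the background. Columns with at
least 50% residues become match states; emissions and transitions are
Laplace-smoothed counts. Scoring is local Viterbi log-odds in bits with
free flanking residues; entry and exit are uniform over the L match
states, contributing a `-2 log2(L)` term that keeps chance runs on long
random sequences below threshold. The hit threshold defaults to 10 bits
— chosen as a reproducible stand-in for HMMER's "default cutoff", which
is not a single number — and calibrates well: at most 1 in 100 random
120-mers reaches it in the suite's null check. The forward algorithm
(global mode) exists primarily as a correctness anchor: it is compared
against brute-force enumeration of all state paths on tiny models.

## Iterative PSSM search

Round 0 scores the database against each query by Smith–Waterman with
BLOSUM62 and BLAST-style affine gaps (a gap of length k costs
11 + k). E-values use the Karlin–Altschul form with Gumbel parameters
fitted by moment matching on seeded random alignments; we use 2000
calibration pairs (the fit is stable well before that, and calibration
happens at every fresh session). Hits at E ≤ 1e-10 are locally aligned
back to the query; observed residue frequencies per query position are
mixed half-and-half with BLOSUM62 conditional target frequencies
(`q(b|a) ∝ p_b 2^{s_ab/2}`) into a half-bit PSSM, which rescans the
database until a round adds nothing or `max_iter` is reached. The same
Gumbel parameters are reused for PSSM rounds; this is an approximation,
acceptable because the cutoff is extreme and the suite verifies the
false-positive rate directly.

## Domain grammar

Sequence-level detectors: CC by the fraction of hydrophobic residues
(L/I/V/M/F/A) at heptad a/d positions in a 28-residue window (call at
≥ 0.6 — an invented, configurable threshold; the original analysis used
an external annotator for CC); LRR by at least 3 LxxLxL signature
matches within 90 residues; TM by mean Kyte–Doolittle hydropathy > 1.8
over 19 residues. One curation rule proved necessary: LRR and TIR
repeats are leucine-rich enough to phase-match the heptad lattice, so CC
calls overlapping another domain call by half or more of their length
are discarded as artefacts. Classification is then purely grammatical:
NB + LRR means full-length, subclassed by the N-terminal-most of
TIR/RPW8/CC (none present: the distinct class "NL", which we report
separately rather than fold into CNL); otherwise the label is the
hyphenated list of core domains present in N-to-C order, which
reproduces the published partial classes and stays total over all 32
kind subsets (an exhaustive property test).

## Cluster genomics

The Richly rule is applied literally: per chromosome, in start order,
maximal runs of NLR genes in which adjacent NLRs are separated by at
most 8 intervening non-NLR genes; gaps are counted in genes, never base
pairs, and strand is ignored. Runs of 1/2/3 are singletons, pairs and
triplets; 4 and larger is a cluster — the only reading under which the
published compositions (e.g. a mean cluster size of 5.7 alongside
separate pair and triplet columns) are arithmetically consistent.
Grouped percentages are rounded half-up. The chi-square test of
chromosomal distribution takes expected counts proportional to
chromosome length in base pairs (the alternative — gene-count weighting
— is one argument away), delegated to `stats::chisq.test`.

## Phylogeny

Sequences covering less than half of the reference NB domain length are
excluded (coverage exactly 0.5 is kept). Alignment is a deterministic
progressive aligner: UPGMA guide tree on 3-mer cosine distances, then
profile–profile Needleman–Wunsch on BLOSUM62 expected column scores with
affine gaps (open 10, extend 1). Distances are pairwise maximum
likelihood under the JTT substitution model (golden-section search on
[1e-6, 10]); trees are neighbor joining with negative branches clamped
to zero. This replaces a full ML topology search with BIC model
selection: for clade-level grouping — the use these trees are put to —
NJ on ML distances is adequate, deterministic and fast, and we fix the
model to JTT rather than re-select it. Bootstrap support resamples
alignment columns, rebuilds the tree, and maps bipartition frequencies
onto the full-data NJ tree (supports on a single drawn tree, not a
majority-rule consensus topology). Collapsing contracts internal edges
below a support threshold into polytomies, dropping the contracted
length (the usual consensus convention; preserving all path lengths
through a polytomy is impossible). Both collapse thresholds that appear
in practice (> 80 for strong clades, ≥ 50 for weaker groupings) are just
values of the one `min_support` parameter.

## Selection

SLAC-style counting with Fitch parsimony for ancestral codons (ML
reconstruction would also be defensible; parsimony is exact, fast and
reproducible, and the hook is a single function). Ties resolve toward
the parent state, root ties by observed codon frequency then
lexicographically, which makes the whole analysis deterministic and
invariant to row order and column permutation (tested). Branch changes
decompose into synonymous/nonsynonymous fractional counts by averaging
over all shortest mutational pathways, excluding pathways through stop
codons. Expected site counts are codon-specific synonymous site
fractions averaged over the codons observed at the site. The per-site
test is a two-tailed extended binomial (regularised incomplete beta, so
fractional counts are handled exactly) of the nonsynonymous count
against the neutral expectation EN/(EN+ES), at `alpha = 0.1` by default
— the conventional SLAC level; neutrality (ω = 1) is the null. Global
ω divides total-count rates: `(ΣNS/ΣEN) / (ΣSS/ΣES)`, reported as 0 when
nothing changed and infinite when dS = 0 with dN > 0.

Divergence π is the mean pairwise Tamura–Nei distance after complete
deletion, with base frequencies pooled across the whole alignment — the
composite-likelihood pooling; saturated pairs are excluded with a
warning rather than poisoning the mean.

## Family dynamics

The equal-rates linear birth–death kernel is the workhorse. Its closed
form is an alternating sum that cancels catastrophically for large
families, so it is computed instead as the s-fold convolution of the
single-gene offspring law `P(0) = α, P(k) = (1-α)² α^{k-1}` — an
algebraically identical, all-positive formulation whose truncation at
`max_count` (default 100) is exact for every reported entry. Likelihoods
are Felsenstein pruning over family sizes 0..`max_count` with the root
marginalised uniformly over 1..`max_count` (conditioning on a non-extinct
root; CAFE's default root treatment is not precisely documented, so this
is the package's choice and is configurable in principle through the
pruning code). λ is a single global rate (the analyses this supports use
one published rate, 0.01397 gains+losses per gene per million years);
the MLE is a one-dimensional search on log λ. Ancestral sizes are
maximum-posterior states from the up/down pruning tables, ties to the
smaller count; per-species "average expansion" is the mean terminal
change across families, reported unrounded. Rapid-family p-values are
Monte Carlo: the root is fixed at its MAP state, `n_sim` profiles are
simulated under the fitted kernel, and `p = (k+1)/(n_sim+1)` with k the
simulations whose likelihood is at or below the observed one — the +1
convention keeps p in (0, 1].

## qPCR

Relative expression is `2^-ΔCt` against an endogenous calibrator (in the
motivating experiments, the ubiquitin fusion protein gene). Replicates
are averaged on the expression scale, matching how such validations are
plotted with standard-error bars; averaging ΔCt first is available via
an argument.

## What the generators emulate — and what they do not

The synthetic transcriptome plants CNL/TNL/RNL architectures built from
fixed synthetic domain stand-ins (the NB stand-in carries
P-loop/kinase-2/GLPL-like motif words; CC is a perfect heptad; LRR an
exact LxxLxL repeat — exact repeats give the detectors a clean margin by
construction) with polar linkers, mutates them at 3% per site, and
fragments 70% of NLR transcripts below 700 bp by default — the
short-transcript share reported for real fragmented Cucurbita
assemblies, and the reason most eNLR records are partial. Genome layouts
plant compositions with intra-group gaps ≤ 8 and inter-group gaps ≥ 9,
so the caller's recovery must be exact. Codon alignments evolve under a
Goldman–Yang-style model with uniform codon frequencies; family sizes
evolve by exact Gillespie simulation, giving an independent route
against the closed-form kernel.

What passing these tests shows: the algorithms are implemented
correctly, calibrated under their own nulls, and recover parameters from
data generated under their assumed models. What it does not show:
performance on real assemblies, where domains diverge far beyond 3%,
linkers are not conveniently polar, coiled-coils are imperfect heptads,
transcript fragmentation is biased rather than uniform, codon
frequencies are skewed, and assembly artefacts inflate family-size
counts. Thresholds that are exact on synthetic margins (the 0.6 CC
fraction, the 10-bit HMM cutoff) will trade sensitivity against
precision differently on real proteomes and should be tuned there.

## Problem sizes

The shipped validation runs at deliberately moderate scale, chosen so
the whole suite replays in a few minutes on a laptop core: motif
elicitation on 30–50 sequences of ~120 residues; HMM nulls on 100
random 120-mers; 200 random cluster layouts against the brute-force
oracle; λ recovery from 20 × 500 simulated families on a 5-taxon tree
(state space truncated at 60 where tip counts stay far below it); ω
recovery from 50 alignments of 8 × 300 codons; 1000 chi-square null
draws; 10^5 Gillespie draws against the kernel; end-to-end architecture
recovery on 40 planted proteins. All of these scale up by changing the
arguments; none of the defaults encode anything other than the study
conditions stated above.

## Known limitations

The profile HMM is single-hit and local-only — tandem NB domains are
reported once. The iterative search reuses round-0 Gumbel parameters for
PSSM rounds. The aligner is progressive without iterative refinement, so
deep alignments inherit guide-tree errors. SLAC with parsimony ancestors
undercounts on high-divergence branches (multiple hits collapse), which
biases ω toward the reconstruction; the ω recovery band in the
acceptance checks reflects that. The birth–death model assumes equal
birth and death rates and one global λ; per-branch rates and
assembly-error deconvolution are out of scope.
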