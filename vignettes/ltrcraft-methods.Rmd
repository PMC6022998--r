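---
title: "Models and design choices behind ltrcraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind ltrcraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ltrcraft is a desk-scale pipeline for libraries of predicted full-length LTR
retrotransposons: it annotates protein domains, classifies elements into
superfamilies, lineages and non-autonomous classes, dates insertions from
LTR divergence, and builds RT-domain trees. This vignette explains the
models the package implements, the parameters that matter, and the design
choices made where more than one reasonable option existed. It states no
empirical result beyond what the package's tests and `scripts/acceptance.R`
themselves compute.

## The biological setting

A full-length LTR retrotransposon is flanked by two Long Terminal Repeats
that are identical at the moment of insertion. Autonomous elements encode
up to six protein domains — GAG (capsid), AP (aspartic protease), RT
(reverse transcriptase), RNaseH, INT (integrase) and occasionally ENV — and
fall into the *Gypsy* and *Copia* superfamilies, subdivided into lineages
(Gypsy: TAT, Athila, Galadriel, Reina, CRM, Del; Copia: Tork, Retrofit,
Oryco, SIRE, Bianca). Defective derivatives that have lost coding capacity
are non-autonomous: TRIM (small), LARD (large) or TR-GAG (GAG only
retained).

## Domain annotation

Each element is translated in all six frames and every frame is aligned
locally (exact Smith–Waterman, affine gaps) against every protein in a
lineage-labelled reference library. There is no seeding heuristic: element
libraries are small (10^2–10^4 elements, dozens of references), so exact
dynamic programming is affordable and reproducible. Frameshifted domains
are reported as separate per-frame hits; no cross-frame stitching is
attempted in this version — a known limitation for very degenerate
elements.

Hit significance uses the Karlin–Altschul formula `E = K m n exp(-lambda S)`
with the published *ungapped* BLOSUM62 constants (`lambda = 0.3176`,
`K = 0.134`) held fixed, `m` the translated frame length and `n` the summed
library length. The default cutoff is `E <= 1e-4`. Because the constants
are ungapped, the translated search uses gap penalties stiff enough (open
11, extend 2) to keep random local scores in the ungapped regime; with a
cheap extension penalty (e.g. 0.5) gapped alignment of unrelated proteins
drifts toward the linear phase and the fixed constants understate E,
producing spurious pol-domain hits. This is a deliberate, documented pairing
of penalties and statistics, not a calibration to data.

## Classification rules

Classification consumes only the best hit per domain kind and the element
length, in a fixed rule order that is total over every combination:

1. pol domains (RT/INT/RNaseH) carrying both RLC and RLG labels → putative
   chimera, `NO_CLASS`. The chimera check runs first so that neither
   superfamily can win arbitrarily.
2. at least one pol domain with a single superfamily label → `GYPSY`
   or `COPIA`. The lineage is the RT best hit's lineage when an RT hit
   exists (RT is the most conserved domain); otherwise the majority lineage
   among INT/RNaseH, ties resolved toward the higher-scoring hit.
3. no domains at all → `TRIM` below 2000 bp, `LARD` at or above 2000 bp.
4. only GAG, or exactly GAG+AP → `TR_GAG`.
5. anything else (ENV-only, AP-only, pol domains without RLC/RLG labels) →
   `NO_CLASS`. Superfamily membership is never inferred from GAG/AP/ENV
   labels alone.

Non-autonomous categories never carry a lineage.

`NO_CLASS` elements can be rescued by the 80/80/80 rule: a local alignment
against a classified donor must cover ≥ 80% of the *unclassified* element,
at ≥ 80% nucleotide identity, over ≥ 80 aligned bases. All three thresholds
are strict minima and coverage is measured on the unclassified element.
Donors are elements classified directly by the decision tree (all
categories, including non-autonomous ones); rescued elements do not donate
in turn, which makes the pass idempotent and donor-order independent (ties
broken by alignment score, then donor id). Identity counts `N` against
anything — including `N` — as a mismatch, a conservative choice for a rule
thresholded at 80%.

## Alignment scoring

Pairwise alignment is computed with Biostrings' affine-gap implementation;
a gap of length L costs `gap_open + L * gap_extend`. Defaults follow the
EMBOSS tools for each alphabet: nucleotide +5/−4 with gaps 16/4 (the
stretcher DNA defaults — stretcher is the natural reference point because
global LTR alignment is its job here), protein BLOSUM62 with 10/0.5 for
global alignment and 11/2 for the translated local search (see above).
With +5/−4 and an extension penalty of 0.5, local alignment of unrelated
nucleotide sequences chains matches through cheap gaps (linear phase), so
the cheaper EMBOSS protein-style defaults are *not* used for DNA. Ties in
the dynamic program are broken deterministically (diagonal over up over
left), so identical inputs give identical alignments.

## Insertion dating

The two LTRs of an element are aligned globally and their divergence is
corrected with the Kimura 2-parameter model: with transition proportion
`P` and transversion proportion `Q` over gap-free columns,

    K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

and the age is `T = K / (2r)` with `r = 1.3e-8` substitutions per site per
year by default (configurable). Columns containing a gap or an `N` in
either row are excluded from `P` and `Q`; the reference EMBOSS distmat
behaviour for such columns is not documented, so exclusion is our recorded
choice. When a log argument drops to zero or below the pair is *saturated*:
the element is kept in the dating table with `K = NA` and flagged, never
clamped — clamping would fabricate spuriously old age bins. Ages are
reported in million years and binned at 0.5 MY by default; per-group
percentages are computed over non-saturated elements, with saturated counts
reported alongside.

When the input carries no LTR annotation, a terminal-repeat locator scans
candidate lengths L and compares the length-L prefix and suffix directly
(the repeats of a full-length element are anchored at the termini, so no
seed-and-extend search over interior positions is needed); the
highest-identity L wins, ties going to the longer repeat, with a 70%
identity floor and non-overlap enforced.

## RT phylogenies

The best RT hit span of each autonomous element is translated in the hit's
frame (single-frame translation of the best hit replaces frameshift-aware
gene models; deterministic and adequate for intact elements, a documented
limitation for decayed ones). A trailing stop is trimmed; an internal stop
truncates the peptide. The length filter is strict — *larger than* 200
amino acids for element libraries, larger than 150 for genome-level scans —
so 200-aa and 150-aa peptides are rejected.

The multiple alignment is progressive: merge order from single-linkage
clustering of 3-mer-count cosine distances, profile–profile alignment under
BLOSUM62 with affine gaps. Distances between aligned rows are protein
p-distances over mutually ungapped columns, and the tree is standard
neighbor-joining with negative branch-length estimates clamped to zero (the
count is kept in an attribute). Neighbor-joining is used deliberately
instead of a likelihood method: the common practice of reading a tree off a
progressive aligner's guide-tree output is itself a distance method in
disguise; NJ makes the distance basis explicit, is exact on additive
matrices, and is fast. Leaf labels carry
`elementID#category#lineage` so trees are readable without side tables.

## The synthetic element generator

The generator is first-class, tested code; it is how every stage of the
pipeline is validated without external data. `make_reference_library()`
draws independent random proteins per lineage and domain kind (150–400 aa;
RT at least 220 aa so embedded full-length copies pass the 200-aa filter);
independent random proteins are far below the 40% identity that would blur
lineage labels. `simulate_element()` builds an ancestral LTR (TG…CA
termini), embeds exact back-translations of the reference proteins
(deterministic one-codon-per-residue table) for coding categories, copies
the LTR to both ends and mutates each copy independently with per-site
substitution probability `r·T` and a transition:transversion count ratio
`kappa = 2`, so the expected LTR divergence is `K* = 2 r T` — exactly the
quantity the dating module inverts.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: indel evolution in LTRs, nested
insertions, solo-LTR recombination products, domain decay and frameshifts,
multiple substitutions per site (negligible at the `K <= 0.1` divergences
simulated), and base-composition or codon-usage bias. Classification
accuracy of 100% on clean simulated elements is a correctness check of the
rule logic, not an accuracy claim for degenerate genomic elements.

## Determinism and parallelism

Element-level work is distributed over forked workers and merged in input
order; no step consumes random numbers after dataset generation, so all
analysis outputs are byte-identical for any worker count. The run manifest
records the configuration snapshot, input digests, seed and a timestamp; it
is log metadata, deliberately excluded from the byte-identity contract that
the tests enforce on analysis outputs.

## Problem sizes

The test suite and the acceptance script validate at sizes chosen to
exercise every rule while staying desk-scale: a 60-element mixed library
(16 Gypsy, 12 Copia, 10 TRIM, 10 LARD, 10 TR-GAG, 2 chimeras) over a
4-lineage reference library for the end-to-end contract; two 50-element
cohorts with 1-kb LTRs at true ages 1.25 and 1.75 MY for dating recovery
(binomial sampling error of the cohort mean is then ~2–3%, comfortably
inside the 10% recovery tolerance); 100 random 5–8 taxon additive matrices
for tree recovery; and enumeration-oracle comparison on random sequence
pairs up to length 12 for the alignment kernels.

## Known limitations

* No cross-frame stitching of frameshifted domains; decayed elements may
  lose their RT to the stop-codon truncation rule.
* E-values use fixed ungapped constants; they order hits sensibly and gate
  noise at `1e-4`, but are not calibrated gapped statistics.
* The LTR locator assumes terminal, substitution-diverged repeats; it is a
  fallback for inputs lacking predictor annotation, not a structural
  predictor.
* Family-level clustering, solo-LTR detection and rate heterogeneity across
  lineages are out of scope.
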