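---
title: "Phylogenetic focusing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic focusing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Identifying the members of one gene family (here: the ten canonical insect
Hox genes) inside whole predicted proteomes is harder than it sounds.  A
plain similarity search against Hox queries drags in every homeodomain
protein — the DNA-binding domain is shared across a large superfamily — and
reciprocal-best-hit filters stumble on recent duplicates and on fast-evolving
members such as *zen* and *ftz*.  Phylogenetic focusing tackles this by
letting a gene tree do the discrimination: harvest broadly, build a
per-species tree of everything the harvest returned together with known
reference homologs, root it on a related-but-outside clade (non-ANTP-class
homeodomain proteins), keep only the subclade containing the focal class,
then pool the survivors across species, filter them, and read family
membership off reference-anchored monophyletic clades in a final support
pruned tree.

`hoxfocus` implements that pipeline end to end, along with the companion
procedures a Hox survey needs: functional-region annotation of Hox proteins
(homeodomain, hexapeptide, linker, SSYF/UbdA/QAQA/poly-A/TDWM/PFER motifs),
genomic cluster cartography with near-identical scaffold-overlap merging,
and a synthetic-data generator that makes every stage testable without any
external database.

## Pipeline stages and their parameters

1. **Harvest** (`search_proteome`).  Smith–Waterman local alignment with
   BLOSUM62 and affine gaps 11/1 (a gap of length $L$ costs $11 + L$);
   significance via the Karlin–Altschul model $E = Kmn\,e^{-\lambda S}$ with
   the gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$.  Default
   cutoff $E \le 10^{-5}$.  The alignment engine is `Biostrings::
   pairwiseAlignment`; the test suite checks it against an exhaustive
   enumeration of all gapped local alignments on short words.
2. **Dedup** (`cluster_greedy`).  CD-HIT-style greedy incremental
   clustering at identity $c = 0.98$ with word size $n = 5$ as a prefilter
   only.  Identity is matched residues of the best local alignment divided
   by the shorter sequence length (the CD-HIT convention).
3. **Per-species tree and focus** (`focus_species`).  Queries plus
   candidate representatives are aligned by the built-in progressive
   aligner, a neighbor-joining tree with bootstrap supports is built,
   rooted above the outgroup queries, and the clade spanned by the ingroup
   queries is extracted.
4. **Pool and refine** (`pool_and_refine`).  Focused sets are pooled with
   the queries, deduplicated, filtered by a profile HMM built from the
   aligned queries (keep at $\ge 0$ bits), aligned, pruned by the
   alignment editor ($w = 347$, $g = 0.9$), re-aligned, and the final
   bootstrap NJ tree is rooted and collapsed at support $< 95$.
5. **Assignment** (`assign_clades`).  For each family the smallest clade
   containing all of that family's references is located; if it contains no
   foreign references, unknown leaves inside are assigned to the family
   with the clade's support.  Families whose references are interleaved
   with others yield a logged monophyly failure and no assignments — the
   conservative outcome appropriate for rogue, fast-evolving families such
   as *zen* and *ftz*, which rarely form supported clades.  Unknowns
   between family clades stay "unassigned"; no rule is invented for them.

## Tree inference: a deliberate substitution

Field implementations of this workflow typically use maximum-likelihood
inference (IQ-Tree with model selection and mixture models) scored with
ultrafast-bootstrap and SH-aLRT supports.  This package substitutes distance-based neighbor joining on Poisson-corrected pairwise
distances with nonparametric column-resampling bootstrap.  The substitution
is deliberate: the pipeline's logic — rooting, subclade extraction, support
collapse, clade assignment — is agnostic to the inference engine, NJ is
exact on additive distances (a tested invariant), and the package stays
free of external executables.  The usual dual support thresholds (95 UFBoot / 80
SH-aLRT, which we combine with AND where both exist) map onto the single
available support measure with the stricter threshold, 95; nodes with
support strictly below it are contracted into polytomies
(`collapse_low_support`), so a node at exactly 95 is retained.  `B = 100` replicates is the default: the collapse decision
needs 1-point support granularity at worst, and replicates dominate the
pipeline's cost.  `B` is a config knob for users who want 1000.

## Profile-HMM domain filter

`build_profile_hmm` estimates a compact match/insert/delete profile from an
alignment: columns with gap fraction $\le 0.5$ become match states;
emissions are counts plus one pseudocount-weight of the background
(the alignment's overall residue composition, which doubles as the null
model); transitions come from the observed state paths with Laplace
smoothing.  Scoring is local — the domain may sit anywhere — with flanking
residues emitted by the null, so they contribute zero log-odds.  One
numerical choice matters: the entry cost includes a uniform prior over both
the entry/exit match states and the domain start position
($-2\log L - \log(n{+}1)$ nats).  Without the position term, the forward
sum over the $\mathcal{O}(nL)$ possible placements inflates the score of
*any* sequence by roughly $\log_2 nL$ bits and unrelated proteins score
positive; with it, random sequences score just below zero and planted
domains score far above (about 160 bits for the packaged homeodomain
model), so the domain-presence filter can use a natural 0-bit default.  The forward score is reported (and is never
below the Viterbi score, a tested identity); Viterbi with traceback
localizes the domain for annotation.

## Progressive alignment

The built-in aligner stands in for MAFFT: a UPGMA guide tree on a shared
k-mer distance ($k = 3$), then bottom-up profile–profile global dynamic
programming (Gotoh, affine 11/1, end gaps charged), implemented in C++.
UPGMA is used for the guide tree only — deliberately distinct from the NJ
used for phylogenies, and conventional for progressive alignment.  On two
sequences it reproduces the pairwise global DP optimum (tested against
Biostrings); rows are never reordered and ungapping any row reproduces its
input exactly.  No iterative refinement is attempted; for desk-scale
problems (tens of sequences, a few hundred residues) the progressive pass
is sufficient to hold family clades together, which is all the pipeline
asks of it.

## The alignment editor

In practice fragmentary transcript models force long gap blocks onto an
alignment and are pruned before tree building, traditionally by eye.  The
mechanized rule adopted here, with the workflow's standard parameters
$w = 347$, $g = 0.9$: a row is removed iff it has some window of $w$
consecutive columns in which *its own* gap fraction is at least $g$ — the
signature of a fragment that gaps out most of the alignment.  $w$ is
clamped to the alignment width; whole rows are removed rather than
trimmed; surviving rows are re-reported with all-gap columns dropped.  The
operation is idempotent, and that is a tested property.

## Motif annotation conventions

The homeodomain is localized by the packaged profile (a synthetic
60-column reference panel built around the canonical Antp-class consensus;
see `hd_reference_alignment()`), with a 10-bit Viterbi cutoff; a second
disjoint window above the cutoff raises a chimera flag — misassembled
transcripts occasionally fuse two homeodomain coding regions — and no
split or repair is attempted.  The hexapeptide is the nearest upstream
`Y[PK]WM` (`[YF].WM` behind a relaxed flag).  The linker is measured from
the end of the four-residue hexapeptide core to the homeodomain start;
figure-style annotations box the two regions without fixing a measurement
convention, so this one is fixed here and an offset is configurable.  On
constructs with the anterior-to-posterior linker spacings reported for
mayfly Hox proteins it reproduces 69/15/14/4 residues exactly.  SSYF must start within the first ten residues; UbdA, QAQA and
poly-A (three or more consecutive alanines) are sought C-terminal of the
homeodomain; TDWM and PFER inside the linker; an Abd-B-type single
conserved tryptophan is reported when the hexapeptide is absent.  QAQA,
poly-A, SSYF, TDWM and PFER are literal by definition; UbdA has no
universally agreed literal consensus, so its default pattern (`KELNE`) is
an explicit, overridable package choice.  The diagnostic-residue check
uses columns 19 (Glu, helix 1), 31/33 (Arg/Glu, helix 2) and 54 (Met,
helix 3) of the packaged reference alignment — the four residues
characteristic of Hox homeodomains, placed at the spacings the Hox
literature reports — and is likewise supplied as data, not code.  Clade assignment always outranks motif evidence in
`classify_hox`; motifs corroborate or conflict, never override.

## Scaffold merging and cluster maps

Two scaffolds are concatenated only if their best ends-free alignment is a
suffix–prefix overlap of at least 50 bp (a declared default — no standard
minimum exists) at $\ge 99.8\%$ identity, the stringency used in practice
to justify concatenating Hox-bearing mayfly scaffolds; both orientations of
the right scaffold are tried, and only the terminal 10 kb of each side is
scanned so chromosome-scale input stays tractable.  At overlap mismatches
the left scaffold's base is kept (with two sequences, "majority with ties
to the left" degenerates to exactly that).  Cluster maps sort loci by
coordinate and report intergenic gaps (negative when coding annotations
overlap), majority-strand orientation flags, and order anomalies as the
complement of the longest common subsequence against the canonical order —
so a single translocated *lab* after *Abd-B* is one anomaly, not eight.
Rendering compresses gaps above 500 kb into labeled ellipses and emits a
footer with the drawn length and its share of the full sequence, in both a
plain-text diagram and SVG.

## What the simulator emulates — and what it does not

`simulate_proteomes` plants eight families, each descended from a distinct
ancestor that carries random flanks, a hexapeptide, and a copy of the
packaged homeodomain consensus mutated 10% per family.  Species descendants
mutate at 0.15 per site per edge (indel rate 0.01 in the flanks), with
domain sites at one third of that as a purifying-selection surrogate; each
species also receives 50 uniform-random decoys of 80–300 residues.  The
query panel carries two reference homologs per family drawn at divergence
0.2 — above the within-family rate, because references sampled from distant
insect orders bracket the diversity of any one species, and the assignment
rule anchors a family clade at the references' MRCA; with a single
reference per family that clade is a single leaf and nothing could ever be
assigned.  Three outgroup references descend from one ancestor whose
domain is 35% diverged, forming the coherent rootable outgroup clade that
non-ANTP-class proteins form in real data.  Substitutions are uniform over
residues (no rate matrix), and decoys are composition-free random strings;
passing tests therefore demonstrate the pipeline's logic under clean clade
signal, not robustness to real-data pathologies such as compositional
bias, alignment ambiguity in repeat regions, or assembly artifacts.
Cluster simulations place coding sequences of 900 bp at 2–20 kb spacings in
canonical order, optionally invert one gene, translocate the first family
after the last, or cut the scaffold into two pieces sharing an exact
overlap (200 bp default) for merge round-trips.

## Problem sizes, determinism, degenerate inputs

The regression and acceptance runs use the reference conditions above:
per seed, a run takes roughly 15 s on one CPU, and the end-to-end
recovery check aggregates precision and recall over ten seeds (both
$\ge 0.95$; in practice both are 1.0 under these conditions).  All
randomness flows from a single integer seed per run: simulators call
`set.seed` on entry, the bootstrap records its seed, and identical
configurations reproduce byte-identical trees and assignment tables (a
tested guarantee).  Degenerate inputs are handled explicitly: species with
zero harvest hits are dropped with a log note, not an error; fewer than
four sequences yield a tree without supports and a warning; an outgroup
that spans the whole tree falls back to the largest outgroup-only clade
with a warning; pairs with no comparable alignment columns are an error in
the exported distance function but map to the distance ceiling (10) inside
bootstrap replicates, where resampling can legitimately produce them.

## Known limitations

NJ-with-bootstrap is a weaker inference engine than the mixture-model ML it
replaces; on hard real data (deep splits, rate heterogeneity) family
clades may earn lower supports and collapse, which moves members to
"unassigned" rather than mislabeling them — conservative, but lossy.  The
aligner performs no consistency refinement.  The HMM has no
composition-bias correction beyond its background null.  Reciprocal-best-
hit labeling uses a user-supplied labeled panel, not a full nr-scale
database, so its "none" label means "not in the panel".  Motif scanning is
pattern-exact by design and will miss divergent variants unless the
relaxed flags or custom patterns are used.
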