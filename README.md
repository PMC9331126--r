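# hoxfocus

Targeted gene-family phylogenomics in R, built around **phylogenetic
focusing**: identify the members of one gene family (the canonical insect
Hox genes are the motivating case) inside whole predicted proteomes, where
a plain similarity search returns the entire homeodomain superfamily and
reciprocal-best-hit filters stumble on duplicates and fast-evolving members.

The pipeline, per species, is

```
BLASTp-style harvest (E ≤ 1e-05)
  → CD-HIT-style dedup (c = 0.98, n = 5)
  → progressive alignment + bootstrap NJ tree
  → root on the non-focal (outgroup) clade
  → extract the focal (ANTP-class) subclade
```

then, pooled across species,

```
dedup → profile-HMM domain filter → align
  → alignment editor (w = 347, g = 0.9) → re-align
  → bootstrap NJ, collapse supports < 95
  → assign unknowns to reference-anchored monophyletic family clades
```

Search significance uses the Karlin–Altschul model *E = K·m·n·exp(−λS)*
(gapped BLOSUM62, λ = 0.267, K = 0.041, gaps 11/1); trees are
Saitou–Nei neighbor joining on Poisson-corrected distances
(*d = −ln(1 − p)*) with nonparametric column-bootstrap supports; the domain
filter is a local profile HMM scored in forward log-odds bits against the
alignment-composition null.

Companion modules annotate Hox functional regions — homeodomain (profile
HMM), hexapeptide (`Y[PK]WM`), linker length, SSYF / UbdA / QAQA / poly-A /
TDWM / PFER motifs, the Abd-B conserved tryptophan, diagnostic helix
residues — map Hox clusters on genomic scaffolds (near-identical
suffix–prefix overlap merging at ≥ 99.8 % identity, gene order / orientation
/ intergenic-distance maps, text + SVG rendering), and simulate proteomes
and clustered loci with truth tables so every stage is testable offline.

## Worked example

Simulate three proteomes with eight planted Hox-like families among 50
decoys each, run the pipeline, and compare against the truth table:

```r
library(hoxfocus)

sim <- simulate_proteomes(sim_config(seed = 11))
res <- run_focus(sim$proteomes, sim$queries, focus_config(seed = 11))

head(res$assignments)
#>     seq_id family clade_support n_references_in_clade
#> 1 sp2_p017     pb           100                     2
#> 2 sp3_p013     pb           100                     2
#> 3 sp1_p010     pb           100                     2
#> 4 sp2_p023    Ubx           100                     2
#> 5 sp3_p020    Ubx           100                     2
#> 6 sp1_p011    Ubx           100                     2

m <- merge(res$assignments, sim$truth, by = "seq_id")
mean(m$family.x[m$family.x != "unassigned"] ==
     m$family.y[m$family.x != "unassigned"])   # precision
#> [1] 1
```

All 24 planted members are assigned to their true family with clade
support 100; the 150 decoys are never harvested past the E-value cutoff.
Annotating a Hox-like protein:

```r
dom <- gsub("-", "", hd_reference_alignment()[[1]])
s <- paste0("M", strrep("G", 25), "YPWM", strrep("S", 69), dom,
            "QAQAKELNEAAAA")
annotate_hox(s, id = "anterior_like")
#> Hox annotation for anterior_like
#>   homeodomain: 99-159 (158.5 bits)
#>   hexapeptide: YPWM at 26 ; linker 69 residues
#>   motif UbdA : KELNE at 163
#>   motif QAQA : QAQA at 159
#>   motif polyA : AAAA at 168
```

A split scaffold round trip:

```r
cl <- simulate_cluster(sim_config(seed = 5, split_scaffold = TRUE))
mg <- merge_scaffolds(cl$pieces[1, ], cl$pieces[2, ])
identical(mg$merged$seq, cl$scaffold$seq)   # byte-exact reconstruction
#> [1] TRUE
```

A thin command-line wrapper over the same functions ships at
`inst/cli/hoxfocus.R` (subcommands `focus`, `annotate`, `synteny`,
`simulate`).

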