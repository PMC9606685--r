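# phylowave

Phylogroup-aware analysis of protein family evolution in R.

## The problem

Families like the Slc11 proton-coupled Mn²⁺ transporters (bacterial MntH
phylogroups MB, MA/MAV, MH and the MntH C subgroups; eukaryotic Nramp types)
span an ordered evolutionary succession, and their alignments carry the
record of it: columns whose evolutionary regime *shifted* between groups,
and columns whose residue state became *fixed* at a particular phylogroup
and stayed fixed ever after. phylowave is for molecular evolutionists who
want to extract both signals reproducibly and map them onto carrier
structures:

* **Curation** — global pairwise identity (BLOSUM62, affine gaps) and greedy
  identity-tier filtering (the "filtered at 95/70/60% identity" style of
  representative selection); parsimony-informative site counts.
* **Profiling** — group-specific sequence logos over selected segments,
  inclusive PROSITE-verbose patterns (`D-[DN]-x(2,5)-…`), an exact scanner,
  taxonomic profiles of hits, and fixed-point pattern refinement.
* **Rate shifts** — per-column typing between two groups
  (type I: conserved/variable heterotachy; type II: conserved/conserved on
  radically different residues, Grantham ≥ 60; mixed I/II), a permutation
  test on the divergence statistic
  `D = (1 − f₁(m₂)) + (1 − f₂(m₁))` with Benjamini–Hochberg FDR control.
* **Fixation stages** — the earliest group from which a column's modal
  residue is conserved through every later group, tracing stepwise
  accretion of functional machinery (e.g. a proton-network) along the
  succession; significant sites grouped into coevolution collections, split
  by 3D connectivity when structures are given.
* **Structures** — CA neighbor networks per conformation, Jaccard
  comparison of neighborhoods across conformations, Kabsch superposition
  RMSD, classical-MDS conformer maps with nearest-reference labels.
* **Topology** — Kyte–Doolittle hydropathy and transmembrane-segment
  counting (11- vs 12-TMS architectures).
* **Synthetic truth** — seeded generators for grouped alignments, scan
  databases, TMS architectures and paired-conformation helical structures
  with planted ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(phylowave)

out <- tempfile("demo_")
report <- run_pipeline(list(seed = 1, outdir = out), quiet = TRUE)

report$msa$pi_sites
#> [1] 36
report$rateshift$significant
#> $I
#> [1] 5
#> $II
#> [1] 4
report$trace$planted_stage_recovery
#> [1] 1
report$map3d
#> $n_sites            8
#> $clusters_recovered 2
#> $clusters_planted   2
#> $rearranged_sites   4
#> $conformer_rmsd     3.83...
```

The demonstration pipeline plants 4 type II, 4 type I and 6
stage-conserved columns in a 5-group, 40-sequence, 120-column alignment and
recovers them between the contrast groups MA and MH: all 4 type II and all
4 type I plants are typed correctly and pass FDR (the fifth type I call is
a stage-conserved column fixed at MH but still variable in MA — a genuine
heterotachous contrast, not a false positive); every stage-conserved column
is traced to its exact phylogroup (`planted_stage_recovery = 1`); the two
planted 3D site clusters come back as the two network components; and the
sites rearranged between the two conformations are exactly those on the
pivoted helix. The JSON report (`<out>/report.json`) contains no
timestamps, so a rerun with the same seed is byte-identical.

Individual pieces work standalone, e.g.

```r
reps  <- greedy_filter(read_fasta("seqs.fa"), threshold = 0.70)
aln   <- grouped_alignment(read_fasta("msa.fa"), read_labels("labels.tsv"),
                           group_order = c("OG","MB","MA","MH","pN"))
calls <- rate_shift_calls(aln, groups = c("MA","MH"), B = 999, seed = 1)
fix   <- fixation_stages(aln)
```

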