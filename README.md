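# epscan

Detection and comparative analysis of exopolysaccharide (*eps*)
biosynthesis gene clusters across bacterial genome assemblies.

Marine *Vibrionaceae* carry an ~17-gene *eps* locus — regulators,
export machinery (Wza/Wzx/Wzy/Wzc), glycosyltransferases and a priming
glycosyltransferase, labelled A–R after the *Aliivibrio fischeri* *syp*
orthologs. `epscan` answers, for a cohort of assemblies in the NCBI
two-file convention (`protein.faa` + `cds_from_genomic.fna`):

* **which genomes carry an orthologous cluster**, by local protein
  alignment (Smith–Waterman, BLOSUM62, gap 11/1) with a
  Karlin–Altschul expectation screen and the alignment-length-ratio
  statistics

  MinLrap = L<sub>match</sub> / min(L<sub>prot1</sub>, L<sub>prot2</sub>),  MaxLrap = L<sub>match</sub> / max(L<sub>prot1</sub>, L<sub>prot2</sub>)

  with acceptance at E < 10⁻²⁵, identity > 40%, both ratios ≥ 0.8 and a
  protein size ratio ≤ 1.5 (the last two configurable);
* **how each cluster's architecture varies** — per-gene slots classified
  PRESENT / ABSENT / PSEUDOGENE / FRAGMENTED / TRUNCATED by
  genomic-context walking from a seed gene, insertions between cluster
  genes identified against an auxiliary query catalog, splits within or
  across contigs detected with exact separation distances;
* **how clusters relate phylogenetically** — a Neighbor-Joining tree of
  concatenated cluster proteins (Poisson correction, −ln(1−p)) and a
  five-gene MLSA tree (*pyrH*, *gapA*, *mreB*, *gyrB*, *topA*
  reference ranges, 2943 positions; Jukes–Cantor correction), both with
  seeded column-resampling bootstrap.

A seeded synthetic-genome generator plants clusters subject to every
variation class (deletion, insertion, pseudogenization, fragmentation,
truncation, divergence, contig splitting) with ground-truth manifests;
it defines the study conditions for the shipped tests and results. The
bundled reference cluster and catalog are synthetic stand-ins generated
in code (`synthetic_reference_cluster()`); real reference proteins can
be supplied via `read_reference_cluster()`.

## Worked example

```r
library(epscan)

ref <- synthetic_reference_cluster()
pg <- plant_genome(ref$cluster,
                   events = list(ev_diverge(0.75),
                                 ev_insert_catalog("E", after = "D",
                                                   before = "F"),
                                 ev_truncate("F", keep = 0.5)),
                   seed = 11, genome_id = "demo")
arch <- scan_genome(pg$genome, ref)
arch
#> <eps_architecture> demo
#>   seed A; PRESENT:15 TRUNCATED:1 FRAGMENTED:0 PSEUDOGENE:0 ABSENT:0
#>   insertions: (D,F)x1
#>   synteny fraction: 0.929
```

The scan seeded at gene A, found all 16 cluster genes (F truncated to
half its reference length, hence MaxLrap 0.5 with MinLrap 1), one gene
inserted between D and F (identified as the SypE-like regulator E), and
two of fifteen reference adjacencies broken — one by the insertion, one
by the truncation reclassifying F out of the PRESENT set.

```r
print(tidy(arch), n = 5)
#> # A tibble: 16 × 8
#>   genome_id label status    locus_tags identity_pct min_lrap max_lrap contig_id
#>   <chr>     <chr> <chr>     <chr>             <dbl>    <dbl>    <dbl> <chr>
#> 1 demo      A     PRESENT   DEMO_00105         75.4    0.991    0.991 DEMO_ctg1
#> 2 demo      B     PRESENT   DEMO_00110         75.3    0.996    0.996 DEMO_ctg1
#> 3 demo      C     PRESENT   DEMO_00115         75      1        1     DEMO_ctg1
#> 4 demo      D     PRESENT   DEMO_00120         74.9    1        1     DEMO_ctg1
#> 5 demo      F     TRUNCATED DEMO_00130         78.0    1        0.5   DEMO_ctg1
```

Identity percents sit at the planted 75% divergence target. Cohort
workflows chain the same pieces:

```r
cohort <- default_cohort(seed = 20180206)     # 30 genomes, 21 with clusters
scan <- scan_cohort(cohort$genomes, cohort$reference)
im <- build_identity_matrix(scan$architectures)
plot_identity_matrix(im)                      # genes x genomes heatmap
summarize_genes(im$long)                      # per-gene percentile boxes

twin <- generate_cohort(seed = 42)            # 8 genomes on a known tree
tsc <- scan_cohort(twin$genomes, twin$reference)
ct <- cluster_protein_tree(tsc, twin$genomes, twin$reference,
                           n_replicates = 100, seed = 7)
mt <- mlsa_tree(twin$housekeeping, n_replicates = 100, seed = 7)
robinson_foulds(ct$tree, twin$guide_tree)     # 0: topology recovered
```

A thin CLI wraps the same functions
(`exec/epscan simulate|scan|matrix|tree`); genome directories each hold
the two NCBI files. See the vignette
(`vignettes/eps-cluster-scanning.Rmd`) for the model, parameter
meanings and design decisions.

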