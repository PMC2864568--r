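# falsedup

Detection and correction of false segmental duplications in whole-genome
shotgun assemblies of diploid organisms.

## The problem

Assemblers are built for haploid input. When the two haplotypes of a
heterozygous region diverge enough (typically 1–2%), the assembler builds
one contig per haplotype, and the scaffolder — guided by mate pairs that
genuinely link both contigs to the same flanking sequence — places them
side by side on the chromosome. The released assembly then shows a
high-identity "recent segmental duplication" that is really the second
allele, and the SNPs/indels between the haplotypes are lost. `falsedup`
finds these regions, decides each case with the reads' mate pairs, and
recovers the hidden variants.

Two signatures are detected among nearby contigs:

* **DCC** — *duplicated contained contig*: a short contig aligning over
  >93% of its length at >95% identity into the interior of a nearby
  contig;
* **DOC** — *duplicated overlapping contigs*: an alignment of >300 bp at
  >95% identity joining the facing ends (within 300 bp) of two adjacent
  contigs.

## The statistics at the core

**Mate-pair placement likelihood.** With `reads(c)` the relevant reads of
contig `c`, `frag(r, l)` the fragment size implied by read `r` and its
mate when `c` sits at location `l`, and `lib(r)` the fragment-size model
of `r`'s library,

```
L(c, l) = prod over r in reads(c) of lib(r)( frag(r, l) )
```

computed in log space. `c` is called a mis-assembled erroneous duplication
iff `log L` at the merged location (the contig superimposed on / joined
with its alignment partner) strictly exceeds `log L` at its current
location. `lib(r)` is the library's nominal Normal(mean, SD) unless a
Kolmogorov–Smirnov test rejects it at *P* < 0.01, in which case the
density is re-estimated from the assembly's own mate pairs by cubic
smoothing spline. Every model is floored at the probability value whose
sub-threshold sizes carry ≤ 10⁻⁴ total mass (≈ a ±4 SD interval for a
normal), so disoriented pairs and absurd distances enter the product at
the floor instead of vetoing it.

**Coverage check.** Each call is annotated with the A-statistic,

```
A = L * R / G  -  k * ln 2
```

the Poisson log-odds that the `k` reads with 5' ends in the alignment span
of length `L` (counting both contigs) reflect single-copy rather than
two-copy sequence, at the genome-wide arrival rate `R/G`. `A > 0` supports
the mis-assembly interpretation; variant reporting is restricted to such
calls.

**Unplaced contigs** are screened with stricter thresholds (96%/94% DCC,
96%/400 bp DOC) and called haplotype variants when ≥2 and ≥30% of their
outside mates are consistent with the anchored location (probability above
the 0.05-tail floor, ≈ ±2 SD).

## Worked example

The package ships a fully labeled synthetic diploid-assembly generator, so
the whole pipeline can be exercised without any downloads:

```r
library(falsedup)

cfg    <- sim_config(seed = 7, genome_length = 4e5, n_het_tracts = 11,
                     true_dup_count = 10, n_clean_unplaced = 2)
bundle <- simulate_assembly(cfg)
res    <- run_all(list(contigs = bundle$contigs, agp = bundle$agp,
                       layout = bundle$layout, libraries = bundle$libraries))

res$detect$calls[verdict == "mis_assembled",
                 .(moved_contig_id, anchor_contig_id, kind, n_relevant,
                   loglik_original, loglik_merged, a_stat)][1:5]
#>    moved_contig_id anchor_contig_id   kind n_relevant loglik_original loglik_merged    a_stat
#> 1:         hap0001         ctg00005    DCC          6       -81.76141     -49.07055 10.278612
#> 2:         hap0002         ctg00014    DCC         14      -190.52634    -113.13992  2.913371
#> 3:         hap0004         ctg00024    DCC         10      -139.95714     -78.55399  1.029605
#> 4:         hap0005         ctg00027    DCC          3       -43.69759     -31.10469  7.457067
#> 5:         hap0006         ctg00027    DCC         18      -274.50616    -152.42488  5.093158

str(res$summary$mis_assembled)
#> List of 7
#>  $ DCC                 : int 5
#>  $ DOC                 : int 5
#>  $ DCC_bp              : int 13949
#>  $ DOC_bp              : int 260820
#>  $ total               : int 10
#>  $ total_bp            : int 274769
#>  $ single_copy_fraction: num 1

res$variants[1:3, .(chrom, position, ref_allele, alt_allele, var_type,
                    depth_ref, depth_alt)]
#>     chrom position ref_allele alt_allele var_type depth_ref depth_alt
#> 1:   chr1    36618          T          A      SNP         4         2
#> 2:   chr1    36770          A         AT      indel        3         4
#> 3:   chr1    36877          C          G      SNP         3         4
```

Each mis-assembled call shows the likelihood comparison that decided it
(`loglik_merged > loglik_original`: the mate pairs fit better with the
contig superimposed on its anchor), the number of relevant mate pairs, and
the coverage log-odds (`a_stat > 0`: single-copy read depth, confirming a
false duplication). All ten planted mis-assemblies are recovered; the ten
planted true duplications are kept. The variant table lists the
heterozygous SNPs/indels that re-merging the haplotypes exposes, with
per-allele read depths; `run_all(..., out_dir = ...)` also writes the call
table (TSV + BED), a corrected AGP, per-library model JSON, a VCF and a
JSON summary.

On real assemblies the same pipeline runs from files — contig FASTA, AGP
placements, a 7-column read layout (read, contig, start, end, strand,
library, mate) and library means/SDs — via `run_all()` or the thin CLI in
`exec/falsedup`; precomputed whole-genome aligner output (PAF or
`show-coords` TSV) can replace the internal aligner.

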