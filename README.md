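# autozyg

Homozygosity mapping and shared-haplotype scanning for autosomal
recessive disease loci in consanguineous pedigrees.

## The problem

In an inbred family segregating a recessive disorder, all affected
individuals are expected to be *autozygous* at the causal locus: they
carry two copies of one ancestral haplotype, inherited through
consanguineous loops. On a genome-wide SNP array this shows up as a long
run of markers at which every affected is homozygous for the identical
allele — identical by state (IBS) because identical by descent.
Parametric linkage is often impractical in such families (deep loops,
no reliable allele frequencies for an isolate), so localisation proceeds
by two non-parametric scans:

- **Homozygous-haplotype (HH) scan.** Each affected's genotype vector is
  reduced to its completely homozygous markers. A marker at which one
  affected is A/A and another B/B is a *discordance point* and cannot lie
  in a shared autozygous segment. Maximal discordance-free stretches,
  additionally split across physical gaps larger than `largegap_bp`
  between informative markers (400 kb default, centromere-like gaps),
  are reported when their genetic length reaches `cutoff_cm` (3.0 cM
  default). Candidate regions are intersected with known disease loci to
  test exclusion.
- **Shared-IBS run scan.** Maximal runs of consecutive markers at which
  *every* affected is homozygous for the same allele, reported at
  `min_run_snps` (35) or more consecutive SNPs, sized inclusively
  (`end − start + 1`). Long autozygous runs are typically interrupted by
  isolated false-heterozygote genotype calls; runs separated by at most
  `bridge_max_gap_snps` markers that are heterozygous in at most
  `bridge_max_carriers` samples (and conflict-free) are bridged, then
  candidates are contrasted against unaffected relatives and ranked by
  SNP count — a single autozygous region stands out as an outlier over
  the background of chance runs.

Supporting modules repair centimorgan positions by linear interpolation
in physical coordinates (array annotations routinely carry empty, zero
or non-monotone genetic distances), annotate splice-acceptor point
mutations (nearest-downstream-AG cryptic acceptor, frameshift and
truncation of the encoded protein), and simulate pedigree genotypes by
gene dropping under the Haldane model with an implanted autozygous tract
and a one-directional homozygote→heterozygote error model, so the whole
pipeline is testable without any external data.

## Worked example

Simulate the bundled 23-member multiply consanguineous pedigree (six
affecteds in three first-cousin sibships), scan, bridge and rank:

```r
library(autozyg)
sim <- simulate_panel(config = sim_config(seed = 42))
sim
#> sim_result: 3000 markers x 23 samples, causal 1:75900000
#>   detectable tract: markers 532-911 (380 SNPs); 20 perturbed cells

runs   <- shared_ibs_runs(sim$panel, affected_ids(sim$panel))
merged <- bridge_runs(runs, sim$panel)
ranked <- rank_candidates(contrast_unaffected(merged, sim$panel,
                                              unaffected_ids(sim$panel)))
ranked[1, c("chrom", "start_bp", "end_bp", "n_snps", "n_runs", "not_segregating")]
#>   chrom start_bp  end_bp n_snps n_runs not_segregating
#> 1     1 54100000 9.2e+07    380      3           FALSE

make_table1_report(runs, merged)[1:3, ]
#>   SNPs Chr StartSNP   EndSNP Start(bp)  End(bp) Size(bp) Contiguous
#> 1  258   1 snp1_654 snp1_911  66300000 92000000 25700001        yes
#> 2   73   1 snp1_532 snp1_604  54100000 61300000  7200001        yes
#> 3   47   1 snp1_606 snp1_652  61500000 66100000  4600001        yes
```

The implanted causal position (1:75,900,000) lies inside the top-ranked
region: the 380-SNP autozygous tract was split into three runs by false
heterozygote calls, re-joined by bridging (`n_runs = 3`, `Contiguous`),
and no unaffected relative carries the haplotype homozygously
(`not_segregating = FALSE`). `run_pipeline(run_config(...))` executes the
same stages end to end, writing every stage's TSV plus a JSON manifest;
the splice module is driven through `annotate_splice_mutation()` on a
transcript model (GFF3 + FASTA via `read_transcript()`).

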