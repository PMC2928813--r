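---
title: "Homozygosity mapping in consanguineous pedigrees: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping in consanguineous pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The mapping model

An autosomal recessive disorder in a multiply consanguineous family is
expected to be caused by a variant for which all affecteds are
*autozygous*: homozygous by descent for one founder haplotype reached
through two or more consanguineous loops. On a dense biallelic SNP panel
(AB-coded calls: AA, AB, BB, missing) this creates a long interval over
which every affected is homozygous for the identical allele at every
marker. `autozyg` localises such intervals with two deliberately simple,
frequency-free scans, which is what makes them usable in population
isolates where marker allele frequencies cannot be estimated.

**HH scan** (`shared_rcch()`). Each affected contributes its
*homozygosity haplotype* — the ordered subset of markers at which it is
completely homozygous, with the carried allele. Heterozygous and missing
calls carry no information against autozygosity (a heterozygous call in
one sample may be an error; a missing call is nothing at all), so the
only positive evidence *against* linkage is a marker where two affecteds
are homozygous for opposite alleles. Maximal stretches free of such
discordance points are candidate regions; they are additionally split
wherever two consecutive informative markers (homozygous in at least one
affected) are further apart than `largegap_bp`, since a long physical
gap (centromere, array coverage hole) silently spans unobserved
recombination. Regions are kept when their genetic length reaches
`cutoff_cm`. Region boundaries are the outermost concordant markers;
discordance points are excluded. Unaffected samples play no role in
this scan.

**Shared-IBS run scan** (`shared_ibs_runs()`). The stricter run
definition requires every affected to be homozygous *and* identical in
state at every marker of the run. Under array error rates a several-Mbp
autozygous tract is usually interrupted by isolated false-heterozygote
calls — single markers, typically heterozygous in a single sample, on an
otherwise perfectly shared homozygous background. `bridge_runs()`
therefore merges runs separated by at most `bridge_max_gap_snps`
markers, each non-conforming only because at most `bridge_max_carriers`
samples are heterozygous there. Two exclusions are absolute: an allele
conflict (one affected A/A, another B/B) is genuine evidence against
sharing and never bridges, and a missing call never bridges because the
interruption model is specifically *miscalled heterozygotes*, not
missingness. Bridging is transitive. Candidates are then contrasted
against unaffected relatives and ranked by SNP count; the ratio of each
region's count to the next-ranked one is the outlier diagnostic that
separates one true autozygous interval from the tail of chance runs.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cutoff_cm` | 3.0 | cM | minimum genetic length of an HH region; short discordance-free stretches arise constantly by chance |
| `largegap_bp` | 400,000 | bp | maximum gap between consecutive informative markers; sized for ~610k-marker arrays where 400 kb also covers non-centromeric holes |
| `min_run_snps` | 35 | markers | minimum consecutive shared-homozygous SNPs for a reported run |
| `bridge_max_gap_snps` | 1 | markers | isolated single-marker interruptions are the false-heterozygote signature |
| `bridge_max_carriers` | 1 | samples | most interruptions occur in one sample at a time |
| `contrast_threshold` | 0.95 | fraction | an unaffected matching the shared homozygous genotype at ≥95% of region markers carries the haplotype homozygously; the disease haplotype should then not be called segregating. The per-region fraction rule (rather than a per-marker rule) is a design choice of this package |

All are exposed through `hh_config()` and `scan_config()`. Whether a
minimum informative-SNP count should accompany the cM cutoff in the HH
scan is left configurable (`min_informative_snps`, default 0 — no such
minimum).

## Genetic-map repair

Array annotation files carry centimorgan positions that are empty, zero,
or locally non-monotone. `classify_invalid()` flags a value as invalid
when it is absent, exactly zero (except at the first marker of a
chromosome, kept as a chromosome-start anchor), or off the longest
non-decreasing subsequence of the remaining valid values — the minimal
repair set restoring monotonicity. Among equally long subsequences the
chain ending at the smallest value is chosen (upward spikes are treated
as the errors) and reconstruction prefers the earliest feasible
predecessor (a later dip is flagged, not the trend it dips below).
`interpolate_cm()` then fills flagged markers linearly in physical
position between the nearest valid flanks; beyond the first/last valid
marker the value is held constant, which cannot produce negative or
decreasing map positions. The repair is idempotent and leaves valid maps
untouched.

## Coordinate and rounding conventions

Coordinates are 1-based inclusive throughout; interval size is
`end − start + 1` (`run_size_bp()`), a convention fixed by checking it
against the complete published interval table the worked example
reconstructs. BED input (known loci) is 0-based half-open and converted
on read. Headline spans in Mbp (`span_mbp()`) use the simple coordinate
difference `(end − start)/10^6`, rounded half-up; at two decimals the
inclusive variant (also exposed) agrees for Mbp-scale intervals.
Candidate tables are sorted by descending SNP count with ties broken by
(chromosome, start); reports never contain thousands separators.

## The simulator: what it emulates, and what not

`simulate_panel()` provides ground-truth data for every pipeline stage:

- **Founders.** Two haplotypes per founder, B-allele drawn independently
  per marker from per-marker frequencies (default uniform on
  [0.05, 0.5], the ascertainment range of array content). There is *no*
  linkage disequilibrium among founder haplotypes: shared runs in
  descendants arise only from identity by descent, which is exactly the
  signal the scans must detect. Real data contain LD-driven background
  homozygosity, so real candidate tables have heavier tails of chance
  runs than simulated ones — passing tests here demonstrate correctness
  of the detection logic, not field performance on any particular array.
- **Transmission.** Haldane (no-interference) crossovers: switch
  probability `(1 − exp(−2d))/2` per adjacent-marker interval of `d`
  Morgans. The default map is featureless — 2 chromosomes × 1500 markers
  at 100 kb spacing, 1 cM/Mb, i.e. ~150 cM chromosomes — so tracts
  localise within a chromosome at a desk-scale marker count. (A first
  design at 5 kb spacing produced 7.5 cM chromosomes on which whole
  chromosomes were co-inherited; genetic length, not marker count, is
  what must be realistic.)
- **Autozygosity conditioning.** The bundled pedigree
  (`example_pedigree()`) has six affecteds in three first-cousin
  sibships descending from one founder couple. Naive whole-pedigree
  rejection sampling — redraw the entire gene drop until all six
  affecteds are homozygous by descent at the causal marker — has
  acceptance probability around 10^-11 and is unusable. Instead the
  conditioning is *staged*: the meioses on the descent paths from the
  causal founder to the affecteds are identified in advance
  (`condition_on_autozygosity()`), and each such meiosis is redrawn
  until it transmits the carrier haplotype intact across a window of
  `target_region_snps` markers (default 300) around the causal position
  — a handful of draws per meiosis. Unconstrained meioses are drawn
  once. This yields the exact conditional distribution for the
  conditioned transmissions and guarantees the implanted tract width.
- **Errors.** One-directional: a truly homozygous call becomes
  heterozygous with `het_error_rate` (default 5 × 10^-4), matching the
  observed interruption pattern; heterozygous truth is never converted
  to homozygous. Missingness (`missing_rate`) is modelled but defaults
  to 0: array call rates are near-complete, and since missing calls
  break runs without being bridgeable, nonzero missingness is a
  fragmentation stress test rather than part of the baseline conditions.
- **Truth.** Besides each affected's homozygous-by-descent tract and
  their intersection, the truth records the *detectable* tract: the IBD
  intersection extended outward while every affected remains homozygous
  for the identical allele in the error-free calls. Chance identity in
  state immediately beyond an IBD boundary is common (the extension
  probability per flanking marker is roughly the shared allele's
  frequency), so the IBS-visible tract is systematically a superset of
  the IBD intersection — any IBS-based scan recovers the detectable
  tract, not the IBD tract, and recovery tests compare against it. It is
  computed by a plain marker-by-marker walk inside the simulator,
  independent of the scan implementation.

All randomness flows from `sim_config(seed = )`; identical seeds give
identical results.

## Splice-acceptor consequences

The annotator models the acceptor as the intron-terminal AG dinucleotide
and nothing else — no branch point, polypyrimidine tract or strength
scores. `check_acceptor_disruption()` reports the intron whose terminal
AG contains a point substitution leaving a non-AG dinucleotide;
`next_cryptic_acceptor()` takes the nearest downstream AG (within a
200 nt window, configurable) as the aberrant acceptor, the behaviour
observed in patient RNA when an acceptor is destroyed and an AG sits a
few bases into the exon; `apply_aberrant_splice()` deletes the skipped
exonic bases from the mature CDS and translates to the first in-frame
stop, reporting frameshift status, reference and mutant protein lengths
and the intact codon prefix, with a `stop_lost` flag when no stop is
reached. Minus-strand models are reverse-complemented to a
transcript-forward frame first; offsets are transcript-coordinate.
`synthetic_lrsam1_like()` builds a fully synthetic 25-exon model with
this architecture — 723-residue reference protein, penultimate exon
beginning AG — on which the full pipeline yields a 2-base deletion,
an obligatory frameshift and truncation after residue 643. Real
transcript models can be supplied as GFF3 + FASTA via
`read_transcript()`.

## Degenerate inputs and edge rules

- AB coding is defined per marker by the observed alleles
  (lexicographically smaller = A); a marker at which allele A is never
  observed round-trips through `.ped` with labels swapped, which no IBS
  computation can distinguish.
- `bridge_runs(bridge_max_gap_snps = 0)` is the identity on run
  geometry. An empty run table bridges, contrasts and ranks to empty
  outputs, and an empty region list excludes every known locus.
- A single region (or the bottom-ranked one) reports ratio `Inf`.
- X-chromosome genotypes are treated like autosomes throughout; male
  hemizygosity is not modelled, and X-specific handling is the user's
  responsibility.

## Problem sizes used by the test-suite

Unit fixtures are tens of markers. Property checks run the scans against
naive brute-force enumerations on 200 random panels of up to 200 markers
× 8 samples. Recovery checks use 50 seeded replicates of the default
simulation (3000 markers × 23 samples); calibration uses 10,000 meioses
against the map length in Morgans and a binomial check of the error
model. These sizes were chosen as the smallest at which the properties
are sharp (3 SE / 3 SD bands, exact boundary equality).

## Known limitations

- Frequency-free by design: no population-frequency weighting of runs
  and no genotype-likelihood/HMM autozygosity model; the scans assume a
  pedigree of jointly autozygous affecteds, not population cohorts.
- Founder haplotypes are LD-free, so simulated background run lengths
  are optimistic relative to real arrays.
- The splice model ignores acceptor strength; where several AGs compete,
  the nearest downstream one is always chosen.
- Exact reproduction of a real gene's residue numbers requires the real
  transcript model and sequence, supplied by the user; packaged
  fixtures are synthetic.
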