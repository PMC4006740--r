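---
title: "Methods: homozygosity mapping and recessive variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity mapping and recessive variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homsift)
```

## The model

`homsift` targets the classic study design for rare autosomal-recessive
disease in consanguineous families. Its probabilistic backbone is
identity by descent (IBD): the kinship coefficient φ(a, b) is the
probability that one allele drawn from each of a and b is IBD, computed
by the tabular recursion with founders assumed unrelated and non-inbred
(`kinship()`), and the inbreeding coefficient F of an individual is the
kinship of its parents (`inbreeding()`). For the built-in
first-cousin-union pedigree (`family_pedigree()`) this gives F = 1/16:
at any autosomal locus, the proband's two alleles are copies of a single
ancestral allele with probability 1/16, and a recessive causal variant
is expected to be homozygous in the proband while each parent is a
heterozygous carrier.

The analysis is a deterministic filter cascade over annotated variant
calls (`run_cascade()`): the inheritance filter (trio IBD pattern, or
proband homozygosity when parents are unsequenced), region and effect
filters on functional classes, a frequency filter against an exclusion
database of common non-pathogenic variants, a control-panel filter
against homozygous calls in unaffected exomes, a cross-family
intersection on full variant identity, and a predictor-consensus
ranking. Every filter is contractive and idempotent, and filters that
test independent predicates commute; the per-stage audit report makes
each shrinkage step inspectable.

Autozygosity leaves a second, positional signature: long runs of
homozygosity (ROH). `call_roh()` scans position-sorted calls for maximal
runs of homozygous genotypes, `shared_regions()` intersects ROH across
patients, and the STR functions (`phase_str_trio()`,
`minimal_shared_haplotype()`) delineate the minimal ancestral haplotype
shared by patients from different families — the signature of a founder
mutation.

## Tunable parameters

* **ROH calling** (`call_roh`): `min_variants = 10` non-missing calls,
  `min_length_bp = 1e5`, `max_het = 0`. At exome variant density a
  single heterozygous call is strong evidence against autozygosity, so
  the default tolerates none; the 100 kb span is the same threshold used
  to report shared regions. Missing calls are skipped without breaking a
  run (they carry no evidence either way).
* **Shared regions** (`shared_regions`): `min_shared_length_bp = 1e5`.
  Shared regions are computed by intersecting per-sample ROH calls
  rather than jointly scanning pooled genotypes; under `max_het = 0`
  the two formulations coincide, and the interval form is simpler.
* **Exclusion database** (`build_exclusion_db`): `min_freq = 0.01`.
  The construction rule removes pathogenic-flagged records, records
  below the threshold and records without frequency information; the
  boundary is read literally, so a variant at exactly 1% is retained as
  a member (and therefore filtered out of candidate lists).
* **Predictor consensus** (`predictor_consensus`): SIFT-like damaging
  strictly below 0.05, PolyPhen-like above 0.5, PROVEAN-like at or below
  −2.5, categorical callers damaging at `"disease_causing"`. The default
  `k` is the number of configured tools — unanimity — because the design
  expects a single surviving candidate to be flagged by every tool;
  `k` is configurable for laxer consensus. Absent scores never count as
  damaging.

## The simulator

`simulate_dataset()` gene-drops founder haplotypes through two
independent four-generation pedigrees, each with a first-cousin union
producing the proband (F = 1/16). Defaults describe the emulated study
conditions:

* three chromosomes (chr1 110 Mb, chr2 90 Mb, chr16 90 Mb) with 900
  variant sites each — roughly one variant per 3 kb of exonic sequence
  at a ~3% exonic fraction, a desk-scale stand-in for a full exome;
* allele frequencies drawn per site from uniform(0.01, 0.5) with a 15%
  rare tail on uniform(0.001, 0.01); 3% of sites lack a frequency-table
  record and 1% are flagged pathogenic, so both removal clauses of the
  exclusion rule are exercised;
* meiosis under the Haldane model: crossover counts Poisson with mean
  the genetic length at 1 cM/Mb, breakpoints uniform, no interference —
  the simplest defensible model, since crossover interference is
  irrelevant at the multi-megabase scale analysed here;
* a causal variant at chr16:4.6 Mb (coding position 226 of a
  PAM16-like gene), population frequency zero, written onto one founder
  haplotype per family together with an identical 4 Mb ancestral segment
  of flanking variant and STR alleles — the two families share the
  haplotype content, emulating a founder mutation;
* per family, gene drops are rejected until the proband carries two
  copies of that ancestral haplotype at the causal site while both
  parents carry exactly one. Rejection sampling (expected ≈ 64 attempts,
  the reciprocal of the per-haplotype autozygosity probability 1/64)
  preserves the correct IBD tract structure around the causal site,
  which forced copying would distort;
* 14 unrelated control exomes drawn in Hardy–Weinberg proportions from
  the same frequencies, and 550 control chromosomes screened for the
  causal allele (always absent, since its population frequency is 0);
* 12 STR markers spanning 8.7 Mb around the causal locus, each with a
  6–10 allele ladder;
* predictor scores falling in their damaging range with probability 0.9
  per tool for the causal variant and 0.1 for neutral variants, which
  exercises the consensus rule without re-implementing any predictor.

All randomness flows from one master seed through fixed labelled
substreams, so adding a stage never perturbs earlier draws and emitted
bundles are byte-identical across runs with equal seed.

What the simulator does *not* emulate: sequencing or genotyping error,
X/Y/mitochondrial inheritance, indel realignment ambiguity, linkage
disequilibrium between sites (founder alleles are drawn independently
per site), population structure in the controls, and realistic exome
variant counts (the paper-scale candidate counts depend on a specific
variant database release and tens of thousands of sites). Passing tests
therefore demonstrate the correctness of the filtering, mapping and
arithmetic machinery under the stated genetic model — not calibration
against any particular sequencing platform or database.

## Numerical and design choices

* **Region length** is `end − start` (difference convention), not
  `end − start + 1`: this matches how such region sizes are
  conventionally quoted from their coordinates
  (4,057,603–7,657,432 → 3,599,829 bp → 3.6 Mb); the single-bp
  discrepancy is immaterial at megabase scale but matters for exact
  tests. Mb renderings round half-up (never banker's), with
  `digits = 0` giving the "~3 Mb" integer style.
* **Coordinates** are 1-based fully closed internally, per VCF; BED
  export is 0-based half-open and the converters are exact inverses.
* **ROH boundaries** are the positions of the first and last homozygous
  call in a run, so a tolerated het or a missing call never defines an
  endpoint. Reported runs are feasible windows maximal under
  containment; the scanner is equivalent to exhaustive window
  enumeration (property-tested against a brute-force oracle).
* **Kinship evaluation order**: individuals are processed founders-first
  in topological order with lexicographic tie-breaks, making the
  recursion (which must expand the later-generation argument) and all
  outputs deterministic.
* **Missing genotypes** disqualify a variant from the inheritance
  filters rather than being imputed — conservative, and avoids
  fabricating inheritance patterns.
* **Family-1 mode** drops only the parental-heterozygosity condition
  (the parents were not sequenced); every downstream filter is
  identical, so the two families' candidate sets remain comparable for
  the intersection.
* **STR phasing** assigns a child allele paternal origin only when the
  assignment is unique given both parental genotypes; both-compatible
  configurations stay unresolved, and Mendelian-inconsistent markers are
  flagged rather than raised. The minimal shared haplotype is the
  longest run of consecutive markers at which every patient is
  homozygous for the same allele, with boundaries at the first
  discordant or heterozygous flanking marker on each side (the run's
  edge marker when it touches the panel end) — so the reported span is
  an upper bound on the ancestral segment, shrinking as markers or
  patients are added.
* **Multi-allelic VCF records** are split into one key per alternate,
  with diploid genotypes recoded per alternate (a 1/2 call is
  heterozygous for each alternate); variant identity is the full
  (chrom, pos, ref, alt) tuple afterwards.
* **Degenerate inputs**: empty genotype matrices yield empty candidate
  sets with all-zero report counts; an empty exclusion database makes
  the frequency filter the identity; pedigrees with parental cycles are
  rejected before any recursion; zero-length regions have length 0.

## Verification strategy

The test suite checks each component against an independent oracle
rather than against itself: recursive kinship against single-locus
allele-dropping Monte Carlo (3-standard-error agreement at 100,000
replicates); gene-dropped autozygous genome fraction against the
pedigree inbreeding coefficient (50 replicates, 3 SE); the ROH scanner
against exhaustive window enumeration on instances of up to 30 variants;
single-codon consequence arithmetic against whole-sequence
translation-and-diff on random coding sequences; and the full pipeline
against the simulator's planted truth across 100 seeds, requiring the
planted variant in the final candidate set with a shared ROH containing
the planted site in at least 95% of runs and fewer than five false
positives per run on average. The problem sizes (2,700-site exomes,
100-seed end-to-end runs, 10<sup>5</sup>-replicate Monte Carlo) were
chosen so the whole suite runs comfortably on a single CPU while leaving
the Monte-Carlo standard errors small enough to be discriminating.

## Known limitations

Kinship is autosomal only (no X-linked recursion); compound-heterozygous
and de-novo inheritance models are out of scope; ROH calling is the
rule-based scanner described above, not a model-based autozygosity HMM,
and no LOD scores are computed; annotation (transcript mapping, predictor
scoring) is consumed, never produced; and the consequence checker handles
single-base substitutions under the standard nuclear genetic code only —
the gene under study is nucleus-encoded, so the mitochondrial code is
irrelevant, and indel consequence arithmetic is out of scope.
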