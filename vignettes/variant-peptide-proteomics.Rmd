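---
title: "Variant peptides, MS-PAVs and the epitope effect: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant peptides, MS-PAVs and the epitope effect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavprot)
library(dplyr)
```

## The model

Bottom-up proteomics infers proteins from tryptic peptides. A common
missense variant (a PAV) changes one residue, so the peptide covering the
variant site exists in two allelic forms. Under codominant expression the
reference-allele peptide's abundance is proportional to the number of
reference allele copies: full in reference homozygotes, halved in
heterozygotes, absent in alternate homozygotes (and symmetrically for the
alternate-allele peptide). `pavprot` exploits this twice:

* **Detection as genotype readout.** For each variant-peptide *signal* —
  a unique (peptide, nanoparticle fraction, precursor charge,
  missed-cleavage form) combination — detection across donors is tested
  against carrier status of each allele with two 2×2 Fisher's exact tests
  (`p-maj` for presence of ≥ 1 major-allele copy, `p-min` for ≥ 1
  minor-allele copy); the stronger association is reported. Signals are
  the Bonferroni family: significance means `p < α / n_signals`, strictly.
* **Exclusion for unbiased quantification.** Protein-level genotype
  associations are fit on quantities derived from the *PAV-exclusive*
  library, from which every variant-overlapping peptide (both alleles) has
  been removed. An association that survives exclusion reflects protein
  abundance; one that disappears was carried by the
  genotype-dependently-missing peptide — the MS analogue of an epitope
  effect in affinity assays.

### Library construction rules

Digestion cleaves strictly after every K or R with at most one missed
cleavage and no proline exception (matching `--cut K*,R*` search-engine
settings); peptide length is restricted to 7–30 residues, filters applied
after enumeration; protein N-terminal methionine excision additionally
emits the start peptide without its leading M (`--met-excision`). Variants
are injected one at a time into the pure reference background — multiple
substitutions in one peptide are deliberately not combined. Reference and
injected digests are compared per missed-cleavage stratum: pairs with
equal length, equal start position and differing sequence are *simple*
matches; unpaired alternate peptides caused by K/R gain or loss are
*discarded*; other unpaired variant-overlapping peptides are flagged
*complex*. Only simple-match alternate peptides enter the PAV-inclusive
library (plus one full-length isoform entry per variant, named
`proteinid_rsid`, falling back to `chrom:pos:ref:alt` when no rsID
exists).

### Gene model resolution

The gene model pairs a protein FASTA with BED12 coding blocks (BED
coordinates 0-based half-open; VCF and protein positions 1-based). When a
protein id maps to several placements the cascade is: unique mapping kept;
else exact CDS-translation matches preferred; else in-frame translations
starting with methionine; across chromosomes canonical entries win, then
the alphanumerically first chromosome; within one chromosome the first BED
record wins. A single trailing stop codon is trimmed silently; internal
stops or a CDS length not divisible by three invalidate an entry. Only
single-nucleotide missense consequences are mapped: synonymous, stop-gain
and stop-loss variants are excluded (the library builder's contract is
substitution-only; how rare stop-affecting common variants should be
injected is genuinely underdetermined, and exclusion is the conservative
choice).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| MAF threshold | 0.10 (strict >) | common-variant filter for injection |
| peptide length | 7–30 aa | search-engine digest window |
| missed cleavages | ≤ 1 | tryptic enumeration depth |
| Fisher sidedness | two-sided | default of the analysis environment; configurable |
| MS-PAV α | 0.05 / n_signals | strict Bonferroni on the signal family |
| MS-pQTL threshold | 5 × 10⁻⁸ | genome-wide significance, strict |
| detection-fraction filters | > 0.20 (QC), > 0.80 (PWAS) | strict row filters |
| concordance flag | > 0.90 discordant detection | both alleles detected in samples lacking them |

Ties between `p-maj` and `p-min` report the minor allele — ties are
measure-zero in practice and a deterministic rule keeps output stable.
Samples present in proteomics but absent from genotyping are dropped per
test. Degenerate 2×2 tables (a zero margin) return p = 1 and are flagged
rather than erroring: an undetected peptide is evidence, not a failure.

## Protein roll-up: a documented stand-in

The quantification engine's protein inference (MaxLFQ-like) is not
reproduced. `rollup_protein()` offers `median_log` (median of log2
intensities of detected library peptides — the default, robust summary)
and `sum` (sum of raw intensities, absent peptides contributing nothing).
The roll-up's only contract is sensitivity to library membership. For the
epitope demonstration the `sum` method is used deliberately: a median over
*detected* peptides is, by construction, robust to one dropped peptide and
would mask the very mechanism under study, whereas engine estimates are
demonstrably affected by a missing high-intensity peptide — which is what
the `sum` reproduces. This is a package design choice, recorded here
because the default and the demonstration differ.

## The pQTL and PWAS models

Protein intensities are inverse-normal transformed within the analyzed
complete cases (average ranks, Blom offset `(r − 3/8)/(n + 1/4)`; the tie
rule is a convention choice). The pQTL model regresses the transformed
intensity on minor-allele dosage with age, sex, BMI, diabetes status and
three genotype principal components as covariates; `beta` is therefore in
inverse-normal (≈ standard-deviation) units per allele copy. The
peptide-level model (`pX`) instead sets missing intensities to zero,
because non-detection of an allele-specific peptide is informative at the
peptide level. One stated ambiguity in the source protocol — both protein
and genotype described as the dependent variable — is resolved the only
internally consistent way: protein is the outcome. Nanoparticle fractions
are analyzed separately; when one association per variant is needed the
minimum-p fraction is reported and labelled as such.

## What the simulator emulates — and what it does not

The generator states a world matching the analyzed cohort: n = 325
genotyped donors; HWE genotypes at MAF uniform in (0.10, 0.50]; age
uniform 18–80, sex and diabetes balanced Bernoulli, BMI normal(28, 4.5²),
three standard-normal genotype PCs; five nanoparticle fractions with
log-normal offsets; variant-peptide detection at 58% sensitivity in
carriers and 5% false positives in non-carriers — the rates implied by the
motivating worked example (130/223 carriers, 5/102 non-carriers).
Protein log2-intensities have unit conditional variance (sd 0.5 on the
log2 scale times covariate structure), so simulated effect sizes are in
the same inverse-normal units as reported pQTL betas; the default
`pqtl_beta = 0.7` sits mid-range of typical strong plasma pQTLs and is
applied as an abundance *decrease* per minor allele (destabilizing
missense), which keeps composition and abundance signals aligned in the
`true_pqtl` scenario. Allele-specific peptide intensity scales linearly
with allele copy number — the dose model is not independently known, but
heterozygote intensity patterns motivate proportionality. The variant
peptide's ionization budget defaults to 2^1.5 ≈ 2.8 times its protein's
summed invariant ionization: engine protein estimates are dominated by the
best-ionizing peptides, and a detectable epitope effect presupposes the
variant peptide carries real quantitative weight.

Three presets: `epitope` (allele-specific peptide, no abundance effect),
`true_pqtl` (genuine abundance shift), `null` (variant peptide detected
regardless of genotype — a spectral-confusion false identification, the
pattern the concordance QC flags).

Not emulated: retention times, fragmentation, ion mobility, match-between-
runs, LD between variants, relatedness. A green simulation test therefore
establishes that the statistical machinery recovers the stated mechanisms
at realistic scale — not that any real search engine behaves identically.

## Numerical choices

* Fisher p-values are computed exactly from the hypergeometric density
  with the conventional `(1 + 1e-7)` tie tolerance (the `fisher.test`
  convention), clamped to 1; an exhaustive enumeration oracle checks all
  2×2 tables with N ≤ 40 to 10⁻¹² relative error in the test suite.
* All strict-inequality thresholds (MAF > 0.10, p < α/n, detection
  fraction > 0.20/0.80) are implemented strictly; boundary cases are
  tested.
* The regimen classification in the simulated single-variant cohort uses a
  per-test threshold of 10⁻⁴ rather than the genome-wide 5 × 10⁻⁸, which
  belongs to a proteome-wide scan; the choice was fixed before any
  calibration run.
* Rank-deficient regression designs abort naming the collinear columns;
  constant genotypes and all-identical intensity vectors are errors, not
  silent NAs.

## Known limitations

Peptides shared between proteins stay in every carrier protein's entry
(protein-group inference is delegated to the report producer). Indels,
multi-nucleotide variants, alternative codon tables and splice-isoform
inference are out of scope. External summary-statistic overlap uses exact
variant matching only — no LD expansion — so its `cis`/`trans` taxonomy is
conservative with respect to tag-variant hits. The assayed-target set of
an external platform defaults to the targets present in the supplied
table, which understates platform coverage when the table is sparse;
supply `assayed_targets` when known.
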