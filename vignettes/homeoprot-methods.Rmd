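---
title: "Calling homeolog-specific gene products in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling homeolog-specific gene products in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoprot)
```

## The problem

Many crops are allopolyploids: their nuclei carry chromosome sets from
distinct parental species. Triploid ABB banana combines one *Musa
acuminata* (A) and two *Musa balbisiana* (B) subgenome copies, and the
two parental genomes differ at roughly one SNP per 39 bp. Homeologous
gene copies therefore encode slightly different proteins, and tryptic
peptides spanning a single amino acid polymorphism (SAAP) make the
subgenome of origin visible at the protein level. Two questions follow:

1. **Which identified peptides are cultivar- (allele-) specific?** A
   peptide present in the ABB cultivar's protein database but absent
   from both AAA databases is evidence of a B-subgenome product.
2. **Is homeolog expression dosage-balanced?** With one A and two B
   copies, B transcripts are expected at 2/3 of a locus's reads. The
   package tests each locus's observed B-read share against a null
   proportion of 0.66 (the printed convention for 2/3) and classifies
   loci as balanced, positively/negatively biased, or dominant (only one
   homeoallele expressed).

`homeoprot` implements the full workflow — cultivar database
construction, cross-database specificity calling with codon-level
ambiguity resolution, binomial bias testing, quantitative feature
selection, and GO enrichment — together with a seeded synthetic
generator that reproduces the statistical structure the analysis
assumes, so every stage is testable without external downloads.

## Cultivar databases and the meaning of X

`build_cultivar_db()` applies a cultivar's RNA-seq variant calls to the
reference (A subgenome) coding sequences and translates with the
standard genetic code. An allele counts as present when its pooled
allele depth is positive. Heterozygous codons whose alleles encode more
than one amino acid cannot be written as a single residue; they become
`X`, and the ambiguity side-table records every candidate amino acid
with its codon variant and the genomic positions of the heterozygous
sites. Synonymous heterozygosity keeps the shared residue. Minus-strand
loci are reverse-complement aware throughout. Two deliberate choices:

* A variant that leaves only stop codons at a position truncates the
  protein there — the simplest biologically meaningful treatment.
* Triploid sites with three observed alleles enumerate all codon
  combinations; `X` appears whenever at least two distinct amino acids
  result, and all candidates are recorded.

## Specificity calling

`best_match()` scans each peptide against every protein of each
database at every ungapped offset. Tryptic peptides aligned to proteins
of their own locus never require gaps, which is why an exhaustive
ungapped scan can replace a heuristic aligner and makes scores exact
and reproducible. `X` in the subject is a provisional wildcard — an
ambiguous position, not a mismatch. Ties in identity resolve to the
smallest offset, then to locus id order, so results are deterministic.
Peptides matching several loci are evaluated per locus.

`resolve_ambiguity()` then asks the transcriptome which amino acid the
`X` really is: each candidate codon variant's allele depth is read from
the cultivar's VCF (for codons with several heterozygous sites, the
best-covered site speaks). The query residue is *present* when a
variant encoding it reaches `min_support` reads (default 5) and
`min_prop` of the site total (default 0.05); otherwise *absent*, which
counts as a mismatch. Real resolutions of this kind rest on hundreds or
thousands of supporting reads (the worked example in the test suite uses
1,558), far above any sensible floor; the defaults here are deliberately
conservative and configurable. A codon missing from the
VCF leaves the call unresolved rather than guessing.

A peptide is **specific** to a cultivar set S when it is exact or
ambiguous-present in all of S and mismatched or ambiguous-absent in at
least one other database; exact/present everywhere is **shared**.
Isoleucine and leucine are treated as distinct residues, but any I/L
mismatch is flagged (`il_mismatch`) because mass spectrometry cannot
distinguish them and users may wish to exclude those calls.

## Homeolog quantification

Variant records first pass the stated filters: mapping quality strictly
above 30, and SNP clusters (more than 2 SNPs in any 10-bp window)
dropped wholesale. `saap_codon_sites()` collects, for calls specific to
the ABB cultivar *alone*, the genomic sites whose alleles encode the
ABB-specific residue — from the ambiguity resolution for X-residues, and
for exact matches (typical of dominance loci, where the database holds a
plain homozygous B residue) from the mismatched residue's codon.
Restricting to ABB-alone calls matters: a peptide absent from just one
AAA database reflects a cultivar-private variant, and its supporting
allele would contaminate the B-read count with A-subgenome reads.

`attribute_reads()` pools depths over the control (0% PEG) replicates;
codons with several heterozygous sites contribute through the site with
maximal coverage, so one codon is never double-counted.
`binomial_test()` is the two-sided exact test (minimum-likelihood
method) against `p0 = 0.66` — kept at the printed two-decimal value
rather than 2/3, and configurable. After Benjamini–Hochberg adjustment,
`classify_bias()` applies: proportion exactly 1 or 0 is expression-level
dominance; adjusted p < 0.05 calls positive or negative bias by the side
of 0.66; everything else is balanced.

One subtlety the synthetic experiments exposed: summing reads over
*all* of a locus's nonsynonymous codons inflates the effective n to the
point where the 0.66-vs-2/3 rounding discrepancy itself becomes
significant and dosage-balanced loci are miscalled. Attribution is
therefore anchored on protein-evidenced SAAP codons (as in real data,
where only validated peptides contribute), and the recovery experiments
use one evidenced codon per locus.

## Quantitative selection

`fit_splsda()` is a from-scratch sparse PLS-DA: intensities are log2
transformed (missing values imputed as the feature minimum),
column-standardised, and the genomic constitution groups (ABB, AAAh,
AAA — the two AAA cultivars are distinct classes in the response but
pooled for specificity labels) are one-hot encoded and standardised.
Per component, the dominant singular direction of the cross-covariance
gives the feature weights; soft-thresholding keeps exactly `keep`
features (default 50), weights are renormalised to unit Euclidean norm,
and both matrices are deflated by regression on the component scores.
With `keep` equal to the feature count no thresholding occurs and the
fit coincides with dense PLS-DA (verified against an independent
implementation in the test suite). `orient_components()` fixes the sign
convention — ABB mean score negative — so ABB-specific features always
take negative component-1 loadings.

Selection combines three criteria, mirroring the printed rule: an
oriented component-1 loading beyond the cutoffs, a BH-adjusted
Kruskal–Wallis p below 0.01 across the genomic groups, and a compact
letter display (pairwise rank-sum tests at 0.05, letters in descending
median order) placing the ABB cultivar alone at the top or bottom. The
published cutoffs (−0.0125 and 0.0075) are properties of that study's
ion map and are kept only as defaults; for synthetic data the package
derives cutoffs from the loading scale itself, `±0.5/sqrt(keep)` — half
the magnitude an equal-weight unit-norm loading vector would give each
kept feature.

The control-vs-PEG response is tested per feature with two-group
Kruskal–Wallis tests inside the ABB cultivar and inside the pooled AAA
cultivars at α = 0.1, deliberately without multiplicity adjustment (the
screen is meant to be permissive); a locus is flagged when any of its
peptides responds. The
resulting per-feature false-positive rate is nominal-α by construction
and the test suite checks that calibration.

## GO enrichment

`fisher_enrichment()` performs one-sided Fisher exact tests of each
biological-process term among the selected (allele-specific) loci
against the identified-proteome background, reporting terms with
p < 0.05. No multiple-testing correction is applied by default —
matching the selection rule of the original analysis — but BH adjustment
and transitive ancestor propagation (given a child–parent edge table)
are available.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: divergence 1/39
per bp, an ABB plus two AAA cultivars, three biological replicates per
cultivar and treatment (0% and 5% PEG), and locus classes with true
B-proportions of exactly 2/3 (balanced), U(0.72, 0.95) (positive bias),
U(0.30, 0.60) (negative bias), 1 and 0 (dominance). The biased-class
ranges were fixed once, on a design power analysis: at 500 reads per
site and three control replicates they are separable from 0.66, while
balanced loci at 2/3 are not. Allele depths are multinomial draws per
replicate with Poisson site totals; dominance loci genuinely produce
zero reads for the silent allele. A configurable fraction of loci
(default 0.3) receives one forced nonsynonymous A/B difference placed
inside a tryptic peptide of 7–30 residues with a substitution avoiding
K, R and P, so that the planted positive class is detectable and both
variants share their cleavage context. Because at 1 SNP/39 bp nearly
every gene truly carries SAAPs, and what limits observed SAAP loci in
real experiments is MS undersampling, variant-spanning peptides of
non-forced loci are identified only with probability
`saap_detect_prob` (default 0.1).

The intensity panel defaults to 60 peptide ions with 20 ABB-specific
and 20 AAA-specific features shifted by 4 noise-sd (allelic ions in
real data behave close to presence/absence, so this is conservative).
The panel is deliberately compact: with three rank-test groups of six
samples the smallest attainable Kruskal–Wallis p is about 3×10⁻³, so
the Benjamini–Hochberg step retains power at α = 0.01 only while the
null block stays comparable in size to the planted blocks. The methods
tests use these sizes; recovery experiments for bias classes use 500
loci at depth 500, and the specificity recovery experiment 60 loci.

Not emulated: read-level alignment and its reference bias, intron
structure (loci are intron-free, so CDS coordinates map linearly to the
genome), spectral identification error (engine scores are decorative),
inter-run normalisation, and real GO topology (terms are synthetic with
one planted enrichment). Passing tests therefore demonstrate the
statistical machinery under the model's own assumptions, not robustness
to alignment or identification artefacts.

Recovery claims are scoped accordingly: a dominance-A locus expresses
no B protein, so no proteomic evidence of its B allele can exist — such
loci are excluded from specificity-recovery expectations (not from the
quantification, which classifies them correctly from their read
proportions when other evidence anchors the codon).

## Numerical and degenerate-input conventions

* "Above 100 reads", "mapping quality superior to 30": strict
  inequalities, read literally.
* Fully tied Kruskal–Wallis input returns H = 0, p = 1 rather than an
  error; zero-variance features are dropped from the sPLS-DA with a
  warning; loci with zero usable depth are excluded from attribution
  with a warning.
* All randomness flows from a single integer seed; reruns are
  byte-identical, and every tie-break (offsets, locus order, letter
  classes) is deterministic.

## A small worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run", seed = 1,
                       sim = sim_config(n_loci = 40, seed = 1),
                       lower_cut = "auto", upper_cut = "auto")
res <- run_all(cfg)
res$report
```

The report lists per-stage record counts: simulated loci and variant
records, database sizes, peptides surviving the read-count filter,
specificity calls and SAAP loci, bias-class counts, selected features,
PEG-differential loci, and the allele-specific locus union (SAAP loci ∪
quantitatively selected loci) that feeds the enrichment stage.
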