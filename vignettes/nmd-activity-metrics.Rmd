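---
title: "Measuring NMD activity from paired RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring NMD activity from paired RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdactivity)
```

## The problem

Nonsense-mediated mRNA decay (NMD) degrades transcripts carrying premature
termination codons (PTCs). Because NMD inhibition can expose tumor
neo-antigens, the *basal* NMD activity of a tumor matters: a tumor in which
NMD is already weak has little to gain from further inhibition. This package
estimates NMD activity per sample in a paired tumor/normal RNA-seq cohort and
asks, patient by patient, whether the tumor's NMD activity differs from its
matched normal tissue.

The estimand is never an absolute decay rate. Each read-out compares the
abundance of an NMD-*substrate* RNA species to a matched NMD-*immune*
reference, so stronger NMD means a *smaller* value:

* `R_mRNA = mE_NMD / median(mE_nonNMD)` — expression of an NMD target gene
  over the per-sample median expression of non-target genes.
* `R_isoform = sE_NMD / (sE_NMD + sE_nonNMD)` — the NMD-inducing splice
  form's share of a cassette-exon event's junction reads; bounded in [0, 1].
* `R_allele = aE_NMD / aE_nonNMD` — at a heterozygous nonsense SNV, reads
  from the PTC allele over reads from the wild-type allele of the *same*
  gene, the most internally controlled of the three.

Per patient, each metric's per-feature tumor/normal ratios are summarized by
their median and tested with a paired Wilcoxon signed-rank test; p-values are
BH-adjusted across the cohort (the adjustment family is the cohort within one
metric). A patient is called `lower`/`higher` only when significant *and* the
median ratio falls on the matching side of 1. Figures of this design are
sometimes captioned "paired Wilcoxon rank sum test"; a rank-sum test cannot
be paired, and the test implemented here is the signed-rank test.

## Which splice events are informative

Only cassette (exon-skipping) events are considered: a focal exon with two
flanking exons that are *constitutive* — every transcript of the gene that
overlaps a flank uses exactly the same boundaries. This guarantees the two
splice forms differ only in the focal exon, so a difference in NMD fate is
attributable to that exon alone. Intron retention and alternative splice
sites are out of scope.

NMD fate is decided by the classical last-junction rule: a stop codon whose
last base lies at least `threshold_nt` upstream of the final exon-exon
junction triggers NMD; stops in the last exon never do. The literature places
the boundary at 50-55 nt without an agreed operational cutoff, so
`threshold_nt` is a parameter (default 50, measured from the stop codon's
last base). Both splice forms are rebuilt from the *same* annotated CDS start
— taken from the longest-CDS transcript containing the exon trio — and an
event is kept only when exactly one form is an NMD substrate; it is labelled
with that form (`inclusion` or `exclusion`). No ORF inference is performed:
transcripts without an annotated CDS are never scanned, because annotation
CDS calls are curated and ORF calling would add an uncontrolled error source.
Codons containing `N` are never stops, and events with `N` in the scanned
region are discarded rather than guessed.

## Read-level filters

Junction reads supporting a splice form must pass three filters: mapping
quality at the unique-mapper threshold (default 50, TopHat2's sentinel;
implemented as `>=` with an exact-equality mode because other aligners use
other scales), at least 6 nt aligned on each side of the junction
(soft-clips do not count), and no mismatch or indel within 6 nt of any
junction the read spans (mismatches from the MD tag; without MD tags the
filter degrades to indel-only with a loud warning). Counts are deduplicated
by read name so a fragment counts once per form. An event enters a patient's
comparison only with more than 10 supporting reads in *both* tissues — so
the informative event set legitimately differs between patients; a
`shared_events_only` mode restricts to events informative in every patient.

Allele counts at PTC sites require total depth of at least 5 in both tissues
and both alleles seen in mapped reads. Whether "both alleles seen" applies
per tissue or pooled across the pair is ambiguous; the default is the
stricter per-tissue reading, with `scope = "pooled"` available.

## Target and non-target genes

R_mRNA needs a trusted list of NMD targets and a background of non-targets.
Evidence comes from four NMD-inhibition study types: two expression arrays
(gene fold change upon UPF1 knockdown), one mRNA-stability study (a boolean
"stabilized" call — its half-life criterion is not re-derivable from fold
changes, so it enters as a column), and one isoform-resolution RNA-seq study.
Genes absent from any study are excluded before classification. A gene is a
target when at least one study supports it (≥2-fold in an array, stabilized,
or an isoform ≥3-fold up and ≥5 FPKM); `support` counts supporting studies
and the working target set keeps `support >= 3` by default. A gene is a
non-target only when *every* study argues against targeting (<1.5-fold in
both arrays, not stabilized, all isoforms <2-fold). Genes meeting neither
rule are `unclassified` and enter neither set — using them anywhere would
dilute both the signal and the background.

## Numerical and degenerate-input policy

* Zero denominators are *excluded and counted*, never patched: an
  event/sample with zero total reads, a site with zero wild-type reads, a
  feature with zero normal-tissue value. Every exclusion shows up in the
  manifest so `kept + excluded = input` always reconciles. An optional
  pseudocount (0.5) is available for R_allele but off by default — the
  exclusion policy keeps the estimator unbiased at the cost of sites, and
  the accounting makes the cost visible.
* Wilcoxon zero differences are dropped (classical treatment; Pratt's
  method available); the exact null is used for n ≤ 25 untied pairs, the
  continuity-corrected normal approximation otherwise. Fewer than 6
  informative pairs returns p = 1 with a warning rather than pretending
  power exists.
* Expression is upper-quartile normalized (each sample divided by its 75th
  percentile, linear-interpolation quantile) after dropping genes with
  fewer than 10 reads in half or more of the samples. R_mRNA is invariant
  to any per-sample scale factor because the non-target median cancels it.
* Spearman correlations use average ranks; exact permutation p for n ≤ 10,
  t approximation otherwise; degenerate (constant) inputs yield `NA`, not
  an error.

## The synthetic cohort generator

Every upstream stage is testable without external data because the package
can generate a complete cohort with known ground truth. The generative model
ties everything to a per-sample NMD strength $\lambda$: the NMD-inducing
form of any feature is produced at the same rate as its NMD-free counterpart
but decays $\lambda k$ times faster ($k$ = the feature's NMD
susceptibility), so

$$E[R_{isoform}] = \frac{1}{1 + \lambda k}, \qquad
  E[R_{allele}] = \frac{c}{\lambda}, \qquad
  E[mE_{target}] \propto \frac{1}{\lambda},$$

with $c$ a baseline (NMD-independent) allelic imbalance. Tumor strength is
the matched normal's strength times a per-patient factor $f$, so
$\log(\text{median ratio})$ regressed on $\log(1/f)$ should have slope near
1 — the package's parameter-recovery check. Counts are negative binomial
(size 10) rather than Poisson so the paired tests see realistic
overdispersion.

Defaults emulate a 72-patient lung-adenocarcinoma-sized cohort: 50
high-confidence targets against 4074 background genes, 776 cassette events
with 68% triggering NMD on inclusion, 60 heterozygous PTC sites (few on
purpose — scarcity of nonsense SNVs is what limits R_allele in practice),
median NMD susceptibility $k = 12$ (lognormal, sdlog 0.35; NMD typically
depletes PTC+ isoforms by roughly an order of magnitude), mean junction
depth 60, allele depth 30, and per-patient factors $f$ lognormal(0, 0.3) —
most tumors near their normal baseline, some clearly shifted in either
direction. These were chosen once, from the generative arithmetic, before
any end-to-end measurement.

Annotation sequences use a small trick: exon bodies are drawn from the
{A,C,G} alphabet, in which no stop codon can arise in *any* reading frame,
and explicit ATG/TAA codons are planted where needed. Each event's NMD form
is therefore known by construction — including four-exon genes where
skipping a frame-shifting exon creates a downstream PTC (the
exclusion-triggers-NMD case) — and decoy genes (both forms NMD, neither
form NMD, non-constitutive flank) must yield no event. The SAM writer emits
clean junction reads plus contaminants each violating exactly one filter
(mapq 49, 5-nt overhang, mismatch 3 nt into the acceptor exon), so the
counter must recover planted clean totals *exactly*.

What the generator does **not** emulate: mapping ambiguity and alignment
artefacts (reads are planted at exact junctions), fragment-length and
positional coverage biases, FPKM estimation error (expression is NB counts
scaled by a library factor), cis-regulatory variation beyond a lognormal
allelic imbalance, and any coupling between the three feature classes within
a gene. Passing tests therefore demonstrate the *estimators and statistics*
are correct under the stated generative model — not that a real aligner's
output is bias-free.

## Validation summary

The test suite checks, among others: the stop-scanner and last-junction rule
against a codon-by-codon translation oracle on random transcripts (including
the exact 49/50 nt boundary); event discovery against an exhaustive
exon-triple enumeration; form classification against brute-force translation
of both rebuilt isoforms; strand-flip invariance of discovery; exact
recovery of planted clean junction-read counts; filter monotonicity; the
statistics against independent enumeration/closed-form oracles to 1e-8;
type-I error control on null cohorts (tumor strength = normal strength);
and recovery of planted strength factors with regression slope in
[0.8, 1.2] and power above 0.8 for two-fold shifts. Problem sizes used in
the heavier checks (e.g. 200 null cohorts of 72 patients for the type-I
check) were sized to give tight binomial bounds while keeping the suite
quick to run routinely.

## Known limitations

* uORF- and long-3'UTR-mediated NMD are not modeled; only the
  last-junction rule selects substrates.
* CDS annotations are trusted as-is; a wrong CDS start yields a wrong form
  call (mitigated by the longest-CDS choice).
* R_mRNA assumes target-gene expression changes are NMD-driven; indirect
  targets dilute it.
* Normalizing by the matched normal assumes normal-tissue NMD varies
  little between patients; a shifted normal shifts the patient's calls.
* The effector-correlation analysis is correlational; expression of the
  nine effectors (UPF1, UPF2, UPF3A, UPF3B, SMG1, SMG5, SMG6, SMG7, PNRC2)
  need not be the rate-limiting determinant of pathway activity.

## A compact worked run

```{r worked, eval = FALSE}
cfg <- simulation_config(n_patients = 24, strength_factors = rep(c(0.5, 1, 2), 8),
                         seed = 42)
sim <- simulate_counts(cfg)
events <- data.frame(event_id = names(sim$truth$nmd_form),
                     nmd_form = unname(sim$truth$nmd_form))
targets <- select_target_set(classify_genes(sim$evidence))
fit <- nmd_assess(sim$samples,
                  expression = sim$expression, raw_counts = sim$raw_counts,
                  target_set = targets,
                  event_counts = sim$event_counts, events = events,
                  allele_counts = sim$allele_counts,
                  effector_expr = sim$effector_expr)
summary(fit)
plot(fit)
```
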