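---
title: "Methods: identifying graft-mobile mRNAs from accession-diagnostic SNPs"
author: "graftmobile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying graft-mobile mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmobile)
```

## The problem

When two *Arabidopsis* accessions are surgically joined into a heterograft
(scion from one accession, rootstock from the other), some mRNAs cross the
graft junction. Because the accessions differ at hundreds of thousands of
single-nucleotide polymorphisms, a sequencing read carrying the *other*
accession's allele in a tissue is direct evidence that the transcript
travelled there. The difficulty is that sequencing errors also produce
foreign-looking alleles, at rates comparable to the signal from weakly
mobile transcripts. This package implements the complete decision pipeline:
building a trustworthy set of accession-diagnostic SNPs, separating genuine
foreign-allele reads from error with a Bayes factor anchored on homograft
controls, calling mobile transcripts and classifying when (under which
phosphate regimes) they move, asking whether they are ribosome-associated
in the recipient tissue (TRAP-seq), and characterizing the secondary
structure of their untranslated regions.

All stages run on synthetic data with known ground truth, generated by the
package itself, so every rule is testable at desk scale.

## Reference SNP construction

Candidate variants pass a fixed ladder; a record is attributed to the
*first* stage it fails, which makes audit logs reproducible (the order
itself is this package's choice — the four criteria are individually
standard):

1. **Hard filter** on the variant caller's annotations: fail if
   QD < 2.0, MQ < 40.0, FS > 60.0, SOR > 3.0 or DP < 10. Missing
   annotations are an error, never a silent pass.
2. **Support**: at least 10 reads in both the genomic and the RNA-seq data
   of both accessions (configurable `min_depth`).
3. **Genotype consistency**: every dataset of accession A reports one
   allele, every dataset of accession B the other, no sharing.
   Heterozygous calls and ambiguity codes fail — a diagnostic site must be
   fixed within each accession.
4. **Organelle exclusion**: mitochondrial and plastid contigs are removed
   because organellar RNA editing mimics SNPs.
5. **Biallelic check**: exactly one single-nucleotide alternative.

Relaxing any threshold can only grow the output (tested as a property).
On clean synthetic evidence the builder recovers the simulated truth set
with precision and recall 1.

## The Bayes-factor gate

At one site, let the heterograft show $k_1$ foreign-allele reads out of
$n_1$, and the matched homograft (same self genotype, tissue and
condition — a sample in which *no* read can genuinely be foreign) show
$k_2$ of $n_2$. Two models:

* $M_0$ (error only): both samples share one error rate
  $\theta \sim \mathrm{Beta}(a_0, b_0)$;
* $M_1$ (mobility): the homograft keeps its error rate while the
  heterograft has an independent foreign-read rate
  $\theta_{mob} \sim \mathrm{Beta}(a_1, b_1)$.

Both marginal likelihoods are beta-binomial, so the Bayes factor is exact:

$$
\mathrm{BF} = \frac{B(a_1+k_1,\, b_1+n_1-k_1)\,/\,B(a_1,b_1)\;\cdot\;
               B(a_0+k_2,\, b_0+n_2-k_2)\,/\,B(a_0,b_0)}
              {B(a_0+k_1+k_2,\, b_0+n_1+n_2-k_1-k_2)\,/\,B(a_0,b_0)}
$$

Sites pass with $\log_{10}\mathrm{BF} > 1$, a strict inequality. Priors
default to Beta(1, 1) and are configurable. The closed form is verified in
the tests against an independent numeric-quadrature oracle, and the
implementation is monotone in $k_1$ by construction.

Two choices here are the package's own:

* Replicates are **pooled** within a condition × tissue before the gate
  (the gate asks "is this site trustworthy here", a per-site question for
  which pooling maximizes power); detection afterwards is per replicate.
* A heterograft site with no matched homograft observation keeps
  $k_2 = n_2 = 0$; the gate then leans entirely on the prior, which is
  conservative.

One consequence of uniform priors worth knowing: when the heterograft
counts look exactly like the homograft's (say 1 of 200 vs 1 of 200), the
Bayes factor *actively favours* the shared-rate model
($\log_{10}\mathrm{BF} \approx -1.7$), because the uniform mobility prior
spreads its mass over implausibly large rates. That is correct behaviour
for a gate.

## Mobile calling, abundance, index and categories

Over the informative (gate-passing) sites of a transcript, foreign reads
are counted per biological replicate. A transcript is detected in a
condition and direction when **more than 3** foreign SNP reads appear in
**at least 2** replicates; both thresholds are arguments. The ">3 per
replicate" reading (rather than aggregate) is adopted and configurable.

*Mobile abundance* is foreign reads per million SNP-covering reads of the
same sample (the normalization scale is this package's choice; the index
below is insensitive to it as long as numerator and denominator use the
same scale). The *mobile index* (MI) is mean recipient mobile abundance
divided by mean donor-tissue local abundance, computed over the **same**
informative-site set so site composition cancels. For a transcript moving
in one direction, MI estimates the fraction of its reads in the recipient
that arrived by transport; for bidirectional transcripts the donor itself
loses local reads, so MI exceeds the one-way transfer ratio — the
simulation-recovery checks therefore compare MI to the simulated ratio on
unidirectional transcripts only.

Direction is read off the tissue: foreign reads in the root are
shoot-to-root transport, foreign reads in the shoot root-to-shoot;
transcripts detected both ways are reported in both direction tables.

Condition specificity partitions the detected-condition set over the four
phosphate regimes (`FP7D`, `NP3D`, `NP7D`, `NP7DRP2D`):

* **PSI-specific** — detected under starvation (NP3D/NP7D) only;
* **PSD-specific** — detected under sufficiency (FP7D/NP7DRP2D) only;
* **common** — at least one condition of each group;
* **other** — the empty set.

The "≥ 1 condition in a group" set logic matches an upset-diagram reading
of condition overlap; an "all conditions in the group" variant would be a
one-line change and is deliberately not the default.

## Translatome

TRAP-seq IP observations go through the *identical* informative-site and
detection thresholds as the RNA-seq. A mobile transcript detected in the
IP is classified translated, otherwise untranslated — operationalizing
"absent from TRAP-seq" as failing the same detection rule rather than
literal zero, which would be hostage to a single stray read.
Translational efficiency is TRAP abundance over RNA abundance on
identically normalized per-million scales; condition effects are reported
as log2 TE ratios, with 1.5-fold as the default "changed" convention
(the underlying studies state no test for this quantity).

## Expression

Normalization is median-of-ratios: per sample, the median over
all-positive genes of count / geometric row mean. This is the standard
size-factor construction and is cross-checked in the tests against an
independent implementation. Differential calls use the printed cutoff
semantics — status Up iff $\log_2\mathrm{FC} > 1$ and $P < 0.05$, Down for
the mirror — with fold-changes stabilized by a pseudocount of 1 and
$P$-values from a two-sided Welch test on log2(normalized + 1). This is a
deliberately simple, clearly-labelled stand-in for a full
negative-binomial framework: the pipeline's claims about differential
expression go no further than the cutoff rule, so nothing heavier is
warranted. $P$-values are unadjusted by default (`adjust = TRUE` applies
Benjamini-Hochberg).

## RNA structure

Folding is pluggable:

* **vienna** — the production backend; shells out to `RNAfold`
  (nearest-neighbor thermodynamic model, 37 °C, default parameters) and is
  the one to use for kcal/mol values comparable to published numbers.
* **basepair** — a self-contained dynamic program minimizing a simple
  additive energy: GC −3, AU −2, GU −1 per pair, −1 stacking bonus when a
  pair sits directly inside another, hairpin loops of at least 3 unpaired
  bases. It is not thermodynamically calibrated; its virtue is exact
  testability — the suite checks it equals an exhaustive enumeration of
  all structures on hundreds of short random sequences.

Region statistics report $\Delta G \le 0$ and $-\Delta G/\mathrm{nt} \ge 0$
separately; lower $-\Delta G/\mathrm{nt}$ means a less structured region.
Group comparisons use the two-sample Kolmogorov-Smirnov test (D is the
maximal ECDF separation; exact small-sample $P$, verified against full
permutation) and the two-sided Wilcoxon rank-sum test. The quartile layout
ranks $-\Delta G/\mathrm{nt}$ ascending and labels the lowest
$\lceil n/4 \rceil$ values `bottom25` (least structured), the highest
$\lceil n/4 \rceil$ `top25`, ties broken by identifier order so labels are
deterministic; per-stratum enrichment of a query set is upper-tail
hypergeometric.

## DMS reactivity

Dimethyl sulfate methylates unpaired A and C; mismatches introduced during
reverse transcription read the modification out, so raw reactivity is
mismatch/depth at A/C positions. Processing order is fixed and
order-sensitive (the tests include a crafted example where swapping steps
changes the result):

1. per-position mismatch/depth from aligned reads, discarding mismatches
   within 3 nt of an indel in the same read (depth still counts);
2. replicate QC: a replicate fails when > 90% of A/C rates are below 0.005
   while some position spikes to ≥ 0.05 — the PCR-jackpot signature; the
   three thresholds are concrete defaults for a qualitative exclusion rule
   and are configurable;
3. positionwise averaging of raw rates over passing replicates;
4. normalization by the median of the highest 5% of rates
   ($\lceil 0.05n \rceil$ positions, midpoint median for even subsets),
   then winsorization of values > 1.0 down to 1.0;
5. SHAPE-style export (−999 at non-A/C or no-data positions).

The per-position depth default (500) reflects targeted amplicon
sequencing. Agreement with a reference structure is summarized as the
ROC AUC of normalized reactivity separating unpaired from paired A/C.

## dCAPS genotyping

Graft tissues are genotype-verified in silico: virtual PCR (unique best
primer pair placement, ≤ 1 mismatch, 3'-terminal mismatches abolish
priming — the standard dCAPS convention) followed by virtual restriction
digestion (enzymes as recognition/cut-offset pairs; RsaI and BamHI built
in) and multiset matching of fragment lengths against expected
per-genotype patterns with a ±2 bp tolerance. Fragment lengths always sum
to the amplicon length, and zero or multiple pattern matches return
"ambiguous" rather than a guess.

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure the decision rules
rely on: two accessions fixed for different alleles at biallelic SNPs
inside annotated transcripts; organellar decoy SNPs; heterograft and
homograft samples over tissues × four phosphate regimes × replicates;
Poisson site depths scaled by log-normal expression; mobile transcripts
contributing foreign reads at a set rate only in their conditions and
directions; sequencing errors substituting uniformly over the three
non-self bases (so one third of errors mimic the foreign allele — the
paper-silent substitution model chosen here); TRAP IP as binomial thinning
with a hard zero for ribosome-free foreign transcripts; DMS mismatches
binomial with pairing-state rates.

It does **not** emulate read-length effects, alignment artifacts,
mapping bias between the two genomes, PCR duplication, overdispersion
beyond Poisson, RNA editing, or expression changes induced by grafting
itself. Passing tests therefore demonstrate that the decision rules are
implemented correctly and behave as designed under the assumed error
model — not that the thresholds are optimal for any particular real
dataset.

Default study-scale sizes (200 transcripts of mean length 1 kb, SNP
density 0.01/nt, 15% mobile at a 10% foreign-read rate, depth 50 per SNP,
error 0.2%, 3 replicates) were chosen once to mirror a desk-scale version
of the heterograft design: per-transcript foreign-read expectations sit
well above the detection threshold for mobile transcripts and well below
it for error-only ones. The mobile-index recovery scenarios use depth 100
(300 for the 2% transfer ratio) so that evaluated transcripts carry at
least 50 foreign reads, the regime where a ±20% recovery claim is
meaningful.

## Numerical choices and degenerate inputs

* Bayes factors are computed in log space via `lbeta`; `n_het = 0` yields
  `NA` and the site is non-informative.
* A donor-tissue local abundance of zero leaves the mobile index
  undefined (`NA`, with a warning), as does zero RNA abundance for TE.
* Median-of-ratios normalization errors when no gene is positive in all
  samples; the DMS normalizer errors on an all-zero profile.
* Quartile boundaries use $\lceil n/4 \rceil$ ranks; ties break by id.
* All generators restore the caller's RNG state; identical seeds give
  byte-identical outputs.

## Known limitations

* The homograft-anchored Bayes gate assumes the homograft error process
  matches the heterograft's; mapping-bias differences between genomes
  would violate this and are not modelled.
* MI for bidirectional transcripts is not a transfer ratio (see above).
* The basepair folding backend's energies are on an arbitrary scale;
  only the vienna backend yields kcal/mol comparable across studies.
* The DE stand-in has no dispersion shrinkage and is underpowered at
  n = 3; it exists to express the cutoff rule, not to replace a dedicated
  DE framework.
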