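---
title: "Methods: quantifying retrograde- and light-controlled alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retrograde- and light-controlled alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosplice)
```

## The problem

Chloroplast-to-nucleus (retrograde) signals — triggered experimentally
with norflurazon or lincomycin — reprogram the nuclear transcriptome of
Arabidopsis seedlings, largely through the chloroplast protein GUN1, and
converge antagonistically with light signaling. Beyond transcription,
these signals also reshape alternative splicing (AS): junction-level PSI
(percent spliced in) of retained introns (IR), skipped exons (ES) and
alternative 5'/3' splice sites (ALT5/ALT3) shifts under treatment, and
many of the induced isoforms carry premature termination codons (PTCs)
that commit them to nonsense-mediated decay (NMD). The coupled outcome —
"repressive" AS events — lowers the productive mRNA output of the host
gene, preferentially for chloroplast-protein genes.

`retrosplice` implements the full analysis chain for this kind of study:
PSI quantification from junction reads with coverage tiers, a
threshold-based differential caller with the standard filter cascade, a
percent-of-response statistic for attenuated genotypes, isoform
reconstruction with PTC detection under the 50-nt rule, regulatory
feature comparison, and the convergence statistics (Fisher enrichment,
Kruskal–Wallis letter displays, NMD-shift and light-antagonism
summaries). Because the original deposited read data are not required,
a synthetic-data generator reproduces the statistical structure of the
study designs so the whole pipeline is testable end to end.

## Quantification model

For every AS event, per-sample PSI is estimated from junction-spanning
reads only:

$$\mathrm{PSI} = 100\,\frac{I}{I+E}$$

where $I$ counts inclusion-supporting junction reads and $E$
exclusion-supporting (exon–exon) reads. For IR events, $I$ is the mean
of the two exon–intron junction counts; an event whose two exon–intron
junctions are significantly imbalanced (two-sided exact binomial test at
$P < 0.05$) is treated as unreliable and discarded. PSI is undefined —
never zero — when $I+E=0$, so missing coverage cannot masquerade as a
splicing change.

Each estimate carries a coverage tier derived from $I+E$ (defaults:
`N` < 5 reads, `VLOW` 5–9, `LOW` 10–14, `OK` 15–99, `SOK` ≥ 100). The
exact band edges are package defaults exposed in the configuration; only
the discard behaviour matters downstream: the differential caller drops
events tiered `N` or `VLOW` in either compared sample. To raise
coverage, replicates of a condition are pooled — counts are summed and
PSI/tier recomputed — rather than averaging per-replicate PSIs, which
would weight low-coverage replicates equally.

Gene expression uses cRPKM (reads per million mapped, corrected by the
number of uniquely mappable positions), quantile-normalized across the
compared samples (`limma::normalizeQuantiles`, ties averaged).

## The differential callers

An event is called differentially spliced between two merged samples iff

1. its tier is at least `LOW` in both samples,
2. (IR only) the junction-balance test passes in both samples,
3. (ALT5/ALT3 only) the host exon has PSI ≥ 25 in both samples
   (inclusive), and
4. $|\Delta\mathrm{PSI}| > 15$ — strictly; an event at exactly 15 counts
   as a non-regulated control.

Events passing 1–3 but not 4 form the control set for every downstream
contrast. No multiple-testing correction is applied anywhere: the
procedure is threshold-based by design, and the package makes no FDR
claim.

A gene is called differentially expressed iff it survives the joint
expression filter and shows a fold change of at least 2, in a consistent
direction, between **every** cross-sample replicate pair (computed on
normalized cRPKM with pseudocount 1; the pseudocount is a package
choice, exposed in the configuration). The joint filter sentence ("read
counts < 50 and not expressed at cRPKM > 5 across all replicates of at
least one sample") admits two parses; the package keeps a gene iff at
least one sample has *every* replicate passing (count ≥ 50 **or**
cRPKM > 5), and offers the alternate parse (`any_sample_all_fail`) in
the configuration. Both are covered by tests; the default was chosen as
the stricter, more conservative reading.

The attenuation of a mutant genotype is summarized as the percent of
response, $R = 100\,\Delta_{mut}/\Delta_{wt}$ per event or gene (ΔPSI or
log2 fold change), reported as median and mean over called items; items
with $\Delta_{wt}=0$ are excluded rather than clipped, and over-reversal
($R<0$) is preserved.

## ORF impact and the 50-nt rule

For each event the package reconstructs both isoforms from the gene
model and genome sequence (minus-strand genes are handled in transcript
orientation), translates from the annotated start codon to the first
in-frame stop, and classifies the stop as premature iff an exon–exon
junction lies **at least 50 nt** downstream of the stop codon's last
nucleotide (inclusive: exactly 50 triggers). Any downstream junction
qualifies by default; the classical last-junction variant is selectable
and equivalent for a single stop. Transcripts with no in-frame stop are
flagged nonstop, not PTC.

The three-way category follows: `unproductive_on_inclusion` iff only the
inclusion isoform carries a PTC, `unproductive_on_exclusion` iff only
the exclusion isoform does, `protein_isoform` iff neither; both-PTC
events are recorded as degenerate and excluded from category
percentages. Only CDS-located events receive a category — the UTR-located
ones are classified by region only. Events straddling a CDS boundary are
assigned to CDS. A 3'UTR event whose splicing would leave a junction
≥ 50 nt downstream of the reference stop would render the reference
itself NMD-sensitive; the generator avoids such configurations and the
classifier flags them (`utr3_ptc_flag`).

A called event is **repressive** when its direction of change increases
the unproductive isoform: up-regulation of an
`unproductive_on_inclusion` event, or down-regulation of an
`unproductive_on_exclusion` event.

## Regulatory features and splice-site strength

For regulated vs control introns/exons the package compares: length of
the alternative sequence and of its upstream/downstream exons and
introns (transcript orientation; a missing flank is NA, never 0), GC
fractions, and splice-site strengths S5/S3. Strength is the sum of
per-position log2 odds over a position weight matrix trained on the
annotation's constitutive donor (3 exonic + 6 intronic nt) and acceptor
(20 intronic + 3 exonic nt) windows, with pseudocount 0.5 against the
genome's background base composition. This replaces the maximum-entropy
scoring of the dedicated feature tools, which the source studies use as
a black box: a PWM preserves the ordinal weaker/stronger semantics the
comparisons rely on while remaining fully self-contained. Which sites
are scored is stated explicitly per type: IR uses the retained intron's
own donor and acceptor; ES the skipped exon's downstream donor and
upstream acceptor; ALT5 the distal (inclusion) donor plus the shared
acceptor; ALT3 the shared donor plus the proximal (inclusion) acceptor.
Group comparisons use group medians and two-sided Mann–Whitney tests at
$P<0.05$, uncorrected across the ~10 features, matching the per-test
semantics of the figure-style summaries.

## Convergence statistics

Enrichment questions are asked as exact two-sided Fisher tests on 2×2
tables over an **explicit** universe; the default universe is the
coverage-passing non-regulated set plus the regulated set (the same
construction as the control sets), with an override in every call. The
odds ratio reported is the sample ratio $ad/bc$ (undefined with a zero
margin, in which case $p=1$). Gene-ontology enrichment against live
annotation services is out of scope; the same Fisher machinery runs over
user-supplied gene→category tables (e.g. subcellular localization), with
unknown-localization genes removable from the universe.

Multi-group PSI comparisons use the tie-corrected Kruskal–Wallis test;
when the omnibus test is significant at 0.05, pairwise two-sided
Mann–Whitney tests (Dunn's z-test selectable) with Holm adjustment drive
a compact letter display built by insert-and-absorb; groups sharing a
letter are not pairwise distinguishable. The letter partition is
invariant to group order (groups are canonicalized by name before
testing).

The NMD analysis contrasts repressive-event PSI between the wild type
and each upf-like genotype with unpaired two-sided Mann–Whitney tests
(per the conventions of the source figure legends), with
protein-isoform events as the negative control. The light-antagonism
summary reports, per NF-direction class, the median light-vs-dark ΔPSI,
the fraction of events whose light shift opposes the NF sign, and
letters across {WT-light, pifq-dark, pifq-light} against a same-condition
null ΔPSI built by splitting the dark-grown WT replicates into two merged
halves.

## The synthetic-data generator

The generator is first-class, tested code: every downstream stage reads
only its emitted files, and the planted truth is consulted only for
scoring. One AS event is planted per gene in a multi-exon model laid out
on both strands of a toy genome.

**What is planted.** Condition structure mirrors the four experimental
series: control/NF/lincomycin in WT and a gun1-like genotype
(retrograde factor $r$, default 0.5 — "around half of the WT response"),
a dark/light grid in WT and a pifq-like genotype (dark-grown pifq mimics
light), and an untreated NMD series (WT, upf1-, upf3-, upf1upf3-like
with NMD efficiencies 1/0.3/0.5/0). True PSI follows
$\psi = \psi_0 + s\,\delta\,r$ under retrograde treatment
($\delta = 30$ PSI points, $s \in \{-1,0,+1\}$) and
$\psi = \psi_0 - s\,\delta\,\lambda$ for light-antagonistic events in the
light series ($\lambda = 1$); values are clipped to $[0,100]$ with a
logged warning count. The light term applies only within the light
series: the experimental series are separate batches, as in the
underlying designs. The paper-stated couplings are planted rather than
independent draws: regulated IR events are predominantly up-regulated
(0.8), and a regulated CDS event's category is drawn as
direction-aligned-unproductive / protein / direction-opposed (0.67 /
0.25 / 0.08) so that repressive events dominate the regulated set.
Combinations that cannot be constructed — an exclusion-unproductive IR
or ALT event, whose exclusion isoform *is* the clean reference — fall
back to `protein_isoform`.

**Sequence guarantees.** Transcribed sequence is generated T-free
outside planted elements (start codon, terminal stop, planted PTCs, GT
donor dinucleotides). Since every stop codon contains T, the only
in-frame stops in any isoform and any reading frame are the planted
ones, which is what lets the generator *guarantee* each event's ORF
impact: a planted unproductive-on-inclusion event carries an in-frame
TAA in its alternative sequence at least 50 nt upstream of a downstream
junction of the inclusion isoform; ES exclusion-unproductive genes use a
50-nt poison-skippable exon whose removal shifts the frame onto a stop
planted out-of-frame in the next exon (which is 151 nt so the inclusion
CDS stays a codon multiple). Exon/intron chunk lengths are codon
multiples so splice junctions sit at phase 0, which keeps planted stops
codon-aligned by construction. Full-consensus GTAAGT donors appear only
in introns that are never transcribed into any isoform; AS introns use
T-free donor variants ("strong" consensus-like vs "weak" C/G-only),
with weak donors and 3× lengths planted on up-regulated retained introns
to provide the recoverable regulatory-feature signal.

**Read sampling.** Per event, replicate and condition, total informative
reads are Poisson at the configured depth (500 by default; a Gamma
overdispersion knob exists and defaults to off), inclusion reads are
binomial at the *effective* PSI after NMD steady-state decay — the
abundance of a PTC-bearing isoform is multiplied by $(1-d\eta)$ with
decay fraction $d = 0.8$ and the condition's NMD efficiency $\eta$
before the ratio is formed. IR inclusion support is observed at the two
exon–intron junctions as a symmetric binomial split of twice the
support, so the junction mean equals the support exactly and the PSI
estimator stays consistent while the balance test sees a
Binomial($n$, 0.5) draw. Gene counts are Poisson around baseline
expression (lognormal, cRPKM scale) × planted transcriptional fold
change (4-fold for NF-responsive genes, attenuated by $r$) × the
PSI-weighted NMD survival factor × mappable length × library size.
Repressive-event genes receive elevated probabilities of transcriptional
down-regulation (0.5 vs 0.1) and of chloroplast localization (0.55 vs
0.20), planting the expression and localization enrichments the
statistics stage recovers.

**What it does not emulate.** No read sequences, alignment or
mappability structure (mappable length is an annotation field); no
overdispersion by default; one AS event per gene; UTR-located events are
IR-only; host-exon inclusion of ALT events is condition-independent;
splice-site strength differences are two-class rather than continuous.
Passing tests therefore demonstrate that the analysis recovers planted
effects through the full filter cascade under the stated sampling model —
not that the pipeline is robust to alignment artifacts, overdispersed
libraries or annotation errors in real data.

## Numerical choices and problem sizes

Coordinates are 1-based inclusive throughout (Bioconductor convention);
GTF emission is direct. PTC distance is measured from the stop codon's
last nucleotide, inclusive at 50. Degenerate inputs are defined rather
than accidental: zero junction coverage gives NA PSI and tier `N`; a
zero-total balance test is inapplicable and retains the event; a
zero-margin Fisher table reports an undefined odds ratio with $p=1$;
all-identical Kruskal–Wallis groups give $H=0$, $p=1$, one letter.
Determinism is part of the contract: a seed fixes annotation, truth and
counts byte-for-byte, and the pipeline summary is reproducible.

The shipped study size is 300 genes/events, 3 replicates, depth 500,
12 conditions — large enough that every planted contrast is recoverable
with comfortable test margins (the recovery checks complete in about a
minute), small enough to iterate on. The junction-balance calibration
check uses 10,000 simulated balanced IR records; the classifier/oracle
equivalence check uses 200 generated genes.

## Known limitations

The caller is deliberately threshold-based on merged samples — no
replicate-aware beta-binomial model of ΔPSI, no FDR control — because
the procedure under study is itself threshold-based. The recovery rate
of planted regulated events is bounded above by three structural
losses that are properties of the procedure, not defects: the
junction-balance test discards its nominal ~5% of genuinely balanced IR
events per compared sample; ALT events planted with a lowly included
host exon (10% of ALT events by default) are designed to be filtered;
and NMD decay compresses observed ΔPSI for the (rare) direction-opposed
unproductive classes. EM-based isoform estimation, transcript-level
TPM, uORF analysis, start-codon reselection, branch-point or
secondary-structure features, and live GO services are out of scope.
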