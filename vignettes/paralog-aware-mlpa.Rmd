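---
title: "Paralog-aware MLPA dosage analysis at the PMS2/PMS2CL locus"
author: "paralogMLPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-aware MLPA dosage analysis at the PMS2/PMS2CL locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogMLPA)
```

## The problem

*PMS2*, a mismatch-repair gene on 7p22 whose heterozygous germline mutations
cause Lynch syndrome, sits ~0.7 Mb from its transcribed pseudogene *PMS2CL*,
the product of an inverted ~100-kb segmental duplication covering exons
9--15 (minus a 2.7-kb block containing exon 10). Ongoing recombination
between the duplicons has homogenised their 3' ends and produces *hybrid
alleles*: physical gene copies carrying pseudogene-derived tracts and vice
versa. Such hybrids are common (roughly 70% of individuals of European
ancestry carry at least one) and the vast majority are clinically silent,
because pseudogene-derived coding differences downstream of exon 12 are
synonymous (with one known missense exception in exon 14). The same
homogenisation, however, defeats naive sequence- and dosage-based assays:
a gene-specific probe cannot tell whether a "missing" gene copy reflects a
deletion or merely a nondeleterious hybrid, and a deleterious hybrid
accompanied by its reciprocal partner restores perfectly balanced dosage.

Multiplex ligation-dependent probe amplification (MLPA) addresses this with
paralog-discriminating probes: probes whose ligation site covers a
paralogous sequence variant (PSV) and therefore binds only the gene or only
the pseudogene version of a shared exon, complemented by nonspecific
(universal) probes that count both. This package implements the full
interpretation layer for such an assay: reference qualification, integer
dosage calling, combinatorial genotype deduction, PSV-level breakpoint
mapping, and an in-silico allele-specific PCR (ASP) that resolves the
dosage blind spot.

## The locus model

A `LocusMap` holds the probe sites (24 gene-specific over exons 1--15, 5
pseudogene-specific and 5 universal over the exon 11--15 shared region,
plus 11 off-locus reference probes), the PSV catalog, and the duplicon
geometry. Every locus probe receives a transcript-ordered integer *rank*;
all positional logic runs on ranks or on a numeric HGVS order key, so
intronic offsets such as `c.1145-942` (942 nt upstream of the first base of
exon 11) compare correctly against coding and 3'UTR positions. Inclusive
spans are computed only where the coordinates themselves carry the
distance: two coding positions, or two offsets anchored to the same exon
boundary. The published anchors -- the exon-11 ligation site
`c.1360_1361`, the intron-12 discriminating sites
`c.2174+1097_2174+1099`, the five intron-10 PSV positions, the exon-11
frameshift PSVs, the exon-14 missense PSV and the 3'UTR duplication -- are
encoded exactly; the remaining exon boundaries, ligation positions and
three intron-10 flanking PSVs are synthetic placeholders (marked as such in
the fixture) chosen to be consistent with those anchors.

A `Haplotype` is a mosaic of gene-/pseudogene-origin segments over the rank
axis with at most one origin transition (the crossover model), optional
deletions (gene locus only), and optional sub-probe structure: a breakpoint
region bounded by two HGVS anchors plus explicit per-PSV origins inside it,
the footprint left by double-Holliday-junction resolution. Gene-conversion
haplotypes relax the single-transition rule at PSV resolution through the
same fine map. A `DiploidGenotype` carries two haplotypes per locus; its
noise-free copy vector counts, per probe, the haplotypes that cover the
site with a matching origin (universal probes count both origins). Because
the pseudogene lacks exon 10 and all exon-10 probes are gene-specific,
pseudogene-origin segments contribute nothing there by construction.

## Signal model and dosage calling

Raw signals follow the assay's ratio semantics: `100 * copies/reference *
exp(N(0, sigma))`, with reference copies 2 for specific and reference
probes and 4 for universal probes. The multiplicative lognormal noise
(default `sigma = 0.05`, per-probe independent) is a deliberate
simplification -- the real assay also shows fragment-length trends and
inter-run batch effects, which are out of scope.

Normalisation is two-stage. Intra-sample scaling divides by the mean of the
reference-probe signals; these off-locus controls are always two copies, so
the most efficient estimator is appropriate. (For maps without reference
probes the fallback is the median over all probes, which resists a single
aberrant region -- but note that a whole-gene deletion halves more than
half of the locus probes, which is exactly why reference probes exist.)
The scaled signal is then divided by the panel mean of the same quantity,
so 0.5 at a specific probe means one copy, 1.5 means three, and 0.75 at a
universal probe means three of four.

Integer calls are `round(relative * reference_copies)` with two abstention
gates, both tunable in `callCopyNumbers()`:

* **band** (default 0.15 on the relative-signal scale): estimates further
  than `band * reference_copies` from the nearest integer are NO_CALL.
  At `sigma = 0.05` the post-normalisation noise SD is about 0.055; a
  band of 0.1 would abstain on ~8% of probes per sample and make most true
  2:2 reference candidates indeterminate, while 0.15 abstains well under
  1% per specific probe and leaves miscalls beyond 4 SD.
* **margin** (default 0.1 copies): estimates within `margin` of the
  midpoint between two integers are NO_CALL. This gate matters only for
  universal probes, where `band * 4 = 0.6` exceeds the 0.5-copy rounding
  half-width: without it, a universal estimate drifting past 3.5 would
  miscall rather than abstain. With the margin, wrong integer calls
  require a >3 SD excursion and the pipeline prefers abstention, which
  the genotype enumeration treats as an unconstrained site.

Accuracy statements in the tests are therefore over calls made:
abstentions are reported (and stay around 2% of probes at the default
settings) but are not errors.

## Reference qualification and panel construction

Copy numbers are only as good as the reference panel: a panel whose members
carry unbalanced hybrid configurations biases every downstream quotient.
A reference DNA qualifies iff every paralog-discriminating probe site in
the exon 11--15 region calls exactly two copies (`qcReference()`); a
NO_CALL there yields a distinct *indeterminate* verdict. Qualification
itself needs normalised signals, so `buildPanel()` bootstraps: candidates
are scaled, normalised against the candidate-cohort median (resistant to
the sites where more than a third of candidates deviate, as exons 13--15
routinely do under the hybrid population), called and qualified; the
cohort statistic is then recomputed as the plain mean over the surviving
members and the loop repeats until stable. The panel is the first five
qualified candidates, mirroring the assay's five-references-per-run
practice. With roughly a third of candidates expected to qualify, a batch
of 24 occasionally yields fewer than five; that is a genuine failure mode
of the workflow and is raised as a typed error rather than patched over.

Balanced hybrid pairs (a deleterious hybrid plus its reciprocal) pass the
2:2 criterion -- the assay's documented blind spot, flagged in the verdict
notes and resolved only by the ASP check below.

## Genotype enumeration

`enumerateGenotypes()` searches the bounded configuration space in which
each of the four haplotypes carries at most one event: a single origin
breakpoint (gene-locus breakpoints restricted to the duplicon homology,
exon 9 onward), or -- at the gene locus -- one contiguous deletion.
Deletions exist at assay granularity only: an event is defined by the
detectable sites it silences, so intervals start and end on sites the
haplotype contributes to. This keeps the space free of dosage-invisible
phantom states (a "deletion" covering only a pseudogene-probe ligation
region would be indistinguishable from no event at every probe).

A configuration is a solution when its noise-free copy vector equals the
called profile at every called site; NO_CALL sites are wildcards. The
implementation prunes states that overshoot the target or leave an
uncoverable deficit, then matches gene-pair sums against a hash of
pseudogene-pair sums (a two-part base-5 key over the called sites, exact in
double precision); a property test verifies set-level equality with a
quadruple-loop generate-and-filter oracle on a reduced locus. Solutions
are ranked by total event count, ties broken by fewer deleterious alleles
and then by a lexicographic encoding, so reports are deterministic; an
empty set is reported as *uninterpretable*.

Classification of a solution set follows parsimony with an explicit
ambiguity rule: *deleterious* when every minimal-event solution carries a
deleterious gene-locus allele (whole-gene deletion, exon deletion, or a
hybrid whose pseudogene tract reaches exon 11 or starts 5' of exon 10);
*ambiguous* when solutions disagree; *normal* when none is deleterious.
Because a deleterious hybrid stacked with its reciprocal partner can be
added to *any* genotype without changing dosage, every profile admits some
deeper deleterious solution; `interpretSample()` therefore reports the
class of the parsimonious solutions and, when deleteriousness enters only
through such dosage-equivalent stacked configurations, returns *normal*
with `maskingPossible = TRUE` and recommends the allele-specific PCR --
the same follow-up the assay's designers applied to their unresolved
patients. Deletions are modelled at the gene locus only and mosaicism
(non-integer copies) is unsupported; both are documented limitations.

## Breakpoint mapping and in-silico ASP

`mapBreakpoint()` reduces an ordered PSV origin readout to a breakpoint
call: the 5' anchor is the last position at or upstream of which all PSVs
carry the upstream origin (inclusive), the 3' anchor the first position at
or downstream of which all carry the downstream origin (inclusive);
interior PSVs may interleave. The mechanism is *crossover* when the
readout starts and ends with different origins (durable switch),
*conversion_tract* when a discordant run is flanked by the same origin on
both sides, and *none* when all origins agree (anchors are then NA, not an
error). Region length is the inclusive HGVS span, which for the packaged
intron-10 readout is 153 bp with three interior PSVs.

`insilicoASP()` applies origin logic, not thermodynamics: the
allele-specific product appears iff one haplotype carries the required
origin at both primer sites (gene at the forward site, pseudogene at the
reverse site for the packaged intron-10 assay); product lengths (239 bp,
696-bp control) are assay constants. Under the population model hybrid
tracts start 3' of exon 12, so no background genotype can place a
gene-to-pseudogene switch inside intron 10 and the screen's specificity is
structural -- the tests confirm zero positives over 10,000 background
draws, and the control product (exon-15 nonspecific primers) amplifies in
every genotype that retains any exon-15 template.

`boundDeletion()` performs the interval arithmetic for array-probe tracks:
innermost (last-deleted minus first-deleted) and outermost
(flanking-retained) size bounds plus the two breakpoint-containing
intervals, with one-sided runs flagged. Whether a reported "~125 kb" is
the minimal or a midpoint figure is unknowable from a probe track, so both
bounds are always reported. `expectedGenerations()` is the recombination
clock: the reciprocal of the per-meiosis recombination fraction
`distance_Mb * rate_cM_per_Mb / 100`, valid under the small-interval
approximation (refused at >= 50 cM) and returned unrounded (0.7 Mb at
1.1 cM/Mb gives 129.87..., conventionally quoted as ~130 generations).

## The synthetic cohort

The generator supplies everything the original study obtained from
patients and repository DNAs. The population model draws each of the four
haplotypes independently as a nondeleterious hybrid with probability
`q = 1 - (1 - 0.70)^(1/4)` (approximately 0.26), so the carrier fraction
converges to the 70% figure; tract starts are confined to the boundaries
3' of exon 12 (intron 12, exon 13, exon 14, exon 15), with the
exon-14-covering classes weighted to a 0.10 allele fraction among each
locus's haplotypes (the published population range for the exon-14
missense hybrid is 4--25%) and the remainder on the exon-15-only class.
Both parameters are tunable in `PopulationModel()`. The three patient
archetypes are fixed constructions: `CH8` (whole-gene deletion plus two
gene-origin-E13--E15 hybrid pseudogene alleles), `CH11` (exon-8 deletion)
and `TR13` (the intron-10 crossover hybrid with its complex nondeleterious
companions); `TR13_MASKED` adds the reciprocal hybrid instead, producing a
copy vector identical to normal at every probe.

What the generator does *not* emulate: electrophoresis and fragment-size
effects, inter-run batch structure, PCR kinetics, sequencing errors in PSV
readouts, mosaicism, pseudogene-locus deletions, and rare 5'-of-exon-12
hybrids in the background population (these are only ever injected
deliberately as archetypes). Passing tests therefore demonstrate the
interpretation logic under the stated noise model, not robustness to every
artefact of real capillary data.

## Problem sizes and determinism

The shipped tests run the conservation property over 1,000 random
genotypes, the carrier-frequency check over 10,000 draws, oracle
equivalence over 200 random profiles on a reduced seven-site locus,
calibration over 1,000 simulated samples, genotype recovery over 500
simulated samples, ASP specificity over 10,000 background genotypes, and
cohort runs of 13 samples with 24 reference candidates -- sizes chosen so
the whole suite completes in a few minutes while keeping binomial noise
well inside the asserted margins. All generators take explicit seeds;
`runCohort()` seeds the entire pipeline once and restores the session RNG
state, and identical seeds reproduce byte-identical signal tables and
reports. Test panels follow the practical acquisition workflow: candidate
batches of 24 are drawn until five qualify, since a batch with fewer than
five true 2:2 samples cannot support the assay at all.
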