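---
title: "Star-allele diplotype calling for CYP2D6 and CYP2C19"
author: "stardiplo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele diplotype calling for CYP2D6 and CYP2C19}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stardiplo)
```

## The problem

*CYP2D6* sits on chromosome 22 next to its highly homologous pseudogene
*CYP2D7*, and the locus recombines readily: whole-gene deletions (the \*5
allele), tandem duplications and multiplications (xN), and fusion genes
that are part *CYP2D7*, part *CYP2D6* (*CYP2D7–2D6* hybrids such as \*13;
*CYP2D6–2D7* hybrids such as \*36, \*68 and \*4.013), sometimes in cis with
a full gene ("hybrid tandems" such as \*13 + \*2 or \*36 + \*10). Clinical
genotyping platforms interrogate a panel of single-nucleotide variants as
categories (WT/HET/MUT) and a handful of copy-number probes; none of them
observes a phased sequence. *CYP2C19* is simpler (SNV-defined haplotypes
\*2–\*10 and \*17) but platforms differ in which haplotypes they can see at
all.

`stardiplo` turns these partial, per-platform observations into ranked
diplotype calls, cross-platform consensus genotypes with an evidence
trail, metabolizer phenotypes, and a recommended next assay.

## The data model

A `HaplotypeTable` holds one row per star allele: a variant-state vector
over the registered panel sites (states `ref`, `var`, or undefined — e.g.
sequence on the *CYP2D7*-derived side of a hybrid), a structural class
(full gene, deletion, or hybrid with a switch interval), known in-cis
tandem partners, and an activity value. Site identity is canonical: rsIDs
where they exist, otherwise a normalized legacy label, with both legacy
numbering dialects (e.g. "2850C>T" and "2851C>T") registered as aliases of
one site, because published tables mix the two spellings. The shipped
tables are ordinary TSV files parsed by `parseHaplotypeTable()`; users can
replace or extend them, including the activity column — only the \*13 = 0
and reference \*1 = 1 values are treated as fixed points by the test suite.
Translation tables here have no size limit, so the multi-file workarounds
that some vendor translator software forces are unnecessary.

A `PlatformPanel` records what each of the six supported technologies can
see: assayed sites, distinguishable star alleles, CNV probe regions, and
flags for hybrid, deletion and duplication detection. The AmpliChip panel
encodes exactly the 32 *CYP2D6* variant haplotypes that assay reported and
only \*2/\*3 for *CYP2C19*; the Luminex panel covers \*2–\*12 (with \*5),
\*14–\*41 content plus the hybrid haplotypes its translator can derive; the
TaqMan panel carries the three CNV probe assays (intron 2, intron 6,
exon 9) and the SNV assay set. Where a platform's exact site list is not
public (AmpliSeq's "20 *CYP2D6* and 11 *CYP2C19* variants"), the panel
encodes a defensible subset of the registry and says so in its metadata.

## Copy-number model

Each gene unit contributes to each probe region: a full gene 1 copy
everywhere, a deletion 0, a hybrid 1 exactly on its *CYP2D6*-derived side
of the switch interval (ordered 5'→3': five_prime_flank < intron2 <
intron6 < exon9 < three_prime_flank). The forward model sums
contributions:

```{r}
d6 <- builtinHaplotypeTable("CYP2D6")
cnvCalls(expectedCnv("*13 + *4/*5", d6))    # 1, 2, 2
cnvCalls(expectedCnv("*36x2 + *10/*1", d6)) # 4, 4, 2: CYP2D7-derived exon 9
```

The inverse classifier merges all platforms' usable region calls into one
5'→3' map (calls with confidence below 0.95 are flagged and excluded,
mirroring the two-probe screening rule with the third probe consulted on
inequality) and reads off the hypothesis: flat = standard/deletion/xN;
rising = *CYP2D7–2D6* hybrid with the switch between the last lower-call
and first higher-call region; falling = the reverse. Platforms
contradicting each other on a shared region produce a `conflict`
hypothesis that retains both readings — conflicts are never voted away;
the workflow converts them into repeat/confirm actions.

## Calling diplotypes from categories

Multiplex assays report categories, not allele dosages, so consistency is
defined by presence semantics: at every non-NOCALL site, HET holds iff
some unit carries the variant and some the reference; MUT iff variant
only; WT iff reference only. Deletion units carry neither allele, so a
\*X/\*5 sample is hemizygous (WT or MUT, never HET), and with three or
more copies HET only means "both alleles present somewhere" — dosage is
deliberately delegated to phasing. The enumerator generates every
chromosome configuration up to the unit budget (single stars ×1–3, the
deletion alone, hybrids ×1–2, hybrid + full tandems), keeps pairs whose
expected CNV matches the observed vectors and whose carriers satisfy the
categories, and ranks by (structural events, novel tandem, name). The
default `maxUnits = 4` covers \*13 + \*2 / \*41x3-style samples while
keeping enumeration instantaneous; all candidates are reported because
real samples do produce alternative calls (e.g. \*10/\*41 vs
\*39.001/\*69, which the built-in tables reproduce).

Hemizygous amplicon genotyping (`matchAmplicon`) matches a WT/MUT-only
vector from a long-range-PCR product against single haplotype rows, most
specific first; a HET call in an amplicon is by definition a mixed
template, and `detectMixedAmplicon` localizes the point where
heterozygosity begins, which brackets the hybrid switch region. A mixed
hybrid amplicon is also evidence that a REP6-type deletion template was
co-amplified, which is how `deriveConsensus` separates \*13 + \*4/\*5 from
the category-equivalent \*13/\*4: the `mixed_amplicon` evidence requires a
deletion unit among the candidates.

## Phasing duplications

For a site heterozygous on genomic DNA in a sample with n gene copies, the
variant-probe signal fraction var/(var+wt) clusters near m/n. `phaseXn`
averages replicate fractions and assigns the nearest lattice point m/n
only when the estimate is within 0.12 absolute *and* within half the
distance to the competing lattice point; otherwise the assignment is
ambiguous. The 0.12 default reflects that signal ratios carry real
uncertainty that published work acknowledges without quantifying; it is a
package choice, exposed as an argument, and known-genotype control samples
can re-center lattice points. Two degenerate cases are handled explicitly:
when only one probe amplifies, C/C, CC/C, CC/− and C/− are
indistinguishable (ambiguous, flagged), and the balanced m = n−m
configuration cannot be attributed to either haplotype (ambiguous, with
the copy estimate still recorded). Duplicate genotyping runs are compared
three-way (pass / repeat_needed on any NOCALL / fail on contradiction);
the underlying automated method in the source work is unpublished, so the
three-way rule is this package's own definition.

## Consensus, concordance and revision

`collapseCall` maps a diplotype onto a platform's representable space:
covered stars are kept, sub-alleles fall back to a covered core star,
uncovered full genes to \*1 (flagged), hybrids vanish on hybrid-blind
panels, and a deletion on a deletion-blind panel leaves the surviving
chromosome apparently homozygous — which is exactly how an AmpliChip
reports \*4/\*4 for a \*13 + \*4/\*5 sample. The consensus is the unique
candidate consistent with every platform's call-after-collapse (a no-call
with alternatives constrains via the alternatives; "UNK" matches any
chromosome) and with all CNV/phasing/amplicon observations; ties are
broken by evidence tier (sequencing-grade 3 > multiplex 2 > screening 1 —
a hierarchy the source material implies but never states). Concordance
tables count no-calls in the denominator and print cells as
"97.7 (42/43)"; `revisionReport` tabulates activity-score changes and the
phenotype transition matrix between prior and consensus calls, counting
recovered no-calls as changed.

## Activity scores and phenotypes

The score is the sum over gene units of per-haplotype activity × repeat
count. The shipped values follow the published CPIC activity values
(\*1 = 1, \*2 = 1, \*9 = \*17 = \*29 = 0.5, \*10 = \*41 = 0.25, all
no-function and hybrid alleles 0, \*25/\*26/\*30 uncertain) and are fully
overridable through the table file. Cut-points (lo < s ≤ hi) are also a
TSV: for *CYP2D6*, PM = 0, IM ≤ 1, NM ≤ 2.25, UM above. *CYP2C19* has no
published numeric score system, so the package encodes increased function
as 1.5 and decreased as 0.5 with gene-specific cut-points chosen so that
\*2/\*2 → PM, \*2/\*1 and \*2/\*17 → IM, \*1/\*1 → NM, and \*1/\*17 /
\*17/\*17 → UM; the rapid and ultrarapid classes collapse into UM because
the phenotype vocabulary has four levels. Any unit with uncertain activity
makes the result indeterminate rather than guessing.

## The workflow state machine

`nextAction` is deterministic in the evidence: contradictory duplicate
runs → repeat; cross-platform CNV conflict → repeat; unequal two-probe
calls → third probe; confirmed inequality → hybrid amplicon (with the
caveat that the G amplicon also amplifies *CYP2D7* when the downstream
gene is \*1, \*4 or \*41, and an intron 2/6 copy-loss caveat when only one
platform supports the hybrid); equal calls above two with heterozygous
sites → phase the duplication; then report iff a unique top-ranked
candidate remains (strictly better rank key than the runner-up — a
lexicographic tie is not uniqueness), else Sanger confirmation, else
manual review. Where the original decision diagram's branch order is not
recoverable (whether phasing precedes amplicon work when both apply), the
machine resolves structure first — hybrid confirmation before phasing —
because the hybrid changes the copy total that phasing interprets.
`workflowTrajectory` plays the machine against the noiseless forward model
of a ground truth; every trajectory terminates in at most six transitions.

## The synthetic cohort

`simulateObservations` is the forward model of everything above: presence
semantics restricted to each panel's sites, expected CNV per panel probe
set, duplicate runs where the platform runs in duplicate, and signal pairs
at ideal m/n fractions, with optional noise (per-site NOCALL rate, ±1 CNV
miscount rate, lognormal signal CV) under one explicit seed — identical
seeds give bitwise-identical observation sets, and the caller's RNG state
is untouched. The default cohort specification is the eight-group
*CYP2C19* consensus distribution of the 93-sample validation set
(\*1/\*1: 44, \*1/\*17: 24, \*1/\*2: 16, \*17/\*17: 1, \*2/\*17: 4,
\*2/\*2: 2, \*1/\*8: 1, \*2/\*6: 1); applying the AmpliChip limitation
model to it yields 62/93 = 66.7% concordance (the \*17, \*6 and \*8
carriers collapse into \*1 groups) and the Luminex model 100% — these are
the quantities `scripts/acceptance.R` recomputes.

What the simulator does *not* emulate: probe cross-hybridization, allele
dropout biased by sequence context, the AmpliChip's \*5 sensitivity
mechanism (modeled as a hard limitation, not a stochastic one),
read-level sequencing artifacts, and rare variants absent from the
tables. Passing round-trip tests therefore demonstrates internal
consistency of the model and correctness of the inference code on
category-level data — not robustness to every real-world failure mode.

## Numerical and design choices

* Problem sizes: property suites run the brute-force oracle on a reduced
  10-haplotype *CYP2D6* table (the full table's pair space is the
  enumerator's own job), round-trip every built-in haplotype against \*1
  plus tandem/xN exemplars, and exercise workflow trajectories on sixteen
  representative configurations — the whole suite runs in well under a
  minute on one core.
* Degenerate inputs: \*5/\*5 is consistent with nothing but NOCALLs; an
  empty candidate set is a valid "no call"; empty observation files yield
  empty observation sets; a single usable CNV region is an error rather
  than a guess.
* Ties: star-name order breaks ranking ties deterministically but never
  upgrades a tie to a unique call. Hybrid rows whose defining variants
  fall outside the registry (\*61, \*63, \*83) are intentionally
  state-sparse and therefore tie — they surface as alternatives, as
  alternative calls do in practice.
* The built-in tables encode only haplotypes and sites that the supported
  platforms' public descriptions name; the generic "\*13" row (exon 1
  insertion, undefined downstream states) exists so that samples whose
  exact \*13 variant is unresolvable are still reported at the \*13 group
  level.

## Limitations

No rare-variant discovery (inputs are panel-site categories, not reads or
traces); no raw qPCR curve or bead-level processing; *CYP2C19* structural
variants are out of scope (the workflow is built to be extensible to
them); VCF input is panel-site extraction only, with site identity by
rsID rather than coordinates, so no genome-build liftover is performed.
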