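# stardiplo

Star-allele diplotype calling for *CYP2D6* and *CYP2C19* from
multi-platform genotyping data.

*CYP2D6* and *CYP2C19* metabolize many antidepressants, antipsychotics and
other commonly prescribed drugs, and prescribing guidelines keyed to their
star-allele diplotypes exist. Genotyping *CYP2D6* is hard: the locus sits
next to the highly homologous pseudogene *CYP2D7* and accumulates whole-gene
deletions (\*5), duplications/multiplications (xN), and *CYP2D7–2D6* /
*CYP2D6–2D7* hybrid genes (e.g. \*13, \*36, \*68) including hybrid tandems
(\*13 + \*2, \*36 + \*10). Clinical platforms (AmpliChip, Luminex xTAG v3,
TaqMan, Ion AmpliSeq, PharmacoScan, Agena) each see a different slice of
this variation, so cross-platform interpretation and a defensible workflow
are needed. `stardiplo` is the interpretation engine for that setting: it is
aimed at laboratory scientists and bioinformaticians who have per-platform
site genotype categories (WT/HET/MUT), copy-number probe calls and raw
allelic signals, and need diplotype calls with an evidence trail.

## The model

**Copy-number forward model.** Each chromosome is an ordered list of gene
units. A full gene contributes 1 copy to every probe region (intron 2,
intron 6, exon 9, plus optional 5'/3' flanks), the \*5 deletion contributes
0, and a hybrid contributes 1 exactly on its *CYP2D6*-derived side of the
switch interval. The expected probe vector of a diplotype is the sum of
unit contributions; inversely, probe calls that rise 5'→3' indicate a
*CYP2D7–2D6* hybrid with the switch between the last lower-call and first
higher-call region, falling calls the reverse hybrid, and flat calls a
standard, deleted or multiplied locus. Calls below 95% confidence are
flagged and excluded.

**Diplotype enumeration.** Multiplex platforms report categories, not
dosages, so the consistency predicate is presence semantics: HET at a site
⇔ some unit carries the variant and some the reference; MUT ⇔ variant only;
WT ⇔ reference only; deletion units carry neither (a \*X/\*5 sample is
hemizygous and can never be HET). The caller enumerates every diplotype of
≤ `maxUnits` gene units consistent with the categories and the CNV
evidence, ranked by fewest structural events, known tandem partners before
novel tandems, then name — all alternatives stay visible.

**Phasing, consensus, workflow.** Duplications are assigned to a haplotype
by the variant-signal fraction var/(var+wt), which clusters at m/n for m
variant copies of n; the activity score of a diplotype is the sum of
per-unit activity values (every \*13 scores 0) and maps to PM/IM/NM/UM by a
configurable cut-point table. Cross-platform consensus is consistency after
panel-aware collapse — a hybrid-blind platform's \*4/\*4 is consistent with
\*13 + \*4/\*5 — and a state machine recommends the next assay (third CNV
probe, hybrid amplicon, phasing, Sanger) until a unique candidate or manual
review is reached.

## Worked example

The most intricate configuration in the built-in tables is a *CYP2D7–2D6*
hybrid in tandem with \*4 on one chromosome and the \*5 deletion on the
other:

```r
library(stardiplo)
d6 <- builtinHaplotypeTable("CYP2D6")

cnvCalls(expectedCnv("*13 + *4/*5", d6))
#> intron2 intron6   exon9
#>       1       2       2

classifyCnv(cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2)))
#> StructuralHypothesis: hybrid_2D7_2D6_present  switch in (intron2, intron6]
```

The probe vector 1, 2, 2 says: one chromosome loses *CYP2D6* sequence
upstream of intron 6 — a *CYP2D7–2D6* hybrid. Enumerating diplotypes under
the genotype categories of this sample (MUT at the \*4-defining splice
site, HET at the exon 1 insertion, WT at rs16947):

```r
g <- c(rs1065852 = "HET", "137_138insT" = "HET", rs769258 = "HET",
       rs3892097 = "MUT", rs1135840 = "MUT", rs16947 = "WT")
enumerateDiplotypes(g, cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2)), d6)
#>     diplotype        core events novel_tandem flags
#> 1      *13/*4      *13/*4      1        FALSE
#> 2 *13 + *4/*5 *13 + *4/*5      3         TRUE
```

Both configurations fit the categories and the probe vector; the mixed
hybrid amplicon (the L-PCR co-amplified a REP6 deletion template) settles
it, and the hybrid-blind AmpliChip's \*4/\*4 is consistent after collapse:

```r
obs <- observationSet("S1", "CYP2D6", genotypes = data.frame(
         platform = "PharmacoScan", site = names(g), category = unname(g)),
       cnv = cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2)),
       evidence = list(mixed_amplicon = TRUE))
calls <- list(platformCall("S1", "AmpliChip", "*4/*4", gene = "CYP2D6"),
              platformCall("S1", "PharmacoScan", NA,
                           alternatives = c("*4/UNK", "*4.009/UNK")))
deriveConsensus(calls, obs, d6)
#> ConsensusResult [S1]: *13 + *4/*5

activityScore("*13 + *4/*5", d6)
#> ActivityResult: score = 0 -> PM
```

Score 0: neither the hybrid, nor \*4, nor the deletion encodes functional
enzyme — a poor metabolizer. The same engine phases multiplications
(`phaseXn`), audits duplicate runs (`compareDuplicates`), simulates whole
cohorts (`simulateObservations`, `simulatePlatformLimitedCohort`) and
drives the clinical workflow (`nextAction`, `workflowTrajectory`). A thin
command-line front end ships in `inst/scripts/stardiplo`.

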