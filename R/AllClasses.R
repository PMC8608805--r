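#' @import methods
NULL

#' Ordered CNV probe regions (5' to 3')
#'
#' Region order used for hybrid switch-interval inference: probe calls that
#' increase 5' to 3' indicate a CYP2D7-2D6 hybrid, decreasing calls a
#' CYP2D6-2D7 hybrid.
#'
#' @format Character vector of the five assayable probe regions in gene order.
#' @export
PROBE_REGIONS <- c("five_prime_flank", "intron2", "intron6", "exon9",
                   "three_prime_flank")

#' Site genotype categories
#'
#' Categorical genotype calls reported by multiplex platforms. LOW_SIGNAL is
#' treated as NOCALL for constraint purposes but keeps a distinct flag.
#'
#' @format Character vector of the five category labels.
#' @export
GENOTYPE_CATEGORIES <- c("WT", "HET", "MUT", "NOCALL", "LOW_SIGNAL")

.STRUCTURAL_KINDS <- c("full_gene", "deletion", "hybrid_2D6_2D7",
                       "hybrid_2D7_2D6")

#' HaplotypeTable: star-allele definitions for one gene
#'
#' Holds one row per star allele (or sub-allele): its variant-state vector
#' over the panel sites, structural class (full gene, whole-gene deletion, or
#' CYP2D7-2D6 / CYP2D6-2D7 hybrid with a switch interval), known in-cis tandem
#' partners, and activity score.
#'
#' @slot gene "CYP2D6" or "CYP2C19".
#' @slot defs data.frame with columns star, core, structural_kind, switch_lo,
#'   switch_hi, tandem_partners (comma-separated core names), activity
#'   (character; a number or "uncertain").
#' @slot states character matrix (rows = star alleles, columns = canonical
#'   site ids) with entries "ref", "var" or NA (state undefined, e.g. on the
#'   CYP2D7-derived side of a hybrid).
#' @slot sites data.frame registry of the sites referenced by \code{states}.
#'
#' @seealso [parseHaplotypeTable()], [builtinHaplotypeTable()]
#' @export
setClass("HaplotypeTable",
  representation(gene = "character", defs = "data.frame",
                 states = "matrix", sites = "data.frame"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@defs$star))
    msg <- c(msg, paste0("duplicate star_name: ",
                         object@defs$star[duplicated(object@defs$star)][1]))
  if (!all(object@defs$structural_kind %in% .STRUCTURAL_KINDS))
    msg <- c(msg, "invalid structural_kind")
  hyb <- grepl("^hybrid", object@defs$structural_kind)
  if (any(hyb & (is.na(object@defs$switch_lo) | is.na(object@defs$switch_hi))))
    msg <- c(msg, paste0("hybrid haplotype without switch_interval: ",
                         object@defs$star[hyb & is.na(object@defs$switch_lo)][1]))
  ok <- object@states %in% c("ref", "var") | is.na(object@states)
  if (!all(ok)) msg <- c(msg, "states must be ref/var/NA")
  if (length(msg)) msg else TRUE
})

#' PlatformPanel: what one genotyping technology can see
#'
#' Immutable description of a platform's coverage for one gene: the sites it
#' assays, the variant star alleles it can distinguish, its CNV probe regions,
#' and whether it can detect hybrids, the *5 deletion, and duplications.
#'
#' @slot name platform name.
#' @slot gene "CYP2D6" or "CYP2C19".
#' @slot sites canonical site ids assayed.
#' @slot haplotypes variant star alleles distinguishable (the reference *1 is
#'   implicit; xN entries such as "*2xN" mark duplication alleles the platform
#'   reports).
#' @slot cnvRegions ordered CNV probe regions (possibly empty).
#' @slot detectsHybrids,detectsDeletion,detectsDuplication logical flags.
#' @slot tier evidence tier (3 sequencing-grade, 2 multiplex, 1 screening).
#' @slot metadata assay metadata (e.g. TaqMan CNV assay ids).
#'
#' @seealso [panelOf()]
#' @export
setClass("PlatformPanel",
  representation(name = "character", gene = "character", sites = "character",
                 haplotypes = "character", cnvRegions = "character",
                 detectsHybrids = "logical", detectsDeletion = "logical",
                 detectsDuplication = "logical", tier = "integer",
                 metadata = "list"))

#' Diplotype: two chromosome configurations
#'
#' Each chromosome is an ordered list of gene units (star allele, repeat
#' count), supporting hybrid tandems such as *13 + *2 and multiplications such
#' as *41x3. The pair is unordered: a/b equals b/a.
#'
#' @slot chromA,chromB data.frame with columns star (character) and n
#'   (integer repeat count >= 1).
#'
#' @seealso [diplotype()], [parseDiplotype()], [formatDiplotype()]
#' @export
setClass("Diplotype",
  representation(chromA = "data.frame", chromB = "data.frame"))

#' CnvProbeVector: integer copy calls at probe regions
#'
#' @slot calls named integer vector (names among [PROBE_REGIONS]).
#' @slot confidence named numeric vector in `[0, 1]`; calls below the 0.95
#'   confidence floor are flagged and excluded from classification.
#' @slot platform platform name.
#'
#' @seealso [cnvProbeVector()], [expectedCnv()], [classifyCnv()]
#' @export
setClass("CnvProbeVector",
  representation(calls = "integer", confidence = "numeric",
                 platform = "character"))

setValidity("CnvProbeVector", function(object) {
  msg <- character()
  if (!all(names(object@calls) %in% PROBE_REGIONS))
    msg <- c(msg, "unknown probe region")
  if (any(object@calls < 0L)) msg <- c(msg, "negative copy call")
  if (length(object@confidence) != length(object@calls) ||
      any(object@confidence < 0 | object@confidence > 1))
    msg <- c(msg, "confidence must be one fraction in [0,1] per region")
  if (length(msg)) msg else TRUE
})

#' StructuralHypothesis: inverse-model read of CNV probe vectors
#'
#' @slot kind one of standard_two_copy, deletion_present, xN_present,
#'   hybrid_2D7_2D6_present, hybrid_2D6_2D7_present, conflict.
#' @slot switchLo,switchHi hybrid switch interval bounds (probe regions;
#'   NA unless a hybrid kind).
#' @slot extraGene "none", "in_cis", "in_trans" or "undetermined".
#' @slot totalUnits integer range (lo, hi) for the total gene-unit count.
#' @slot flags character flags (e.g. low-confidence regions excluded).
#' @slot alternatives list of per-platform hypotheses retained on conflict.
#' @export
setClass("StructuralHypothesis",
  representation(kind = "character", switchLo = "character",
                 switchHi = "character", extraGene = "character",
                 totalUnits = "integer", flags = "character",
                 alternatives = "list"))

#' ObservationSet: everything one sample's platforms reported
#'
#' @slot sampleId sample identifier.
#' @slot gene gene the observations refer to.
#' @slot genotypes data.frame(platform, site, category, run, flag).
#' @slot cnv list of [CnvProbeVector-class] objects.
#' @slot signals data.frame(site, replicate_id, wt_signal, var_signal) of raw
#'   duplicate TaqMan probe signal pairs (possibly empty).
#' @slot evidence list of extra evidence items, e.g. mixed_amplicon = TRUE
#'   when a hybrid-specific L-PCR amplicon sequenced as a mixture (implying a
#'   co-amplified REP6 deletion), or amplicon site-genotype vectors.
#' @export
setClass("ObservationSet",
  representation(sampleId = "character", gene = "character",
                 genotypes = "data.frame", cnv = "list",
                 signals = "data.frame", evidence = "list"))

#' PhaseAssignment: which haplotype carries the extra copies
#'
#' @slot outcome "dup_on_ref_haplotype", "dup_on_var_haplotype" or "ambiguous".
#' @slot estVarFraction mean var/(var+wt) signal fraction over replicates.
#' @slot varCopies inferred variant-allele copy count (NA when ambiguous).
#' @slot supportingReplicates number of non-failed replicates used.
#' @slot flags character flags (e.g. "single_probe_amplified").
#' @seealso [phaseXn()]
#' @export
setClass("PhaseAssignment",
  representation(outcome = "character", estVarFraction = "numeric",
                 varCopies = "integer", supportingReplicates = "integer",
                 flags = "character"))

#' PlatformCall: one platform's diplotype call for a sample
#'
#' @slot sampleId,platform identifiers.
#' @slot diplotype diplotype string, or NA for a no-call.
#' @slot alternatives alternative call strings ("UNK" matches any chromosome).
#' @slot tier evidence tier (3 sequencing-grade > 2 multiplex > 1 screening).
#' @seealso [platformCall()], [deriveConsensus()]
#' @export
setClass("PlatformCall",
  representation(sampleId = "character", platform = "character",
                 diplotype = "character", alternatives = "character",
                 tier = "integer"))

#' ConsensusResult: cross-platform consensus with evidence trail
#'
#' @slot sampleId sample identifier.
#' @slot diplotype consensus diplotype string (core-star resolution), or NA
#'   when unresolved.
#' @slot resolved logical.
#' @slot candidates surviving candidate diplotype strings.
#' @slot contributing,discordant platform names.
#' @slot trail character rationale log.
#' @export
setClass("ConsensusResult",
  representation(sampleId = "character", diplotype = "character",
                 resolved = "logical", candidates = "character",
                 contributing = "character", discordant = "character",
                 trail = "character"))

#' ConcordanceTable: per-genotype-group platform concordance
#'
#' @slot table data.frame keyed by consensus genotype group with N and, per
#'   platform, percent concordance plus the raw concordant/assayed fraction.
#'   No-calls count in the denominator.
#' @export
setClass("ConcordanceTable", representation(table = "data.frame"))

#' ActivityResult: activity score and metabolizer phenotype
#'
#' @slot score sum of unit activities times repeat counts (NA when any unit
#'   activity is uncertain).
#' @slot phenotype "PM", "IM", "NM", "UM" or "indeterminate".
#' @seealso [activityScore()]
#' @export
setClass("ActivityResult",
  representation(score = "numeric", phenotype = "character"))

#' WorkflowState: evidence accumulated for one sample
#'
#' @slot observations an [ObservationSet-class].
#' @slot stepsDone workflow steps already executed.
#' @slot phasing list of [PhaseAssignment-class] keyed by site.
#' @slot ampliconCalls list of hemizygous amplicon genotype vectors.
#' @slot flags character flags.
#' @seealso [workflowState()], [nextAction()]
#' @export
setClass("WorkflowState",
  representation(observations = "ObservationSet", stepsDone = "character",
                 phasing = "list", ampliconCalls = "list",
                 flags = "character"))

#' WorkflowAction: the recommended next step
#'
#' @slot action one of report_diplotype, run_third_cnv_probe,
#'   phase_duplication, generate_hybrid_amplicon_and_genotype, sanger_confirm,
#'   repeat_assay, manual_review.
#' @slot warnings caveats attached to the action (e.g. the G-amplicon
#'   CYP2D7 false-positive caveat).
#' @slot rationale short human-readable justification.
#' @slot payload action-specific details (e.g. the reportable diplotype).
#' @export
setClass("WorkflowAction",
  representation(action = "character", warnings = "character",
                 rationale = "character", payload = "list"))
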