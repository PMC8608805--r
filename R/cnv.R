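#' Construct a CNV probe vector
#'
#' @param calls named integer copy calls (names among [PROBE_REGIONS]).
#' @param confidence per-region call confidence; the screening rule requires
#'   at least 0.95 for a call to be used unflagged.
#' @param platform platform name.
#' @return a [CnvProbeVector-class].
#' @examples
#' cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2), platform = "TaqMan")
#' @export
cnvProbeVector <- function(calls, confidence = 1, platform = "TaqMan") {
  calls <- setNames(as.integer(calls), names(calls))
  confidence <- rep_len(confidence, length(calls))
  names(confidence) <- names(calls)
  ord <- order(match(names(calls), PROBE_REGIONS))
  new("CnvProbeVector", calls = calls[ord], confidence = confidence[ord],
      platform = platform)
}

#' @describeIn CnvProbeVector-class the named integer copy calls
#' @param x a CnvProbeVector
#' @export
cnvCalls <- function(x) x@calls

setMethod("show", "CnvProbeVector", function(object) {
  cat("CnvProbeVector [", object@platform, "]: ",
      paste(names(object@calls), object@calls, sep = "=", collapse = ", "),
      "\n", sep = "")
})

# per-unit copy contribution of a haplotype to each probe region:
# full gene = 1 everywhere, deletion = 0, hybrid = 1 only on its
# CYP2D6-derived side of the switch interval
.unitContribution <- function(kind, switch_lo, switch_hi,
                              regions = PROBE_REGIONS) {
  idx <- match(regions, PROBE_REGIONS)
  if (anyNA(idx)) .stop("unknown probe region: ",
                        paste(regions[is.na(idx)], collapse = ", "))
  switch(kind,
    full_gene = rep(1L, length(idx)),
    deletion = rep(0L, length(idx)),
    hybrid_2D7_2D6 = as.integer(idx >= match(switch_hi, PROBE_REGIONS)),
    hybrid_2D6_2D7 = as.integer(idx <= match(switch_lo, PROBE_REGIONS)),
    .stop("unknown structural kind '", kind, "'"))
}

#' Expected CNV probe vector of a diplotype (forward model)
#'
#' Sums per-unit region contributions over all gene units of both
#' chromosomes: a full gene contributes 1 copy to every probe region, the *5
#' deletion 0, and a hybrid contributes 1 exactly to the regions on its
#' CYP2D6-derived side of the switch interval. For the hybrid tandem plus
#' deletion configuration *13 + *4/*5 this yields intron2 = 1, intron6 = 2,
#' exon9 = 2.
#'
#' @param d a [Diplotype-class] (or diplotype string).
#' @param table a [HaplotypeTable-class] defining the structural class of
#'   every unit.
#' @param regions probe regions to evaluate (ordered 5' to 3').
#' @param platform platform label attached to the result.
#' @return a [CnvProbeVector-class] with confidence 1.
#' @examples
#' tab <- builtinHaplotypeTable("CYP2D6")
#' cnvCalls(expectedCnv("*13 + *4/*5", tab))
#' @export
expectedCnv <- function(d, table, regions = c("intron2", "intron6", "exon9"),
                        platform = "expected") {
  if (is.character(d)) d <- parseDiplotype(d, table = table)
  units <- diplotypeUnits(d)
  calls <- setNames(integer(length(regions)), regions)
  for (i in seq_len(nrow(units))) {
    r <- .hapRow(table, units$star[i])
    calls <- calls + units$n[i] *
      .unitContribution(r$structural_kind, r$switch_lo, r$switch_hi, regions)
  }
  cnvProbeVector(calls, confidence = 1, platform = platform)
}

.hypothesis <- function(kind, lo = NA_character_, hi = NA_character_,
                        extra = "none", units = c(NA_integer_, NA_integer_),
                        flags = character(), alternatives = list())
  new("StructuralHypothesis", kind = kind, switchLo = lo, switchHi = hi,
      extraGene = extra, totalUnits = as.integer(units), flags = flags,
      alternatives = alternatives)

# classify one merged region->call map (regions in 5'->3' order)
.classifyMap <- function(calls, flags = character()) {
  k <- unname(calls)
  n <- length(k)
  lo_bound <- max(k)
  hi_bound <- max(k) + max(0L, 2L - min(k))  # deleted units add no copies
  if (all(k == k[1])) {
    kind <- if (k[1] == 2L) "standard_two_copy"
            else if (k[1] < 2L) "deletion_present" else "xN_present"
    return(.hypothesis(kind, units = c(lo_bound, hi_bound), flags = flags))
  }
  d <- diff(k)
  if (all(d >= 0)) {          # calls increase 5'->3': CYP2D7-2D6 hybrid
    i <- max(which(d > 0))    # last step up
    return(.hypothesis("hybrid_2D7_2D6_present",
                       lo = names(calls)[i], hi = names(calls)[i + 1],
                       extra = if (max(k) > 2L) "undetermined" else "none",
                       units = c(lo_bound, hi_bound), flags = flags))
  }
  if (all(d <= 0)) {          # calls decrease 5'->3': CYP2D6-2D7 hybrid
    i <- min(which(d < 0))    # first step down
    return(.hypothesis("hybrid_2D6_2D7_present",
                       lo = names(calls)[i], hi = names(calls)[i + 1],
                       extra = if (max(k) > 2L) "undetermined" else "none",
                       units = c(lo_bound, hi_bound), flags = flags))
  }
  .hypothesis("conflict", units = c(lo_bound, hi_bound),
              flags = c(flags, "non_monotone_pattern"))
}

#' Classify observed CNV probe vectors into a structural hypothesis
#'
#' Merges the usable (confidence >= `minConfidence`) region calls of all
#' platforms into one 5'-to-3' map and reads off the structural hypothesis:
#' equal calls across regions give standard two-copy / deletion / xN; calls
#' increasing 5' to 3' indicate a CYP2D7-2D6 hybrid with the switch interval
#' between the last lower-call region and the first higher-call region;
#' decreasing calls the reverse hybrid. Platforms contradicting each other on
#' a shared region yield a conflict hypothesis retaining the per-platform
#' readings; the workflow turns conflicts into repeat/confirm actions rather
#' than voting.
#'
#' @param vectors a [CnvProbeVector-class] or list of them.
#' @param minConfidence confidence floor below which calls are flagged and
#'   excluded (default 0.95, the screening rule).
#' @return a [StructuralHypothesis-class].
#' @examples
#' classifyCnv(cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2)))
#' @export
classifyCnv <- function(vectors, minConfidence = 0.95) {
  if (is(vectors, "CnvProbeVector")) vectors <- list(vectors)
  if (!length(vectors)) .stop("no CNV probe vectors supplied")
  flags <- character()
  merged <- list()
  for (v in vectors) {
    usable <- v@confidence >= minConfidence
    if (any(!usable))
      flags <- c(flags, paste0("low_confidence:", v@platform, ":",
                               names(v@calls)[!usable]))
    for (r in names(v@calls)[usable]) {
      merged[[r]] <- c(merged[[r]], setNames(v@calls[[r]], v@platform))
    }
  }
  if (length(merged) < 2L)
    .stop("need usable calls for at least two probe regions")
  disagree <- names(merged)[vapply(merged, function(x)
    length(unique(x)) > 1L, logical(1))]
  if (length(disagree)) {
    alts <- lapply(vectors, function(v)
      tryCatch(classifyCnv(v, minConfidence), error = function(e) NULL))
    alts <- Filter(Negate(is.null), alts)
    return(.hypothesis("conflict",
                       flags = c(flags, paste0("cross_platform:", disagree)),
                       alternatives = alts))
  }
  calls <- vapply(merged, `[`, integer(1), 1)
  calls <- calls[order(match(names(calls), PROBE_REGIONS))]
  .classifyMap(calls, flags)
}

#' @describeIn StructuralHypothesis-class the hypothesis kind
#' @param x a StructuralHypothesis
#' @export
hypothesisKind <- function(x) x@kind

#' @describeIn StructuralHypothesis-class hybrid switch interval as
#'   c(lo, hi), or NAs
#' @export
switchInterval <- function(x) c(x@switchLo, x@switchHi)

setMethod("show", "StructuralHypothesis", function(object) {
  cat("StructuralHypothesis:", object@kind)
  if (!is.na(object@switchLo))
    cat("  switch in (", object@switchLo, ", ", object@switchHi, "]",
        sep = "")
  cat("\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

# does the expected CNV of d match every usable observed region call?
.cnvMatches <- function(d, table, vectors, minConfidence = 0.95) {
  for (v in vectors) {
    usable <- names(v@calls)[v@confidence >= minConfidence]
    if (!length(usable)) next
    exp <- cnvCalls(expectedCnv(d, table, regions = usable))
    if (!all(exp == v@calls[usable])) return(FALSE)
  }
  TRUE
}
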