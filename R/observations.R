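.emptyGenotypes <- function()
  data.frame(platform = character(), site = character(),
             category = character(), run = integer(), flag = character(),
             stringsAsFactors = FALSE)

.emptySignals <- function()
  data.frame(site = character(), replicate_id = integer(),
             wt_signal = numeric(), var_signal = numeric(),
             stringsAsFactors = FALSE)

#' Construct an observation set
#'
#' Container for everything the platforms reported about one sample: site
#' genotype categories per platform (and run, for platforms assayed in
#' duplicate), CNV probe vectors, raw duplicate signal pairs, and extra
#' evidence items (e.g. `mixed_amplicon = TRUE`, or `amplicon` = a
#' hemizygous site-genotype vector from L-PCR amplicon genotyping).
#'
#' @param sampleId sample identifier.
#' @param gene "CYP2D6" or "CYP2C19".
#' @param genotypes data.frame with columns platform, site, category (and
#'   optionally run, flag).
#' @param cnv list of [CnvProbeVector-class] objects.
#' @param signals data.frame(site, replicate_id, wt_signal, var_signal).
#' @param evidence named list of extra evidence.
#' @return an [ObservationSet-class].
#' @export
observationSet <- function(sampleId = "sample", gene,
                           genotypes = .emptyGenotypes(), cnv = list(),
                           signals = .emptySignals(), evidence = list()) {
  .assertGene(gene)
  if (nrow(genotypes)) {
    if (!all(c("site", "category") %in% names(genotypes)))
      .stop("genotypes need columns site and category")
    if (is.null(genotypes$platform)) genotypes$platform <- NA_character_
    if (is.null(genotypes$run)) genotypes$run <- 1L
    if (is.null(genotypes$flag)) genotypes$flag <- ""
    bad <- !genotypes$category %in% GENOTYPE_CATEGORIES
    if (any(bad)) .stop("unknown genotype category '",
                        genotypes$category[bad][1], "'")
    genotypes$site <- .canonicalSites(genotypes$site, gene)
    genotypes <- genotypes[, c("platform", "site", "category", "run", "flag")]
  } else genotypes <- .emptyGenotypes()
  if (is(cnv, "CnvProbeVector")) cnv <- list(cnv)
  new("ObservationSet", sampleId = sampleId, gene = gene,
      genotypes = genotypes, cnv = cnv, signals = signals,
      evidence = evidence)
}

#' @describeIn ObservationSet-class the per-platform genotype rows
#' @param x an ObservationSet
#' @export
genotypesOf <- function(x) x@genotypes

#' @describeIn ObservationSet-class the CNV probe vectors
#' @export
cnvOf <- function(x) x@cnv

#' @describeIn ObservationSet-class the raw duplicate signal pairs
#' @export
signalsOf <- function(x) x@signals

#' @describeIn ObservationSet-class extra evidence items
#' @export
evidenceOf <- function(x) x@evidence

setMethod("show", "ObservationSet", function(object) {
  cat("ObservationSet '", object@sampleId, "' (", object@gene, "): ",
      nrow(object@genotypes), " genotype rows, ", length(object@cnv),
      " CNV vectors, ", nrow(object@signals), " signal pairs\n", sep = "")
})

# one consolidated site -> category constraint set across platforms/runs;
# contradictions become per-site conflicts (kept as-is: the enumerator will
# simply find no candidate, and the workflow recommends a repeat)
.pooledGenotypes <- function(obs) {
  g <- obs@genotypes
  g <- g[!g$category %in% c("NOCALL", "LOW_SIGNAL"), , drop = FALSE]
  unique(g[, c("site", "category")])
}
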