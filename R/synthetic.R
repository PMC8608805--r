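#' Noise model for the forward simulator
#'
#' All-zero noise reproduces the deterministic forward model exactly.
#'
#' @param nocall_rate per-site probability of a NOCALL.
#' @param cnv_miscount_rate per-region probability of a +/-1 copy miscount.
#' @param signal_cv coefficient of variation (lognormal) of simulated probe
#'   signal pairs; 0 gives exact ideal fractions.
#' @return a list of class "noiseModel".
#' @export
noiseModel <- function(nocall_rate = 0, cnv_miscount_rate = 0,
                       signal_cv = 0) {
  stopifnot(nocall_rate >= 0, nocall_rate <= 1,
            cnv_miscount_rate >= 0, cnv_miscount_rate <= 1, signal_cv >= 0)
  structure(list(nocall_rate = nocall_rate,
                 cnv_miscount_rate = cnv_miscount_rate,
                 signal_cv = signal_cv), class = "noiseModel")
}

# the true multiplex category of a diplotype at one site (presence semantics)
.trueCategory <- function(units, site, table, masks) {
  if (!site %in% colnames(masks$var)) return("NOCALL")
  V <- R <- FALSE
  for (s in units$star) {
    V <- V || masks$var[s, site]
    R <- R || masks$ref[s, site]
  }
  if (V && R) "HET" else if (V) "MUT" else if (R) "WT" else "NOCALL"
}

#' Simulate per-platform observations for a ground-truth diplotype
#'
#' The forward model inverse to the caller: SNV categories follow the
#' presence semantics restricted to each panel's sites, CNV vectors equal
#' [expectedCnv()] over each panel's probe regions (perturbed per the noise
#' model), platforms run in duplicate get two runs, and sites heterozygous
#' with more than two gene copies get raw signal pairs drawn around the
#' ideal m/n variant fraction. Identical seeds give identical output.
#'
#' @param truth a [Diplotype-class] or diplotype string.
#' @param panels a [PlatformPanel-class] or list of them.
#' @param table a [HaplotypeTable-class].
#' @param noise a [noiseModel()].
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param regions optional override of the CNV probe regions simulated for
#'   every CNV-capable panel (e.g. the initial two-probe screen).
#' @param sampleId sample identifier.
#' @return an [ObservationSet-class].
#' @examples
#' tab <- builtinHaplotypeTable("CYP2D6")
#' obs <- simulateObservations("*13 + *4/*5", panelOf("TaqMan"), tab)
#' cnvCalls(cnvOf(obs)[[1]])
#' @export
simulateObservations <- function(truth, panels, table, noise = noiseModel(),
                                 seed = NULL, regions = NULL,
                                 sampleId = "sample") {
  if (is.character(truth)) truth <- parseDiplotype(truth, table = table)
  if (is(panels, "PlatformPanel")) panels <- list(panels)
  units <- diplotypeUnits(truth)
  for (s in units$star) .hapRow(table, s)
  masks <- .hapMasks(table)
  .withSeed(seed, {
    grows <- list(); cnvs <- list(); sigs <- .emptySignals()
    maxCopies <- max(cnvCalls(expectedCnv(truth, table,
                                          regions = PROBE_REGIONS)))
    for (panel in panels) {
      sites <- intersect(panelSites(panel), colnames(table@states))
      cats <- vapply(sites, .trueCategory, character(1), units = units,
                     table = table, masks = masks)
      nruns <- if (isTRUE(panel@metadata$duplicate_runs)) 2L else 1L
      for (run in seq_len(nruns)) {
        obscats <- cats
        if (noise$nocall_rate > 0) {
          drop <- stats::runif(length(obscats)) < noise$nocall_rate
          obscats[drop] <- "NOCALL"
        }
        grows[[length(grows) + 1L]] <- data.frame(
          platform = panel@name, site = sites, category = unname(obscats),
          run = run, flag = "", stringsAsFactors = FALSE)
      }
      cr <- regions %||% cnvRegions(panel)
      if (length(cnvRegions(panel)) && length(cr)) {
        v <- expectedCnv(truth, table, regions = cr, platform = panel@name)
        calls <- cnvCalls(v)
        if (noise$cnv_miscount_rate > 0) {
          hit <- stats::runif(length(calls)) < noise$cnv_miscount_rate
          calls[hit] <- pmax(0L, calls[hit] +
                               sample(c(-1L, 1L), sum(hit), replace = TRUE))
        }
        cnvs[[length(cnvs) + 1L]] <- cnvProbeVector(calls, confidence = 1,
                                                    platform = panel@name)
      }
      # raw signal pairs for phaseable sites (HET with > 2 gene copies)
      if (maxCopies > 2L) {
        for (site in sites[cats == "HET"]) {
          m <- .varCopyCount(truth, site, table)
          if (m < 1L || m >= maxCopies) next
          f <- function(x) x * exp(stats::rnorm(2L, 0, noise$signal_cv))
          sigs <- rbind(sigs, data.frame(
            site = site, replicate_id = 1:2,
            wt_signal = f(100 * (maxCopies - m) / maxCopies),
            var_signal = f(100 * m / maxCopies),
            stringsAsFactors = FALSE))
        }
      }
    }
    observationSet(sampleId = sampleId, gene = table@gene,
                   genotypes = if (length(grows)) do.call(rbind, grows)
                               else .emptyGenotypes(),
                   cnv = cnvs, signals = sigs)
  })
}

#' Consensus genotype distribution of the CYP2C19 validation cohort
#'
#' The default cohort specification: 93 samples over eight consensus
#' CYP2C19 genotype groups (*1/*1: 44, *1/*17: 24, *1/*2: 16, *17/*17: 1,
#' *2/*17: 4, *2/*2: 2, *1/*8: 1, *2/*6: 1).
#'
#' @return data.frame with columns diplotype, n.
#' @export
table1CohortSpec <- function() {
  data.frame(
    diplotype = c("*1/*1", "*1/*17", "*1/*2", "*17/*17", "*2/*17", "*2/*2",
                  "*1/*8", "*2/*6"),
    n = c(44L, 24L, 16L, 1L, 4L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Apply a platform's limitation model to a cohort of true diplotypes
#'
#' Deterministically collapses every sample's true consensus diplotype to
#' what the platform can represent ([collapseCall()]), producing paired
#' (truth, platform call) lists for concordance simulation.
#'
#' @param spec data.frame(diplotype, n) of consensus genotypes and counts;
#'   defaults to [table1CohortSpec()].
#' @param panel a [PlatformPanel-class].
#' @param table a [HaplotypeTable-class] for the panel's gene.
#' @return data.frame(sample_id, truth, call, representable).
#' @examples
#' tab <- builtinHaplotypeTable("CYP2C19")
#' ch <- simulatePlatformLimitedCohort(panel = panelOf("AmpliChip", "CYP2C19"),
#'                                     table = tab)
#' mean(ch$call == ch$truth)   # 62/93
#' @export
simulatePlatformLimitedCohort <- function(spec = table1CohortSpec(), panel,
                                          table) {
  if (!nrow(spec)) .stop("empty cohort specification")
  truths <- rep(spec$diplotype, spec$n)
  calls <- character(length(truths)); repr <- logical(length(truths))
  canon <- character(length(truths))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(truths)) {
    key <- truths[i]
    if (is.null(cache[[key]])) {
      cc <- collapseCall(key, panel, table)
      cache[[key]] <- list(call = cc$string, repr = cc$representable,
                           canon = .coreString(key))
    }
    calls[i] <- cache[[key]]$call
    repr[i] <- cache[[key]]$repr
    canon[i] <- cache[[key]]$canon
  }
  data.frame(sample_id = sprintf("S%03d", seq_along(truths)),
             truth = canon, call = calls, representable = repr,
             stringsAsFactors = FALSE)
}
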