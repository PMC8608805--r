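.CATEGORY_ALIASES <- c("WT" = "WT", "HET" = "HET", "MUT" = "MUT",
                       "NOCALL" = "NOCALL", "NO_CALL" = "NOCALL",
                       "LOW_SIGNAL" = "LOW_SIGNAL")

# tolerant category normalisation ("Low Signal", "no call", ...)
.normCategory <- function(x)
  unname(.CATEGORY_ALIASES[toupper(gsub("[ -]", "_", x))])

#' Read platform observations from the documented TSV/JSON dialects
#'
#' The genotype TSV has columns sample_id, platform, site, category (and
#' optionally run); the CNV TSV sample_id, platform, region, copy_call,
#' confidence; the signal TSV sample_id, site, replicate_id, wt_signal,
#' var_signal. "Low Signal" and "No Call" spellings are accepted. Unknown
#' site labels are routed through [resolveSite()]; malformed rows raise an
#' error naming the line. A `.json` path may carry the same content as one
#' object (fields genotypes, cnv, signals, evidence).
#'
#' @param path genotype TSV (or JSON) path; an empty file yields an empty
#'   observation set.
#' @param gene "CYP2D6" or "CYP2C19".
#' @param cnvPath,signalPath optional companion TSVs.
#' @param sampleId restrict to one sample (required when the files carry
#'   several).
#' @return an [ObservationSet-class] (or named list of them when several
#'   samples are present and `sampleId` is NULL).
#' @export
readObservations <- function(path, gene, cnvPath = NULL, signalPath = NULL,
                             sampleId = NULL) {
  .assertGene(gene)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(.readObservationsJson(path, gene, sampleId))
  g <- .readTsv(path, c("sample_id", "platform", "site", "category"),
                optional = "run")
  if (nrow(g)) {
    cat0 <- .normCategory(g$category)
    bad <- which(is.na(cat0))
    if (length(bad))
      .stop("unknown genotype category '", g$category[bad[1]], "' at line ",
            g$.line[bad[1]], " of ", path)
    g$category <- unname(cat0)
    g$flag <- ifelse(g$category == "LOW_SIGNAL", "low_signal", "")
    if (is.null(g$run)) g$run <- 1L
  }
  cn <- if (!is.null(cnvPath))
    .readTsv(cnvPath, c("sample_id", "platform", "region", "copy_call",
                        "confidence")) else NULL
  sg <- if (!is.null(signalPath))
    .readTsv(signalPath, c("sample_id", "site", "replicate_id", "wt_signal",
                           "var_signal")) else NULL

  ids <- unique(c(g$sample_id, cn$sample_id, sg$sample_id))
  if (!is.null(sampleId)) ids <- sampleId
  build <- function(id) {
    gi <- g[g$sample_id == id, , drop = FALSE]
    cnv <- list()
    if (!is.null(cn)) {
      ci <- cn[cn$sample_id == id, , drop = FALSE]
      for (p in unique(ci$platform)) {
        pi <- ci[ci$platform == p, , drop = FALSE]
        bad <- !pi$region %in% PROBE_REGIONS
        if (any(bad)) .stop("unknown CNV probe region '",
                            pi$region[bad][1], "' at line ",
                            pi$.line[bad][1], " of ", cnvPath)
        cnv[[length(cnv) + 1L]] <- cnvProbeVector(
          setNames(as.integer(pi$copy_call), pi$region),
          confidence = as.numeric(pi$confidence), platform = p)
      }
    }
    sig <- if (!is.null(sg)) {
      si <- sg[sg$sample_id == id, , drop = FALSE]
      si$site <- .canonicalSites(si$site, gene)
      si[, c("site", "replicate_id", "wt_signal", "var_signal")]
    } else .emptySignals()
    observationSet(sampleId = id, gene = gene,
                   genotypes = if (nrow(gi))
                     gi[, c("platform", "site", "category", "run", "flag")]
                   else .emptyGenotypes(),
                   cnv = cnv, signals = sig)
  }
  if (length(ids) == 0L)
    return(observationSet(sampleId = "empty", gene = gene))
  if (length(ids) == 1L) return(build(ids))
  setNames(lapply(ids, build), ids)
}

.readTsv <- function(path, required, optional = character()) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  if (!nrow(df) && !all(required %in% names(df))) {
    # empty file: synthesise an empty frame with the expected columns
    df <- as.data.frame(setNames(rep(list(character()), length(required)),
                                 required), stringsAsFactors = FALSE)
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  df
}

.readObservationsJson <- function(path, gene, sampleId = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- if (!is.null(x$genotypes) && length(x$genotypes))
    as.data.frame(x$genotypes, stringsAsFactors = FALSE) else .emptyGenotypes()
  if (nrow(g)) {
    g$category <- .normCategory(g$category)
    if (is.null(g$run)) g$run <- 1L
    if (is.null(g$flag)) g$flag <- ""
  }
  cnv <- list()
  if (!is.null(x$cnv)) {
    cl <- x$cnv
    if (is.data.frame(cl)) cl <- split(cl, cl$platform)
    for (p in cl) {
      cnv[[length(cnv) + 1L]] <- cnvProbeVector(
        setNames(as.integer(p$copy_call), p$region),
        confidence = if (!is.null(p$confidence)) as.numeric(p$confidence)
                     else 1, platform = unique(p$platform) %||% "unknown")
    }
  }
  sig <- if (!is.null(x$signals) && length(x$signals))
    as.data.frame(x$signals, stringsAsFactors = FALSE) else .emptySignals()
  observationSet(sampleId = x$sample_id %||% sampleId %||% "sample",
                 gene = gene, genotypes = g, cnv = cnv, signals = sig,
                 evidence = as.list(x$evidence %||% list()))
}

#' Write an observation set in the TSV dialects the readers consume
#'
#' @param obs an [ObservationSet-class].
#' @param path genotype TSV path.
#' @param cnvPath,signalPath optional companion TSV paths.
#' @return invisibly, `path`.
#' @export
writeObservations <- function(obs, path, cnvPath = NULL, signalPath = NULL) {
  g <- obs@genotypes
  out <- data.frame(sample_id = obs@sampleId, platform = g$platform,
                    site = g$site, category = g$category, run = g$run,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cnvPath)) {
    rows <- do.call(rbind, lapply(obs@cnv, function(v)
      data.frame(sample_id = obs@sampleId, platform = v@platform,
                 region = names(v@calls), copy_call = unname(v@calls),
                 confidence = unname(v@confidence),
                 stringsAsFactors = FALSE)))
    utils::write.table(rows %||% data.frame(), cnvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(signalPath)) {
    s <- obs@signals
    out <- cbind(sample_id = rep(obs@sampleId, nrow(s)), s)
    utils::write.table(out, signalPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Extract panel-site genotypes from a VCF
#'
#' Reads a VCF restricted to panel sites: records are matched to the site
#' registry by ID (rsID) or by a legacy label; genotypes map 0/0 to WT, 0/1
#' to HET, 1/1 to MUT, and missing to NOCALL. Non-panel records are ignored
#' (counted in a message). Requires the vcfR package.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param panel a [PlatformPanel-class].
#' @param sample sample name; required when the VCF has several samples.
#' @return named character vector site -> category covering every panel
#'   site (NOCALL where the VCF has no record).
#' @export
readVcfSites <- function(path, panel, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stop("readVcfSites requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1)
  if (ncol(gt) > 1L) {
    if (is.null(sample))
      .stop("multi-sample VCF: specify 'sample'")
    if (!sample %in% colnames(gt))
      .stop("sample '", sample, "' not in VCF")
    gt <- gt[, sample, drop = FALSE]
  }
  ids <- vcfR::getID(v)
  out <- setNames(rep("NOCALL", length(panelSites(panel))),
                  panelSites(panel))
  skipped <- 0L
  for (i in seq_along(ids)) {
    canon <- tryCatch(resolveSite(ids[i], geneOf(panel))$canonical_id,
                      error = function(e) NA_character_)
    if (is.na(canon) || !canon %in% names(out)) {
      skipped <- skipped + 1L
      next
    }
    g <- gsub("\\|", "/", gt[i, 1])
    out[canon] <- if (is.na(g) || g %in% c("./.", ".")) "NOCALL"
      else if (g == "0/0") "WT"
      else if (g %in% c("0/1", "1/0")) "HET"
      else if (g == "1/1") "MUT" else "NOCALL"
  }
  if (skipped) message(skipped, " non-panel VCF record(s) ignored")
  if (all(out == "NOCALL"))
    warning("no panel sites found in ", path)
  out
}

#' Write a JSON call report
#'
#' Serialises caller/consensus/workflow results as a versioned JSON report:
#' ranked candidates with flags, activity score and phenotype, consensus and
#' concordance (cells formatted like "97.7 (42/43)"), and the workflow
#' action log.
#'
#' @param results a named list; recognised elements are `candidates` (from
#'   [enumerateDiplotypes()]), `activity` (an [ActivityResult-class]),
#'   `consensus` (a [ConsensusResult-class]), `concordance` (a
#'   [ConcordanceTable-class]) and `actions` (list of
#'   [WorkflowAction-class]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(results, path) {
  out <- list(schema_version = "1.0")
  if (!is.null(results$sample_id)) out$sample_id <- results$sample_id
  if (!is.null(results$candidates))
    out$candidates <- results$candidates
  if (!is.null(results$activity))
    out$activity <- list(score = scoreOf(results$activity),
                         phenotype = phenotypeOf(results$activity))
  if (!is.null(results$consensus)) {
    cr <- results$consensus
    out$consensus <- list(sample_id = cr@sampleId, diplotype = cr@diplotype,
                          resolved = cr@resolved, candidates = cr@candidates,
                          contributing = cr@contributing,
                          discordant = cr@discordant, trail = cr@trail)
  }
  if (!is.null(results$concordance))
    out$concordance <- concordanceFrame(results$concordance)
  if (!is.null(results$actions))
    out$actions <- lapply(results$actions, function(a)
      list(action = actionOf(a), warnings = actionWarnings(a),
           rationale = a@rationale))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
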