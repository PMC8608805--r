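#' Construct a workflow state
#'
#' Evidence accumulated so far for one sample in the clinical genotyping
#' workflow: the initial multiplex SNV + CNV screen, plus any follow-up
#' results (third CNV probe, phasing assignments, hybrid amplicon
#' genotypes).
#'
#' @param observations an [ObservationSet-class] (must contain at least the
#'   initial screen).
#' @param stepsDone workflow steps already executed.
#' @param phasing named list of [PhaseAssignment-class] keyed by site.
#' @param ampliconCalls list of hemizygous amplicon genotype vectors
#'   (site -> category).
#' @param flags character flags.
#' @return a [WorkflowState-class].
#' @export
workflowState <- function(observations, stepsDone = character(),
                          phasing = list(), ampliconCalls = list(),
                          flags = character()) {
  new("WorkflowState", observations = observations, stepsDone = stepsDone,
      phasing = phasing, ampliconCalls = ampliconCalls, flags = flags)
}

.action <- function(action, warnings = character(), rationale = "",
                    payload = list())
  new("WorkflowAction", action = action, warnings = warnings,
      rationale = rationale, payload = payload)

#' @describeIn WorkflowAction-class the recommended action
#' @param x a WorkflowAction
#' @export
actionOf <- function(x) x@action

#' @describeIn WorkflowAction-class attached warnings
#' @export
actionWarnings <- function(x) x@warnings

setMethod("show", "WorkflowAction", function(object) {
  cat("WorkflowAction:", object@action, "\n")
  if (nzchar(object@rationale)) cat("  ", object@rationale, "\n")
  for (w in object@warnings) cat("  warning:", w, "\n")
})

# variant-allele copy count of a diplotype at one site
.varCopyCount <- function(d, site, table) {
  units <- diplotypeUnits(d)
  st <- table@states
  total <- 0L
  for (i in seq_len(nrow(units))) {
    s <- st[units$star[i], site]
    if (!is.na(s) && s == "var" &&
        .hapRow(table, units$star[i])$structural_kind != "deletion")
      total <- total + units$n[i]
  }
  total
}

# candidates surviving all evidence in a workflow state
.stateCandidates <- function(state, table, maxUnits = 4L) {
  obs <- state@observations
  reqDel <- isTRUE(obs@evidence$mixed_amplicon)
  cand <- enumerateDiplotypes(.pooledGenotypes(obs), cnv = obs@cnv,
                              table = table, maxUnits = maxUnits,
                              requireDeletion = reqDel)
  if (!nrow(cand)) return(cand)
  keep <- rep(TRUE, nrow(cand))
  for (ac in state@ampliconCalls) {
    hits <- tryCatch(matchAmplicon(ac, table), error = function(e) character())
    if (!length(hits)) next
    cores <- starCore(hits)
    keep <- keep & vapply(cand$diplotype, function(ds) {
      units <- diplotypeUnits(parseDiplotype(ds))
      any(units$star %in% hits | starCore(units$star) %in% cores)
    }, logical(1), USE.NAMES = FALSE)
  }
  for (site in names(state@phasing)) {
    pa <- state@phasing[[site]]
    if (is.na(varCopies(pa))) next
    keep <- keep & vapply(cand$diplotype, function(ds)
      .varCopyCount(parseDiplotype(ds), site, table) == varCopies(pa),
      logical(1), USE.NAMES = FALSE)
  }
  sanger <- obs@evidence$sanger
  if (!is.null(sanger))
    keep <- keep & cand$core == .coreString(sanger)
  cand[keep, , drop = FALSE]
}

# unique rank-1 candidate: strictly better (events, novel) key than the
# runner-up, or no runner-up at all
.uniqueTop <- function(cand) {
  if (!nrow(cand)) return(NULL)
  if (nrow(cand) == 1L) return(cand$diplotype[1])
  if (cand$events[1] < cand$events[2] ||
      (cand$events[1] == cand$events[2] &&
       !cand$novel_tandem[1] && cand$novel_tandem[2]))
    return(cand$diplotype[1])
  NULL
}

#' Recommend the next workflow step from the current evidence
#'
#' Deterministic clinical workflow: an initial multiplex SNV + CNV screen is
#' followed, as the evidence requires, by the third CNV probe (on unequal
#' two-probe calls), hybrid-specific L-PCR amplicon generation and multiplex
#' genotyping (on confirmed inequality), duplication phasing (equal calls
#' above two with heterozygous sites), Sanger confirmation, and finally a
#' diplotype report or manual review. Caveats surface as warnings: the
#' hybrid-specific G amplicon can also amplify CYP2D7 when the downstream
#' gene is *1, *4 or *41, and a hybrid supported by a single platform may be
#' a false-positive intron 2/6 copy-loss.
#'
#' @param state a [WorkflowState-class].
#' @param table a [HaplotypeTable-class].
#' @param maxUnits forwarded to the enumerator.
#' @return a [WorkflowAction-class].
#' @export
nextAction <- function(state, table, maxUnits = 4L) {
  obs <- state@observations
  if (nrow(obs@genotypes) == 0L && length(obs@cnv) == 0L)
    .stop("empty workflow state: run the initial SNV+CNV screen first")

  # duplicate-run comparison (platforms assayed in duplicate)
  g <- obs@genotypes
  for (p in unique(g$platform)) {
    runs <- unique(g$run[g$platform %in% p])
    if (length(runs) >= 2L) {
      r1 <- g[g$platform %in% p & g$run == runs[1], ]
      r2 <- g[g$platform %in% p & g$run == runs[2], ]
      common <- intersect(r1$site, r2$site)
      if (!length(common)) next
      cmp <- compareDuplicates(setNames(r1$category[match(common, r1$site)], common),
                               setNames(r2$category[match(common, r2$site)], common))
      if (any(cmp$status == "fail") && !"repeat" %in% state@stepsDone)
        return(.action("repeat_assay",
                       rationale = paste0("duplicate runs contradict at ",
                                          paste(cmp$site[cmp$status == "fail"],
                                                collapse = ", "))))
    }
  }

  hyp <- NULL
  if (length(obs@cnv))
    hyp <- tryCatch(classifyCnv(obs@cnv), error = function(e) NULL)

  if (!is.null(hyp) && hypothesisKind(hyp) == "conflict" &&
      !"repeat" %in% state@stepsDone)
    return(.action("repeat_assay", warnings = "cnv_cross_platform_conflict",
                   rationale = "CNV probe vectors contradict across platforms"))

  cand <- .stateCandidates(state, table, maxUnits)

  if (!is.null(hyp) && grepl("^hybrid", hypothesisKind(hyp))) {
    regionsSeen <- unique(unlist(lapply(obs@cnv, function(v) names(v@calls))))
    warnings <- character()
    if (length(obs@cnv) == 1L)
      warnings <- c(warnings,
                    "hybrid supported by a single platform: intron 2/6 copy-loss false positives possible")
    if (hypothesisKind(hyp) == "hybrid_2D6_2D7_present" &&
        any(starCore(unlist(strsplit(cand$core, "[/+x ]"))) %in%
              c("*1", "*4", "*41")))
      warnings <- c(warnings,
                    "amplicon G also amplifies CYP2D7 where the downstream gene is *1, *4 or *41")
    if (!"third_cnv_probe" %in% state@stepsDone &&
        !"intron6" %in% regionsSeen && length(obs@cnv) == 1L)
      return(.action("run_third_cnv_probe", warnings = warnings,
                     rationale = "two-probe CNV calls unequal: add the intron 6 probe"))
    if (!"hybrid_amplicon" %in% state@stepsDone &&
        !length(state@ampliconCalls))
      return(.action("generate_hybrid_amplicon_and_genotype",
                     warnings = warnings,
                     rationale = "confirmed unequal CNV calls: generate the hybrid-specific L-PCR amplicon and genotype it"))
  }

  if (!is.null(hyp) && hypothesisKind(hyp) == "xN_present" &&
      !"phase" %in% state@stepsDone && length(state@phasing) == 0L) {
    het <- unique(g$site[g$category == "HET"])
    if (length(het))
      return(.action("phase_duplication",
                     rationale = paste0("more than two gene copies with heterozygous site(s) ",
                                        paste(het, collapse = ", "),
                                        ": assign the extra copies by allelic ratio")))
  }

  top <- .uniqueTop(cand)
  if (!is.null(top)) {
    res <- activityScore(top, table)
    return(.action("report_diplotype",
                   rationale = paste0("unique top-ranked candidate ", top),
                   payload = list(diplotype = top,
                                  core = .coreString(top),
                                  score = scoreOf(res),
                                  phenotype = phenotypeOf(res),
                                  alternatives = cand$diplotype[-1])))
  }
  if (!nrow(cand) && !"repeat" %in% state@stepsDone)
    return(.action("repeat_assay",
                   rationale = "no diplotype is consistent with all observations"))
  if (!"sanger" %in% state@stepsDone)
    return(.action("sanger_confirm",
                   rationale = paste0(nrow(cand),
                                      " candidates remain: confirm by Sanger sequencing")))
  .action("manual_review",
          rationale = "evidence exhausted without a unique candidate",
          payload = list(candidates = cand$diplotype))
}

#' Simulate a full workflow trajectory for a ground-truth diplotype
#'
#' Runs the state machine against noiseless simulated evidence: the initial
#' TaqMan-style two-probe screen, then whatever follow-up [nextAction()]
#' requests, each follow-up answered from the forward model of `truth`.
#' Useful for exercising and auditing the workflow; every trajectory
#' terminates in report_diplotype or manual_review.
#'
#' @param truth a [Diplotype-class] or diplotype string.
#' @param table a [HaplotypeTable-class].
#' @param maxSteps safety cap on transitions.
#' @param maxUnits forwarded to the enumerator.
#' @return list with `actions` (character vector of the actions taken),
#'   `final` (the terminal [WorkflowAction-class]) and `state`.
#' @export
workflowTrajectory <- function(truth, table, maxSteps = 8L, maxUnits = 4L) {
  if (is.character(truth)) truth <- parseDiplotype(truth, table = table)
  # initial screen: multiplex SNV genotypes plus the two-probe CNV screen
  snv <- simulateObservations(truth,
                              panels = list(panelOf("PharmacoScan",
                                                    table@gene)),
                              table = table, regions = character())
  screen <- expectedCnv(truth, table, regions = c("intron2", "exon9"),
                        platform = "TaqMan")
  obs <- observationSet(sampleId = "trajectory", gene = table@gene,
                        genotypes = genotypesOf(snv), cnv = list(screen),
                        signals = signalsOf(snv))
  state <- workflowState(obs)
  actions <- character()
  for (step in seq_len(maxSteps)) {
    act <- nextAction(state, table, maxUnits = maxUnits)
    actions <- c(actions, actionOf(act))
    if (actionOf(act) %in% c("report_diplotype", "manual_review"))
      return(list(actions = actions, final = act, state = state))
    state <- .applyAction(state, act, truth, table)
  }
  list(actions = actions, final = act, state = state)
}

# answer a follow-up request from the noiseless forward model of `truth`
.applyAction <- function(state, act, truth, table) {
  obs <- state@observations
  a <- actionOf(act)
  if (a == "run_third_cnv_probe") {
    v3 <- expectedCnv(truth, table, regions = c("intron2", "intron6", "exon9"),
                      platform = "TaqMan")
    obs@cnv <- list(v3)
    state@observations <- obs
    state@stepsDone <- c(state@stepsDone, "third_cnv_probe")
  } else if (a == "generate_hybrid_amplicon_and_genotype") {
    units <- diplotypeUnits(truth)
    hybs <- units$star[vapply(units$star, function(s)
      grepl("^hybrid", .hapRow(table, s)$structural_kind), logical(1))]
    calls <- lapply(unique(hybs), function(h) {
      st <- table@states[h, ]
      setNames(ifelse(is.na(st), "NOCALL", ifelse(st == "var", "MUT", "WT")),
               colnames(table@states))
    })
    state@ampliconCalls <- c(state@ampliconCalls, calls)
    state@stepsDone <- c(state@stepsDone, "hybrid_amplicon")
  } else if (a == "phase_duplication") {
    g <- obs@genotypes
    het <- unique(g$site[g$category == "HET"])
    n <- max(cnvCalls(expectedCnv(truth, table)))
    for (s in het) {
      m <- .varCopyCount(truth, s, table)
      if (m < 1L || m >= n) next
      pairs <- data.frame(wt_signal = c(n - m, n - m) * 100,
                          var_signal = c(m, m) * 100)
      state@phasing[[s]] <- phaseXn(pairs, totalCopies = n)
    }
    state@stepsDone <- c(state@stepsDone, "phase")
  } else if (a == "sanger_confirm") {
    obs@evidence$sanger <- formatDiplotype(truth, "sub")
    state@observations <- obs
    state@stepsDone <- c(state@stepsDone, "sanger")
  } else if (a == "repeat_assay") {
    state@stepsDone <- c(state@stepsDone, "repeat")
  }
  state
}
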