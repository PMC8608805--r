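#' Collapse a diplotype to what a platform's panel can represent
#'
#' Maps each gene unit to the panel's best representation: haplotypes the
#' panel distinguishes are kept; sub-alleles collapse to a covered core star;
#' other full-gene haplotypes fall back to the reference *1 (flagged).
#' Structurally undetectable features are dropped: a hybrid on a
#' hybrid-blind panel disappears, and a whole-gene deletion on a
#' deletion-blind panel leaves the remaining chromosome apparently homozygous
#' (so *13 + *4/*5 collapses to *4/*4 on the AmpliChip, and *1/*17 to *1/*1
#' on the AmpliChip CYP2C19 panel). Repeats collapse to single copies unless
#' the panel reports duplications (or lists the matching "*NxN" allele).
#'
#' @param d a [Diplotype-class] or diplotype string.
#' @param panel a [PlatformPanel-class].
#' @param table a [HaplotypeTable-class].
#' @return list with elements `diplotype` (a [Diplotype-class], or NULL when
#'   nothing is detectable), `string` (canonical core-resolution string or
#'   NA), `representable` (FALSE when a structural feature was dropped), and
#'   `flags`.
#' @examples
#' tab <- builtinHaplotypeTable("CYP2C19")
#' collapseCall("*1/*17", panelOf("AmpliChip", "CYP2C19"), tab)$string
#' @export
collapseCall <- function(d, panel, table) {
  if (is.character(d)) d <- parseDiplotype(d, table = table)
  flags <- character(); representable <- TRUE
  hl <- panelHaplotypes(panel)
  mapChrom <- function(ch) {
    stars <- character(); ns <- integer()
    for (i in seq_len(nrow(ch))) {
      star <- ch$star[i]; n <- ch$n[i]
      row <- .hapRow(table, star)
      core <- row$core
      kind <- row$structural_kind
      if (kind == "deletion") {
        if (!panel@detectsDeletion) {
          flags <<- c(flags, paste0("deletion_undetectable:", star))
          representable <<- FALSE
          next
        }
        mapped <- if (star %in% hl || core %in% hl) star else star
      } else if (grepl("^hybrid", kind)) {
        if (star %in% hl) mapped <- star
        else if (core %in% hl) mapped <- core
        else {
          flags <<- c(flags, paste0("hybrid_undetectable:", star))
          representable <<- FALSE
          next
        }
      } else {
        if (star %in% hl || star == "*1") mapped <- star
        else if (core %in% hl || core == "*1") mapped <- core
        else {
          flags <<- c(flags, paste0("collapsed_to_reference:", star))
          mapped <- "*1"
        }
      }
      if (n > 1L && !(panel@detectsDuplication ||
                      paste0(core, "xN") %in% hl)) {
        flags <<- c(flags, paste0("duplication_undetectable:", star))
        n <- 1L
      }
      stars <- c(stars, mapped); ns <- c(ns, n)
    }
    if (!length(stars)) return(NULL)
    data.frame(star = stars, n = ns, stringsAsFactors = FALSE)
  }
  a <- mapChrom(d@chromA); b <- mapChrom(d@chromB)
  if (is.null(a) && is.null(b))
    return(list(diplotype = NULL, string = NA_character_,
                representable = FALSE,
                flags = unique(c(flags, "no_genes_detectable"))))
  if (is.null(a)) { a <- b; flags <- c(flags, "hemizygous_appears_homozygous") }
  if (is.null(b)) { b <- a; flags <- c(flags, "hemizygous_appears_homozygous") }
  dd <- diplotype(a, b)
  list(diplotype = dd, string = formatDiplotype(dd, "core"),
       representable = representable, flags = unique(flags))
}

#' Construct a platform call
#'
#' @param sampleId,platform identifiers.
#' @param diplotype diplotype string, or NA for a no-call.
#' @param alternatives alternative call strings; "UNK" matches any
#'   chromosome (e.g. "*4/UNK").
#' @param tier evidence tier; defaults to the platform's built-in tier
#'   (3 sequencing-grade > 2 multiplex > 1 screening).
#' @param gene gene (used to look up the default tier).
#' @return a [PlatformCall-class].
#' @export
platformCall <- function(sampleId = "sample", platform, diplotype = NA,
                         alternatives = character(), tier = NULL,
                         gene = "CYP2D6") {
  if (is.null(tier))
    tier <- tryCatch(evidenceTier(panelOf(platform, gene)),
                     error = function(e) 2L)
  new("PlatformCall", sampleId = sampleId, platform = platform,
      diplotype = as.character(diplotype), alternatives = alternatives,
      tier = as.integer(tier))
}

# does core-resolution diplotype string x match pattern (may contain UNK)?
.matchWithUnk <- function(x, pattern) {
  xs <- sort(strsplit(x, "/", fixed = TRUE)[[1]])
  ps <- strsplit(pattern, "/", fixed = TRUE)[[1]]
  if (length(ps) != 2L || length(xs) != 2L) return(FALSE)
  norm <- function(s) starCore(trimws(s))
  ps <- vapply(ps, norm, character(1))
  xs2 <- vapply(xs, function(s)
    paste(norm(strsplit(s, "+", fixed = TRUE)[[1]]), collapse = " + "),
    character(1))
  for (perm in list(c(1, 2), c(2, 1))) {
    ok <- all(ps[perm] == "UNK" | ps[perm] == xs2)
    if (ok) return(TRUE)
  }
  FALSE
}

.coreString <- function(x, table = NULL) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    tryCatch(formatDiplotype(parseDiplotype(s), "core"),
             error = function(e) s)
  }, character(1), USE.NAMES = FALSE)
}

#' Derive the cross-platform consensus diplotype
#'
#' The consensus is the unique diplotype consistent, after [collapseCall()]
#' per platform, with every platform's call (or alternatives) and with all
#' CNV, phasing and amplicon observations. Consistency, not majority vote: a
#' hybrid-blind platform's *4/*4 is consistent-after-collapse with
#' *13 + *4/*5. Ties are broken by evidence tier; otherwise the result is
#' unresolved with the surviving candidate set and a rationale trail.
#'
#' @param calls list of [PlatformCall-class] objects.
#' @param observations optional [ObservationSet-class]; when genotype or CNV
#'   observations are present the candidate pool is enumerated from them
#'   (`mixed_amplicon` evidence restricts candidates to configurations
#'   containing a whole-gene deletion).
#' @param table a [HaplotypeTable-class].
#' @param maxUnits forwarded to [enumerateDiplotypes()].
#' @return a [ConsensusResult-class].
#' @export
deriveConsensus <- function(calls, observations = NULL, table,
                            maxUnits = 4L) {
  gene <- table@gene
  trail <- character()
  haveObs <- !is.null(observations) &&
    (nrow(observations@genotypes) > 0L || length(observations@cnv) > 0L)
  if (!haveObs && !length(calls))
    .stop("need at least one platform call or raw observations")

  if (haveObs) {
    reqDel <- isTRUE(observations@evidence$mixed_amplicon)
    cand <- enumerateDiplotypes(.pooledGenotypes(observations),
                                cnv = observations@cnv, table = table,
                                maxUnits = maxUnits,
                                requireDeletion = reqDel)
    pool <- cand$diplotype
    trail <- c(trail, paste0(length(pool),
                             " candidate(s) from pooled observations",
                             if (reqDel) " (deletion required by mixed hybrid amplicon)"))
  } else {
    pool <- unique(stats::na.omit(unlist(lapply(calls, function(k)
      c(k@diplotype, k@alternatives)))))
    pool <- pool[!grepl("UNK", pool)]
    trail <- c(trail, paste0(length(pool), " candidate(s) from platform calls"))
  }
  if (!length(pool))
    return(new("ConsensusResult", sampleId = .sampleIdOf(calls, observations),
               diplotype = NA_character_, resolved = FALSE,
               candidates = character(), contributing = character(),
               discordant = character(), trail = c(trail, "no candidates")))

  keep <- rep(TRUE, length(pool))
  for (k in calls) {
    panel <- tryCatch(panelOf(k@platform, gene), error = function(e) NULL)
    if (is.null(panel)) next
    cc <- vapply(pool, function(p)
      collapseCall(p, panel, table)$string %||% NA_character_, character(1))
    if (!is.na(k@diplotype)) {
      ok <- !is.na(cc) & cc == .coreString(k@diplotype)
    } else if (length(k@alternatives)) {
      ok <- vapply(seq_along(pool), function(i)
        !is.na(cc[i]) && any(vapply(k@alternatives, function(a)
          .matchWithUnk(cc[i], a), logical(1))), logical(1))
    } else ok <- rep(TRUE, length(pool))
    trail <- c(trail, paste0(k@platform, " (",
                             if (is.na(k@diplotype)) "no call" else k@diplotype,
                             "): ", sum(keep & ok), " candidate(s) remain"))
    keep <- keep & ok
  }
  surv <- pool[keep]

  if (length(surv) > 1L && length(calls)) {
    tiers <- sort(unique(vapply(calls, function(k) k@tier, integer(1))),
                  decreasing = TRUE)
    for (t in tiers) {
      asserted <- .coreString(stats::na.omit(vapply(
        calls[vapply(calls, function(k) k@tier, integer(1)) == t],
        function(k) k@diplotype, character(1))))
      hit <- .coreString(surv) %in% asserted
      if (any(hit) && sum(hit) < length(surv)) {
        surv <- surv[hit]
        trail <- c(trail, paste0("tie broken by tier-", t, " evidence"))
      }
      if (length(surv) == 1L) break
    }
  }

  resolved <- length(surv) == 1L
  consensus <- if (resolved) .coreString(surv) else NA_character_
  contributing <- discordant <- character()
  if (resolved) {
    for (k in calls) {
      panel <- tryCatch(panelOf(k@platform, gene), error = function(e) NULL)
      if (is.null(panel)) next
      cc <- collapseCall(surv, panel, table)$string
      agrees <- !is.na(k@diplotype) && !is.na(cc) &&
        cc == .coreString(k@diplotype)
      if (agrees) contributing <- c(contributing, k@platform)
      else if (!is.na(k@diplotype)) discordant <- c(discordant, k@platform)
    }
    trail <- c(trail, paste0("consensus: ", consensus))
  } else {
    trail <- c(trail, paste0("unresolved; ", length(surv),
                             " surviving candidate(s)"))
  }
  new("ConsensusResult", sampleId = .sampleIdOf(calls, observations),
      diplotype = consensus, resolved = resolved,
      candidates = .coreString(surv), contributing = contributing,
      discordant = discordant, trail = trail)
}

.sampleIdOf <- function(calls, observations) {
  if (!is.null(observations)) return(observations@sampleId)
  if (length(calls)) return(calls[[1]]@sampleId)
  "sample"
}

#' @describeIn ConsensusResult-class the consensus diplotype string (NA when
#'   unresolved)
#' @param x a ConsensusResult
#' @export
consensusDiplotype <- function(x) x@diplotype

#' @describeIn ConsensusResult-class rationale trail
#' @export
consensusTrail <- function(x) x@trail

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult [", object@sampleId, "]: ",
      if (object@resolved) object@diplotype else
        paste0("unresolved (", length(object@candidates), " candidates)"),
      "\n", sep = "")
})

#' Format a concordance cell the way concordance tables print it
#'
#' @param concordant,assayed counts (no-calls included in `assayed`).
#' @return "100" when fully concordant, otherwise e.g. "97.7 (42/43)".
#' @export
formatConcordanceCell <- function(concordant, assayed) {
  if (assayed == 0L) return("NA")
  if (concordant == assayed) return("100")
  sprintf("%s (%d/%d)",
          formatC(100 * concordant / assayed, digits = 1, format = "f"),
          concordant, assayed)
}

#' Per-genotype-group platform concordance with the consensus
#'
#' For each consensus genotype group (core-star resolution) and platform:
#' percent concordance = 100 x (calls equal to the consensus) / (samples
#' assayed on that platform), with no-calls counted in the denominator.
#'
#' @param calls data.frame(sample_id, platform, call); `call` NA = no-call.
#'   A sample is "assayed" on a platform iff it has a row for it.
#' @param consensus data.frame(sample_id, consensus).
#' @return a [ConcordanceTable-class]; the underlying data.frame has one row
#'   per genotype group plus an "overall" row, and per platform the columns
#'   `<platform>_pct`, `<platform>_n` ("c/n") and `<platform>_cell`.
#' @export
concordanceTable <- function(calls, consensus) {
  stopifnot(all(c("sample_id", "platform", "call") %in% names(calls)),
            all(c("sample_id", "consensus") %in% names(consensus)))
  if (!all(calls$sample_id %in% consensus$sample_id))
    .stop("every called sample needs a consensus")
  cons <- setNames(.coreString(consensus$consensus), consensus$sample_id)
  calls$consensus <- cons[calls$sample_id]
  calls$concordant <- !is.na(calls$call) &
    .coreString(calls$call) == calls$consensus
  groups <- c(sort(unique(calls$consensus)), "overall")
  platforms <- unique(calls$platform)
  rows <- lapply(groups, function(gp) {
    sub <- if (gp == "overall") calls else
      calls[calls$consensus == gp, , drop = FALSE]
    row <- list(group = gp, N = length(unique(sub$sample_id)))
    for (p in platforms) {
      ps <- sub[sub$platform == p, , drop = FALSE]
      n <- nrow(ps); cc <- sum(ps$concordant)
      row[[paste0(p, "_pct")]] <- if (n) 100 * cc / n else NA_real_
      row[[paste0(p, "_n")]] <- paste0(cc, "/", n)
      row[[paste0(p, "_cell")]] <- if (n) formatConcordanceCell(cc, n) else "NA"
    }
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  new("ConcordanceTable", table = do.call(rbind, rows))
}

#' @describeIn ConcordanceTable-class the underlying data.frame
#' @param x a ConcordanceTable
#' @export
concordanceFrame <- function(x) x@table

setMethod("show", "ConcordanceTable", function(object) {
  cat("ConcordanceTable:\n")
  cells <- grep("_cell$|^group$|^N$", names(object@table))
  print(object@table[, cells], row.names = FALSE)
})

#' Report activity-score revisions between prior and consensus genotypes
#'
#' Counts samples whose activity score differs between the prior calls and
#' the consensus (a no-call prior that gains a genotype counts as changed),
#' and tabulates the metabolizer-phenotype transitions.
#'
#' @param prior,consensus data.frames with columns sample_id, call (prior
#'   `call` may be NA for a no-call); same sample set.
#' @param table a [HaplotypeTable-class].
#' @param cutpoints optional phenotype cut-point override.
#' @return list with nChanged, nTotal, fraction, and `transitions` (a
#'   phenotype x phenotype contingency matrix, prior in rows).
#' @export
revisionReport <- function(prior, consensus, table, cutpoints = NULL) {
  stopifnot(setequal(prior$sample_id, consensus$sample_id))
  cons <- setNames(consensus$call, consensus$sample_id)
  levs <- c("PM", "IM", "NM", "UM", "indeterminate")
  trans <- matrix(0L, 5, 5, dimnames = list(prior = levs, consensus = levs))
  changed <- 0L
  for (i in seq_len(nrow(prior))) {
    sid <- prior$sample_id[i]
    pc <- prior$call[i]; cc <- cons[[sid]]
    pres <- if (is.na(pc)) NULL else activityScore(pc, table, cutpoints)
    cres <- activityScore(cc, table, cutpoints)
    pph <- if (is.null(pres)) "indeterminate" else phenotypeOf(pres)
    cph <- phenotypeOf(cres)
    trans[pph, cph] <- trans[pph, cph] + 1L
    sp <- if (is.null(pres)) NA_real_ else scoreOf(pres)
    sc <- scoreOf(cres)
    dif <- is.na(pc) || is.na(sp) != is.na(sc) ||
      (!is.na(sp) && !is.na(sc) && sp != sc)
    if (dif) changed <- changed + 1L
  }
  list(nChanged = changed, nTotal = nrow(prior),
       fraction = changed / nrow(prior), transitions = trans)
}
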