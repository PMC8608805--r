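# Per-haplotype site masks. Deletion units carry neither ref nor var at any
# site; hybrid rows carry NA where their state is undefined.
.hapMasks <- function(table) {
  st <- table@states
  del <- table@defs$structural_kind == "deletion"
  varM <- !is.na(st) & st == "var"
  refM <- !is.na(st) & st == "ref"
  varM[del, ] <- FALSE
  refM[del, ] <- FALSE
  list(var = varM, ref = refM)
}

.normGenotypes <- function(genotypes, gene) {
  if (is.null(genotypes) ||
      (is.data.frame(genotypes) && !nrow(genotypes)) ||
      (!is.data.frame(genotypes) && !length(genotypes)))
    return(data.frame(site = character(), category = character(),
                      stringsAsFactors = FALSE))
  if (!is.data.frame(genotypes))
    genotypes <- data.frame(site = names(genotypes),
                            category = unname(genotypes),
                            stringsAsFactors = FALSE)
  if (!all(c("site", "category") %in% names(genotypes)))
    .stop("genotypes need columns 'site' and 'category'")
  bad <- !genotypes$category %in% GENOTYPE_CATEGORIES
  if (any(bad)) .stop("unknown genotype category '",
                      genotypes$category[bad][1], "'")
  genotypes$site <- .canonicalSites(genotypes$site, gene)
  genotypes
}

#' Is a diplotype consistent with observed site genotype categories?
#'
#' Presence semantics for multiplex category data: at every non-NOCALL site,
#' HET holds iff some gene unit carries the variant and some unit carries the
#' reference; MUT iff at least one unit carries the variant and none the
#' reference; WT the reverse. Deletion units carry neither allele and are
#' skipped, so a hemizygous *X/*5 yields WT or MUT, never HET. With three or
#' more gene copies HET means "both alleles present somewhere" (dosage
#' refinement is delegated to phasing), so *41x3/*1 is consistent with HET at
#' the *41-defining site.
#'
#' @param d a [Diplotype-class] or diplotype string.
#' @param genotypes named character vector (site -> category) or data.frame
#'   with columns site, category. Categories among [GENOTYPE_CATEGORIES];
#'   NOCALL and LOW_SIGNAL impose no constraint.
#' @param table a [HaplotypeTable-class].
#' @param panel optional [PlatformPanel-class]; genotypes at sites outside
#'   the panel are an error.
#' @return logical scalar.
#' @examples
#' tab <- builtinHaplotypeTable("CYP2D6")
#' isConsistent("*4/*5", c(rs3892097 = "MUT"), tab)
#' isConsistent("*1/*1", c(rs3892097 = "HET"), tab)
#' @export
isConsistent <- function(d, genotypes, table, panel = NULL) {
  if (is.character(d)) d <- parseDiplotype(d, table = table)
  g <- .normGenotypes(genotypes, table@gene)
  if (!is.null(panel)) {
    out <- setdiff(g$site, panelSites(panel))
    if (length(out)) .stop("genotype at site(s) outside the ", panel@name,
                           " panel: ", paste(out, collapse = ", "))
  }
  g <- g[!g$category %in% c("NOCALL", "LOW_SIGNAL"), , drop = FALSE]
  if (!nrow(g)) return(TRUE)
  masks <- .hapMasks(table)
  units <- diplotypeUnits(d)
  for (s in units$star) .hapRow(table, s)
  sites <- g$site
  known <- sites %in% colnames(masks$var)
  V <- R <- setNames(rep(FALSE, length(sites)), sites)
  for (s in units$star) {
    V[known] <- V[known] | masks$var[s, sites[known]]
    R[known] <- R[known] | masks$ref[s, sites[known]]
  }
  want <- g$category
  all((want != "HET" | (V & R)) &
      (want != "MUT" | (V & !R)) &
      (want != "WT"  | (!V & R)))
}

## ---- chromosome configuration space --------------------------------------

# All chromosome configurations with at most maxChrom gene units: single
# stars with repeat 1..3, the deletion alone, hybrids (x1, x2) alone, and
# hybrid tandems (hybrid xm + full gene xn). Precomputes site carrier masks,
# probe-region copy sums and the structural-event rank key.
.configSpace <- function(table, maxChrom = 3L) {
  key <- paste0("cfg_", table@gene, "_", maxChrom, "_", nrow(table@defs), "_",
                sum(table@states == "var", na.rm = TRUE), "_",
                paste(range(rownames(table@states)), collapse = ""))
  if (!is.null(.sd_cache[[key]])) return(.sd_cache[[key]])

  defs <- table@defs
  masks <- .hapMasks(table)
  nsite <- ncol(table@states)
  contrib <- t(vapply(seq_len(nrow(defs)), function(i)
    .unitContribution(defs$structural_kind[i], defs$switch_lo[i],
                      defs$switch_hi[i]), integer(length(PROBE_REGIONS))))
  rownames(contrib) <- defs$star

  stars <- list(); ns <- list()
  full <- defs$star[defs$structural_kind == "full_gene"]
  dels <- defs$star[defs$structural_kind == "deletion"]
  hybs <- defs$star[grepl("^hybrid", defs$structural_kind)]
  for (s in full) for (n in seq_len(min(3L, maxChrom))) {
    stars[[length(stars) + 1L]] <- s; ns[[length(ns) + 1L]] <- n
  }
  for (s in dels) { stars[[length(stars) + 1L]] <- s; ns[[length(ns) + 1L]] <- 1L }
  for (h in hybs) {
    for (m in seq_len(min(2L, maxChrom))) {
      stars[[length(stars) + 1L]] <- h; ns[[length(ns) + 1L]] <- m
      for (f in full) for (n in seq_len(maxChrom - m)) {
        stars[[length(stars) + 1L]] <- c(h, f)
        ns[[length(ns) + 1L]] <- c(m, n)
      }
    }
  }

  ncfg <- length(stars)
  varAt <- matrix(FALSE, ncfg, nsite, dimnames = list(NULL, colnames(table@states)))
  refAt <- varAt
  regionSum <- matrix(0L, ncfg, length(PROBE_REGIONS),
                      dimnames = list(NULL, PROBE_REGIONS))
  events <- integer(ncfg); novel <- logical(ncfg)
  unitsN <- integer(ncfg); label <- character(ncfg)
  partners <- strsplit(defs$tandem_partners, ",", fixed = TRUE)
  names(partners) <- defs$star
  kindOf <- setNames(defs$structural_kind, defs$star)

  for (i in seq_len(ncfg)) {
    ss <- stars[[i]]; nn <- ns[[i]]
    varAt[i, ] <- apply(masks$var[ss, , drop = FALSE], 2, any)
    refAt[i, ] <- apply(masks$ref[ss, , drop = FALSE], 2, any)
    regionSum[i, ] <- as.integer(nn %*% contrib[ss, , drop = FALSE])
    events[i] <- sum(kindOf[ss] != "full_gene") + sum(nn - 1L) +
      (length(ss) - 1L)
    unitsN[i] <- sum(nn)
    label[i] <- .formatChrom(data.frame(star = ss, n = nn))
    if (length(ss) == 2L)
      novel[i] <- !(starCore(ss[2]) %in% partners[[ss[1]]] ||
                    ss[2] %in% partners[[ss[1]]])
  }
  cs <- list(stars = stars, ns = ns, varAt = varAt, refAt = refAt,
             regionSum = regionSum, events = events, novel = novel,
             unitsN = unitsN, label = label)
  .sd_cache[[key]] <- cs
  cs
}

## ---- enumeration ---------------------------------------------------------

#' Enumerate diplotypes consistent with genotype categories and CNV evidence
#'
#' Returns exactly the diplotypes with at most `maxUnits` gene units that
#' satisfy the presence semantics of [isConsistent()] at every non-NOCALL
#' site and whose forward-model CNV ([expectedCnv()]) matches the observed
#' probe vectors (or the structural hypothesis). Candidates are ranked by
#' fewest structural events, then known tandem partners before novel
#' tandems, then star-name lexicographic order; all candidates are reported
#' so that alternative calls remain visible. An empty result is a valid
#' outcome ("no call").
#'
#' @inheritParams isConsistent
#' @param cnv CNV evidence: a [CnvProbeVector-class], a list of them, a
#'   [StructuralHypothesis-class], or NULL (no copy-number constraint).
#' @param maxUnits maximum total gene units per diplotype (default 4, which
#'   covers *13 + *2 and *41x3 style configurations).
#' @param requireDeletion when TRUE, only candidates containing a whole-gene
#'   deletion unit are kept (used for mixed hybrid-amplicon evidence).
#' @return data.frame with columns diplotype, core, events, novel_tandem,
#'   flags; rows in rank order. Attribute "nocall_sites" lists unconstrained
#'   sites.
#' @examples
#' tab <- builtinHaplotypeTable("CYP2C19")
#' enumerateDiplotypes(c(rs4244285 = "HET", rs12248560 = "HET"), NULL, tab)
#' @export
enumerateDiplotypes <- function(genotypes, cnv, table, panel = NULL,
                                maxUnits = 4L, requireDeletion = FALSE) {
  if (maxUnits < 2L) .stop("maxUnits must be >= 2")
  g <- .normGenotypes(genotypes, table@gene)
  if (!is.null(panel)) {
    out <- setdiff(g$site, panelSites(panel))
    if (length(out)) .stop("genotype at site(s) outside the ", panel@name,
                           " panel: ", paste(out, collapse = ", "))
  }
  nocall <- g$site[g$category %in% c("NOCALL", "LOW_SIGNAL")]
  lowsig <- g$site[g$category == "LOW_SIGNAL"]
  g <- g[!g$category %in% c("NOCALL", "LOW_SIGNAL"), , drop = FALSE]

  cs <- .configSpace(table, maxChrom = maxUnits - 1L)
  ncfg <- length(cs$label)
  known <- g$site %in% colnames(cs$varAt)
  W <- g$site[g$category == "WT" & known]
  M <- g$site[g$category == "MUT" & known]
  H <- g$site[g$category == "HET" & known]
  # an observed category at a site no haplotype defines states for
  if (any(!known & g$category %in% c("MUT", "HET")))
    return(.emptyCandidates(nocall, lowsig))

  # per-config prefilter: a config carrying var at a WT site, or ref at a
  # MUT site, can never be part of a consistent pair
  keep <- rep(TRUE, ncfg)
  if (length(W)) keep <- keep & !apply(cs$varAt[, W, drop = FALSE], 1, any)
  if (length(M)) keep <- keep & !apply(cs$refAt[, M, drop = FALSE], 1, any)
  if (requireDeletion) {
    hasDel <- vapply(seq_len(ncfg), function(i)
      any(cs$regionSum[i, ] == 0L) &&
        any(vapply(cs$stars[[i]], function(s)
          .hapRow(table, s)$structural_kind == "deletion", logical(1))),
      logical(1))
  }
  idx <- which(keep)
  if (!length(idx)) return(.emptyCandidates(nocall, lowsig))

  rs <- cs$regionSum[idx, , drop = FALSE]
  un <- cs$unitsN[idx]
  P <- outer(un, un, "+") <= maxUnits
  P[lower.tri(P)] <- FALSE

  vectors <- NULL; hypothesis <- NULL
  if (is(cnv, "CnvProbeVector")) vectors <- list(cnv)
  else if (is(cnv, "StructuralHypothesis")) hypothesis <- cnv
  else if (is.list(cnv) && length(cnv)) vectors <- cnv
  if (!is.null(vectors)) {
    for (v in vectors) {
      usable <- names(v@calls)[v@confidence >= 0.95]
      for (r in usable)
        P <- P & (outer(rs[, r], rs[, r], "+") == v@calls[[r]])
    }
  }
  for (s in M) P <- P & outer(cs$varAt[idx, s], cs$varAt[idx, s], "|")
  for (s in W) P <- P & outer(cs$refAt[idx, s], cs$refAt[idx, s], "|")
  for (s in H) {
    P <- P & outer(cs$varAt[idx, s], cs$varAt[idx, s], "|") &
             outer(cs$refAt[idx, s], cs$refAt[idx, s], "|")
  }
  hits <- which(P, arr.ind = TRUE)
  if (!nrow(hits)) return(.emptyCandidates(nocall, lowsig))

  i <- idx[hits[, 1]]; j <- idx[hits[, 2]]
  if (requireDeletion) {
    ok <- hasDel[i] | hasDel[j]
    i <- i[ok]; j <- j[ok]
  }
  if (!is.null(hypothesis) && length(i)) {
    ok <- vapply(seq_along(i), function(k) {
      hyp <- .classifyMap(setNames(
        cs$regionSum[i[k], ] + cs$regionSum[j[k], ], PROBE_REGIONS))
      .hypCompatible(hyp, hypothesis)
    }, logical(1))
    i <- i[ok]; j <- j[ok]
  }
  if (!length(i)) return(.emptyCandidates(nocall, lowsig))

  dip <- paste0(pmin(cs$label[i], cs$label[j]), "/",
                pmax(cs$label[i], cs$label[j]))
  events <- cs$events[i] + cs$events[j]
  novel <- cs$novel[i] | cs$novel[j]
  dupes <- duplicated(dip)
  out <- data.frame(diplotype = dip[!dupes], events = events[!dupes],
                    novel_tandem = novel[!dupes], stringsAsFactors = FALSE)
  out$core <- vapply(out$diplotype, function(x)
    formatDiplotype(parseDiplotype(x), "core"), character(1),
    USE.NAMES = FALSE)
  out <- out[order(out$events, out$novel_tandem, out$diplotype), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$flags <- if (length(nocall))
    paste0("nocall:", paste(nocall, collapse = ",")) else ""
  out <- out[, c("diplotype", "core", "events", "novel_tandem", "flags")]
  attr(out, "nocall_sites") <- nocall
  attr(out, "low_signal_sites") <- lowsig
  out
}

.emptyCandidates <- function(nocall = character(), lowsig = character()) {
  out <- data.frame(diplotype = character(), core = character(),
                    events = integer(), novel_tandem = logical(),
                    flags = character(), stringsAsFactors = FALSE)
  attr(out, "nocall_sites") <- nocall
  attr(out, "low_signal_sites") <- lowsig
  out
}

# is a candidate's own classification compatible with an observed hypothesis?
.hypCompatible <- function(cand, obs) {
  if (obs@kind == "conflict") return(TRUE)
  if (cand@kind != obs@kind) return(FALSE)
  if (grepl("^hybrid", obs@kind) && !is.na(obs@switchLo) &&
      !is.na(cand@switchLo)) {
    lo <- max(match(c(cand@switchLo, obs@switchLo), PROBE_REGIONS))
    hi <- min(match(c(cand@switchHi, obs@switchHi), PROBE_REGIONS))
    return(lo < hi)
  }
  TRUE
}

## ---- amplicon matching ---------------------------------------------------

#' Match a hemizygous amplicon genotype vector to single haplotypes
#'
#' Long-range PCR amplicons interrogate a single haplotype, so their
#' genotypes are WT/MUT only. Returns every haplotype whose state vector
#' matches the calls at the assayed sites (sites with undefined state are
#' skipped), most specific (most matched variant sites) first.
#'
#' @param calls named character vector (site -> category) or data.frame with
#'   columns site, category; categories WT/MUT/NOCALL/LOW_SIGNAL.
#' @param table a [HaplotypeTable-class].
#' @return character vector of star-allele names, most specific first.
#' @examples
#' tab <- builtinHaplotypeTable("CYP2D6")
#' matchAmplicon(c(rs769258 = "MUT", `137_138insT` = "MUT",
#'                 rs16947 = "WT", rs1135840 = "MUT"), tab)[1]
#' @export
matchAmplicon <- function(calls, table) {
  g <- .normGenotypes(calls, table@gene)
  if (any(g$category == "HET"))
    .stop("HET call at ", g$site[g$category == "HET"][1],
          ": amplicon is not single-haplotype; use detectMixedAmplicon()",
          class = "stardiplo_mixed_amplicon")
  g <- g[g$category %in% c("WT", "MUT"), , drop = FALSE]
  st <- table@states
  keep <- table@defs$structural_kind != "deletion"
  res <- character(); spec <- integer()
  for (i in which(keep)) {
    sites <- intersect(g$site, colnames(st))
    s <- st[i, sites]
    use <- !is.na(s)
    want <- g$category[match(sites, g$site)][use] == "MUT"
    if (all((s[use] == "var") == want)) {
      res <- c(res, table@defs$star[i])
      spec <- c(spec, sum(want))
    }
  }
  res[order(-spec, res)]
}

#' Detect a mixed (two-template) amplicon from ordered site calls
#'
#' A hybrid-specific L-PCR amplicon that co-amplified two molecules appears
#' WT/MUT-only upstream and heterozygous from some point onwards; the
#' boundary localises the switch region. Returns NULL when no HET call is
#' present.
#'
#' @param calls data.frame with columns site, category, ordered 5' to 3' (or
#'   a named vector; ordering by registry position is applied when `gene` is
#'   given).
#' @param gene optional gene for position-based ordering.
#' @return NULL, or a list with elements `upstreamSite` (last clean site
#'   before the first HET; NA at sequence start), `firstHetSite`, and
#'   `regionInterval` c(lo, hi): the probe-region boundary within which the
#'   template switch must lie.
#' @export
detectMixedAmplicon <- function(calls, gene = NULL) {
  g <- if (is.data.frame(calls)) calls else
    data.frame(site = names(calls), category = unname(calls),
               stringsAsFactors = FALSE)
  if (!is.null(gene)) {
    g$site <- .canonicalSites(g$site, gene)
    g <- g[order(.sitePosition(g$site, gene)), , drop = FALSE]
  }
  het <- which(g$category == "HET")
  if (!length(het)) return(NULL)
  first <- min(het)
  upstream <- if (first > 1L) g$site[first - 1L] else NA_character_
  lo <- "five_prime_flank"
  if (!is.null(gene)) {
    reg <- resolveSite(g$site[first], gene)$region
    lo <- switch(reg, exon1_intron2 = "five_prime_flank",
                 intron2_intron6 = "intron2", intron6_exon9 = "intron6",
                 five_prime_flank = "five_prime_flank", "five_prime_flank")
  }
  list(upstreamSite = upstream, firstHetSite = g$site[first],
       regionInterval = c(lo, g$site[first]))
}

## ---- activity score ------------------------------------------------------

.cutpoints <- function(gene) {
  key <- "cutpoints"
  if (is.null(.sd_cache[[key]]))
    .sd_cache[[key]] <- utils::read.delim(.extdata("phenotype_cutpoints.tsv"),
                                          comment.char = "#",
                                          stringsAsFactors = FALSE)
  cp <- .sd_cache[[key]]
  cp[cp$gene == gene, , drop = FALSE]
}

#' Activity score and metabolizer phenotype of a diplotype
#'
#' The score is the sum over all gene units (both chromosomes, repeats
#' counted) of the per-haplotype activity value; every *13 hybrid and the *5
#' deletion score 0. The phenotype is read from a configurable cut-point
#' table (default: the shipped CPIC-style cut-points, lo < score <= hi).
#' Units with "uncertain" activity make the result indeterminate.
#'
#' @param d a [Diplotype-class] or diplotype string.
#' @param table a [HaplotypeTable-class] carrying the activity column.
#' @param cutpoints optional data.frame(gene, phenotype, lo, hi) overriding
#'   the shipped cut-points.
#' @return an [ActivityResult-class].
#' @examples
#' tab <- builtinHaplotypeTable("CYP2D6")
#' activityScore("*41x3/*1", tab)   # 3 x 0.25 + 1 = 1.75, NM
#' @export
activityScore <- function(d, table, cutpoints = NULL) {
  if (is.character(d)) d <- parseDiplotype(d, table = table)
  units <- diplotypeUnits(d)
  act <- activityOf(table)
  vals <- act[units$star]
  if (anyNA(match(units$star, names(act))))
    .stop("haplotype not in table: ",
          units$star[is.na(match(units$star, names(act)))][1])
  if (anyNA(vals))
    return(new("ActivityResult", score = NA_real_,
               phenotype = "indeterminate"))
  score <- sum(vals * units$n)
  cp <- cutpoints %||% .cutpoints(table@gene)
  cp <- cp[cp$gene == table@gene | !nzchar(cp$gene), , drop = FALSE]
  hit <- which(score > cp$lo & score <= cp$hi)
  new("ActivityResult", score = score,
      phenotype = if (length(hit)) cp$phenotype[hit[1]] else "indeterminate")
}

#' @describeIn ActivityResult-class numeric score
#' @param x an ActivityResult
#' @export
scoreOf <- function(x) x@score

#' @describeIn ActivityResult-class metabolizer phenotype
#' @export
phenotypeOf <- function(x) x@phenotype

setMethod("show", "ActivityResult", function(object) {
  cat("ActivityResult: score =", object@score, "->", object@phenotype, "\n")
})
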