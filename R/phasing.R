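#' Phase a duplication/multiplication from replicate allelic signal ratios
#'
#' For a site called HET on genomic DNA in a sample with `totalCopies` gene
#' copies, the variant-signal fraction var/(var+wt) clusters near m/n for m
#' variant copies of n. The estimate (mean over non-failed replicates) is
#' assigned to the nearest lattice point m/n when it is within `tol`
#' absolutely and within half the distance to the nearest competing lattice
#' point; otherwise the assignment is ambiguous. When only one probe
#' amplifies the configuration cannot be resolved (C/C vs CC/C vs CC/- vs
#' C/-) and the result is ambiguous.
#'
#' @param pairs data.frame with columns wt_signal, var_signal (and optionally
#'   replicate_id); a replicate with both signals zero is a failed well.
#' @param totalCopies total gene copies (>= 3).
#' @param tol absolute assignment tolerance on the fraction scale (default
#'   0.12).
#' @param controls optional named numeric vector of observed control
#'   fractions re-centering lattice points (names = variant copy count m).
#' @return a [PhaseAssignment-class]; outcome is dup_on_var_haplotype when
#'   the variant haplotype carries the extra copies (m > 1, n - m = 1),
#'   dup_on_ref_haplotype in the mirror case, and ambiguous otherwise
#'   (including the balanced m = n - m configuration, where varCopies is
#'   still recorded).
#' @examples
#' phaseXn(data.frame(wt_signal = c(32, 35), var_signal = c(68, 65)),
#'         totalCopies = 3)   # fraction ~ 2/3: duplication on the variant
#' @export
phaseXn <- function(pairs, totalCopies, tol = 0.12, controls = NULL) {
  if (totalCopies < 3L) .stop("phasing applies to 3 or more gene copies")
  if (!all(c("wt_signal", "var_signal") %in% names(pairs)))
    .stop("pairs need columns wt_signal and var_signal")
  if (any(pairs$wt_signal < 0 | pairs$var_signal < 0))
    .stop("signals must be non-negative")
  live <- pairs$wt_signal > 0 | pairs$var_signal > 0
  if (!any(live)) .stop("all replicates failed (both signals zero)")
  p <- pairs[live, , drop = FALSE]
  f <- p$var_signal / (p$var_signal + p$wt_signal)
  est <- mean(f)
  nrep <- nrow(p)

  if (all(p$var_signal == 0) || all(p$wt_signal == 0))
    return(new("PhaseAssignment", outcome = "ambiguous",
               estVarFraction = est, varCopies = NA_integer_,
               supportingReplicates = as.integer(nrep),
               flags = "single_probe_amplified"))

  n <- as.integer(totalCopies)
  m <- seq_len(n - 1L)
  lattice <- m / n
  if (!is.null(controls)) {
    idx <- match(names(controls), as.character(m))
    lattice[idx[!is.na(idx)]] <- controls[!is.na(idx)]
  }
  dist <- abs(est - lattice)
  best <- which.min(dist)
  # assign only if closer than tol and than half the gap to the runner-up
  sep <- if (length(lattice) > 1L)
    min(abs(lattice[best] - lattice[-best])) / 2 else Inf
  if (dist[best] >= tol || dist[best] >= sep)
    return(new("PhaseAssignment", outcome = "ambiguous",
               estVarFraction = est, varCopies = NA_integer_,
               supportingReplicates = as.integer(nrep),
               flags = "no_unique_lattice_point"))
  mv <- m[best]; mr <- n - mv
  outcome <- if (mv > 1L && mr == 1L) "dup_on_var_haplotype"
             else if (mr > 1L && mv == 1L) "dup_on_ref_haplotype"
             else "ambiguous"   # balanced (e.g. 2 of 4): not attributable
  new("PhaseAssignment", outcome = outcome, estVarFraction = est,
      varCopies = mv, supportingReplicates = as.integer(nrep),
      flags = if (outcome == "ambiguous") "balanced_configuration"
              else character())
}

#' @describeIn PhaseAssignment-class the assignment outcome
#' @param x a PhaseAssignment
#' @export
phaseOutcome <- function(x) x@outcome

#' @describeIn PhaseAssignment-class inferred variant-allele copy count
#' @export
varCopies <- function(x) x@varCopies

setMethod("show", "PhaseAssignment", function(object) {
  cat("PhaseAssignment:", object@outcome,
      sprintf("(est. var fraction %.3f, %d replicates)",
              object@estVarFraction, object@supportingReplicates), "\n")
})

#' Compare duplicate genotyping runs site by site
#'
#' Automated comparison of duplicate runs: identical non-NOCALL categories
#' pass; a NOCALL (or LOW_SIGNAL) in either run requires a repeat;
#' contradictory categories fail.
#'
#' @param run1,run2 named character vectors (site -> category) or data.frames
#'   with columns site, category; both runs must cover the same sites.
#' @return data.frame(site, run1, run2, status) with status in
#'   pass/repeat_needed/fail.
#' @export
compareDuplicates <- function(run1, run2) {
  norm <- function(r) {
    if (is.data.frame(r)) setNames(r$category, r$site) else r
  }
  r1 <- norm(run1); r2 <- norm(run2)
  if (!setequal(names(r1), names(r2)))
    .stop("duplicate runs cover different site sets")
  sites <- names(r1)
  r2 <- r2[sites]
  nc <- c("NOCALL", "LOW_SIGNAL")
  status <- ifelse(r1 %in% nc | r2 %in% nc, "repeat_needed",
                   ifelse(r1 == r2, "pass", "fail"))
  data.frame(site = sites, run1 = unname(r1), run2 = unname(r2),
             status = unname(status), stringsAsFactors = FALSE,
             row.names = NULL)
}
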