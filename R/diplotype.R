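.parseChrom <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) .stop("empty chromosome configuration")
  units <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  m <- regmatches(units, regexec("^(\\*.+?)(?:[x×]([0-9]+))?$", units))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) .stop("cannot parse gene unit '", units[bad][1], "'")
  data.frame(star = vapply(m, `[`, character(1), 2),
             n = vapply(m, function(x)
               if (nzchar(x[3])) as.integer(x[3]) else 1L, integer(1)),
             stringsAsFactors = FALSE)
}

.formatChrom <- function(ch, resolution = "sub") {
  star <- if (resolution == "core") starCore(ch$star) else ch$star
  paste(paste0(star, ifelse(ch$n > 1L, paste0("x", ch$n), "")),
        collapse = " + ")
}

#' Construct a diplotype
#'
#' @param chromA,chromB chromosome configurations, each either a string such
#'   as `"*13[GQ162807] + *2"` or `"*41x3"`, or a data.frame with columns
#'   star and n. The pair is unordered.
#' @param table optional [HaplotypeTable-class]; when given, every star name
#'   must resolve in it.
#' @return a [Diplotype-class].
#' @examples
#' diplotype("*13[GQ162807] + *2", "*1")
#' diplotype("*41x3", "*1")
#' @export
diplotype <- function(chromA, chromB, table = NULL) {
  a <- if (is.data.frame(chromA)) chromA else .parseChrom(chromA)
  b <- if (is.data.frame(chromB)) chromB else .parseChrom(chromB)
  d <- new("Diplotype", chromA = a, chromB = b)
  if (!is.null(table))
    for (s in c(a$star, b$star)) .hapRow(table, s)
  for (ch in list(a, b)) {
    if (any(ch$n < 1L)) .stop("repeat count must be >= 1")
  }
  d
}

#' Parse a diplotype string
#'
#' Accepts the field's notation: chromosomes separated by "/", in-cis tandem
#' units joined by " + ", repeats as "xN" (ASCII) or with the multiplication
#' sign.
#'
#' @param x a string such as `"*13 + *4/*5"` or `"*36x2 + *10/*1"`.
#' @inheritParams diplotype
#' @return a [Diplotype-class].
#' @export
parseDiplotype <- function(x, table = NULL) {
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    .stop("a diplotype has exactly two chromosomes: '", x, "'")
  diplotype(parts[1], parts[2], table = table)
}

#' Format a diplotype as its canonical string
#'
#' Chromosome strings are sorted so that the unordered pair has a unique
#' canonical form; at `resolution = "core"` sub-alleles and sequence-anchored
#' variants are merged into their core star group (e.g. "*13[EU093102] +
#' *4/*5" prints as "*13 + *4/*5").
#'
#' @param d a [Diplotype-class].
#' @param resolution "sub" (full names) or "core".
#' @return character scalar.
#' @export
formatDiplotype <- function(d, resolution = c("sub", "core")) {
  resolution <- match.arg(resolution)
  sides <- sort(c(.formatChrom(d@chromA, resolution),
                  .formatChrom(d@chromB, resolution)))
  paste(sides, collapse = "/")
}

#' @describeIn Diplotype-class all gene units as one data.frame with columns
#'   star, n, chrom
#' @param d a Diplotype
#' @export
diplotypeUnits <- function(d) {
  rbind(cbind(d@chromA, chrom = "A", stringsAsFactors = FALSE),
        cbind(d@chromB, chrom = "B", stringsAsFactors = FALSE))
}

#' Total gene-unit count of a diplotype
#' @param d a [Diplotype-class].
#' @export
totalUnits <- function(d) sum(d@chromA$n) + sum(d@chromB$n)

setMethod("show", "Diplotype", function(object) {
  cat("Diplotype:", formatDiplotype(object), "\n")
})
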