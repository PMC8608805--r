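.REQ_COLS <- c("star_name", "gene", "structural_kind", "switch_interval",
               "tandem_partners", "activity")

#' Core star group of a star-allele name
#'
#' Sub-alleles (e.g. "*2.001") and sequence-anchored variants (e.g.
#' "*13[EU093102]") share a core star group ("*2", "*13") used for reporting
#' at core resolution.
#'
#' @param star character vector of star-allele names.
#' @return character vector of core names.
#' @examples
#' starCore(c("*4.013", "*13[GQ162807]", "*2"))
#' @export
starCore <- function(star) {
  s <- sub("\\[.*\\]$", "", star)
  sub("\\.[0-9]+$", "", s)
}

#' Parse a haplotype definition table
#'
#' Reads the documented tabular dialect: UTF-8 TSV, `#` comment lines, columns
#' star_name, gene, structural_kind, switch_interval, tandem_partners
#' (comma-list), activity, then one column per site (canonical id or legacy
#' label) holding ref/var/na state codes. Unknown site columns are rejected,
#' not silently dropped. Sites absent from the table are implicitly ref.
#'
#' @param stream a file path, connection, or character vector of TSV lines.
#' @return a validated [HaplotypeTable-class].
#' @examples
#' tab <- builtinHaplotypeTable("CYP2C19")
#' starNames(tab)
#' @export
parseHaplotypeTable <- function(stream) {
  if (is.character(stream) && length(stream) > 1L)
    stream <- textConnection(stream)
  df <- utils::read.delim(stream, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(.REQ_COLS, names(df))
  if (length(miss))
    .stop("haplotype table is missing required column(s): ",
          paste(miss, collapse = ", "))
  if (!nrow(df)) .stop("haplotype table has no rows")
  gene <- .assertGene(unique(df$gene))
  if (length(unique(df$gene)) != 1L)
    .stop("haplotype table mixes genes")
  for (col in c("switch_interval", "tandem_partners", "activity")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  dup <- df$star_name[duplicated(df$star_name)]
  if (length(dup))
    .stop("duplicate star_name '", dup[1], "' (row ",
          which(df$star_name == dup[1])[2], ")")

  sitecols <- setdiff(names(df), .REQ_COLS)
  canon <- character(0)
  if (length(sitecols)) {
    canon <- vapply(sitecols, function(s) {
      hit <- tryCatch(resolveSite(s, gene),
                      stardiplo_unknown_site = function(e)
                        .stop("unknown site column '", s,
                              "' in haplotype table for ", gene))
      hit$canonical_id
    }, character(1))
  }

  sw <- strsplit(ifelse(nzchar(df$switch_interval), df$switch_interval, ":"),
                 ":", fixed = TRUE)
  swlo <- vapply(sw, function(x) if (nzchar(x[1])) x[1] else NA_character_,
                 character(1))
  swhi <- vapply(sw, function(x) if (length(x) > 1 && nzchar(x[2])) x[2]
                 else NA_character_, character(1))
  bad <- !is.na(swlo) & !(swlo %in% PROBE_REGIONS & swhi %in% PROBE_REGIONS)
  if (any(bad)) .stop("invalid switch_interval for ", df$star_name[bad][1])
  hyb <- grepl("^hybrid", df$structural_kind)
  if (any(hyb & is.na(swlo)))
    .stop("hybrid haplotype '", df$star_name[hyb & is.na(swlo)][1],
          "' has no switch_interval")

  states <- as.matrix(df[, sitecols, drop = FALSE])
  colnames(states) <- canon
  states[states %in% c("na", "NA", ".", "")] <- NA
  states[states == "0"] <- "ref"
  states[states == "1"] <- "var"
  rownames(states) <- df$star_name

  defs <- data.frame(star = df$star_name, core = starCore(df$star_name),
                     structural_kind = df$structural_kind,
                     switch_lo = swlo, switch_hi = swhi,
                     tandem_partners = gsub(" ", "", df$tandem_partners),
                     activity = as.character(df$activity),
                     stringsAsFactors = FALSE)
  reg <- siteRegistry(gene)
  new("HaplotypeTable", gene = gene, defs = defs, states = states,
      sites = reg[reg$canonical_id %in% canon, , drop = FALSE])
}

#' Write a haplotype table in the tabular dialect
#'
#' Round-trips with [parseHaplotypeTable()].
#'
#' @param table a [HaplotypeTable-class].
#' @param path output file path (or connection).
#' @return invisibly, the path.
#' @export
writeHaplotypeTable <- function(table, path) {
  stopifnot(is(table, "HaplotypeTable"))
  d <- table@defs
  sw <- ifelse(is.na(d$switch_lo), "", paste0(d$switch_lo, ":", d$switch_hi))
  st <- table@states
  st[is.na(st)] <- "na"
  out <- data.frame(star_name = d$star, gene = table@gene,
                    structural_kind = d$structural_kind, switch_interval = sw,
                    tandem_partners = d$tandem_partners, activity = d$activity,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(st, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in haplotype definition tables
#'
#' The shipped tables encode the star alleles and panel sites named in the
#' platform descriptions: CYP2D6 *1-*41 core alleles, the *5 deletion, the
#' hybrid haplotypes (*13 variants, *36, *57, *61, *63, *68, *83, *4.013) and
#' their known tandem partners, and CYP2C19 *2-*10 and *17.
#'
#' @param gene "CYP2D6" or "CYP2C19".
#' @return a [HaplotypeTable-class].
#' @examples
#' builtinHaplotypeTable("CYP2D6")
#' @export
builtinHaplotypeTable <- function(gene) {
  .assertGene(gene)
  key <- paste0("haptab_", gene)
  if (is.null(.sd_cache[[key]]))
    .sd_cache[[key]] <- parseHaplotypeTable(
      .extdata(paste0(tolower(gene), "_haplotypes.tsv")))
  .sd_cache[[key]]
}

## ---- accessors -----------------------------------------------------------

#' @describeIn HaplotypeTable-class star-allele names in the table
#' @param x,object a HaplotypeTable
#' @export
starNames <- function(x) x@defs$star

#' Numeric activity scores of table entries
#'
#' @param x a [HaplotypeTable-class].
#' @return named numeric vector; NA where activity is "uncertain".
#' @export
activityOf <- function(x) {
  a <- suppressWarnings(as.numeric(x@defs$activity))
  names(a) <- x@defs$star
  a
}

#' Structural kind of table entries
#'
#' @param x a [HaplotypeTable-class].
#' @return named character vector of structural kinds.
#' @export
structuralKind <- function(x) {
  setNames(x@defs$structural_kind, x@defs$star)
}

#' Gene of an object
#' @param x a HaplotypeTable, PlatformPanel or ObservationSet.
#' @export
setGeneric("geneOf", function(x) standardGeneric("geneOf"))

#' @rdname geneOf
#' @export
setMethod("geneOf", "HaplotypeTable", function(x) x@gene)

#' @rdname geneOf
#' @export
setMethod("geneOf", "PlatformPanel", function(x) x@gene)

#' @rdname geneOf
#' @export
setMethod("geneOf", "ObservationSet", function(x) x@gene)

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable for", object@gene, "with", nrow(object@defs),
      "haplotypes over", ncol(object@states), "sites\n")
  k <- table(object@defs$structural_kind)
  cat(" ", paste(names(k), k, sep = ": ", collapse = ", "), "\n")
})

# defs row for one star (error if absent)
.hapRow <- function(table, star) {
  i <- match(star, table@defs$star)
  if (is.na(i)) .stop("haplotype '", star, "' is not in the ", table@gene,
                      " table", class = "stardiplo_unknown_haplotype")
  table@defs[i, , drop = FALSE]
}
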