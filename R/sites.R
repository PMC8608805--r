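#' Variant site registry
#'
#' Returns the built-in registry of panel variant sites for a gene. The
#' canonical id is the rsID where one exists, otherwise a normalised legacy
#' position label; the two legacy numbering dialects (e.g. "2850C>T" and
#' "2851C>T" for rs16947) are stored as aliases of the same site.
#'
#' @param gene "CYP2D6" or "CYP2C19".
#' @return data.frame with columns canonical_id, gene, position, region,
#'   aliases, ref_state, var_state.
#' @examples
#' head(siteRegistry("CYP2D6"))
#' @export
siteRegistry <- function(gene) {
  .assertGene(gene)
  key <- "site_registry"
  if (is.null(.sd_cache[[key]])) {
    df <- utils::read.delim(.extdata("variant_sites.tsv"), comment.char = "#",
                            stringsAsFactors = FALSE)
    df$region[!nzchar(df$region) | is.na(df$region)] <- NA_character_
    .sd_cache[[key]] <- df
  }
  .sd_cache[[key]][.sd_cache[[key]]$gene == gene, , drop = FALSE]
}

#' Resolve a legacy variant label or rsID to its canonical site
#'
#' Dialect-variant labels (the off-by-one M33388 spellings, e.g. "2850C>T"
#' vs "2851C>T") resolve to the same canonical site.
#'
#' @param label a legacy position string or rsID.
#' @param gene "CYP2D6" or "CYP2C19".
#' @return one-row data.frame describing the site (canonical_id, position,
#'   region, ref_state, var_state).
#' @examples
#' resolveSite("2850C>T", "CYP2D6")$canonical_id  # rs16947
#' resolveSite("rs4244285", "CYP2C19")$canonical_id
#' @export
resolveSite <- function(label, gene) {
  reg <- siteRegistry(gene)
  label <- trimws(label)
  hit <- which(reg$canonical_id == label)
  if (!length(hit)) {
    al <- strsplit(reg$aliases, ",", fixed = TRUE)
    hit <- which(vapply(al, function(a) label %in% trimws(a), logical(1)))
  }
  if (length(hit) == 1L) return(reg[hit, , drop = FALSE])
  if (length(hit) > 1L)
    .stop("label '", label, "' is ambiguous in the ", gene, " registry")
  known <- unique(c(reg$canonical_id, unlist(strsplit(reg$aliases, ","))))
  known <- known[nzchar(known)]
  near <- tryCatch(utils::agrep(label, known, max.distance = 0.3, value = TRUE),
                   error = function(e) character())
  .stop("unknown ", gene, " site label '", label, "'",
        if (length(near)) paste0("; nearest known labels: ",
                                 paste(utils::head(near, 5), collapse = ", ")),
        class = "stardiplo_unknown_site")
}

# vectorised canonicalisation of site labels
.canonicalSites <- function(labels, gene) {
  vapply(labels, function(l) resolveSite(l, gene)$canonical_id, character(1),
         USE.NAMES = FALSE)
}

# 5'->3' position of a canonical site
.sitePosition <- function(sites, gene) {
  reg <- siteRegistry(gene)
  reg$position[match(sites, reg$canonical_id)]
}
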