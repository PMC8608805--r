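#' Supported platform names
#' @return character vector of the six supported platforms.
#' @export
platformNames <- function()
  c("AmpliChip", "LuminexXTAGv3", "TaqMan", "AmpliSeq", "PharmacoScan",
    "Agena")

# the 32 CYP2D6 variant haplotypes identified by the AmpliChip CYP450 test
.AMPLICHIP_2D6 <- c(
  "*2", "*3", "*4", "*5", "*6", "*7", "*8", "*9", "*10", "*11", "*14", "*15",
  "*17", "*19", "*20", "*25", "*26", "*29", "*30", "*31", "*35", "*36",
  "*40", "*41", "*114",
  "*1xN", "*2xN", "*4xN", "*10xN", "*17xN", "*35xN", "*41xN")

# defining sites (var states) of a set of stars, from the built-in table
.definingSites <- function(table, stars) {
  stars <- intersect(stars, rownames(table@states))
  st <- table@states[stars, , drop = FALSE]
  colnames(st)[colSums(st == "var", na.rm = TRUE) > 0]
}

.buildPanel <- function(name, gene) {
  tab <- builtinHaplotypeTable(gene)
  allStars <- setdiff(starNames(tab), "*1")
  p <- switch(paste(name, gene),
    "AmpliChip CYP2D6" = list(
      haplotypes = .AMPLICHIP_2D6,
      sites = .definingSites(tab, sub("xN$", "", .AMPLICHIP_2D6)),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 1L,
      meta = list(note = "*114 reported as *14A; *5 detection unreliable")),
    "AmpliChip CYP2C19" = list(
      haplotypes = c("*2", "*3"),
      sites = .definingSites(tab, c("*2", "*3")),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 1L,
      meta = list()),
    "LuminexXTAGv3 CYP2D6" = list(
      haplotypes = setdiff(allStars,
                           c("*19", "*25", "*26", "*30", "*31", "*40")),
      sites = c("rs1080985", "rs769258", "rs1065852", "rs5030862",
                "137_138insT", "883G>C", "rs28371706", "rs61736512",
                "rs5030655", "1758G>T", "1758G>A", "rs3892097",
                "1973_1974insG", "rs35742686", "rs5030656", "rs16947",
                "rs5030867", "rs28371725", "3184G>A", "rs1135840"),
      cnv = character(), hyb = TRUE, del = TRUE, dup = TRUE, tier = 2L,
      meta = list(assay = "xTAG v3, RUO; haplotype translator covers hybrids",
                  deletion_assay = TRUE)),
    "LuminexXTAGv3 CYP2C19" = list(
      haplotypes = c("*2", "*3", "*4", "*5", "*6", "*7", "*8", "*9", "*10",
                     "*17"),
      sites = setdiff(siteRegistry(gene)$canonical_id, "rs374036992"),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 2L,
      meta = list(assay = "xTAG v3, RUO; reports CYP2C19*2-*10 and *17")),
    "TaqMan CYP2D6" = list(
      haplotypes = c("*1xN", "*2", "*2xN", "*3", "*4", "*4xN", "*5", "*6",
                     "*10", "*10xN", "*29", "*35", "*35xN", "*40", "*41",
                     "*41xN"),
      sites = c("rs16947", "rs35742686", "rs3892097", "rs5030655",
                "rs769258", "rs28371725", "rs1065852", "rs61736512",
                "rs72549356"),
      cnv = c("intron2", "intron6", "exon9"),
      hyb = TRUE, del = TRUE, dup = TRUE, tier = 2L,
      meta = list(cnv_assays = c(intron2 = "Hs04083572_cn",
                                 intron6 = "Hs04502391_cn",
                                 exon9 = "Hs00010001_cn"),
                  snv_assays = c("C_27102425_10", "C_32407232_50",
                                 "C_27102431_D0", "C_32407243_20",
                                 "C_27102444_F0", "C_34816116_20",
                                 "C__11484460_40", "ANCFHM6", "ANWRUE2"),
                  duplicate_runs = TRUE)),
    "TaqMan CYP2C19" = list(
      haplotypes = c("*2", "*17"),
      sites = c("rs4244285", "rs12248560"),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 2L,
      meta = list(snv_assays = c(rs4244285 = "C__25986767_70",
                                 rs12248560 = "C_469857_10"))),
    "AmpliSeq CYP2D6" = list(
      haplotypes = setdiff(allStars,
                           c("*19", "*20", "*25", "*26", "*30", "*31")),
      sites = setdiff(siteRegistry(gene)$canonical_id,
                      c("3199C>G", "3277T>C", "4043G>A",
                        "1863_1864ins(TTTCGCCCC)1", "1973_1974insG",
                        "2539_2542delAACT")),
      cnv = c("intron2", "exon9"),
      hyb = TRUE, del = TRUE, dup = TRUE, tier = 2L,
      meta = list(outputs = c("SNV genotypes", "exon 9 CNV",
                              "gene-level CNV"))),
    "AmpliSeq CYP2C19" = list(
      haplotypes = c("*2", "*3", "*4", "*5", "*6", "*7", "*8", "*9", "*10",
                     "*17"),
      sites = siteRegistry(gene)$canonical_id,
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 2L,
      meta = list()),
    "PharmacoScan CYP2D6" = list(
      haplotypes = setdiff(allStars, grep("^\\*13", allStars, value = TRUE)),
      sites = siteRegistry(gene)$canonical_id,
      cnv = c("five_prime_flank", "exon9", "three_prime_flank"),
      hyb = FALSE, del = TRUE, dup = TRUE, tier = 2L,
      meta = list(translator = "r8+20200211")),
    "PharmacoScan CYP2C19" = list(
      haplotypes = c("*2", "*3", "*4", "*5", "*6", "*7", "*8", "*9", "*10",
                     "*17"),
      sites = setdiff(siteRegistry(gene)$canonical_id, "rs374036992"),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 2L,
      meta = list()),
    "Agena CYP2C19" = list(
      haplotypes = c("*2", "*3", "*4", "*5", "*6", "*7", "*8", "*17"),
      sites = c("rs4244285", "rs4986893", "rs28399504", "rs56337013",
                "rs72552267", "rs72558186", "rs41291556", "rs12248560"),
      cnv = character(), hyb = FALSE, del = FALSE, dup = FALSE, tier = 2L,
      meta = list(note = "8 variants enabling 9 haplotype calls")),
    NULL)
  if (is.null(p))
    .stop("platform '", name, "' does not offer a ", gene, " panel")
  new("PlatformPanel", name = name, gene = gene, sites = p$sites,
      haplotypes = p$haplotypes, cnvRegions = p$cnv,
      detectsHybrids = p$hyb, detectsDeletion = p$del,
      detectsDuplication = p$dup, tier = p$tier, metadata = p$meta)
}

#' Built-in platform panel
#'
#' Returns the immutable built-in description of one platform's coverage for
#' a gene, encoding the stated coverage gaps (e.g. the AmpliChip CYP2C19
#' panel covers only *2 and *3 and cannot detect CYP2D6 hybrids).
#'
#' @param name one of [platformNames()].
#' @param gene "CYP2D6" or "CYP2C19".
#' @return a [PlatformPanel-class].
#' @examples
#' panelOf("AmpliChip", "CYP2D6")
#' @export
panelOf <- function(name, gene = "CYP2D6") {
  if (!name %in% platformNames())
    .stop("unknown platform '", name, "'; supported: ",
          paste(platformNames(), collapse = ", "))
  .assertGene(gene)
  key <- paste0("panel_", name, "_", gene)
  if (is.null(.sd_cache[[key]])) .sd_cache[[key]] <- .buildPanel(name, gene)
  .sd_cache[[key]]
}

#' @describeIn PlatformPanel-class variant haplotypes the panel distinguishes
#' @param x a PlatformPanel
#' @export
panelHaplotypes <- function(x) x@haplotypes

#' @describeIn PlatformPanel-class canonical ids of the sites assayed
#' @export
panelSites <- function(x) x@sites

#' @describeIn PlatformPanel-class ordered CNV probe regions
#' @export
cnvRegions <- function(x) x@cnvRegions

#' @describeIn PlatformPanel-class evidence tier (3 > 2 > 1)
#' @export
evidenceTier <- function(x) x@tier

setMethod("show", "PlatformPanel", function(object) {
  cat("PlatformPanel:", object@name, "/", object@gene, "\n")
  cat(" ", length(object@sites), "sites;", length(object@haplotypes),
      "variant haplotypes\n")
  cat("  CNV regions:",
      if (length(object@cnvRegions)) paste(object@cnvRegions, collapse = ", ")
      else "none", "\n")
  cat("  detects: hybrids=", object@detectsHybrids,
      ", deletion=", object@detectsDeletion,
      ", duplication=", object@detectsDuplication, "\n", sep = "")
})
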