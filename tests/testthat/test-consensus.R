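d6 <- builtinHaplotypeTable("CYP2D6")
c19 <- builtinHaplotypeTable("CYP2C19")

test_that("panel collapse models the documented coverage gaps", {
  # the AmpliChip CYP2C19 panel covers only *2 and *3
  expect_identical(
    collapseCall("*1/*17", panelOf("AmpliChip", "CYP2C19"), c19)$string,
    "*1/*1")
  expect_identical(
    collapseCall("*2/*2", panelOf("LuminexXTAGv3", "CYP2C19"), c19)$string,
    "*2/*2")
  expect_identical(
    collapseCall("*2/*6", panelOf("AmpliChip", "CYP2C19"), c19)$string,
    "*1/*2")
  # hybrids are invisible to a hybrid-blind panel
  cc <- collapseCall("*13 + *2/*1", panelOf("AmpliChip", "CYP2D6"), d6)
  expect_false(cc$representable)
  expect_match(cc$flags, "hybrid_undetectable", all = FALSE)
  expect_identical(cc$string, "*1/*2")
  # a deletion-blind panel sees the hemizygous haplotype as homozygous
  cc <- collapseCall("*13 + *4/*5", panelOf("AmpliChip", "CYP2D6"), d6)
  expect_identical(cc$string, "*4/*4")
  expect_true("hemizygous_appears_homozygous" %in% cc$flags)
  # sub-alleles collapse to a covered core star
  expect_identical(
    collapseCall("*2.001/*1", panelOf("AmpliChip", "CYP2D6"), d6)$string,
    "*1/*2")
})

test_that("panel collapse is idempotent", {
  dips <- c("*1/*17", "*2/*6", "*1/*8", "*2/*2")
  for (p in c("AmpliChip", "LuminexXTAGv3", "Agena")) {
    panel <- panelOf(p, "CYP2C19")
    for (ds in dips) {
      once <- collapseCall(ds, panel, c19)
      twice <- collapseCall(once$diplotype, panel, c19)
      expect_identical(twice$string, once$string,
                       label = paste(p, ds))
    }
  }
  for (ds in c("*13 + *4/*5", "*36 + *10/*1", "*41x3/*1", "*2.001/*5")) {
    for (p in c("AmpliChip", "LuminexXTAGv3", "PharmacoScan")) {
      panel <- panelOf(p, "CYP2D6")
      once <- collapseCall(ds, panel, d6)
      if (is.null(once$diplotype)) next
      expect_identical(collapseCall(once$diplotype, panel, d6)$string,
                       once$string, label = paste(p, ds))
    }
  }
})

test_that("consensus requires consistency, not majority vote", {
  calls <- list(
    platformCall("S1", "LuminexXTAGv3", "*1/*2", gene = "CYP2C19"),
    platformCall("S1", "Agena", "*1/*2", gene = "CYP2C19"))
  cr <- deriveConsensus(calls, table = c19)
  expect_true(cr@resolved)
  expect_identical(consensusDiplotype(cr), "*1/*2")

  # two platforms asserting incompatible diplotypes at equal tier
  calls <- list(
    platformCall("S1", "LuminexXTAGv3", "*1/*2", gene = "CYP2C19"),
    platformCall("S1", "Agena", "*1/*17", gene = "CYP2C19"))
  cr <- deriveConsensus(calls, table = c19)
  expect_false(cr@resolved)
  expect_true(is.na(consensusDiplotype(cr)))
})

test_that("the hybrid tandem plus deletion sample resolves by consensus", {
  g <- data.frame(
    platform = "PharmacoScan",
    site = c("rs1065852", "137_138insT", "rs769258", "rs3892097",
             "rs1135840", "rs16947"),
    category = c("HET", "HET", "HET", "MUT", "MUT", "WT"))
  obs <- observationSet("S1", "CYP2D6", genotypes = g,
    cnv = list(cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2),
                              platform = "TaqMan"),
               cnvProbeVector(c(intron2 = 1, exon9 = 2),
                              platform = "AmpliSeq")),
    evidence = list(mixed_amplicon = TRUE))
  calls <- list(
    platformCall("S1", "AmpliChip", "*4/*4", gene = "CYP2D6"),
    platformCall("S1", "PharmacoScan", NA,
                 alternatives = c("*4/UNK", "*4.009/UNK"), gene = "CYP2D6"))
  cr <- deriveConsensus(calls, obs, d6)
  expect_true(cr@resolved)
  expect_identical(consensusDiplotype(cr), "*13 + *4/*5")
  # the hybrid-blind AmpliChip call is consistent-after-collapse, hence
  # contributing, not discordant
  expect_true("AmpliChip" %in% cr@contributing)
  expect_length(cr@discordant, 0L)

  # consensus containment: the consensus collapsed to a contributing
  # platform's panel equals that platform's call
  expect_identical(
    collapseCall(consensusDiplotype(cr), panelOf("AmpliChip", "CYP2D6"),
                 d6)$string, "*4/*4")
})

test_that("concordance cells match the printed format and bounds", {
  expect_identical(formatConcordanceCell(42, 43), "97.7 (42/43)")
  expect_identical(formatConcordanceCell(40, 42), "95.2 (40/42)")
  expect_identical(formatConcordanceCell(10, 10), "100")
  expect_identical(formatConcordanceCell(0, 1), "0.0 (0/1)")

  calls <- data.frame(
    sample_id = rep(c("a", "b", "c"), each = 2),
    platform = rep(c("LuminexXTAGv3", "Agena"), 3),
    call = c("*1/*2", "*1/*2", "*1/*2", NA, "*1/*1", "*1/*1"),
    stringsAsFactors = FALSE)
  cons <- data.frame(sample_id = c("a", "b", "c"),
                     consensus = c("*1/*2", "*1/*2", "*1/*1"),
                     stringsAsFactors = FALSE)
  ct <- concordanceFrame(concordanceTable(calls, cons))
  overall <- ct[ct$group == "overall", ]
  # the no-call counts in the denominator
  expect_identical(overall$Agena_cell, "66.7 (2/3)")
  expect_identical(overall$LuminexXTAGv3_cell, "100")
  pcts <- unlist(ct[, grep("_pct$", names(ct))])
  expect_true(all(is.na(pcts) | (pcts >= 0 & pcts <= 100)))
  expect_error(concordanceTable(
    data.frame(sample_id = "zzz", platform = "Agena", call = "*1/*1"),
    cons), "needs a consensus")
})

test_that("revision reports count activity-score changes", {
  prior <- data.frame(sample_id = c("a", "b", "c", "d"),
                      call = c("*1/*1", "*1/*4", NA, "*1/*1"),
                      stringsAsFactors = FALSE)
  cons <- data.frame(sample_id = c("a", "b", "c", "d"),
                     call = c("*1/*1", "*4/*4", "*13/*1", "*1/*1"),
                     stringsAsFactors = FALSE)
  rr <- revisionReport(prior, cons, d6)
  # b changed score, c was a no-call gaining a genotype
  expect_identical(rr$nChanged, 2L)
  expect_identical(rr$nTotal, 4L)
  expect_identical(sum(rr$transitions), 4L)
  expect_identical(unname(rr$transitions["NM", "NM"]), 2L)
  expect_identical(unname(rr$transitions["indeterminate", "IM"]), 1L)

  same <- revisionReport(prior[1:2, ],
                         data.frame(sample_id = c("a", "b"),
                                    call = c("*1/*1", "*1/*4")), d6)
  expect_identical(same$nChanged, 0L)
})
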