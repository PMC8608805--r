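d6 <- builtinHaplotypeTable("CYP2D6")
c19 <- builtinHaplotypeTable("CYP2C19")

test_that("zero noise reproduces the deterministic forward model", {
  obs <- simulateObservations("*1/*1", panelOf("TaqMan", "CYP2D6"), d6)
  g <- genotypesOf(obs)
  expect_true(all(g$category == "WT"))
  expect_identical(cnvCalls(cnvOf(obs)[[1]]),
                   c(intron2 = 2L, intron6 = 2L, exon9 = 2L))
  # TaqMan runs in duplicate
  expect_identical(sort(unique(g$run)), c(1L, 2L))

  obs <- simulateObservations("*13 + *4/*5", panelOf("TaqMan", "CYP2D6"), d6)
  expect_identical(cnvCalls(cnvOf(obs)[[1]]),
                   c(intron2 = 1L, intron6 = 2L, exon9 = 2L))
  expect_error(simulateObservations("*999/*1",
                                    panelOf("TaqMan", "CYP2D6"), d6),
               "not in the CYP2D6 table")
})

test_that("simulated categories agree with the oracle per panel site", {
  set.seed(13)
  for (ds in c("*4/*5", "*41x3/*1", "*13[GQ162807] + *2/*1", "*2/*35")) {
    units <- diplotypeUnits(parseDiplotype(ds))
    obs <- simulateObservations(ds, panelOf("LuminexXTAGv3", "CYP2D6"), d6)
    g <- genotypesOf(obs)
    for (i in sample(nrow(g), 6)) {
      expect_identical(g$category[i], oracle_category(d6, units, g$site[i]),
                       label = paste(ds, g$site[i]))
    }
  }
})

test_that("identical seeds give identical observation sets", {
  nm <- noiseModel(nocall_rate = 0.2, cnv_miscount_rate = 0.2,
                   signal_cv = 0.3)
  a <- simulateObservations("*41x3/*1", panelOf("TaqMan", "CYP2D6"), d6,
                            noise = nm, seed = 99L)
  b <- simulateObservations("*41x3/*1", panelOf("TaqMan", "CYP2D6"), d6,
                            noise = nm, seed = 99L)
  expect_identical(genotypesOf(a), genotypesOf(b))
  expect_identical(lapply(cnvOf(a), cnvCalls), lapply(cnvOf(b), cnvCalls))
  expect_identical(signalsOf(a), signalsOf(b))
  c <- simulateObservations("*41x3/*1", panelOf("TaqMan", "CYP2D6"), d6,
                            noise = nm, seed = 100L)
  expect_false(identical(genotypesOf(a), genotypesOf(c)))
  # the caller's RNG stream is not consumed
  set.seed(1); x <- runif(1)
  set.seed(1)
  invisible(simulateObservations("*1/*1", panelOf("TaqMan", "CYP2D6"), d6,
                                 seed = 7L))
  expect_identical(runif(1), x)
})

test_that("signal pairs cluster at the ideal variant fraction", {
  obs <- simulateObservations("*41x3/*1", panelOf("TaqMan", "CYP2D6"), d6)
  s <- signalsOf(obs)
  expect_gt(nrow(s), 0)
  f <- s$var_signal / (s$var_signal + s$wt_signal)
  expect_true(all(abs(f - 3 / 4) < 1e-9))
})

test_that("platform limitation on the consensus cohort matches hand counts", {
  ch <- simulatePlatformLimitedCohort(panel = panelOf("AmpliChip", "CYP2C19"),
                                      table = c19)
  expect_identical(nrow(ch), 93L)
  expect_identical(sum(ch$call == ch$truth), 62L)
  chL <- simulatePlatformLimitedCohort(
    panel = panelOf("LuminexXTAGv3", "CYP2C19"), table = c19)
  expect_identical(sum(chL$call == chL$truth), 93L)
  one <- simulatePlatformLimitedCohort(
    data.frame(diplotype = "*2/*17", n = 1L),
    panel = panelOf("Agena", "CYP2C19"), table = c19)
  expect_identical(one$call, one$truth)
  expect_error(simulatePlatformLimitedCohort(
    data.frame(diplotype = character(), n = integer()),
    panel = panelOf("Agena", "CYP2C19"), table = c19), "empty cohort")
})

test_that("noiseless simulate-then-call round trips recover the truth", {
  stars <- starNames(d6)
  singles <- paste0(stars, "/*1")
  extras <- c("*41x3/*1", "*1x2/*4", "*36 + *10/*1", "*4.013 + *4/*1",
              "*13[GQ162807] + *2/*1", "*2x2/*35", "*4/*5", "*17/*41")
  for (ds in c(singles, extras)) {
    truth <- parseDiplotype(ds, table = d6)
    obs <- simulateObservations(truth,
                                list(panelOf("PharmacoScan", "CYP2D6")), d6,
                                regions = character())
    g <- unique(genotypesOf(obs)[, c("site", "category")])
    v <- expectedCnv(truth, d6, regions = PROBE_REGIONS)
    cand <- enumerateDiplotypes(g, v, d6)
    expect_true(formatDiplotype(truth) %in% cand$diplotype, label = ds)
    # rank 1 whenever the truth is the unique consistent candidate
    if (nrow(cand) == 1L)
      expect_identical(cand$diplotype[1], formatDiplotype(truth))
  }
})

test_that("raising the no-call rate never shrinks the candidate set on average", {
  sizes <- function(rate) {
    out <- numeric(0)
    for (seed in 1:5) {
      obs <- simulateObservations("*2/*17", panelOf("LuminexXTAGv3",
                                                    "CYP2C19"), c19,
                                  noise = noiseModel(nocall_rate = rate),
                                  seed = seed)
      g <- genotypesOf(obs)[, c("site", "category")]
      out <- c(out, nrow(enumerateDiplotypes(g,
        cnvProbeVector(c(intron2 = 2)), c19)))
    }
    mean(out)
  }
  expect_lte(sizes(0), sizes(0.5))
})
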