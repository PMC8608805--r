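d6 <- builtinHaplotypeTable("CYP2D6")
c19 <- builtinHaplotypeTable("CYP2C19")

test_that("presence semantics handle hemizygosity and multiplications", {
  # deletion on one allele, the *4 on the other: MUT, never HET
  expect_true(isConsistent("*4/*5", c(rs3892097 = "MUT"), d6))
  expect_false(isConsistent("*4/*5", c(rs3892097 = "HET"), d6))
  expect_false(isConsistent("*1/*1", c(rs16947 = "HET"), d6))
  # four gene copies carrying both alleles
  expect_true(isConsistent("*41x3/*1", c(rs28371725 = "HET"), d6))
  # no gene present at all: nothing can be called
  expect_false(isConsistent("*5/*5", c(rs3892097 = "WT"), d6))
  # NOCALL imposes no constraint
  expect_true(isConsistent("*1/*1", c(rs16947 = "NOCALL"), d6))
  # legacy dialect labels are accepted
  expect_true(isConsistent("*2/*1", c("2850C>T" = "HET"), d6))
  expect_error(isConsistent("*1/*1", c(rs4244285 = "WT"), d6),
               "unknown CYP2D6 site")
  expect_error(
    isConsistent("*1/*1", c(rs5030867 = "WT"), d6,
                 panel = panelOf("TaqMan", "CYP2D6")),
    "outside the TaqMan panel")
})

test_that("consistency agrees with the brute-force oracle", {
  set.seed(21)
  sub <- d6_sub_table()
  cfgs <- oracle_configs(sub, maxChrom = 3L)
  sites <- colnames(sub@states)
  for (rep in 1:60) {
    i <- sample(length(cfgs), 1); j <- sample(length(cfgs), 1)
    d <- diplotype(cfgs[[i]], cfgs[[j]])
    g <- data.frame(site = sample(sites, 4),
                    category = sample(c("WT", "HET", "MUT", "NOCALL"), 4,
                                      replace = TRUE))
    expect_identical(isConsistent(d, g, sub),
                     oracle_consistent(sub, diplotypeUnits(d), g),
                     label = paste(formatDiplotype(d),
                                   paste(g$site, g$category, collapse = ",")))
  }
})

test_that("enumeration recovers worked examples", {
  # CYP2C19 heterozygous at the *2 and *17 sites with two gene copies
  cand <- enumerateDiplotypes(c(rs4244285 = "HET", rs12248560 = "HET"),
                              cnvProbeVector(c(intron2 = 2)), c19)
  expect_identical(cand$diplotype[1], "*17/*2")
  expect_identical(nrow(cand), 1L)

  # all wild-type with a flat two-copy vector: *1/*1 is the unique
  # top-ranked candidate (a duplication in trans with a deletion mimics the
  # vector but costs two structural events)
  allwt <- setNames(rep("WT", ncol(d6@states)), colnames(d6@states))
  cand <- enumerateDiplotypes(allwt,
    cnvProbeVector(c(intron2 = 2, intron6 = 2, exon9 = 2)), d6)
  expect_identical(cand$diplotype[1], "*1/*1")
  expect_identical(cand$events[1], 0L)
  if (nrow(cand) > 1L) expect_gt(cand$events[2], 0L)

  # the hybrid tandem plus deletion sample
  g <- c(rs1065852 = "HET", "137_138insT" = "HET", rs769258 = "HET",
         rs3892097 = "MUT", rs1135840 = "MUT", rs16947 = "WT")
  cand <- enumerateDiplotypes(g,
    cnvProbeVector(c(intron2 = 1, intron6 = 2, exon9 = 2)), d6)
  expect_true("*13 + *4/*5" %in% cand$diplotype)

  # no consistent diplotype is a valid empty outcome
  none <- enumerateDiplotypes(c(rs3892097 = "MUT", rs16947 = "MUT"),
    cnvProbeVector(c(intron2 = 2, intron6 = 2, exon9 = 2)), d6,
    maxUnits = 2L)
  expect_identical(nrow(none), 0L)
  expect_error(enumerateDiplotypes(c(rs16947 = "WT"), NULL, d6,
                                   maxUnits = 1L), "maxUnits")
})

test_that("enumeration equals the brute-force oracle", {
  set.seed(31)
  sub <- d6_sub_table()
  subsites <- colnames(sub@states)
  cfgs <- oracle_configs(sub, maxChrom = 3L)
  for (rep in 1:8) {
    i <- sample(length(cfgs), 1); j <- sample(length(cfgs), 1)
    truth <- diplotype(cfgs[[i]], cfgs[[j]])
    if (totalUnits(truth) > 4L) next
    g <- oracle_genotypes(sub, formatDiplotype(truth), subsites)
    calls <- oracle_expected_cnv(sub, diplotypeUnits(truth),
                                 c("intron2", "intron6", "exon9"))
    got <- enumerateDiplotypes(g, cnvProbeVector(calls), sub)
    expect_setequal(got$diplotype,
                    oracle_enumerate(sub, g, calls))
    expect_true(formatDiplotype(truth) %in% got$diplotype)
  }
  # the full CYP2C19 table is small enough for the oracle directly
  for (rep in 1:6) {
    g <- data.frame(site = sample(colnames(c19@states), 3),
                    category = sample(c("WT", "HET", "MUT"), 3,
                                      replace = TRUE))
    calls <- c(intron2 = sample(1:3, 1))
    got <- enumerateDiplotypes(g, cnvProbeVector(calls), c19)
    expect_setequal(got$diplotype, oracle_enumerate(c19, g, calls))
  }
})

test_that("enumeration is invariant under input order and row swap", {
  g <- data.frame(site = c("rs16947", "rs1135840", "rs28371725"),
                  category = c("HET", "HET", "HET"))
  v <- cnvProbeVector(c(intron2 = 2, intron6 = 2, exon9 = 2))
  a <- enumerateDiplotypes(g, v, d6)
  b <- enumerateDiplotypes(g[3:1, ], v, d6)
  expect_identical(a$diplotype, b$diplotype)
})

test_that("collapsing a site to NOCALL only grows the candidate set", {
  set.seed(41)
  sub <- d6_sub_table()
  subsites <- colnames(sub@states)
  for (rep in 1:6) {
    g <- data.frame(site = sample(subsites, 4),
                    category = sample(c("WT", "HET", "MUT"), 4,
                                      replace = TRUE))
    v <- cnvProbeVector(c(intron2 = 2, intron6 = 2, exon9 = 2))
    full <- enumerateDiplotypes(g, v, sub)
    g2 <- g; g2$category[1] <- "NOCALL"
    dropped <- enumerateDiplotypes(g2, v, sub)
    expect_true(all(full$diplotype %in% dropped$diplotype))
  }
})

test_that("hemizygous amplicon patterns resolve to the deposited sequences", {
  # sample 1: variant at 31G>A, the exon 1 T insertion and 4181G>C,
  # wild-type at 2851C>T, low signal at 2989G>A
  s1 <- c("31G>A" = "MUT", "100C>T" = "WT", "124G>A" = "WT",
          "137_138insT" = "MUT", "882G>C" = "WT", "1660G>A" = "WT",
          "1708delT" = "WT", "1847G>A" = "WT", "2550delA" = "WT",
          "2851C>T" = "WT", "2936A>C" = "WT", "2989G>A" = "LOW_SIGNAL",
          "3184G>A" = "WT", "4181G>C" = "MUT")
  expect_identical(matchAmplicon(s1, d6)[1], "*13[EU093102]")

  # sample 3: additionally variant at 2851C>T
  s3 <- s1
  s3["2851C>T"] <- "MUT"; s3["2989G>A"] <- "WT"
  expect_identical(matchAmplicon(s3, d6)[1], "*13[GQ162807]")

  allwt <- setNames(rep("WT", ncol(d6@states)), colnames(d6@states))
  expect_identical(matchAmplicon(allwt, d6)[1], "*1")

  err <- tryCatch(matchAmplicon(c(rs16947 = "HET"), d6), error = identity)
  expect_s3_class(err, "stardiplo_mixed_amplicon")
  expect_match(conditionMessage(err), "detectMixedAmplicon")
})

test_that("mixed amplicons localise the template switch", {
  calls <- c("31G>A" = "MUT", "137_138insT" = "MUT", "1023C>T" = "WT",
             "1847G>A" = "HET", "2851C>T" = "HET", "4181G>C" = "HET")
  mx <- detectMixedAmplicon(calls, gene = "CYP2D6")
  expect_identical(mx$firstHetSite, "rs3892097")
  expect_identical(mx$regionInterval[1], "intron2")
  expect_identical(mx$upstreamSite, "rs28371706")

  expect_null(detectMixedAmplicon(c("31G>A" = "MUT", "100C>T" = "WT"),
                                  gene = "CYP2D6"))
  allhet <- detectMixedAmplicon(c("31G>A" = "HET", "1847G>A" = "HET"),
                                gene = "CYP2D6")
  expect_true(is.na(allhet$upstreamSite))
})

test_that("activity scores and phenotypes follow the cut-point table", {
  r <- activityScore("*13/*13", d6)
  expect_identical(scoreOf(r), 0)
  expect_identical(phenotypeOf(r), "PM")
  r <- activityScore("*1/*1", d6)
  expect_identical(scoreOf(r), 2)
  expect_identical(phenotypeOf(r), "NM")
  r <- activityScore("*41x3/*1", d6)
  expect_identical(scoreOf(r), 1.75)
  expect_identical(phenotypeOf(r), "NM")
  r <- activityScore("*13 + *4/*5", d6)
  expect_identical(scoreOf(r), 0)
  expect_identical(phenotypeOf(r), "PM")
  # uncertain unit activity makes the result indeterminate
  r <- activityScore("*25/*1", d6)
  expect_identical(phenotypeOf(r), "indeterminate")
  # CYP2C19: increased-function cut-points
  expect_identical(phenotypeOf(activityScore("*1/*17", c19)), "UM")
  expect_identical(phenotypeOf(activityScore("*2/*17", c19)), "IM")
  expect_identical(phenotypeOf(activityScore("*2/*2", c19)), "PM")
})
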