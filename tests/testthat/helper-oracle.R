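# Independent brute-force oracles: plain loops over the table slots, kept
# deliberately separate from the package's vectorised implementation.

oracle_unit_contrib <- function(table, star, region) {
  i <- match(star, table@defs$star)
  kind <- table@defs$structural_kind[i]
  ord <- match(region, PROBE_REGIONS)
  if (kind == "full_gene") return(1L)
  if (kind == "deletion") return(0L)
  lo <- match(table@defs$switch_lo[i], PROBE_REGIONS)
  hi <- match(table@defs$switch_hi[i], PROBE_REGIONS)
  if (kind == "hybrid_2D7_2D6") as.integer(ord >= hi)
  else as.integer(ord <= lo)
}

oracle_expected_cnv <- function(table, units, regions) {
  vapply(regions, function(r)
    sum(mapply(function(s, n) n * oracle_unit_contrib(table, s, r),
               units$star, units$n)), numeric(1))
}

# carriers of ref/var at one site across a unit list (deletions carry none)
oracle_carriers <- function(table, units, site) {
  V <- R <- FALSE
  for (k in seq_len(nrow(units))) {
    s <- units$star[k]
    if (table@defs$structural_kind[match(s, table@defs$star)] == "deletion")
      next
    st <- table@states[s, site]
    if (is.na(st)) next
    if (st == "var") V <- TRUE else R <- TRUE
  }
  c(V = V, R = R)
}

oracle_category <- function(table, units, site) {
  cr <- oracle_carriers(table, units, site)
  if (cr["V"] && cr["R"]) "HET"
  else if (cr["V"]) "MUT" else if (cr["R"]) "WT" else "NOCALL"
}

oracle_consistent <- function(table, units, genotypes) {
  for (i in seq_len(nrow(genotypes))) {
    cat <- genotypes$category[i]
    if (cat %in% c("NOCALL", "LOW_SIGNAL")) next
    if (oracle_category(table, units, genotypes$site[i]) != cat)
      return(FALSE)
  }
  TRUE
}

# independent chromosome-configuration generator (same modeling rules:
# single stars x1..3, the deletion alone, hybrids x1..2, hybrid+full tandems)
oracle_configs <- function(table, maxChrom = 3L) {
  defs <- table@defs
  full <- defs$star[defs$structural_kind == "full_gene"]
  dels <- defs$star[defs$structural_kind == "deletion"]
  hybs <- defs$star[grepl("^hybrid", defs$structural_kind)]
  out <- list()
  add <- function(stars, ns)
    out[[length(out) + 1L]] <<- data.frame(star = stars, n = ns,
                                           stringsAsFactors = FALSE)
  for (s in full) for (n in 1:min(3L, maxChrom)) add(s, n)
  for (s in dels) add(s, 1L)
  for (h in hybs) for (m in 1:min(2L, maxChrom)) {
    add(h, m)
    for (f in full) for (n in seq_len(maxChrom - m)) add(c(h, f), c(m, n))
  }
  out
}

oracle_enumerate <- function(table, genotypes, cnvcalls = NULL,
                             maxUnits = 4L) {
  cfgs <- oracle_configs(table, maxChrom = maxUnits - 1L)
  res <- character()
  for (i in seq_along(cfgs)) for (j in i:length(cfgs)) {
    units <- rbind(cfgs[[i]], cfgs[[j]])
    if (sum(units$n) > maxUnits) next
    if (!is.null(cnvcalls)) {
      exp <- oracle_expected_cnv(table, units, names(cnvcalls))
      if (!all(exp == cnvcalls)) next
    }
    if (!oracle_consistent(table, units, genotypes)) next
    res <- c(res, formatDiplotype(diplotype(cfgs[[i]], cfgs[[j]])))
  }
  sort(unique(res))
}

# reduced CYP2D6 table keeping the oracle loops tractable
d6_sub_table <- function(stars = c("*1", "*2", "*4", "*5", "*10", "*17",
                                   "*41", "*13[EU093102]", "*13[GQ162807]",
                                   "*36")) {
  path <- system.file("extdata", "cyp2d6_haplotypes.tsv",
                      package = "stardiplo")
  lines <- readLines(path)
  first <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  keep <- grepl("^#", lines) | first == "star_name" | first %in% stars
  parseHaplotypeTable(lines[keep])
}

# simulated genotype vector over a site subset, via the oracle
oracle_genotypes <- function(table, dipstring, sites) {
  units <- diplotypeUnits(parseDiplotype(dipstring))
  data.frame(site = sites,
             category = vapply(sites, function(s)
               oracle_category(table, units, s), character(1)),
             stringsAsFactors = FALSE)
}
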