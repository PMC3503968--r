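toyMatrix <- function() {
  ## L1 paternal-only, L2 shared, L3 maternal-only, L4 absent in parents
  calls <- rbind(L1 = c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0),
                 L2 = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0),
                 L3 = c(0, 1, 0, 0, 0, 0, 1, 1, 0, 0),
                 L4 = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  colnames(calls) <- paste0("a", sprintf("%02d", 1:10))
  MarkerMatrix(calls, "TOY")
}

test_that("parental status partitions loci by diploid presence", {
  sch <- makeScheme(nPer = 2)
  cl <- classifyParentalBands(toyMatrix(), sch)
  st <- parentalStatus(cl)
  expect_equal(unname(as.character(st)),
               c("paternal_specific", "shared_parental", "maternal_specific",
                 "absent_in_parents"))
})

test_that("a constructed matrix reproduces the published Au parental row", {
  ## 15 shared + 37 paternal-only + 35 maternal-only loci, one carrier each
  n <- 15 + 37 + 35
  calls <- matrix(0L, n, 10,
                  dimnames = list(sprintf("L%02d", 1:n),
                                  paste0("a", sprintf("%02d", 1:10))))
  calls[1:15, c(1, 3)] <- 1L                       # shared: SYL + TRI
  calls[16:52, 4] <- 1L                            # paternal-specific
  calls[53:87, 2] <- 1L                            # maternal-specific
  cl <- classifyParentalBands(MarkerMatrix(calls, "Au"), makeScheme(2))
  tab <- table(parentalStatus(cl))
  expect_equal(unname(tab[["shared_parental"]]), 15)
  expect_equal(unname(tab[["paternal_specific"]]), 37)
  expect_equal(unname(tab[["maternal_specific"]]), 35)
  expect_equal(sum(tab) - tab[["absent_in_parents"]], 87)
})

test_that("deviation labels match brute-force set algebra on random matrices", {
  sch <- makeScheme(nPer = 2)
  for (seed in 1:25) {
    m <- randomMarker(seed, nLoci = 25, nPer = 2, p = 0.35)
    cl <- classifyBands(m, sch)
    oracle <- bruteClassify(markerCalls(m), sch)
    expect_equal(unname(as.character(parentalStatus(cl))),
                 unname(oracle$status))
    expect_equal(deviationLabels(cl), oracle$labels)
  }
})

test_that("perfect additivity and total loss are labelled correctly", {
  sch <- makeScheme(nPer = 2)
  ## polyploids carry exactly the parental union
  calls <- rbind(L1 = c(1, 0, 0, 0, rep(1, 6)),
                 L2 = c(0, 0, 1, 0, rep(1, 6)))
  colnames(calls) <- paste0("a", sprintf("%02d", 1:10))
  cl <- classifyBands(MarkerMatrix(calls, "TE"), sch)
  expect_true(all(deviationLabels(cl) == "additive_present"))
  s <- deviationSummary(cl)
  expect_equal(s@newBlock$in_all, 0)
  expect_equal(s@lostBlock$in_all, 0)

  ## polyploids all-zero: every parental band missing, nothing new
  calls2 <- calls; calls2[, 5:10] <- 0L
  cl2 <- classifyBands(MarkerMatrix(calls2, "TE"), sch)
  s2 <- deviationSummary(cl2)
  expect_equal(s2@lostBlock$in_all, s2@parental[["total"]])
  expect_equal(s2@newBlock$in_all, 0)
})

test_that("sharing-category counts equal powerset enumeration", {
  sch <- makeScheme(nPer = 2)
  for (seed in 1:15) {
    m <- randomMarker(seed + 100, nLoci = 30, nPer = 2, p = 0.3)
    cl <- classifyBands(m, sch)
    lab <- deviationLabels(cl)[!locusIds(cl) %in% flaggedLoci(cl), ,
                               drop = FALSE]
    for (blk in c("new", "lost")) {
      want <- if (blk == "new") "new" else "missing"
      expect_equal(as.integer(partitionSharingCategories(cl, blk)),
                   unname(brutePartition(lab, want, polyploids(sch))))
    }
  }
  ## single-polyploid scheme: everything lands in the singleton category
  sch1 <- TaxonScheme(setNames(rep(c("SYL", "TRI", "NUD"), each = 2),
                               paste0("a", sprintf("%02d", 1:6))),
                      "SYL", "TRI", "NUD")
  calls <- randomCalls(20, 6, seed = 3, p = 0.4)
  colnames(calls) <- paste0("a", sprintf("%02d", 1:6))
  cl1 <- classifyBands(MarkerMatrix(calls, "TE"), sch1)
  cats <- partitionSharingCategories(cl1, "new")
  expect_named(cats, "NUD")
  lab <- deviationLabels(cl1)[!locusIds(cl1) %in% flaggedLoci(cl1), ,
                              drop = FALSE]
  expect_equal(unname(cats), sum(lab[, "NUD"] == "new"))
})

test_that("results are invariant to locus and accession order", {
  sch <- makeScheme(nPer = 2)
  m <- randomMarker(7, nLoci = 30, nPer = 2, p = 0.35)
  s1 <- deviationSummary(classifyBands(m, sch))
  set.seed(99)
  calls <- markerCalls(m)[sample(30), sample(10)]
  s2 <- deviationSummary(classifyBands(MarkerMatrix(calls, "TEST"), sch))
  expect_equal(s1@parental, s2@parental)
  expect_equal(s1@newBlock$categories, s2@newBlock$categories)
  expect_equal(s1@lostBlock$categories, s2@lostBlock$categories)
})

test_that("parental origin of losses excludes unattributable shared bands", {
  sch <- makeScheme(nPer = 2)
  ## L1, L2 paternal-specific lost in NUD; L3 maternal-specific kept;
  ## L4 shared parental lost in NUD
  calls <- rbind(L1 = c(0, 0, 1, 0, 0, 0, 1, 0, 1, 0),
                 L2 = c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
                 L3 = c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0),
                 L4 = c(1, 0, 1, 0, 0, 0, 1, 1, 1, 1))
  colnames(calls) <- paste0("a", sprintf("%02d", 1:10))
  cl <- classifyBands(MarkerMatrix(calls, "TE"), sch)
  o <- parentalOriginOfLosses(cl, "NUD")
  expect_equal(o$paternal_lost, 2)
  expect_equal(o$maternal_lost, 0)
  expect_equal(o$shared_lost, 1)
  expect_equal(o$fraction_paternal, 1.0)
  ## symmetric case: equal losses give fraction 1/2 and a zero 1:1 statistic
  expect_equal(chisqRatioGof(c(10, 10))$statistic, 0)
  ## no attributable losses -> flagged undefined
  callsOk <- rbind(L4 = calls["L4", ], L5 = c(1, 1, 1, 1, rep(1, 6)))
  cl2 <- classifyBands(MarkerMatrix(callsOk, "TE"), sch)
  o2 <- parentalOriginOfLosses(cl2, "NUD")
  expect_false(o2$defined)
  expect_true(is.na(o2$fraction_paternal))
})

test_that("summary percentages follow the published denominators", {
  ## construct counts mirroring the Au row: 87 parental, 21 new (17 in NUD),
  ## then check the three percentage conventions
  sch <- makeScheme(nPer = 2)
  m <- randomMarker(11, nLoci = 40, nPer = 2, p = 0.4)
  s <- deviationSummary(classifyBands(m, sch))
  ptot <- s@parental[["total"]]
  expect_equal(s@newBlock$pct$in_all, 100 * s@newBlock$in_all / ptot)
  expect_equal(unname(s@newBlock$pct$per_taxon["NUD"]),
               100 * unname(s@newBlock$per_taxon["NUD"]) /
                 max(s@newBlock$in_all, 1))
  expect_equal(unname(s@lostBlock$pct$per_taxon["NUD"]),
               100 * unname(s@lostBlock$per_taxon["NUD"]) / ptot)
  expect_equal(unname(s@lostBlock$pct$categories),
               unname(100 * s@lostBlock$categories /
                        max(s@lostBlock$in_all, 1)))
  ## deviation proportion definition
  expect_equal(unname(s@deviationProportion["REP"]),
               unname((s@newBlock$per_taxon["REP"] +
                         s@lostBlock$per_taxon["REP"]) /
                        (ptot + s@newBlock$per_taxon["REP"])))
  ## new bands are disjoint from parental bands; missing is within parental
  lab <- deviationLabels(classifyBands(m, sch))
  st <- as.character(parentalStatus(classifyBands(m, sch)))
  expect_true(all(st[rowSums(lab == "new") > 0] == "absent_in_parents"))
  expect_true(all(st[rowSums(lab == "missing") > 0] != "absent_in_parents"))
})
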