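test_that("uncorrected P distance counts differing loci", {
  calls <- rbind(L1 = c(0, 0, 1), L2 = c(1, 1, 1), L3 = c(1, 0, 0),
                 L4 = c(0, 1, 1))
  colnames(calls) <- c("x", "y", "z")
  d <- uncorrectedPDistance(MarkerMatrix(calls, "TE"))
  expect_equal(d["x", "x"], 0)
  expect_equal(d["x", "y"], 2 / 4)     # profiles 0110 vs 0011
  expect_equal(d["y", "z"], 1 / 4)
  expect_true(isSymmetric(unname(d)))
  ## complementary profiles over any number of loci are at distance 1
  comp <- cbind(p = rep(c(0L, 1L), 5), q = rep(c(1L, 0L), 5))
  rownames(comp) <- paste0("L", 1:10)
  expect_equal(uncorrectedPDistance(MarkerMatrix(comp, "TE"))["p", "q"], 1)
})

test_that("three-taxon networks use the closed-form star decomposition", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.7
  d["a", "c"] <- d["c", "a"] <- 0.9
  d["b", "c"] <- d["c", "b"] <- 0.4
  net <- neighborNet(d)
  w <- setNames(splitWeights(net), sapply(splits(net), function(s)
    paste(net@taxa[s], collapse = "")))
  expect_equal(w[["a"]], (0.7 + 0.9 - 0.4) / 2)
  expect_equal(w[["b"]], (0.7 + 0.4 - 0.9) / 2)
  expect_equal(w[["c"]], (0.9 + 0.4 - 0.7) / 2)
})

test_that("NeighborNet recovers additive tree metrics exactly", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- cophenetic(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    net <- neighborNet(D)
    ## split system equals the tree's edges with branch-length weights
    expect_equal(length(splits(net)), nrow(tr$edge))
    fit <- splitDistances(net)
    expect_lt(max(abs(fit[rownames(D), colnames(D)] - D)), 1e-8)
    ## every tree bipartition appears among the network's splits
    bip <- ape::prop.part(tr)
    treeKeys <- sapply(bip[-1], function(idx) {
      side <- sort(tr$tip.label[idx])
      other <- sort(setdiff(tr$tip.label, side))
      paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
            max(paste(side, collapse = ","), paste(other, collapse = ",")),
            sep = "|")
    })
    expect_true(all(treeKeys %in% splitKeys(net)))
  }
})

test_that("synthesized circular split systems are recovered to 1e-8", {
  set.seed(22)
  for (i in 1:5) {
    n <- 6
    cyc <- sample(n)
    w <- ifelse(runif(n * (n - 1) / 2) < 0.4, 0, runif(n * (n - 1) / 2, 0.2, 1))
    D <- circularMetric(cyc, w)
    net <- neighborNet(D)
    expect_lt(max(abs(splitDistances(net) - D)), 1e-8)
    expect_true(all(splitWeights(net) >= 0))
  }
})

test_that("network construction is deterministic and circular-consistent", {
  sch <- makeScheme(2)
  m <- randomMarker(23, nLoci = 40, nPer = 2)
  d <- uncorrectedPDistance(m)
  n1 <- neighborNet(d); n2 <- neighborNet(d)
  expect_identical(cycleOrder(n1), cycleOrder(n2))
  expect_identical(splits(n1), splits(n2))
  expect_equal(splitWeights(n1), splitWeights(n2))
  ## validity enforces circular compatibility of every returned split
  expect_true(validObject(n1))
  expect_error(neighborNet(d - 0.01), "nonnegative")
})

test_that("NeighborNet agrees with the phangorn implementation on tree metrics", {
  set.seed(24)
  tr <- ape::rtree(7, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  D <- cophenetic(tr)
  nn <- phangorn::neighborNet(D)
  net <- neighborNet(D[rownames(D), rownames(D)])
  ## same fitted distances on a tree metric (both recover the tree exactly)
  expect_lt(max(abs(splitDistances(net)[rownames(D), colnames(D)] - D)), 1e-6)
  expect_s3_class(nn, "networx")
})

test_that("bootstrap supports are replayable and filter at the threshold", {
  ## identical loci: every replicate reproduces the same network exactly
  base <- c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  calls <- matrix(rep(base, each = 12), 12, 10, byrow = FALSE,
                  dimnames = list(paste0("L", 1:12),
                                  paste0("a", sprintf("%02d", 1:10))))
  m <- MarkerMatrix(calls, "TE")
  bs <- bootstrapConfidenceNetwork(m, nBoot = 20, threshold = 1, seed = 1)
  expect_true(all(splitSupports(bs$network) == 1))
  expect_equal(length(splits(bs$confidenceNetwork)),
               length(splits(bs$network)))

  ## random data: supports equal recomputation from the logged replicates
  m2 <- randomMarker(25, nLoci = 30, nPer = 1)
  bs2 <- bootstrapConfidenceNetwork(m2, nBoot = 25, threshold = 0.6, seed = 7)
  keys <- splitKeys(bs2$network)
  manual <- sapply(seq_along(keys), function(k) {
    s <- splits(bs2$network)[[k]]
    taxa <- bs2$network@taxa
    key <- ssapdyn:::.splitKey(s, taxa)
    mean(sapply(bs2$replicateSplits, function(rk) key %in% rk))
  })
  expect_equal(unname(splitSupports(bs2$network)), unname(manual))
  ## threshold contract
  expect_true(all(splitSupports(bs2$confidenceNetwork) >= 0.6))
  expect_equal(length(splits(bs2$confidenceNetwork)),
               sum(splitSupports(bs2$network) >= 0.6))
  ## determinism under a fixed seed
  bs3 <- bootstrapConfidenceNetwork(m2, nBoot = 25, threshold = 0.6, seed = 7)
  expect_equal(splitSupports(bs3$network), splitSupports(bs2$network))
})

test_that("NEXUS output round-trips and indexes taxa as a permutation", {
  m <- randomMarker(26, nLoci = 25, nPer = 1)
  bs <- bootstrapConfidenceNetwork(m, nBoot = 10, seed = 2)
  net <- bs$network
  path <- withr::local_tempfile(fileext = ".nex")
  writeSplitsNexus(net, path)
  back <- readSplitsNexus(path)
  expect_identical(back@taxa, net@taxa)
  expect_identical(cycleOrder(back), cycleOrder(net))
  expect_identical(splits(back), splits(net))
  expect_equal(splitWeights(back), splitWeights(net), tolerance = 1e-9)
  expect_equal(splitSupports(back), splitSupports(net), tolerance = 1e-9)
  expect_setequal(cycleOrder(back), seq_along(net@taxa))
  ## an empty split set still yields a valid file with a TAXA block
  empty <- new("SplitNetwork", taxa = c("a", "b", "c", "d"), cycle = 1:4,
               splits = list(), weights = numeric(0), supports = numeric(0))
  writeSplitsNexus(empty, path)
  back2 <- readSplitsNexus(path)
  expect_identical(back2@taxa, c("a", "b", "c", "d"))
  expect_length(splits(back2), 0)
})
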