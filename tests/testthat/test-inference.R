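test_that("Yates 2x2 statistic matches the shortcut formula and base oracle", {
  expect_equal(yatesChisq2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(yatesChisq2x2(rbind(c(10, 10), c(10, 10)))$p_one_sided, 0.5)
  ## N(|ad-bc| - N/2)^2 / (r1 r2 c1 c2), computed independently
  tab <- rbind(c(18, 48), c(38, 28))
  N <- sum(tab)
  shortcut <- N * (abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) - N / 2)^2 /
    prod(rowSums(tab)) / prod(colSums(tab))
  r <- yatesChisq2x2(tab)
  expect_equal(r$statistic, shortcut, tolerance = 1e-12)
  expect_equal(r$statistic, 11.197, tolerance = 1e-3)
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 12) + 1, 2, 2)
    r <- yatesChisq2x2(tab)
    raw <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    cor <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_lte(r$statistic, unname(raw$statistic) + 1e-12)
    expect_equal(r$statistic, unname(cor$statistic), tolerance = 1e-10)
    expect_equal(r$p_two_sided, unname(cor$p.value), tolerance = 1e-10)
    expect_true(r$p_one_sided >= 0 && r$p_one_sided <= 1)
  }
  ## direction gating: mismatched alternative flips to the complementary tail
  tab <- rbind(c(30, 10), c(10, 30))
  pMatch <- yatesChisq2x2(tab, "row1_greater")$p_one_sided
  pMiss <- yatesChisq2x2(tab, "row1_less")$p_one_sided
  expect_equal(pMatch + pMiss, 1)
  expect_error(yatesChisq2x2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("ratio goodness of fit applies the continuity correction", {
  expect_equal(chisqRatioGof(c(10, 10))$statistic, 0)
  expect_equal(chisqRatioGof(c(30, 10))$statistic, 2 * 9.5^2 / 20)
  set.seed(9)
  for (i in 1:50) {
    k <- rpois(2, 20) + 1
    r <- chisqRatioGof(k)
    expect_equal(r$p_two_sided,
                 pchisq(r$statistic, 1, lower.tail = FALSE))
  }
  expect_error(chisqRatioGof(c(0, 0)), "zero total")
})

test_that("one-sided Fisher p equals hypergeometric enumeration (N <= 12)", {
  expect_equal(fisherExactOneSided(rbind(c(1, 0), c(0, 1)))$p_one_sided, 0.5)
  ## identical rows carry no signal: 'greater' tail from the observed cell is 1
  pid <- fisherExactOneSided(rbind(c(0, 5), c(0, 5)), "greater")$p_one_sided
  expect_equal(pid, 1)
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    if (a + b + cc + d == 0 || a + b + cc + d > 12) next
    tab <- rbind(c(a, b), c(cc, d))
    for (dir in c("greater", "less")) {
      expect_equal(fisherExactOneSided(tab, dir)$p_one_sided,
                   enumFisherP(tab, dir), tolerance = 1e-12)
    }
  }
  ## cross-check against the base implementation on larger tables
  set.seed(10)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2, 2) + 1
    for (dir in c("greater", "less"))
      expect_equal(fisherExactOneSided(tab, dir)$p_one_sided,
                   fisher.test(tab, alternative = dir)$p.value,
                   tolerance = 1e-9)
  }
})

test_that("Wilson limits satisfy the score equation and cover k/n", {
  expect_equal(newcombeWilsonCi(0, 10)[["lower"]], 0)
  expect_equal(newcombeWilsonCi(10, 10)[["upper"]], 1)
  z <- qnorm(0.975)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:200, 1); k <- sample(0:n, 1)
    ci <- newcombeWilsonCi(k, n)
    p <- k / n
    expect_gte(p, ci[["lower"]] - 1e-12)
    expect_lte(p, ci[["upper"]] + 1e-12)
    for (end in ci) {
      if (end %in% c(0, 1) && p %in% c(0, 1)) next
      expect_equal((p - end)^2, z^2 * end * (1 - end) / n, tolerance = 1e-8)
    }
  }
})

test_that("Holm step-down equals the base adjustment and dominates Bonferroni", {
  expect_equal(holmAdjust(0.03)$adjusted, 0.03)
  expect_false(any(holmAdjust(rep(1, 6))$reject))
  set.seed(12)
  for (i in 1:500) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    h <- holmAdjust(p)
    expect_equal(h$adjusted, p.adjust(p, "holm"), tolerance = 1e-12)
    bon <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(h$reject[bon]))          # Holm rejects whatever Bonferroni does
  }
})

test_that("one-way ANOVA and Tukey HSD match the base fits", {
  ## two groups: F is the squared pooled-variance t statistic
  set.seed(13)
  g1 <- rnorm(6); g2 <- rnorm(8, 1)
  r <- onewayAnovaTukey(list(a = g1, b = g2))
  tt <- t.test(g2, g1, var.equal = TRUE)
  expect_equal(r$anova$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
  ## identical observations: no between-group variance
  r0 <- onewayAnovaTukey(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(r0$anova$ss[1], 0)
  expect_equal(r0$anova$f[1], 0)
  ## random unbalanced designs against aov/TukeyHSD
  for (i in 1:10) {
    k <- sample(3:5, 1)
    ni <- sample(3:7, k, replace = TRUE)
    y <- rnorm(sum(ni), rep(rnorm(k, sd = 2), ni))
    g <- factor(rep(letters[1:k], ni))
    mine <- onewayAnovaTukey(y, g)
    base <- anova(lm(y ~ g))
    expect_equal(mine$anova$ss, c(base$`Sum Sq`), tolerance = 1e-10)
    expect_equal(mine$anova$f[1], base$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$anova$p[1], base$`Pr(>F)`[1], tolerance = 1e-10)
    ## SS decomposition and df bookkeeping
    expect_equal(sum(mine$anova$ss), sum((y - mean(y))^2), tolerance = 1e-10)
    expect_equal(sum(mine$anova$df), length(y) - 1)
    tk <- TukeyHSD(aov(y ~ g))$g
    mk <- mine$tukey
    key <- paste(mk$group2, mk$group1, sep = "-")
    expect_equal(mk$diff, unname(tk[key, "diff"]), tolerance = 1e-10)
    expect_equal(mk$lower, unname(tk[key, "lwr"]), tolerance = 1e-8)
    expect_equal(mk$p_adj, unname(tk[key, "p adj"]), tolerance = 1e-6)
  }
  ## invariance under positive affine transforms of the observations
  y <- rnorm(20); g <- factor(rep(1:4, each = 5))
  f1 <- onewayAnovaTukey(y, g)$anova$f[1]
  f2 <- onewayAnovaTukey(100 * y + 7, g)$anova$f[1]
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("Mantel correlation and permutation p behave as advertised", {
  set.seed(14)
  n <- 6
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  self <- mantelTest(D, D, nPerm = 99, seed = 1)
  expect_equal(self$statistic, 1)
  expect_gte(self$p_one_sided, 1 / 100)   # identity included in reference set
  ## r always within [-1, 1]
  for (i in 1:5) {
    E <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(E) <- dimnames(D)
    r <- mantelTest(D, E, nPerm = 49, seed = i)$statistic
    expect_gte(r, -1); expect_lte(r, 1)
  }
  ## exact enumeration on 4 taxa matches a direct loop over all 4! permutations
  n <- 4
  A <- as.matrix(dist(matrix(rnorm(8), 4)))
  B <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(A) <- dimnames(B) <- list(paste0("x", 1:4), paste0("x", 1:4))
  ex <- mantelTest(A, B, exact = TRUE)
  lt <- lower.tri(A)
  r0 <- cor(A[lt], B[lt])
  rs <- sapply(allPerms(4), function(p) {
    Bp <- B[p, p]; cor(A[lt], Bp[lt])
  })
  expect_equal(ex$p_one_sided, mean(rs >= r0 - 1e-12))
  expect_equal(ex$n_perm, 24)
  ## agreement with the vegan implementation on the veridical statistic
  vg <- vegan::mantel(A, B, permutations = 99)
  expect_equal(ex$statistic, unname(vg$statistic), tolerance = 1e-10)
  expect_error(mantelTest(A, B[4:1, 4:1]), "identical labels")
})
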