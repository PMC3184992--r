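test_that("pedigree simulation produces the requested pair structure", {
  co <- simulatePedigree(128, 128, seed = 1)
  expect_equal(length(individuals(co)), 512)
  expect_equal(nPairs(co), 256)
  p <- pairTable(co)
  expect_equal(sum(p$zygosity == "MZ"), 128)
  expect_equal(length(unique(p$family_id)), 256)

  expect_equal(nPairs(simulatePedigree(0, 0, seed = 1)), 0)

  co2 <- simulatePedigree(2, 3, seed = 7)
  expect_equal(length(individuals(co2)), 10)
  expect_equal(nPairs(co2), 5)
  expect_equal(length(unique(pairTable(co2)$family_id)), 5)

  expect_error(simulatePedigree(-1, 3), "non-negative")
  expect_identical(simulatePedigree(5, 5, seed = 3),
                   simulatePedigree(5, 5, seed = 3))
  # MZ co-twins always share sex
  sx <- co@sex
  expect_true(all(sx[p$member1[p$zygosity == "MZ"]] ==
                  sx[p$member2[p$zygosity == "MZ"]]))
})

test_that("cohort validity rejects malformed pair tables", {
  p <- pairTable(tiny_cohort())
  p$zygosity[1] <- "XX"
  expect_error(TwinCohort(p), "MZ")
  p2 <- pairTable(tiny_cohort())
  p2$member2[2] <- p2$member1[1]
  expect_error(TwinCohort(p2), "one pair")
})

test_that("MZ co-twins share phased genotypes; frequencies behave", {
  co <- tiny_cohort(20, 20)
  snps <- list(snpModel("s1", c("A", "G"), 0.3),
               snpModel("s2", c("C", "T"), 0.8))
  g <- simulateGenotypes(co, snps, seed = 5)
  p <- pairTable(co)
  for (s in c("s1", "s2")) {
    gs <- g[g$snp == s, ]
    rownames(gs) <- gs$individual
    mz <- p[p$zygosity == "MZ", ]
    expect_equal(gs[mz$member1, c("maternal", "paternal")],
                 gs[mz$member2, c("maternal", "paternal")],
                 ignore_attr = TRUE)
  }
  # frequency 0: everyone homozygous for the other allele
  g0 <- simulateGenotypes(co, list(snpModel("z", c("A", "G"), 0)),
                          seed = 2)
  expect_true(all(g0$maternal == "G" & g0$paternal == "G"))
})

test_that("heterozygote fraction matches Hardy-Weinberg at freq 0.5", {
  co <- simulatePedigree(2500, 2500, seed = 11)
  g <- simulateGenotypes(co, list(snpModel("s", c("A", "G"), 0.5)),
                         seed = 12)
  expect_equal(mean(g$maternal != g$paternal), 0.5, tolerance = 0.04)
})

test_that("linked SNPs are co-inherited with the stated phase", {
  co <- tiny_cohort(50, 50)
  g <- simulateGenotypes(co, defaultSnpModels(), seed = 4)
  a <- g[g$snp == "rs10732516", ]
  b <- g[g$snp == "rs2839701", ]
  expect_identical(ifelse(a$maternal == "A", "G", "C"), b$maternal)
  expect_identical(ifelse(a$paternal == "A", "G", "C"), b$paternal)
})

test_that("zero-variance methylation equals its baselines", {
  co <- tiny_cohort()
  rg <- list(regionModel("R", 3, c(0.1, 0.5, 0.9), 0.9))
  ms <- simulateMethylation(co, NULL, rg, list(), seed = 1)
  m <- alleleLevels(ms, "maternal")
  expect_true(all(m[, 1] == 0.1 & m[, 2] == 0.5 & m[, 3] == 0.9))
  expect_true(all(alleleLevels(ms, "paternal") == 0.9))
  expect_equal(methLevels(ms),
               (alleleLevels(ms, "maternal") +
                alleleLevels(ms, "paternal")) / 2)
})

test_that("intra-pair correlations follow the ACE expectations", {
  co <- simulatePedigree(5000, 5000, seed = 2)
  rg <- list(regionModel("R", 2, 0.5, 0.5, sigmaA2 = 0.03,
                         sigmaC2 = 0.01, sigmaE2 = 0.01, rhoW = 0.5))
  ms <- simulateMethylation(co, NULL, rg, list(), seed = 3)
  m <- methLevels(ms)
  p <- pairTable(co)
  mz <- p[p$zygosity == "MZ", ]; dz <- p[p$zygosity == "DZ", ]
  expect_equal(cor(m[mz$member1, 1], m[mz$member2, 1]), 0.8,
               tolerance = 0.05 / 0.8)
  expect_equal(cor(m[dz$member1, 1], m[dz$member2, 1]), 0.5,
               tolerance = 0.05 / 0.5)
})

test_that("an origin-restricted SNP effect shifts only maternal carriers", {
  co <- simulatePedigree(500, 500, seed = 6)
  snps <- list(snpModel("s", c("A", "G"), 0.5, effectUnits = "R:u01",
                        beta = 0.25))
  g <- simulateGenotypes(co, snps, seed = 7)
  rg <- list(regionModel("R", 1, 0.1, 0.9))
  ms <- simulateMethylation(co, g, rg, snps, seed = 8)
  m <- methLevels(ms)
  gm <- setNames(g$maternal, g$individual)[rownames(m)]
  expect_equal(unname(m[gm == "A", 1]),
               rep(0.625, sum(gm == "A")))
  expect_equal(unname(m[gm == "G", 1]), rep(0.5, sum(gm == "G")))
  expect_error(
    simulateMethylation(co, g, rg,
                        list(snpModel("s", c("A", "G"), 0.5,
                                      effectUnits = "nope:u01",
                                      beta = 0.1)), seed = 1),
    "not found")
})

test_that("simulated values stay in range and are seed-reproducible", {
  co <- tiny_cohort(10, 10)
  ms1 <- simulateMethylation(co, NULL, defaultRegionModels(), list(),
                             seed = 9)
  ms2 <- simulateMethylation(co, NULL, defaultRegionModels(), list(),
                             seed = 9)
  expect_identical(methLevels(ms1), methLevels(ms2))
  m <- methLevels(ms1)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("aberration injection applies the documented shifts", {
  co <- tiny_cohort()
  rg <- list(regionModel("R", 4, 0.5, 0.5))
  ms <- simulateMethylation(co, NULL, rg, list(), seed = 1)
  p <- pairTable(co)
  ev <- aberrationEvent("regional", "LOM", "concordant", 0.2,
                        units = c("R:u01", "R:u02"))
  ms2 <- injectAberrations(ms, list(ev), pairIds = p$pair_id[1],
                           seed = 2)
  m <- methLevels(ms2)
  twins <- c(p$member1[1], p$member2[1])
  expect_equal(unname(m[twins, c("R:u01", "R:u02")]),
               matrix(0.3, 2, 2))
  expect_equal(unname(m[twins, "R:u03"]), c(0.5, 0.5))

  ev2 <- aberrationEvent("local", "GOM", "discordant", 0.3)
  ms3 <- injectAberrations(ms, list(ev2), seed = 3)
  changed <- which(methLevels(ms3) != methLevels(ms), arr.ind = TRUE)
  expect_equal(nrow(changed), 1L)

  expect_error(
    injectAberrations(ms, list(aberrationEvent("local", "LOM",
                                               "discordant", 0.1,
                                               units = "X:u99"))),
    "unknown units")
  expect_error(aberrationEvent("local", "LOM", "discordant", 0),
               "positive")
})

test_that("missingness is Bernoulli at the requested rate", {
  co <- tiny_cohort(25, 25)   # 100 individuals
  rg <- list(regionModel("R", 100, 0.5, 0.5))
  ms <- simulateMethylation(co, NULL, rg, list(), seed = 1)
  expect_identical(methLevels(applyMissingness(ms, 0, seed = 1)),
                   methLevels(ms))
  ms3 <- applyMissingness(ms, 0.3, seed = 2)
  expect_equal(sum(is.na(methLevels(ms3))), 3000, tolerance = 100 / 3000)
  expect_error(applyMissingness(ms, 1), "rate")
  # a unit missing at 50% is dropped by the 75% coverage filter
  m <- methLevels(ms)
  m[runif(nrow(m)) < 0.5, "R:u01"] <- NA
  kept <- colnames(filterUnits(m, 0.75))
  expect_false("R:u01" %in% kept)
})
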