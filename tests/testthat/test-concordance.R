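test_that("pair discordance equals per-unit subtraction", {
  co <- tiny_cohort(2, 2)
  p <- pairTable(co)
  m <- flat_meth(8, 3)
  rownames(m) <- individuals(co)
  expect_true(all(pairDiscordance(m, co, level = "unit")$discordance == 0))
  m[p$member1[1], "R:u01"] <- 0.6
  m[p$member2[1], "R:u01"] <- 0.45
  du <- pairDiscordance(m, co, level = "unit")
  expect_equal(du$discordance[du$pair_id == p$pair_id[1] &
                              du$unit == "R:u01"], 0.15)
  # random table vs brute-force oracle
  set.seed(21)
  m2 <- matrix(runif(8 * 3), 8, 3, dimnames = dimnames(m))
  du2 <- pairDiscordance(m2, co, level = "unit")
  for (i in seq_len(nrow(du2))) {
    pr <- p[p$pair_id == du2$pair_id[i], ]
    expect_equal(du2$discordance[i],
                 abs(m2[pr$member1, du2$unit[i]] -
                     m2[pr$member2, du2$unit[i]]))
  }
})

test_that("region discordance is missing-robust and sum-equivalent", {
  co <- tiny_cohort(1, 1)
  p <- pairTable(co)
  m <- flat_meth(4, 4)
  rownames(m) <- individuals(co)
  m[p$member1[1], ] <- c(0.6, 0.7, 0.5, NA)
  m[p$member2[1], ] <- c(0.5, 0.5, 0.5, 0.5)
  dr <- pairDiscordance(m, co, level = "region")
  # mean |diff| over 3 shared units (0.1, 0.2, 0) scaled by 4 units
  expect_equal(dr$discordance[dr$pair_id == p$pair_id[1]],
               mean(c(0.1, 0.2, 0)) * 4)
  drs <- pairDiscordance(m, co, level = "region", mode = "sum")
  expect_equal(drs$discordance[drs$pair_id == p$pair_id[1]], 0.3)
  # no shared units -> missing
  m[p$member1[2], ] <- NA
  dr2 <- pairDiscordance(m, co, level = "region")
  expect_true(is.na(dr2$discordance[dr2$pair_id == p$pair_id[2]]))
})

test_that("non-related pseudo-pairs never share a family", {
  co <- tiny_cohort(1, 1)
  nr <- makeNonrelatedPairs(co, seed = 3)
  p <- pairTable(co)
  fam <- setNames(rep(p$family_id, each = 2), individuals(co))
  expect_equal(nrow(nr), 2)
  expect_true(all(fam[nr$member1] != fam[nr$member2]))

  co2 <- simulatePedigree(128, 128, seed = 4)
  nr2 <- makeNonrelatedPairs(co2, seed = 5)
  fam2 <- setNames(rep(pairTable(co2)$family_id, each = 2),
                   individuals(co2))
  expect_equal(nrow(nr2), 256)
  expect_equal(sum(fam2[nr2$member1] == fam2[nr2$member2]), 0)
  expect_identical(nr2, makeNonrelatedPairs(co2, seed = 5))

  one_fam <- TwinCohort(data.frame(
    pair_id = "p1", zygosity = "MZ", member1 = "a", member2 = "b",
    family_id = "f1"))
  expect_error(makeNonrelatedPairs(one_fam), "two families")
})

test_that("Kruskal-Wallis H and Dunn z match their formulas", {
  # identical groups: degenerate null
  r0 <- kruskalWallisDunn(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(r0$H, 0)
  expect_equal(r0$p.value, 1)

  g <- list(a = c(1, 2, 3), b = c(7, 8, 9), c = c(4, 5, 6))
  r <- kruskalWallisDunn(g)
  # direct formula: ranks 1..9, rank means 2, 8, 5
  expect_equal(r$H, 12 / (9 * 10) * 3 * ((2 - 5)^2 + (8 - 5)^2))
  expect_equal(r$df, 2)
  # Dunn z for a vs b: (2 - 8) / sqrt((9*10/12) * (2/3))
  zab <- r$comparisons$z[r$comparisons$group1 == "a" &
                         r$comparisons$group2 == "b"]
  expect_equal(zab, (2 - 8) / sqrt((9 * 10 / 12) * (2 / 3)))
  expect_equal(r$comparisons$p.adj,
               pmin(1, r$comparisons$p * 3))
})

test_that("the chi-square p approximates a permutation null", {
  set.seed(9)
  g <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8))
  r <- kruskalWallisDunn(g)
  vals <- unlist(g)
  lab <- rep(names(g), lengths(g))
  perm <- replicate(2000, {
    kruskal.test(vals, factor(sample(lab)))$statistic
  })
  p_perm <- mean(perm >= r$H - 1e-12)
  expect_lt(abs(r$p.value - p_perm),
            3 * sqrt(p_perm * (1 - p_perm) / 2000) + 0.02)
})

test_that("LOM/GOM calls use a strict 0.10 band around the median", {
  m <- flat_meth(9, 1, value = 0.5)
  m[1, 1] <- 0.38   # LOM
  m[2, 1] <- 0.55   # inside the band
  m[3, 1] <- 0.40   # exactly median - 0.10: no call
  m[4, 1] <- 0.65   # GOM
  calls <- callLomGom(m, cutoff = 0.10)
  expect_equal(unname(calls$calls[1:4, 1]),
               c("LOM", "none", "none", "GOM"))
  expect_error(callLomGom(m, cutoff = 0), "cutoff")
})

test_that("pair concordance classes follow the both/exactly-one rule", {
  co <- tiny_cohort(2, 0)
  p <- pairTable(co)
  m <- flat_meth(20, 1, value = 0.5)
  rownames(m)[1:4] <- individuals(co)
  m[p$member1[1], 1] <- 0.2; m[p$member2[1], 1] <- 0.25  # both LOM
  m[p$member1[2], 1] <- 0.2                              # one LOM
  calls <- callLomGom(m, 0.10)
  cls <- classifyPairConcordance(calls, co)
  expect_equal(cls$lom[cls$pair_id == p$pair_id[1]], "concordant")
  expect_equal(cls$lom[cls$pair_id == p$pair_id[2]], "discordant")
  expect_equal(cls$gom, c("none", "none"))
  # a missing member drops the observation
  m[p$member1[1], 1] <- NA
  calls2 <- callLomGom(m, 0.10)
  cls2 <- classifyPairConcordance(calls2, co)
  expect_false(p$pair_id[1] %in% cls2$pair_id)
})

test_that("tabulated percentages reproduce printed one-decimal values", {
  expect_equal(tabulateConcordance(c(60, 265, 2612))$pct,
               c(2.0, 9.0, 88.9))
  expect_equal(tabulateConcordance(c(110, 329, 2498))$pct[1], 3.7)
  expect_equal(tabulateConcordance(c(0, 0, 5))$pct, c(0, 0, 100.0))
  # column counts conserve the number of evaluable observations
  co <- tiny_cohort(4, 4)
  set.seed(12)
  m <- matrix(runif(8 * 2 * 6, 0.2, 0.8), 16, 6,
              dimnames = list(individuals(co),
                              sprintf("R:u%02d", 1:6)))
  cls <- classifyPairConcordance(callLomGom(m, 0.1), co)
  tab <- tabulateConcordance(cls)
  for (z in unique(tab$zygosity)) {
    n_obs <- sum(cls$zygosity == z)
    expect_equal(sum(tab$count[tab$zygosity == z & tab$type == "LOM"]),
                 n_obs)
  }
  # individual-level observations double the pair-level counts
  tab2 <- tabulateConcordance(cls, observation = "individual")
  expect_equal(tab2$count, 2 * tab$count)
})

test_that("3x2 chi-square handles zero margins at fixed df = 2", {
  same <- chiSquare3x2(c(5, 10, 100), c(5, 10, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  r1 <- chiSquare3x2(c(22, 17, 2720), c(0, 17, 2732))
  expect_equal(r1$statistic, 22.0, tolerance = 0.01)
  expect_equal(r1$df, 2)
  expect_lt(r1$p.value, 0.001)

  r2 <- chiSquare3x2(c(0, 52, 2672), c(0, 20, 2735))
  expect_equal(r2$statistic, 14.8, tolerance = 0.01)
  expect_lt(r2$p.value, 0.001)
  # agrees with stats::chisq.test when no margin is zero
  o <- rbind(c(12, 30, 200), c(20, 25, 180))
  expect_equal(chiSquare3x2(o[1, ], o[2, ])$statistic,
               unname(suppressWarnings(chisq.test(o))$statistic))
  expect_error(chiSquare3x2(c(0, 0, 0), c(0, 0, 0)), "all-zero")
})

test_that("call counts are monotone non-increasing in the cutoff", {
  co <- tiny_cohort(6, 6)
  set.seed(13)
  m <- matrix(pmin(1, pmax(0, rnorm(24 * 8, 0.5, 0.15))), 24, 8,
              dimnames = list(individuals(co),
                              sprintf("R:u%02d", 1:8)))
  sweep_out <- cutoffSweep(m, co, c(0.05, 0.10, 0.20, 0.99))
  totals <- vapply(sweep_out, function(tab)
    sum(tab$count[tab$class != "none"]), 0)
  expect_true(all(diff(unname(totals)) <= 0))
  expect_equal(unname(totals[4]), 0)  # extreme cutoff: no calls
  # counts at one cutoff equal a brute-force recount
  med <- apply(m, 2, median)
  brute <- sum(abs(sweep(m, 2, med)) > 0.10)
  calls <- callLomGom(m, 0.10)
  expect_equal(sum(calls$calls != "none"), brute)
})
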