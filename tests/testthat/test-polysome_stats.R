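mk <- defaultMarkers()

labelledSet <- function(n, nCells = 1, occ = NULL) {
  p <- randomParticleTable(n, box = 10000, nTomo = 1)
  p$tomoID <- paste0("c", rep_len(seq_len(nCells), n))
  p$occupancy <- if (is.null(occ)) "1xbS20" else occ
  asParticleSet(p, labels = "occupancy")
}

chainSetOf <- function(...) {
  ch <- list(...)
  new("PolysomeChainSet", chains = lapply(ch, as.integer),
      stepDistances = lapply(ch, function(x) rep(70, length(x) - 1)),
      tomoIDs = rep("c1", length(ch)))
}

test_that("per-chain composition fractions and summaries are exact", {
  ps <- labelledSet(8, occ = c("2xbS20", "2xbS20", "1xbS20", "2xbS20",
                               "1xbS20", "1xbS20", "2xbS20", "2xbS20"))
  cs <- chainSetOf(0:3, 4:5, 6:7)
  out <- compositionFractions(cs, ps, "occupancy", "2xbS20")
  expect_equal(out$perChain$fraction, c(0.75, 0, 1))
  expect_equal(out$mean, mean(c(0.75, 0, 1)))
  expect_equal(out$sd, sqrt(mean((c(0.75, 0, 1) -
                                    mean(c(0.75, 0, 1)))^2)))
  expect_equal(out$weightedMean, (3 + 0 + 2) / 8)
  expect_equal(out$nChains, 3L)
  expect_error(compositionFractions(cs, ps, "missing_label", "x"),
               "label column")
})

test_that("composition mean converges to label prevalence on Bernoulli labels", {
  set.seed(201)
  nChains <- 250
  lens <- 2 + rpois(nChains, 3)
  n <- sum(lens)
  occ <- ifelse(runif(n) < 0.67, "2xbS20", "1xbS20")
  ps <- labelledSet(n, occ = occ)
  bounds <- cumsum(c(0, lens))
  cs <- new("PolysomeChainSet",
            chains = lapply(seq_len(nChains),
                            function(i) (bounds[i]):(bounds[i + 1] - 1L)),
            stepDistances = lapply(lens, function(l) rep(70, l - 1)),
            tomoIDs = rep("c1", nChains))
  out <- compositionFractions(cs, ps, "occupancy", "2xbS20")
  se <- sqrt(0.67 * 0.33 / mean(lens)) / sqrt(nChains)
  expect_lt(abs(out$mean - 0.67), 3 * se)
  expect_equal(out$weightedMean, mean(occ == "2xbS20"))
})

test_that("per-cell occupancy uses the population-SD convention by default", {
  p <- randomParticleTable(10, box = 5000)
  p$tomoID <- rep(c("c1", "c2"), each = 5)
  p$occupancy <- c(rep("2xbS20", 3), rep("1xbS20", 2),   # 0.6
                   rep("2xbS20", 4), "1xbS20")           # 0.8
  ps <- asParticleSet(p, "occupancy")
  out <- occupancyByCell(ps, "occupancy", "2xbS20")
  expect_equal(out$perCell$fraction, c(0.6, 0.8))
  expect_equal(out$mean, 0.7)
  expect_equal(out$sd, 0.1)                 # population SD
  out2 <- occupancyByCell(ps, "occupancy", "2xbS20", sdType = "sample")
  expect_equal(out2$sd, sd(c(0.6, 0.8)))
  all2 <- occupancyByCell(labelledSet(20, nCells = 4, occ = "1xbS20"),
                          "occupancy", "1xbS20")
  expect_equal(all2$mean, 1)
  expect_equal(all2$sd, 0)
})

test_that("occupancy estimator matches the binomial sampling oracle", {
  set.seed(202)
  nCells <- 28; nPer <- 500; pTrue <- 0.67
  occ <- ifelse(runif(nCells * nPer) < pTrue, "2xbS20", "1xbS20")
  ps <- labelledSet(nCells * nPer, nCells = nCells, occ = occ)
  out <- occupancyByCell(ps, "occupancy", "2xbS20")
  seMean <- sqrt(pTrue * (1 - pTrue) / nPer) / sqrt(nCells)
  expect_lt(abs(out$mean - pTrue), 3 * seMean)
  sdExpect <- sqrt(pTrue * (1 - pTrue) / nPer)   # ~0.021
  expect_lt(abs(out$sd - sdExpect) / sdExpect, 0.35)
})

test_that("neighbour distances carry leader/trailer labels and strata", {
  p <- data.frame(particleID = 0:1, tomoID = "t", x = c(0, 300), y = 0,
                  z = 0, rot = 0, tilt = 0, psi = 0)
  p$occupancy <- c("1xbS20", "2xbS20")
  ps <- asParticleSet(p, "occupancy")
  # pre-resolution: one row per particle with a neighbour under 500 A
  nd <- neighbourDistances(ps, mk, "occupancy")
  expect_equal(nrow(nd), 2L)
  lead <- nd[nd$from == 1, ]
  expect_equal(lead$distance, 190, tolerance = 1e-9)   # 300 - 110
  expect_equal(lead$leaderLabel, "2xbS20")             # particle 1 leads
  expect_equal(lead$trailerLabel, "1xbS20")
  expect_equal(nd$distance[nd$from == 0], 410, tolerance = 1e-9)
  # post-resolution keeps only the surviving tracing link
  ndr <- neighbourDistances(ps, mk, "occupancy", resolved = TRUE)
  expect_equal(nrow(ndr), 1L)
  expect_equal(ndr$from, 1L)

  sc <- simulateScene(sceneParams(nCells = 2, nPolysomesPerCell = 3,
                                  monosomeCount = 5, occupancyP = 0),
                      seed = 11)
  nd2 <- neighbourDistances(sc$particles, mk, "occupancy")
  expect_true(all(nd2$leaderLabel == "1xbS20"))
  expect_true(all(nd2$trailerLabel == "1xbS20"))
  expect_true(all(nd2$distance < mk@distanceCutoff))
})

test_that("confidence band is degenerate for identical cells and covers concordant ones", {
  d <- rep(c(60, 70, 80, 90), 25)
  tab <- data.frame(tomoID = rep(paste0("c", 1:4), each = 100),
                    distance = rep(d, 4))
  breaks <- seq(50, 100, by = 10)
  band <- cellConfidenceBand(tab, breaks)
  expect_equal(band$lower, band$point)
  expect_equal(band$upper, band$point)

  # fewer than 3 cells: warning + degenerate band
  tab2 <- tab[tab$tomoID %in% c("c1", "c2"), ]
  expect_warning(band2 <- cellConfidenceBand(tab2, breaks), "fewer than 3")
  expect_equal(band2$lower, band2$upper)

  # one outlier among 20 concordant cells: band brackets the concordant curve
  set.seed(203)
  cells <- lapply(1:20, function(i) {
    dd <- if (i == 1) rnorm(200, 300, 10) else rnorm(200, 80, 10)
    data.frame(tomoID = paste0("c", i), distance = dd)
  })
  tab3 <- do.call(rbind, cells)
  breaks3 <- seq(0, 500, by = 25)
  band3 <- cellConfidenceBand(tab3, breaks3)
  conc <- cellConfidenceBand(tab3[tab3$tomoID != "c1", ], breaks3)
  expect_true(all(conc$point >= band3$lower - 1e-12 &
                    conc$point <= band3$upper + 1e-12))
})

test_that("confidence bands widen as per-cell sample size decreases", {
  set.seed(204)
  width <- function(nPer) {
    tab <- do.call(rbind, lapply(1:15, function(i)
      data.frame(tomoID = paste0("c", i),
                 distance = rnorm(nPer, 80, 15))))
    b <- cellConfidenceBand(tab, seq(0, 200, by = 20))
    sum(b$upper - b$lower)
  }
  wBig <- mean(replicate(3, width(400)))
  wSmall <- mean(replicate(3, width(25)))
  expect_gt(wSmall, wBig)
})

test_that("stratum comparison: identity, power, and Holm adjustment", {
  tab <- data.frame(tomoID = "c1",
                    leaderLabel = rep(c("1xbS20", "2xbS20"), each = 50),
                    trailerLabel = "1xbS20",
                    distance = rep(seq(60, 109, 1), 2))
  out <- compareStrata(tab)
  expect_equal(out$tests$statistic, 0, tolerance = 1e-12)
  expect_equal(out$tests$p, 1)

  set.seed(205)
  shift <- data.frame(tomoID = "c1",
                      leaderLabel = rep(c("a", "b"), each = 400),
                      trailerLabel = "x",
                      distance = c(rnorm(400, 80, 10), rnorm(400, 140, 10)))
  out2 <- compareStrata(shift)
  expect_lt(out2$tests$p, 1e-3)
  expect_equal(out2$strata$median[order(out2$strata$stratum)],
               sort(c(median(shift$distance[1:400]),
                      median(shift$distance[401:800]))))

  # empty/singleton stratum is reported as not testable, not an error
  tiny <- data.frame(tomoID = "c1", leaderLabel = c("a", "a", "b"),
                     trailerLabel = "x", distance = c(70, 75, 80))
  out3 <- compareStrata(tiny)
  expect_false(out3$tests$testable)
  expect_true(is.na(out3$tests$p))
})

test_that("state distributions: proportions, homogeneity test, degenerate input", {
  set.seed(206)
  n <- 5000
  p <- randomParticleTable(2 * n, box = 50000)
  p$occupancy <- rep(c("1xbS20", "2xbS20"), each = n)
  p$tf <- ifelse(runif(2 * n) < 0.88, "bound", "free")
  ps <- asParticleSet(p, c("occupancy", "tf"))
  out <- stateDistribution(ps, "tf", "occupancy")
  se <- sqrt(0.88 * 0.12 / n)
  expect_lt(abs(out$proportions["1xbS20", "bound"] - 0.88), 3 * se)
  expect_lt(abs(out$proportions["2xbS20", "bound"] - 0.88), 3 * se)
  expect_s3_class(out$test, "htest")

  # identical proportions by construction -> statistic ~ 0
  p2 <- p
  p2$tf <- rep(rep(c("bound", "free"), c(88, 12)), length.out = 2 * n)
  out2 <- stateDistribution(asParticleSet(p2, c("occupancy", "tf")),
                            "tf", "occupancy")
  expect_lt(unname(out2$test$statistic), 1e-20)

  # single-state degenerate table: test skipped with notice
  p3 <- p; p3$tf <- "bound"
  out3 <- stateDistribution(asParticleSet(p3, c("occupancy", "tf")),
                            "tf", "occupancy")
  expect_null(out3$test)
  expect_match(out3$note, "degenerate")
})
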