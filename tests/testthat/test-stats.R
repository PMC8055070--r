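mkSummaries <- function(op, th) {
  data.frame(t = seq_along(op), orderParameter = op, direction = th,
             meanSpeed = 1, label = "other")
}

test_that("direction states partition frames by band and coherence", {
  # caudally heading plane wave (theta = 3*pi/2): anteroposterior
  s <- mkSummaries(rep(0.9, 5), rep(3 * pi / 2, 5))
  ds <- directionStates(s)
  expect_true(all(ds$states$state == "anteroposterior"))
  # incoherent frames are disordered regardless of direction
  s2 <- mkSummaries(rep(0.2, 5), rep(pi / 2, 5))
  expect_true(all(directionStates(s2)$states$state == "disordered"))
  # band edges are open intervals
  s3 <- mkSummaries(rep(0.9, 4), c(pi / 4, 3 * pi / 4, 5 * pi / 4, 7 * pi / 4))
  expect_true(all(directionStates(s3)$states$state == "disordered"))
  # every frame gets exactly one state; episodes tile the series
  s4 <- mkSummaries(c(0.9, 0.9, 0.2, 0.2, 0.9),
                    c(pi / 2, pi / 2, 0, 0, 3 * pi / 2))
  d4 <- directionStates(s4)
  expect_equal(sum(d4$episodes$length), 5)
  expect_equal(d4$episodes$state,
               c("posteroanterior", "disordered", "anteroposterior"))
})

test_that("reversal scenarios count boxed sources/sinks in quarter windows", {
  # scripted series: posteroanterior wave, disordered gap, then an
  # anteroposterior wave (condition p-a, scenario a-a/p-a)
  op <- c(rep(0.9, 8), rep(0.2, 8), rep(0.9, 8))
  th <- c(rep(pi / 2, 8), rep(0, 8), rep(3 * pi / 2, 8))
  states <- directionStates(mkSummaries(op, th))
  H <- 20; W <- 20
  # a rostral source present during the last quarter of the disorder
  pts <- data.frame(t = 15:16, row = 2, col = 10, type = "source",
                    trackId = 1L)
  tab <- reversalScenarios(states, pts, c(H, W))
  hit <- tab[tab$scenario == "a-a/p-a" & tab$box == "rostral" &
               tab$type == "source", ]
  expect_equal(hit$count, 1)
  expect_true(all(tab$count[!(tab$scenario == "a-a/p-a" &
                                tab$box == "rostral" &
                                tab$type == "source")] == 0))
  expect_equal(hit$normalized, 1)
  # caudal sink during the first quarter of the following wave
  pts2 <- data.frame(t = 17:18, row = 19, col = 10, type = "sink",
                     trackId = 2L)
  tab2 <- reversalScenarios(states, pts2, c(H, W))
  hit2 <- tab2[tab2$scenario == "a-a/p-a" & tab2$box == "caudal" &
                 tab2$type == "sink", ]
  expect_equal(hit2$count, 1)
  # outside both windows and boxes: nothing counted
  pts3 <- data.frame(t = 10, row = 10, col = 10, type = "source",
                     trackId = 3L)
  expect_true(all(reversalScenarios(states, pts3, c(H, W))$count == 0))
  # no triples: warning and empty counts
  flat <- directionStates(mkSummaries(rep(0.2, 6), rep(0, 6)))
  expect_warning(reversalScenarios(flat, pts, c(H, W)), "no coherent")
})

test_that("emergence maps count occupancy per pixel and type", {
  pts <- data.frame(t = 1:30, row = 10.2, col = 15.4, type = "source")
  maps <- emergenceProbabilityMap(pts, c(20, 20), totalValidFrames = 300)
  expect_equal(maps$source[10, 15], 0.1)
  expect_equal(sum(maps$source), 0.1)
  expect_equal(sum(maps$sink) + sum(maps$saddle), 0)
  # two types at one pixel are independent layers
  pts2 <- rbind(pts, data.frame(t = 1:15, row = 10.2, col = 15.4,
                                type = "sink"))
  maps2 <- emergenceProbabilityMap(pts2, c(20, 20), 300)
  expect_equal(maps2$source[10, 15], 0.1)
  expect_equal(maps2$sink[10, 15], 0.05)
  # a drifting source spreads mass totalling d / totalValidFrames
  drift <- data.frame(t = 1:30, row = seq(3, 17, length.out = 30),
                      col = 10, type = "source")
  md <- emergenceProbabilityMap(drift, c(20, 20), 300)
  expect_equal(sum(md$source), 30 / 300)
  expect_error(emergenceProbabilityMap(pts, c(20, 20), 0), "totalValidFrames")
})

test_that("regional averaging matches analytic means and pools labels", {
  # checkerboard two-region fixture: analytic means
  rm2 <- matrix(1L, 8, 8); rm2[, 5:8] <- 2L
  m <- matrix(0, 8, 8); m[, 1:4] <- 0.2; m[, 5:8] <- 0.6
  ra <- regionalAverage(m, rm2)
  expect_equal(ra$probability, c(0.2, 0.6))
  # uniform map: every region the same
  ru <- regionalAverage(matrix(0.3, 8, 8), rm2)
  expect_equal(ru$probability, c(0.3, 0.3))
  # hemisphere pooling: same label on both sides is averaged together
  rmp <- matrix(1L, 8, 8); rmp[, 3:6] <- 2L   # label 1 on both flanks
  mp <- matrix(0, 8, 8); mp[, 1:2] <- 0.1; mp[, 7:8] <- 0.3
  rap <- regionalAverage(mp, rmp)
  expect_equal(rap$probability[rap$region == 1], 0.2)
})

test_that("hierarchy correlation handles exact, degenerate and small inputs", {
  tab <- data.frame(region = 1:6, source = seq(0.1, 0.6, 0.1),
                    hierarchyIndex = seq(2, 12, 2))
  hc <- hierarchyCorrelation(tab, "source")
  expect_equal(hc$r, 1)
  expect_lt(hc$p, 1e-6)
  tab$flat <- 0.5
  expect_error(hierarchyCorrelation(tab, "flat"), "zero variance")
  expect_error(hierarchyCorrelation(tab[1:3, ], "source"), "at least 4")
  fx <- generateRegionFixture(c(44, 52), 21, -0.76, seed = 9)
  ra <- regionalAverage(fx$probabilityMap, fx$regionMap, fx$hierarchy)
  hc2 <- hierarchyCorrelation(ra, "probability")
  expect_gt(hc2$r, -0.80)
  expect_lt(hc2$r, -0.72)
})

test_that("permutation null is reproducible and centred for null fixtures", {
  fx <- generateRegionFixture(c(30, 30), 12, 0, seed = 4)
  pn1 <- permutationNull(fx$probabilityMap, fx$regionMap, fx$hierarchy,
                         nPerm = 200, seed = 6)
  pn2 <- permutationNull(fx$probabilityMap, fx$regionMap, fx$hierarchy,
                         nPerm = 200, seed = 6)
  expect_identical(pn1$null, pn2$null)
  # target 0: the observed r sits inside the central 95% band
  expect_gte(pn1$observed, pn1$band95[1])
  expect_lte(pn1$observed, pn1$band95[2])
  expect_warning(permutationNull(fx$probabilityMap, fx$regionMap,
                                 fx$hierarchy, nPerm = 50, seed = 1),
                 "unstable")
})

test_that("null ranks are exchangeable for pre-shuffled maps", {
  # observed map drawn from the null itself (one extra pixel shuffle):
  # its rank within the permutation null must be uniform across seeds
  fx <- generateRegionFixture(c(24, 24), 9, 0, seed = 2)
  ranks <- vapply(1:120, function(s) {
    set.seed(1000 + s)
    shuf <- matrix(sample(as.vector(fx$probabilityMap)), 24, 24)
    pn <- permutationNull(shuf, fx$regionMap, fx$hierarchy, nPerm = 100,
                          seed = s)
    (sum(pn$null < pn$observed) + 0.5) / (length(pn$null) + 1)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ranks, "punif"))
  expect_gt(ks$p.value, 0.01)
})
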