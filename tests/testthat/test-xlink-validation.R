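test_that("endpoints resolve over all copies and mark missing sites unmapped", {
  tm <- tinyModel()
  ep <- resolveEndpoints(tm$model, tm$map, "PROTX", 2, "PROTY", 1)
  expect_true(ep$mapped)
  ## two copies of PROTX -> two candidate sites
  expect_equal(nrow(ep$sites1), 2L)
  expect_equal(nrow(ep$sites2), 1L)
  ## residue absent from the model (unmodelled) -> unmapped
  expect_false(resolveEndpoints(tm$model, tm$map, "PROTX", 99, "PROTY", 1)$mapped)
  ## protein absent from the chain map -> unmapped
  expect_false(resolveEndpoints(tm$model, tm$map, "NOPE", 1, "PROTY", 1)$mapped)
  ## protein matching is case-insensitive and whitespace-stripped
  expect_true(resolveEndpoints(tm$model, tm$map, " protx ", 1, "PROTY", 1)$mapped)
})

test_that("minimum distance equals the brute-force all-copy-pair oracle", {
  set.seed(42)
  for (rep in 1:30) {
    ra <- randomAssembly()
    m <- chainMapTable(ra$map)
    for (k in 1:4) {
      p1 <- sample(unique(m$protein), 1)
      p2 <- sample(unique(m$protein), 1)
      r1 <- sample.int(6, 1); r2 <- sample.int(6, 1)
      got <- minCaDistance(ra$model, ra$map, p1, r1, p2, r2)
      want <- oracleMinDist(ra$model, ra$map, p1, r1, p2, r2)
      expect_equal(got$distance, want, tolerance = 1e-12)
    }
  }
})

test_that("a link between a residue and itself is measured across copies", {
  tm <- tinyModel()
  d <- minCaDistance(tm$model, tm$map, "PROTX", 1, "PROTX", 1)
  ## same chain pairing excluded; the two copies are 20 A apart in y
  expect_equal(d$distance, 20)
  expect_false(d$chain1 == d$chain2)
})

test_that("endpoint order never changes the reported distance", {
  set.seed(11)
  for (rep in 1:10) {
    ra <- randomAssembly()
    m <- chainMapTable(ra$map)
    p1 <- sample(unique(m$protein), 1); p2 <- sample(unique(m$protein), 1)
    r1 <- sample.int(6, 1); r2 <- sample.int(6, 1)
    d12 <- minCaDistance(ra$model, ra$map, p1, r1, p2, r2)$distance
    d21 <- minCaDistance(ra$model, ra$map, p2, r2, p1, r1)$distance
    expect_equal(d12, d21)
  }
})

test_that("classification is strict at the threshold", {
  pol <- thresholdPolicy(threshold = 35)
  expect_equal(classifyDistance(34.99, pol), "satisfied")
  expect_equal(classifyDistance(35.0, pol), "violated")
  expect_equal(classifyDistance(151, pol), "violated")
  expect_equal(classifyDistance(95, pol), "violated")
  expect_error(classifyDistance(-1, pol))
})

test_that("raising the threshold never decreases the satisfied count", {
  set.seed(5)
  d <- runif(200, 0, 80)
  counts <- vapply(seq(5, 75, by = 5), function(th)
    sum(classifyDistance(d, thresholdPolicy(threshold = th)) == "satisfied"),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("flexibility rescue follows the confidence rule and window", {
  tm <- tinyModel()
  pol <- thresholdPolicy(confCutoff = 50, rescueWindow = 0L)
  ## chain A residue 2 has confidence 30 -> rescued, reason names it
  r <- flexibilityRescue(tm$model, "A", 2, "B", 3, pol)
  expect_true(r$rescued)
  expect_match(r$reason, "A:2")
  ## both endpoints confident at window 0 -> not rescued
  r2 <- flexibilityRescue(tm$model, "A", 1, "B", 3, pol)
  expect_false(r2$rescued)
  ## widening the window reaches the flexible neighbour
  r3 <- flexibilityRescue(tm$model, "A", 1, "B", 3,
                          thresholdPolicy(rescueWindow = 1L))
  expect_true(r3$rescued)
})

test_that("validateCrossLinks classifies, rescues and reports unmapped links", {
  tm <- tinyModel()
  xl <- xlinkSet(c("PROTX", "PROTX", "PROTX"), c(1L, 1L, 9L),
                 c("PROTX", "PROTY", "PROTY"), c(2L, 1L, 1L))
  rep <- validateCrossLinks(tm$model, tm$map, xl,
                            thresholdPolicy(threshold = 35))
  expect_equal(rep$status, c("satisfied", "violated", "unmapped"))
  ## violated link: chain C residue 1 has confidence 40 -> rescued
  expect_true(rep$rescued[2])
  expect_true(is.na(rep$distance[3]))
  ## rescue flag only meaningful on violated links
  expect_false(rep$rescued[1])
})

test_that("distance histograms bin mapped links and conserve counts", {
  rep <- data.frame(distance = c(10, 20, 70, NA),
                    status = c("satisfied", "satisfied", "violated",
                               "unmapped"))
  h <- distanceHistogram(rep, binWidth = 25)
  expect_equal(h$count, c(2L, 0L, 1L))
  expect_equal(sum(h$count), sum(rep$status != "unmapped"))
  expect_error(distanceHistogram(rep[4, , drop = FALSE], 25), "no mapped")
  ## recount oracle on the planted two-state benchmark
  g <- twoStateFixture()
  vr <- validateCrossLinks(g$modelB, g$map, g$xlinks)
  h2 <- distanceHistogram(vr, binWidth = 10)
  oracle <- table(cut(g$truth$distB, seq(0, max(h2$upper), by = 10),
                      right = FALSE))
  expect_equal(h2$count, as.integer(oracle))
})

test_that("two-state comparison reports both distances and their change", {
  g <- twoStateFixture()
  cmp <- compareStates(g$modelA, g$modelB, g$map, g$map, g$xlinks)
  expect_equal(nrow(cmp), nrow(g$truth))
  expect_equal(cmp$distanceA, g$truth$distA, tolerance = 1e-9)
  expect_equal(cmp$distanceB, g$truth$distB, tolerance = 1e-9)
  expect_equal(cmp$delta, g$truth$distB - g$truth$distA, tolerance = 1e-9)
  ## identical models give identically zero change
  same <- compareStates(g$modelB, g$modelB, g$map, g$map, g$xlinks)
  expect_true(all(abs(same$delta) < 1e-12))
})
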