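oneAtom <- function(at = c(10, 12, 14)) {
  assemblyModel(data.frame(chain = "A", resno = 1L, resid = "ALA",
                           elety = "CA", element = "C", x = at[1],
                           y = at[2], z = at[3], b = 90))
}

test_that("simulated density peaks at the atom and adds linearly", {
  m <- oneAtom()
  g <- simulateDensity(m, resolution = 10, voxel = 2)
  peak <- which(gridData(g) == max(gridData(g)), arr.ind = TRUE)[1, ]
  peakPos <- gridOrigin(g) + (peak - 1) * voxelSize(g)
  expect_true(all(abs(peakPos - c(10, 12, 14)) <= 1 + 1e-9))
  ## two identical atoms double the integral
  two <- assemblyModel(rbind(atoms(m), within(atoms(m), {
    chain <- "B"; x <- x + 4
  })[names(atoms(m))]))
  g2 <- simulateDensity(two, resolution = 10, voxel = 2, pad = 15)
  g1 <- simulateDensity(m, resolution = 10, voxel = 2, pad = 15)
  expect_equal(sum(gridData(g2)) / sum(gridData(g1)), 2, tolerance = 0.01)
})

test_that("translating a model by one voxel shifts its density by one voxel", {
  m <- oneAtom(c(20, 20, 20))
  vox <- 2
  g1 <- simulateDensity(m, 10, vox, pad = 16)
  a <- atoms(m); a$x <- a$x + vox
  m2 <- assemblyModel(a)
  g2 <- xlinkfit:::.addGaussians(dim(gridData(g1)), gridOrigin(g1), vox,
                                 as.matrix(atoms(m2)[, c("x", "y", "z")]),
                                 10 / (2 * sqrt(2 * log(2))))
  d1 <- gridData(g1)
  n <- dim(d1)[1]
  expect_equal(g2[2:n, , ], d1[1:(n - 1), , ], tolerance = 1e-12)
})

test_that("undersampled simulation requests are refused", {
  expect_error(simulateDensity(oneAtom(), resolution = 3, voxel = 2),
               "resolution")
})

test_that("cross-correlation is 1 on self-fit and 0 on degenerate maps", {
  fc <- generateFitCase(nBodies = 1L, atomsPerBody = 24L, seed = 2L)
  cc <- crossCorrelation(fc$bodies[[1]], fc$posesTrue[[1]], fc$grid, 25)
  expect_gte(cc, 0.99)
  uni <- densityGrid(array(1, dim(gridData(fc$grid))), voxelSize(fc$grid),
                     gridOrigin(fc$grid))
  expect_equal(crossCorrelation(fc$bodies[[1]], fc$posesTrue[[1]], uni, 25), 0)
  ## far outside the grid support
  off <- pose(c(1, 0, 0, 0), gridOrigin(fc$grid) - 500, "b")
  expect_equal(crossCorrelation(fc$bodies[[1]], off, fc$grid, 25), 0)
})

test_that("correlation decays monotonically with translation offset", {
  fc <- generateFitCase(nBodies = 1L, atomsPerBody = 24L, seed = 2L)
  p0 <- fc$posesTrue[[1]]
  offs <- seq(0, 24, by = 4)
  ccs <- vapply(offs, function(o)
    crossCorrelation(fc$bodies[[1]],
                     pose(p0@quat, p0@trans + c(o, 0, 0), "b"),
                     fc$grid, 25), numeric(1))
  expect_true(all(diff(ccs) < 1e-6))
})

test_that("pose and schedule classes enforce their invariants", {
  expect_error(new("Pose", quat = c(1, 1, 0, 0, 0), trans = c(0, 0, 0),
                   body = "x"))
  p <- pose(c(0.5, 0.5, 0.5, 0.5), c(1, 2, 3), "b")
  expect_equal(det(xlinkfit:::quatToMatrix(poseQuat(p))), 1, tolerance = 1e-9)
  s <- annealSchedule()
  st <- scheduleStages(s)
  expect_equal(st$temp, c(75000, 30000, 10000, 5000, 1000, 300))
  expect_equal(st$steps, c(1000L, 800L, 800L, 500L, 500L, 300L))
  expect_error(annealSchedule(c(100, 200), c(10L, 10L)), "decreasing")
  expect_error(annealSchedule(c(200, 100), c(10L, 0L)), "positive")
})

test_that("score breakdown applies the default restraint weights to its terms", {
  w <- defaultWeights()
  expect_equal(unname(w[c("connectivity", "xlink", "discrete", "exvol",
                          "em")]), c(1, 30, 10000, 10, 1000))
  ## a single body on its own map at the generating pose: perfect EM fit,
  ## no restraints -> every term zero
  fc0 <- generateFitCase(nBodies = 1L, atomsPerBody = 20L, seed = 5L)
  sb0 <- scoreConfiguration(fc0$bodies, fc0$posesTrue, fc0$grid, 25)
  expect_lt(totalScore(sb0), 1e-4 * 1000 + 1e-6)
  ## a multi-body planted configuration satisfies all restraint terms; the
  ## EM term stays small but non-zero (neighbouring bodies bleed into each
  ## other's support at this blur), and the total is the weighted term sum
  fc <- generateFitCase(nBodies = 2L, atomsPerBody = 20L, seed = 5L)
  sb <- scoreConfiguration(fc$bodies, fc$posesTrue, fc$grid, 25,
                           fc$xlinks, fc$maps)
  expect_equal(unname(scoreTerms(sb)[c("xlink", "connectivity", "exvol",
                                       "discrete")]), rep(0, 4))
  expect_equal(totalScore(sb),
               sum(scoreTerms(sb) * scoreWeights(sb)), tolerance = 1e-12)
  ## a single cross-link 1 A over threshold contributes weight x 1^2
  b1 <- oneAtom(c(0, 0, 0)); b2 <- oneAtom(c(36, 0, 0))
  a2 <- atoms(b2); a2$chain <- "B"; b2 <- assemblyModel(a2)
  maps <- list(chainMap(data.frame(chain = "A", protein = "P1", copy = 1L,
                                   subcomplex = "other", unit = NA_integer_)),
               chainMap(data.frame(chain = "B", protein = "P2", copy = 1L,
                                   subcomplex = "other", unit = NA_integer_)))
  xl <- xlinkSet("P1", 1L, "P2", 1L)
  idPoses <- list(pose(trans = c(0, 0, 0), body = "P1"),
                  pose(trans = c(36, 0, 0), body = "P2"))
  sb2 <- scoreConfiguration(list(b1, b2), idPoses, grid = NULL,
                            xlinks = xl, maps = maps)
  expect_equal(unname(scoreTerms(sb2)["xlink"]), 1)
  expect_equal(totalScore(sb2), 30)
  ## pose count mismatch is an error
  expect_error(scoreConfiguration(list(b1, b2), idPoses[1]), "one pose per")
})

test_that("the restraint score ignores a global rigid motion when EM is off", {
  fc <- generateFitCase(nBodies = 3L, atomsPerBody = 20L, seed = 6L)
  s0 <- scoreConfiguration(fc$bodies, fc$posesTrue, grid = NULL,
                           xlinks = fc$xlinks, maps = fc$maps)
  ## rotate and translate the whole configuration together
  q <- xlinkfit:::axisAngleQuat(c(1, 2, 3), 40)
  R <- xlinkfit:::quatToMatrix(q)
  shift <- c(12, -7, 5)
  moved <- lapply(fc$posesTrue, function(p)
    pose(xlinkfit:::quatMultiply(q, p@quat), as.numeric(R %*% p@trans) + shift,
         p@body))
  s1 <- scoreConfiguration(fc$bodies, moved, grid = NULL,
                           xlinks = fc$xlinks, maps = fc$maps)
  expect_equal(totalScore(s1), totalScore(s0), tolerance = 1e-6)
})

test_that("connectivity and discrete terms penalise broken restraints", {
  b1 <- oneAtom(c(0, 0, 0)); b2 <- oneAtom(c(30, 0, 0))
  a2 <- atoms(b2); a2$chain <- "B"; b2 <- assemblyModel(a2)
  poses <- list(pose(trans = c(0, 0, 0), body = "b1"),
                pose(trans = c(30, 0, 0), body = "b2"))
  conn <- data.frame(chain1 = "A", resno1 = 1L, chain2 = "B", resno2 = 1L,
                     maxGap = 10)
  sb <- scoreConfiguration(list(b1, b2), poses, connectivity = conn)
  expect_equal(unname(scoreTerms(sb)["connectivity"]), (30 - 10)^2)
  cont <- data.frame(chain1 = "A", chain2 = "B", maxDist = 10)
  sb2 <- scoreConfiguration(list(b1, b2), poses, contacts = cont)
  expect_equal(unname(scoreTerms(sb2)["discrete"]), 1)
  ## satisfied contact: no penalty
  cont$maxDist <- 40
  sb3 <- scoreConfiguration(list(b1, b2), poses, contacts = cont)
  expect_equal(unname(scoreTerms(sb3)["discrete"]), 0)
})

test_that("annealing is reproducible for a fixed seed", {
  fc <- generateFitCase(nBodies = 1L, atomsPerBody = 24L, seed = 3L)
  lib <- buildFitLibrary(fc$bodies[[1]], fc$grid, 25, nPositions = 400L,
                         body = "BODY1")
  sched <- annealSchedule(c(1000, 100), c(30L, 20L))
  r1 <- annealFit(fc$bodies, fc$maps, fc$grid, 25, libraries = list(lib),
                  schedule = sched, seed = 7L)
  r2 <- annealFit(fc$bodies, fc$maps, fc$grid, 25, libraries = list(lib),
                  schedule = sched, seed = 7L)
  expect_identical(r1$trace, r2$trace)
  expect_identical(lapply(r1$poses, poseTrans), lapply(r2$poses, poseTrans))
  ## an empty library is an error
  empty <- new("FitLibrary", poses = data.frame(), body = "BODY1",
               params = list())
  expect_error(annealFit(fc$bodies, fc$maps, fc$grid, 25,
                         libraries = list(empty), schedule = sched),
               "empty fit library")
})

test_that("the score histogram flags separated best-score modes only", {
  set.seed(123)
  gauss <- rnorm(60, 100, 5)
  expect_error(scoreHistogram(gauss[1:10]), "at least 30")
  h1 <- scoreHistogram(gauss)
  expect_equal(h1$verdict, "not converged")
  expect_equal(sum(h1$histogram$count), 60L)
  ## planted low-outlier mode (best 5%) well below the main mass
  bimodal <- c(rnorm(57, 100, 5), rnorm(3, 40, 1))
  h2 <- scoreHistogram(bimodal)
  expect_equal(h2$verdict, "converged")
  ## verdict is invariant under positive rescaling
  h3 <- scoreHistogram(bimodal * 1000)
  expect_equal(h3$verdict, "converged")
  h4 <- scoreHistogram(gauss * 1000)
  expect_equal(h4$verdict, "not converged")
})
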