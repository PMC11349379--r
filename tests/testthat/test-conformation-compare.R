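beadModel <- function(xyz, chain = NULL, resid = "ALA") {
  n <- nrow(xyz)
  if (is.null(chain)) chain <- sprintf("c%d", seq_len(n))
  assemblyModel(data.frame(
    chain = chain, resno = if (length(chain) == n && anyDuplicated(chain))
      stop("unique chains expected") else seq_len(n),
    resid = resid, elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 90,
    stringsAsFactors = FALSE))
}

test_that("an isolated residue has its full reference accessibility", {
  m <- beadModel(matrix(0, 1, 3), chain = "A", resid = "GLY")
  p <- calcSASA(m)
  expect_equal(p$relAcc, 1, tolerance = 1e-9)
  expect_equal(p$sasa, 4 * pi * 4.4^2, tolerance = 1e-9)
})

test_that("a residue enclosed by an atom shell has (near) zero SASA", {
  shell <- xlinkfit:::spherePoints(80) * 6
  m <- beadModel(rbind(c(0, 0, 0), shell))
  p <- calcSASA(m)
  expect_lt(p$sasa[1], 1e-9)
})

test_that("two-sphere SASA loss matches the analytic spherical cap", {
  d <- 5
  m <- beadModel(rbind(c(0, 0, 0), c(d, 0, 0)))
  p <- calcSASA(m, nPoints = 960)
  R <- 3.0 + 1.4
  expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  relErr <- abs(p$sasa - expected) / expected
  expect_lt(max(relErr), 0.02)
})

test_that("SASA is deterministic and stable under sphere-point doubling", {
  g <- twoStateFixture(nUnits = 1L)
  p1 <- calcSASA(g$modelB)
  p2 <- calcSASA(g$modelB)
  expect_identical(p1, p2)
  p3 <- calcSASA(g$modelB, nPoints = 1920L)
  ## per-residue change under doubling, relative to the bead reference area
  ref <- 4 * pi * 4.4^2
  expect_lt(max(abs(p1$sasa - p3$sasa)) / ref, 0.03)
})

test_that("zero-atom models are rejected", {
  empty <- assemblyModel(data.frame(
    chain = character(), resno = integer(), resid = character(),
    elety = character(), element = character(), x = numeric(),
    y = numeric(), z = numeric(), b = numeric()))
  expect_error(calcSASA(empty), "no atoms")
})

test_that("identical profiles give an empty burial differential", {
  g <- twoStateFixture(nUnits = 1L)
  p <- calcSASA(g$modelB)
  bd <- burialDifferential(p, p, g$map, g$map)
  expect_equal(nrow(bd$accessibleAburiedB), 0L)
  expect_equal(nrow(bd$accessibleBburiedA), 0L)
})

test_that("the burial differential is antisymmetric under state swap", {
  g <- twoStateFixture(nUnits = 1L)
  pA <- calcSASA(g$modelA)
  pB <- calcSASA(g$modelB)
  bd1 <- burialDifferential(pA, pB, g$map, g$map)
  bd2 <- burialDifferential(pB, pA, g$map, g$map)
  key <- function(df) sort(paste(df$protein, df$copy, df$resno))
  expect_identical(key(bd1$accessibleAburiedB), key(bd2$accessibleBburiedA))
  expect_identical(key(bd1$accessibleBburiedA), key(bd2$accessibleAburiedB))
  ## and the two sets of one comparison are disjoint
  expect_length(intersect(key(bd1$accessibleAburiedB),
                          key(bd1$accessibleBburiedA)), 0L)
})

test_that("unmatched profiles are an error", {
  g <- twoStateFixture(nUnits = 1L)
  p <- calcSASA(g$modelB)
  q <- p; q$resno <- q$resno + 1000L
  expect_error(burialDifferential(p, q, g$map, g$map), "no residues matched")
})

test_that("patch clustering equals connected components on the distance graph", {
  near <- beadModel(rbind(c(0, 0, 0), c(4, 0, 0)))
  res <- data.frame(chain = c("c1", "c2"), resno = 1:2)
  out <- patchCluster(res, near, cutoff = 6)
  expect_equal(length(unique(out$patch)), 1L)
  far <- beadModel(rbind(c(0, 0, 0), c(40, 0, 0)))
  out2 <- patchCluster(res, far, cutoff = 6)
  expect_equal(length(unique(out2$patch)), 2L)
  ## randomized agreement with a plain connected-components oracle
  set.seed(31)
  for (rep in 1:5) {
    xyz <- matrix(runif(30, 0, 25), ncol = 3)
    m <- beadModel(xyz)
    rs <- data.frame(chain = sprintf("c%d", 1:10), resno = 1:10)
    got <- patchCluster(rs, m, cutoff = 7)
    gotAligned <- got$patch[match(rs$chain, got$chain)]
    wantAligned <- oracleComponents(rs, m, cutoff = 7)
    ## same partition up to relabelling: identical co-membership relation
    sameGot <- outer(gotAligned, gotAligned, "==")
    sameWant <- outer(wantAligned, wantAligned, "==")
    expect_identical(sameGot, sameWant)
  }
})

test_that("patches are numbered in decreasing size", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(100, 0, 0))
  m <- beadModel(xyz)
  rs <- data.frame(chain = sprintf("c%d", 1:4), resno = 1:4)
  out <- patchCluster(rs, m, cutoff = 6)
  expect_equal(sum(out$patch == 1), 3L)
  expect_equal(sum(out$patch == 2), 1L)
})

test_that("the repeating-unit contact graph matches the lattice", {
  g <- twoStateFixture()
  cg <- contactGraph(g$modelB, g$map, cutoff = 8)
  ## extended lattice: the central unit touches four neighbours
  expect_equal(cg$degrees$degree[cg$degrees$unit == 3], 4)
  expect_true(isSymmetric(cg$adjacency * 1))
  ## degree is monotone non-decreasing in the cutoff
  cg2 <- contactGraph(g$modelB, g$map, cutoff = 16)
  expect_true(all(cg2$degrees$degree >= cg$degrees$degree))
  ## brute-force all-pairs oracle for the adjacency
  a <- atoms(g$modelB)
  m <- chainMapTable(g$map)
  unit <- m$unit[match(a$chain, m$chain)]
  for (i in 1:4) for (j in (i + 1):5) {
    Xi <- as.matrix(a[unit == i, c("x", "y", "z")])
    Xj <- as.matrix(a[unit == j, c("x", "y", "z")])
    dmin <- sqrt(min(outer(rowSums(Xi^2), rowSums(Xj^2), "+") -
                       2 * Xi %*% t(Xj)))
    expect_equal(unname(cg$adjacency[i, j]), dmin < 8)
  }
})

test_that("two distant units yield an empty contact graph degree", {
  g <- twoStateFixture()
  ## single unit: no pairs at all
  m1 <- chainMapTable(g$map)
  one <- m1[m1$unit == 1, ]
  a <- atoms(g$modelB)
  sub <- assemblyModel(a[a$chain %in% one$chain, ])
  cg <- contactGraph(sub, chainMap(one), cutoff = 8)
  expect_equal(nrow(cg$degrees), 0L)
})

test_that("train metrics report stoichiometry and repeat geometry", {
  g <- twoStateFixture()
  tm <- trainMetrics(g$modelB, g$map)
  ## one IFTA complex and two IFTB complexes per repeating unit
  expect_equal(tm$stoichiometry, 2.0)
  expect_equal(tm$nUnits, 5L)
  ## extended-state unit spacing equals the configured lattice constant
  expect_equal(tm$unitSpacing, 450 / 2, tolerance = 0.01)
  tmA <- trainMetrics(g$modelA, g$map)
  ## compact state: much shorter repeat than the extended state
  expect_lt(tmA$unitSpacing, 0.6 * tm$unitSpacing)
  ## a single unit reports its own axial extent
  m1 <- chainMapTable(g$map)
  one <- m1[m1$unit == 1, ]
  a <- atoms(g$modelB)
  sub <- assemblyModel(a[a$chain %in% one$chain, ])
  t1 <- trainMetrics(sub, chainMap(one))
  expect_equal(t1$nUnits, 1L)
  expect_equal(t1$lengthPerUnit, t1$axialExtent)
  expect_error(trainMetrics(sub, chainMap(data.frame(
    chain = one$chain, protein = one$protein, copy = one$copy,
    subcomplex = "other", unit = one$unit))), "subcomplex")
})
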