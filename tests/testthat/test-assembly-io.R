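test_that("a minimal single-chain PDB parses to the expected model", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 12.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  CA  GLY A   2       5.000   1.000   0.000  1.00 88.00           C",
    "ATOM      4  CA  SER A   3       9.000   2.000   0.000  1.00 50.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- readStructure(f)
  expect_s4_class(m, "AssemblyModel")
  expect_equal(length(chainIds(m)), 1L)
  conf <- residueConfidence(m)
  expect_equal(nrow(conf), 3L)
  expect_equal(conf$resno, 1:3)
  ## B-factor column is carried through as per-residue confidence
  expect_equal(conf$confidence, c(12, 88, 50))
})

test_that("mmCIF round-trips preserve coordinates and numbering", {
  g <- twoStateFixture()
  f <- withr::local_tempfile(fileext = ".cif")
  writeStructure(g$modelB, f)
  m2 <- readStructure(f)
  a1 <- atoms(g$modelB); a2 <- atoms(m2)
  expect_equal(nrow(a2), nrow(a1))
  expect_lt(max(abs(as.matrix(a2[, c("x", "y", "z")]) -
                      as.matrix(a1[, c("x", "y", "z")]))), 1e-3)
  expect_identical(a2$resno, a1$resno)
  expect_identical(a2$chain, a1$chain)
  expect_equal(a2$b, a1$b, tolerance = 1e-6)
})

test_that("multi-model PDB files fall back to the first model with a warning", {
  pdb <- c("MODEL     1",
           "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
           "ENDMDL",
           "MODEL     2",
           "ATOM      1  CA  ALA A   1       9.000   0.000   0.000  1.00 10.00           C",
           "ENDMDL",
           "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_warning(m <- readStructure(f), "first model")
  expect_equal(atoms(m)$x[1], 0)
})

test_that("unreadable structure files raise a format error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(readStructure(f))
  expect_error(readStructure("no/such/file.cif"), "not found")
})

test_that("cross-link CSVs parse with class derivation and row filtering", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2,Residue2,Score,Decoy",
               "IFT139,720,IFT88,667,12.5,false",
               "IFT52,28,IFT52,270,9.1,false",
               "IFT172,1342,IFT172,1741,8.0,true",
               "IFT80,xx,IFT70,12,5.0,false"), f)
  expect_warning(xl <- readCrossLinks(f), "rejected 1")
  l <- linkTable(xl)
  ## decoy row dropped, unparseable row rejected
  expect_equal(nrow(l), 2L)
  expect_equal(l$class, c("heteromeric", "self"))
  expect_equal(l$residue1, c(720L, 28L))
})

test_that("an empty cross-link file with a header yields an empty set", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("Protein1,Residue1,Protein2,Residue2", f)
  xl <- readCrossLinks(f)
  expect_equal(length(xl), 0L)
})

test_that("a missing required cross-link column is a schema error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Protein1,Residue1,Protein2", "A,1,B"), f)
  expect_error(readCrossLinks(f), "residue2")
})

test_that("MRC density maps round-trip through write/read", {
  set.seed(7)
  g <- densityGrid(array(rnorm(8 * 8 * 8), c(8, 8, 8)), 4, c(-3, 2, 11))
  f <- withr::local_tempfile(fileext = ".mrc")
  writeDensity(g, f)
  g2 <- readDensity(f)
  expect_equal(dim(gridData(g2)), c(8L, 8L, 8L))
  expect_equal(voxelSize(g2), 4)
  expect_equal(gridOrigin(g2), c(-3, 2, 11), tolerance = 1e-6)
  ## float32 storage: agreement to single precision
  expect_lt(max(abs(gridData(g2) - gridData(g))), 1e-5)
})

test_that("corrupt MRC headers are rejected", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(255, 2048)), f)
  expect_error(readDensity(f), "corrupt|unsupported")
})

test_that("pseudobond output lists one coloured atom pair per mapped link", {
  rep <- data.frame(chain1 = c("A", "B"), residue1 = c(10L, 20L),
                    chain2 = c("C", "D"), residue2 = c(30L, 40L),
                    status = c("satisfied", "violated"),
                    rescued = c(FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".pb")
  writePseudobonds(rep, f)
  lines <- grep("^;", readLines(f), invert = TRUE, value = TRUE)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "/A:10@CA /C:30@CA green")
  expect_match(lines[2], "purple")
  ## unmapped links are skipped
  rep$status <- "unmapped"
  writePseudobonds(rep, f)
  expect_equal(length(grep("^;", readLines(f), invert = TRUE)), 0L)
})

test_that("an empty report writes a header-only TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReport(data.frame(id = integer(), distance = numeric()), f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("chain maps round-trip through YAML and reject unmapped chains", {
  g <- twoStateFixture()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeChainMap(g$map, f)
  m2 <- readChainMap(f)
  expect_identical(chainMapTable(m2), chainMapTable(g$map))
  ## a map that misses chains must be refused before any downstream stage
  short <- chainMap(chainMapTable(g$map)[-1, ])
  expect_error(validateChainMap(short, g$modelB), "a1u1")
  expect_error(validateCrossLinks(g$modelB, short, g$xlinks), "a1u1")
})
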