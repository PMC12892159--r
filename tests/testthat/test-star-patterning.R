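test_that("axis estimation recovers the row orientation", {
  line <- data.frame(cell_id = 1:10, cell_type = "OHC", row_index = 2L,
                     x = seq(0, 9), y = 0)
  m <- Mosaic(line)
  expect_equal(estimateAxis(m, 2L), 0)

  th <- 30 * pi / 180
  rot <- line
  rot$x <- line$x * cos(th)
  rot$y <- line$x * sin(th)
  expect_equal(estimateAxis(Mosaic(rot), 2L), 30, tolerance = 1e-9)

  jm <- generateLattice(generatorConfig(cellsPerRow = 100L,
                                        jitterSD = 0.05 * 8, seed = 5L))
  ax <- estimateAxis(jm, 2L)
  expect_lt(min(ax, 180 - ax), 2)

  expect_error(estimateAxis(Mosaic(line[1, ], length = 1), 2L), ">= 2 cells")
})

test_that("k-nearest search matches lattice geometry and the id tie-break", {
  dc <- 8
  m <- latticeMosaic(cellsPerRow = 9, nRows = 3, dc = dc)
  df <- cells(m)
  focal <- df[df$row_index == 2L & abs(df$x - 4.5 * dc) < 1e-9, ]
  ids <- findKNearest(focal, df[df$cell_id != focal$cell_id, ], 6L)
  d <- sqrt((df$x[ids] - focal$x)^2 + (df$y[ids] - focal$y)^2)
  expect_equal(d, rep(dc, 6), tolerance = 1e-12)

  # square lattice: 4 axial neighbors at d, then a 4-way tie at d*sqrt(2)
  # resolved toward the smallest cell ids
  sq <- expand.grid(x = 0:4, y = 0:4)
  sq$cell_id <- seq_len(nrow(sq))
  foc <- sq[sq$x == 2 & sq$y == 2, ]
  cand <- sq[sq$cell_id != foc$cell_id, ]
  got <- findKNearest(foc, cand, 6L)
  axial <- sq$cell_id[(abs(sq$x - 2) + abs(sq$y - 2)) == 1]
  diag4 <- sort(sq$cell_id[abs(sq$x - 2) == 1 & abs(sq$y - 2) == 1])
  expect_setequal(got[1:4], axial)
  expect_equal(sort(got[5:6]), diag4[1:2])

  allIds <- findKNearest(foc, cand, nrow(cand))
  dAll <- sqrt((sq$x[allIds] - foc$x)^2 + (sq$y[allIds] - foc$y)^2)
  expect_equal(dAll, sort(dAll))
  expect_setequal(allIds, cand$cell_id)

  expect_error(findKNearest(foc, cand[1:3, ], 6L), "candidate")
  expect_error(findKNearest(foc, sq, 6L), "exclude the focal")
})

test_that("nearest-neighbor search matches the brute-force oracle on random point sets", {
  nSets <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    for (rep in 1:40) {
      n <- sample(10:100, 1)
      pts <- data.frame(cell_id = sample(n) * 3L,  # non-contiguous ids
                        x = round(runif(n, 0, 50), 2),
                        y = round(runif(n, 0, 50), 2))
      focal <- pts[sample(n, 1), ]
      cand <- pts[pts$cell_id != focal$cell_id, ]
      k <- sample(seq_len(min(8, nrow(cand))), 1)
      expect_identical(findKNearest(focal, cand, k),
                       oracleKNearest(focal, cand, k))
      nSets <- nSets + 1L
    }
  }
  expect_gte(nSets, 200L)
})

test_that("arm angles are measured counter-clockwise from the reference axis", {
  f <- list(x = 2, y = 3)
  expect_equal(armAngles(f, data.frame(x = 3, y = 3), axis = 0), 0)
  expect_equal(armAngles(f, data.frame(x = 2, y = 4), axis = 0), 90)
  expect_equal(armAngles(f, data.frame(x = 3, y = 3), axis = 90), 270)
  expect_equal(armAngles(f, data.frame(x = c(3, 2), y = c(3, 4)), axis = 0),
               c(0, 90))
  expect_error(armAngles(f, data.frame(x = 2, y = 3)), "degenerate")
})

test_that("angles bin into half-open sectors of equal arc", {
  expect_identical(binToSectors(0), 1L)
  expect_identical(binToSectors(22.5), 2L)
  expect_identical(binToSectors(359.9), 16L)
  expect_identical(binToSectors(c(0, 60, 120, 180, 240, 300)),
                   c(1L, 3L, 6L, 9L, 11L, 14L))
  expect_identical(binToSectors(c(0, 90, 180, 270), nSectors = 4L),
                   1:4)
  expect_error(binToSectors(360), "\\[0, 360\\)")
  expect_error(binToSectors(-0.1), "\\[0, 360\\)")
})

test_that("the perfect lattice concentrates arms in six sectors at 1/6", {
  m <- latticeMosaic(cellsPerRow = 15)
  p <- computeProfile(m, interiorStarConfig())
  expect_identical(which(sectorCounts(p) > 0L), c(1L, 3L, 6L, 9L, 11L, 14L))
  expect_equal(sectorFrequencies(p)[c(1, 3, 6, 9, 11, 14)], rep(1 / 6, 6),
               tolerance = 1e-12)
  expect_identical(sum(sectorCounts(p)), 6L * nFocal(p))
})

test_that("profiles are invariant under translation and rotate with the frame", {
  m <- generateSamples("control", 1, seed = 31L)[[1]]
  cfg <- starConfig(axisMode = "given", givenAxisAngle = 0)
  p0 <- computeProfile(m, cfg)

  pT <- computeProfile(translateMosaic(m, 500, 500), cfg)
  expect_identical(sectorCounts(pT), sectorCounts(p0))

  cfg37 <- starConfig(axisMode = "given", givenAxisAngle = 37)
  pR <- computeProfile(rotateMosaic(m, 37), cfg37)
  expect_identical(sectorCounts(pR), sectorCounts(p0))

  # estimated axis is translation-invariant too
  pE0 <- computeProfile(m)
  pET <- computeProfile(translateMosaic(m, -120, 42))
  expect_identical(sectorCounts(pET), sectorCounts(pE0))
})

test_that("arm counts and frequencies are conserved across random mosaics", {
  for (s in 1:50) {
    set.seed(s)
    cfg <- generatorConfig(cellsPerRow = sample(15:30, 1),
                           nRows = sample(3:4, 1),
                           jitterSD = runif(1, 0, 0.3) * 8,
                           missingRate = runif(1, 0, 0.1),
                           ectopicRate = runif(1, 0, 0.2), seed = s)
    p <- computeProfile(generateLattice(cfg))
    expect_identical(sum(sectorCounts(p)), 6L * nFocal(p))
    expect_lt(abs(sum(sectorFrequencies(p)) - 1), 1e-12)
  }
})

test_that("too few focal cells is reported with the counts found", {
  m <- latticeMosaic(cellsPerRow = 4)
  expect_error(computeProfile(m, starConfig()), "4 eligible.*10 required")
})

test_that("group aggregation averages per-sample frequency vectors", {
  e1 <- c(1, rep(0, 15))
  e2 <- c(0, 1, rep(0, 14))
  p1 <- makeProfile(e1)
  p2 <- makeProfile(e2)
  expect_equal(aggregateGroup(list(p1)), e1)
  expect_equal(aggregateGroup(list(p1, p1)), e1)
  expect_equal(aggregateGroup(list(p1, p2)), c(0.5, 0.5, rep(0, 14)))
  expect_error(aggregateGroup(list()), "empty")
})
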