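randomProfiles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- runif(16, 0.2, 1)
    makeProfile(f / sum(f), sampleId = paste0("s", i))
  })
}

test_that("identical groups give t = 0 and p = 1 in every sector", {
  g1 <- randomProfiles(3, seed = 1)
  res <- sectorTTest(g1, g1)
  expect_false(any(res$degenerate))
  expect_equal(res$t_stat, rep(0, 16), tolerance = 1e-12)
  expect_equal(res$p_raw, rep(1, 16), tolerance = 1e-12)
  expect_equal(res$p_bh, rep(1, 16), tolerance = 1e-12)
  expect_true(all(res$label == ""))
})

test_that("the sector t statistic equals the textbook pooled-variance t", {
  x <- c(0.10, 0.12, 0.11)
  y <- c(0.20, 0.22, 0.21)
  mk <- function(v3, s) makeProfile(c(v3, rep((1 - v3) / 15, 15)),
                                    sampleId = s)
  g1 <- Map(mk, x, paste0("a", 1:3))
  g2 <- Map(mk, y, paste0("b", 1:3))
  res <- sectorTTest(g1, g2)
  expect_equal(res$t_stat[1], oracleStudentT(x, y), tolerance = 1e-12)
  expect_equal(res$t_stat[1], -12.24744871391589, tolerance = 1e-9)
  expect_equal(res$p_raw[1],
               2 * pt(-abs(oracleStudentT(x, y)), df = 4), tolerance = 1e-12)
})

test_that("swapping the groups negates t and preserves p", {
  g1 <- randomProfiles(4, seed = 10)
  g2 <- randomProfiles(3, seed = 20)
  a <- sectorTTest(g1, g2)
  b <- sectorTTest(g2, g1)
  expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  expect_equal(a$p_bh, b$p_bh, tolerance = 1e-12)
})

test_that("BH adjustment never undercuts the raw p", {
  g1 <- randomProfiles(3, seed = 4)
  g2 <- randomProfiles(3, seed = 5)
  res <- sectorTTest(g1, g2)
  ok <- !is.na(res$p_raw)
  expect_true(all(res$p_bh[ok] >= res$p_raw[ok] - 1e-12))
})

test_that("zero-variance sectors are flagged degenerate and unlabeled", {
  f <- c(0.5, 0.5, rep(0, 14))
  g1 <- lapply(1:3, function(i) makeProfile(f, sampleId = paste0("a", i)))
  g2 <- lapply(1:3, function(i) makeProfile(f, sampleId = paste0("b", i)))
  res <- sectorTTest(g1, g2)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$t_stat)))
  expect_true(all(res$label == ""))
})

test_that("Welch and Student flavors disagree only under unequal variance", {
  mkv <- function(v3, s) makeProfile(c(v3, rep((1 - v3) / 15, 15)),
                                     sampleId = s)
  g1 <- Map(mkv, c(0.10, 0.20, 0.15), paste0("a", 1:3))
  g2 <- Map(mkv, c(0.30, 0.31, 0.32), paste0("b", 1:3))
  st <- sectorTTest(g1, g2, welch = FALSE)
  we <- sectorTTest(g1, g2, welch = TRUE)
  expect_equal(st$t_stat[1], we$t_stat[1], tolerance = 1e-9)  # same center
  expect_false(isTRUE(all.equal(st$p_raw[1], we$p_raw[1])))   # different df
})

test_that("entropy summarizes profile disorder in bits", {
  one <- disorderSummary(makeProfile(c(1, rep(0, 15))))
  expect_equal(one$entropy, 0)
  expect_equal(one$occupied_sectors, 1L)

  uni <- disorderSummary(makeProfile(rep(1 / 16, 16)))
  expect_equal(uni$entropy, 4)
  expect_equal(uni$occupied_sectors, 16L)

  hexFreq <- rep(0, 16)
  hexFreq[c(1, 3, 6, 9, 11, 14)] <- 1 / 6
  hex <- disorderSummary(makeProfile(hexFreq, nFocal = 12L))
  expect_equal(hex$entropy, log2(6), tolerance = 1e-12)
  expect_equal(hex$occupied_sectors, 6L)
})

test_that("mean entropy separates the ordered and disordered presets", {
  ent <- function(preset, seed) {
    m <- generateSamples(preset, 1, seed = seed)[[1]]
    disorderSummary(computeProfile(m))$entropy
  }
  d <- vapply(1:10, function(s) ent("etv_tko", s) - ent("control", s),
              numeric(1))
  expect_gt(mean(d), 0)
  expect_true(all(d > 0))
})

test_that("the end-to-end comparison reports all tables and surfaces stage errors", {
  ctrl <- generateSamples("control", 3, seed = 100L)
  tko <- generateSamples("etv_tko", 3, seed = 200L)
  rpt <- runExperimentComparison(ctrl, tko)
  expect_named(rpt, c("profiles", "radar", "sector_tests", "disorder",
                      "density_records", "density_comparison", "config"))
  expect_equal(nrow(rpt$sector_tests), 16L)
  expect_equal(nrow(rpt$radar), 32L)
  expect_equal(sum(rpt$radar$mean_frequency), 2, tolerance = 1e-9)
  expect_equal(nrow(rpt$disorder), 6L)
  expect_null(rpt$density_comparison)  # single region: no two-way design

  expect_error(runExperimentComparison(ctrl[1], tko[1]), ">= 2 samples")

  short <- generateSamples("control", 1, seed = 1L, cellsPerRow = 4L)
  expect_error(runExperimentComparison(c(ctrl[1:2], short), tko),
               "\\[profile\\].*eligible")
})
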