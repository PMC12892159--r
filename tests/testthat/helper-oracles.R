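# Shared fixtures and independent oracles, all built in code.

DC <- 8  # default within-row spacing used across tests (um)

latticeMosaic <- function(cellsPerRow = 15, nRows = 3, dc = DC, ...) {
  generateLattice(generatorConfig(nRows = nRows, cellsPerRow = cellsPerRow,
                                  colSpacing = dc, jitterSD = 0, ...))
}

# Star configuration that isolates interior second-row cells of a lattice:
# fixed longitudinal axis and a bounding-box margin that trims the first and
# last columns (margin < d_r so the focal row itself survives the y-trim).
interiorStarConfig <- function(dc = DC, ...) {
  starConfig(axisMode = "given", givenAxisAngle = 0,
             edgePolicy = "exclude_margin", margin = 0.6 * dc, ...)
}

rotateMosaic <- function(m, thetaDeg) {
  th <- thetaDeg * pi / 180
  df <- cells(m)
  x <- df$x * cos(th) - df$y * sin(th)
  y <- df$x * sin(th) + df$y * cos(th)
  df$x <- x
  df$y <- y
  suppressWarnings(Mosaic(df, sampleId = sampleId(m), genotype = genotype(m),
                          region = region(m), length = epitheliumLength(m)))
}

translateMosaic <- function(m, dx, dy) {
  df <- cells(m)
  df$x <- df$x + dx
  df$y <- df$y + dy
  suppressWarnings(Mosaic(df, sampleId = sampleId(m), genotype = genotype(m),
                          region = region(m), length = epitheliumLength(m)))
}

# Fabricate a SectorProfile with a prescribed frequency vector.
makeProfile <- function(freqs, sampleId = "s", genotype = "g",
                        region = "base", nFocal = 10L) {
  counts <- as.integer(round(freqs * 6L * nFocal))
  new("SectorProfile", sampleId = sampleId, genotype = genotype,
      region = region, counts = counts, frequencies = freqs,
      nFocal = as.integer(nFocal))
}

# Independent k-nearest oracle: repeated explicit minimum extraction with an
# id tie-break, one neighbor at a time.
oracleKNearest <- function(focal, candidates, k) {
  rem <- candidates
  out <- integer(0)
  for (i in seq_len(k)) {
    d <- sqrt((rem$x - focal$x)^2 + (rem$y - focal$y)^2)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(rem$cell_id[best])]
    out <- c(out, rem$cell_id[best])
    rem <- rem[-best, , drop = FALSE]
  }
  out
}

# Textbook balanced two-way ANOVA by explicit sums of squares.
# df: columns A, B (factors) and y; design must be balanced with r >= 2.
oracleTwoWay <- function(df) {
  A <- factor(df$A)
  B <- factor(df$B)
  y <- df$y
  gm <- mean(y)
  am <- tapply(y, A, mean)
  bm <- tapply(y, B, mean)
  cm <- tapply(y, list(A, B), mean)
  nA <- nlevels(A)
  nB <- nlevels(B)
  r <- length(y) / (nA * nB)
  ssA <- nB * r * sum((am - gm)^2)
  ssB <- nA * r * sum((bm - gm)^2)
  ssAB <- r * sum((cm - outer(am, bm, "+") + gm)^2)
  ssE <- sum((y - cm[cbind(A, B)])^2)
  dfA <- nA - 1L
  dfB <- nB - 1L
  dfAB <- dfA * dfB
  dfE <- length(y) - nA * nB
  list(F = c(A = (ssA / dfA) / (ssE / dfE),
             B = (ssB / dfB) / (ssE / dfE),
             AB = (ssAB / dfAB) / (ssE / dfE)),
       ss = c(A = ssA, B = ssB, AB = ssAB, E = ssE))
}

# Pooled-variance two-sample t, written out from the textbook formula.
oracleStudentT <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
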