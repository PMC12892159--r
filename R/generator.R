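#' Create a generator configuration
#'
#' Default spacings are placeholders chosen for a plausible embryonic (E18)
#' mouse organ of Corti field: the literature does not pin down inter-OHC
#' spacing at this stage, so `colSpacing = 8` um is a documented placeholder
#' and both spacings are user-settable. The default `rowSpacing` of
#' `colSpacing * sqrt(3)/2` makes the noiseless offset lattice hexagonal, so
#' interior cells have six neighbors all at distance `colSpacing` -- the
#' idealized "regular lattice" of a control cochlea.
#'
#' @param nRows number of cell rows (default 3 OHC rows).
#' @param cellsPerRow cells per row (>= 2).
#' @param colSpacing within-row spacing d_c (um).
#' @param rowSpacing between-row spacing d_r (um).
#' @param rowOffsetFraction fraction of d_c by which odd rows are shifted.
#' @param jitterSD isotropic Gaussian positional noise sd (um).
#' @param missingRate per-site probability of cell absence, in [0,1].
#' @param ectopicRate per-column probability of an ectopic cell between row 1
#'   and the pillar-cell position, in [0,1].
#' @param seed integer RNG seed.
#' @param genotypeLabel,regionLabel sample annotations.
#' @return a [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(cellsPerRow = 10, jitterSD = 0)
#' generateLattice(cfg)
#' @export
generatorConfig <- function(nRows = 3L, cellsPerRow = 20L,
                            colSpacing = 8, rowSpacing = colSpacing * sqrt(3) / 2,
                            rowOffsetFraction = 0.5, jitterSD = 0,
                            missingRate = 0, ectopicRate = 0, seed = 1L,
                            genotypeLabel = "control", regionLabel = "base") {
  for (v in list(nRows, cellsPerRow, colSpacing, rowSpacing, rowOffsetFraction,
                 jitterSD, missingRate, ectopicRate, seed))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopConfig("all generator parameters must be single finite numbers")
  if (colSpacing <= 0 || rowSpacing <= 0)
    stopConfig("spacings must be > 0 (got colSpacing = %g, rowSpacing = %g)",
               colSpacing, rowSpacing)
  if (cellsPerRow < 2)
    stopConfig("cellsPerRow must be >= 2 (got %d)", as.integer(cellsPerRow))
  new("GeneratorConfig",
      nRows = as.integer(nRows), cellsPerRow = as.integer(cellsPerRow),
      colSpacing = as.numeric(colSpacing), rowSpacing = as.numeric(rowSpacing),
      rowOffsetFraction = as.numeric(rowOffsetFraction),
      jitterSD = as.numeric(jitterSD), missingRate = as.numeric(missingRate),
      ectopicRate = as.numeric(ectopicRate), seed = as.integer(seed),
      genotypeLabel = as.character(genotypeLabel),
      regionLabel = as.character(regionLabel))
}

#' Named generator presets for the two study conditions
#'
#' `"control"` emulates an ordered wild-type mosaic: small positional jitter
#' (0.05 d_c), no missing and no ectopic cells, so nearly all star arms fall
#' in the six lattice sectors. `"etv_tko"` emulates the disordered
#' Etv4/5/1 triple-knockout phenotype: strong jitter (0.25 d_c), 5% missing
#' cells, and ectopic hair cells inserted in the pillar-cell region with
#' probability 0.1 per column (the "partial fourth row").
#'
#' @param preset "control" or "etv_tko".
#' @param seed integer RNG seed.
#' @param regionLabel region annotation (base/mid/apex).
#' @param ... further arguments passed to [generatorConfig()].
#' @return a [GeneratorConfig-class] object.
#' @export
presetConfig <- function(preset = c("control", "etv_tko"), seed = 1L,
                         regionLabel = "base", ...) {
  preset <- match.arg(preset)
  base <- list(seed = seed, regionLabel = regionLabel, ...)
  dc <- if (!is.null(base$colSpacing)) base$colSpacing else 8
  extra <- switch(preset,
    control = list(jitterSD = 0.05 * dc, missingRate = 0, ectopicRate = 0,
                   genotypeLabel = "control"),
    etv_tko = list(jitterSD = 0.25 * dc, missingRate = 0.05, ectopicRate = 0.1,
                   genotypeLabel = "etv_tko"))
  do.call(generatorConfig, c(base[setdiff(names(base), names(extra))], extra))
}

#' Construct a Mosaic from a cell table
#'
#' @param cells data.frame with columns cell_id, cell_type, row_index, x, y
#'   (coordinates in um).
#' @param sampleId,genotype,region sample annotations.
#' @param length epithelium length L in um; defaults to the longitudinal
#'   (x) extent of the cells.
#' @return a [Mosaic-class] object. A warning is raised if the cells extend
#'   beyond `length` (e.g. after strong jitter).
#' @export
Mosaic <- function(cells, sampleId = "sample1", genotype = "unknown",
                   region = "base", length = NULL) {
  cells <- as.data.frame(cells)
  if (is.null(length)) {
    if (!nrow(cells)) stopConfig("length must be given for an empty Mosaic")
    length <- diff(range(cells$x))
    if (length <= 0) length <- 1
  }
  m <- new("Mosaic", cells = cells, sampleId = as.character(sampleId),
           genotype = as.character(genotype), region = as.character(region),
           length = as.numeric(length))
  if (nrow(cells) && diff(range(cells$x)) > m@length + 1e-9)
    warning(sprintf("Mosaic '%s': cell x-extent (%.2f) exceeds epithelium length (%.2f)",
                    m@sampleId, diff(range(cells$x)), m@length), call. = FALSE)
  m
}

#' Generate a synthetic organ-of-Corti mosaic
#'
#' Builds the noiseless offset-row lattice (row i, column j, 0-based:
#' x = j d_c + (i mod 2) * rowOffsetFraction * d_c, y = i d_r, row_index
#' i + 1, cell type "OHC"), then applies, in order and under the
#' configuration seed: random cell loss (each site independently removed with
#' `missingRate`), ectopic insertion (one candidate per column at
#' y = -d_r / 2, each included with `ectopicRate`, cell type "ectopic"), and
#' isotropic Gaussian jitter of sd `jitterSD` on every cell. The epithelium
#' length is fixed at `cellsPerRow * colSpacing` (one spacing of margin past
#' the last column).
#'
#' @param config a [GeneratorConfig-class] object.
#' @return a [Mosaic-class] object.
#' @export
generateLattice <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  dc <- config@colSpacing; dr <- config@rowSpacing
  i <- rep(seq_len(config@nRows) - 1L, each = config@cellsPerRow)
  j <- rep(seq_len(config@cellsPerRow) - 1L, times = config@nRows)
  df <- data.frame(
    cell_id = seq_along(i),
    cell_type = "OHC",
    row_index = i + 1L,
    x = j * dc + (i %% 2L) * config@rowOffsetFraction * dc,
    y = i * dr,
    stringsAsFactors = FALSE)
  L <- config@cellsPerRow * dc

  withSeed(config@seed, {
    if (config@missingRate > 0)
      df <- df[stats::runif(nrow(df)) >= config@missingRate, , drop = FALSE]
    if (config@ectopicRate > 0) {
      take <- stats::runif(config@cellsPerRow) < config@ectopicRate
      if (any(take)) {
        cols <- which(take) - 1L
        ect <- data.frame(
          cell_id = max(df$cell_id, 0L) + seq_along(cols),
          cell_type = "ectopic",
          row_index = 1L,
          x = cols * dc,
          y = -dr / 2,
          stringsAsFactors = FALSE)
        df <- rbind(df, ect)
      }
    }
    if (config@jitterSD > 0) {
      df$x <- df$x + stats::rnorm(nrow(df), sd = config@jitterSD)
      df$y <- df$y + stats::rnorm(nrow(df), sd = config@jitterSD)
    }
  })
  rownames(df) <- NULL
  suppressWarnings(Mosaic(df,
         sampleId = sprintf("%s_%s_s%d", config@genotypeLabel,
                            config@regionLabel, config@seed),
         genotype = config@genotypeLabel, region = config@regionLabel,
         length = L))
}

#' Displace every cell by isotropic Gaussian noise
#'
#' Ids, labels and the epithelium length are unchanged; `sd = 0` returns the
#' mosaic unmodified. With the same (mosaic, sd, seed) the output is
#' bit-identical across calls.
#'
#' @param mosaic a [Mosaic-class] object.
#' @param sd per-axis displacement standard deviation (um), >= 0.
#' @param seed integer RNG seed.
#' @return the jittered [Mosaic-class].
#' @export
addJitter <- function(mosaic, sd, seed = 1L) {
  stopifnot(is(mosaic, "Mosaic"))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stopConfig("jitter sd must be a single finite value >= 0 (got %s)",
               format(sd))
  if (sd == 0) return(mosaic)
  df <- mosaic@cells
  withSeed(seed, {
    df$x <- df$x + stats::rnorm(nrow(df), sd = sd)
    df$y <- df$y + stats::rnorm(nrow(df), sd = sd)
  })
  out <- mosaic
  out@cells <- df
  out
}

#' Insert ectopic cells in the pillar-cell region
#'
#' One candidate site per row-1 cell, displaced medially (toward the
#' pillar-cell position) by half the row spacing; each candidate is included
#' independently with probability `rate` and added as cell type "ectopic"
#' with row_index 1. Existing cells are untouched. The row spacing is taken
#' from the mean separation of adjacent row levels, falling back to
#' sqrt(3)/2 times the median within-row spacing for a single-row mosaic.
#'
#' @param mosaic a [Mosaic-class] object.
#' @param rate inclusion probability in [0,1].
#' @param seed integer RNG seed.
#' @return the augmented [Mosaic-class].
#' @export
insertEctopic <- function(mosaic, rate, seed = 1L) {
  stopifnot(is(mosaic, "Mosaic"))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0 || rate > 1)
    stopConfig("ectopic rate must lie in [0, 1] (got %s)", format(rate))
  if (rate == 0) return(mosaic)
  df <- mosaic@cells
  host <- df[df$cell_type != "ectopic", , drop = FALSE]
  row1 <- host[host$row_index == 1L, , drop = FALSE]
  if (!nrow(row1)) stopData("no row-1 cells to anchor ectopic insertion")
  rowY <- vapply(split(host$y, host$row_index), mean, numeric(1))
  dr <- if (length(rowY) >= 2L) mean(diff(sort(rowY)))
        else sqrt(3) / 2 * stats::median(diff(sort(row1$x)))
  cand <- data.frame(x = row1$x, y = row1$y - dr / 2)
  withSeed(seed, {
    take <- stats::runif(nrow(cand)) < rate
  })
  if (any(take)) {
    ect <- data.frame(
      cell_id = max(df$cell_id) + seq_len(sum(take)),
      cell_type = "ectopic", row_index = 1L,
      x = cand$x[take], y = cand$y[take], stringsAsFactors = FALSE)
    df <- rbind(df, ect)
    rownames(df) <- NULL
  }
  out <- mosaic
  out@cells <- df
  out
}

#' Generate a set of replicate mosaics from a preset
#'
#' @param preset "control" or "etv_tko" (see [presetConfig()]).
#' @param n number of replicate samples.
#' @param seed master seed; each replicate uses a sub-seed derived from it.
#' @param regionLabel region annotation.
#' @param ... passed to [generatorConfig()].
#' @return a list of [Mosaic-class] objects.
#' @export
generateSamples <- function(preset, n = 3L, seed = 1L, regionLabel = "base",
                            ...) {
  lapply(seq_len(n), function(i) {
    cfg <- presetConfig(preset, seed = deriveSeed(seed, i),
                        regionLabel = regionLabel, ...)
    m <- generateLattice(cfg)
    m@sampleId <- sprintf("%s_%s_%d", preset, regionLabel, i)
    m
  })
}
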