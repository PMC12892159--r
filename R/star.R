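#' Create a star-statistic configuration
#'
#' @param k neighbors per star (default 6).
#' @param nSectors number of equal radial sectors (default 16, i.e. 22.5
#'   degrees of arc per sector, numbered 1..16 counter-clockwise from the
#'   reference axis).
#' @param targetRow focal row index (2 = second-row OHCs; 4 for the fourth
#'   PROX1+ row).
#' @param minFocalCells minimum eligible focal cells per sample (default 10).
#' @param candidateTypes cell types in the neighbor pool; first element is
#'   the focal type.
#' @param axisMode "estimated" (principal axis of the focal row) or "given".
#' @param givenAxisAngle reference axis in degrees when axisMode = "given".
#' @param edgePolicy "include" or "exclude_margin".
#' @param margin bounding-box margin in um for edgePolicy = "exclude_margin".
#' @return a [StarConfig-class] object.
#' @export
starConfig <- function(k = 6L, nSectors = 16L, targetRow = 2L,
                       minFocalCells = 10L, candidateTypes = "OHC",
                       axisMode = c("estimated", "given"),
                       givenAxisAngle = 0, edgePolicy = c("include",
                                                          "exclude_margin"),
                       margin = 0) {
  new("StarConfig",
      k = as.integer(k), nSectors = as.integer(nSectors),
      targetRow = as.integer(targetRow),
      minFocalCells = as.integer(minFocalCells),
      candidateTypes = as.character(candidateTypes),
      axisMode = match.arg(axisMode),
      givenAxisAngle = as.numeric(givenAxisAngle),
      edgePolicy = match.arg(edgePolicy), margin = as.numeric(margin))
}

#' Estimate the longitudinal reference axis of a cell row
#'
#' Returns the orientation, in degrees in [0, 180), of the principal axis
#' (direction of maximal variance) of the target-row cell coordinates. Exactly
#' collinear cells return the orientation of their line. Because an axis is
#' undirected, the result is defined modulo 180 degrees; sector profiles of
#' approximately centro-symmetric mosaics are insensitive to the remaining
#' 180-degree ambiguity (a half-turn maps sector s to s + nSectors/2 and the
#' lattice sector set onto itself).
#'
#' @param mosaic a [Mosaic-class] object.
#' @param targetRow row index whose cells define the axis.
#' @return angle in degrees in [0, 180).
#' @export
estimateAxis <- function(mosaic, targetRow = 2L) {
  stopifnot(is(mosaic, "Mosaic"))
  df <- mosaic@cells
  df <- df[df$row_index == targetRow & df$cell_type != "ectopic", , drop = FALSE]
  if (nrow(df) < 2L)
    stopData("axis estimation needs >= 2 cells in row %d (found %d)",
             targetRow, nrow(df))
  xy <- cbind(df$x, df$y)
  xy <- sweep(xy, 2L, colMeans(xy))
  cv <- crossprod(xy) / (nrow(xy) - 1L)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  (atan2(v[2L], v[1L]) * 180 / pi) %% 180
}

#' Find the k nearest neighbors of a focal cell
#'
#' Exhaustive Euclidean search over the candidate set, with deterministic
#' tie-breaking by (distance, cell_id) ascending.
#'
#' @param focal a single-row data.frame (or list) with `x`, `y`, `cell_id`.
#' @param candidates data.frame of candidate cells with `x`, `y`, `cell_id`;
#'   must not contain the focal cell.
#' @param k number of neighbors.
#' @return integer vector of k neighbor cell ids, ordered by distance.
#' @export
findKNearest <- function(focal, candidates, k = 6L) {
  if (any(candidates$cell_id == focal$cell_id))
    stopDomain("candidate set must exclude the focal cell (id %d)",
               focal$cell_id)
  if (nrow(candidates) < k)
    stopData("focal cell %d has only %d candidate neighbors; %d required",
             focal$cell_id, nrow(candidates), k)
  d <- sqrt((candidates$x - focal$x)^2 + (candidates$y - focal$y)^2)
  ord <- order(d, candidates$cell_id)
  candidates$cell_id[ord[seq_len(k)]]
}

#' Arm angles of a neighbor star
#'
#' Angle of each focal-to-neighbor arm measured counter-clockwise from the
#' reference axis direction, in degrees in [0, 360).
#'
#' @param focal single-row data.frame/list with `x`, `y`.
#' @param neighbors data.frame of neighbor cells (ordered as desired).
#' @param axis reference axis in degrees.
#' @return numeric vector of angles in [0, 360).
#' @export
armAngles <- function(focal, neighbors, axis = 0) {
  dx <- neighbors$x - focal$x
  dy <- neighbors$y - focal$y
  if (any(dx == 0 & dy == 0))
    stopDomain("neighbor coincident with focal cell at (%g, %g): degenerate geometry",
               focal$x, focal$y)
  (atan2(dy, dx) * 180 / pi - axis) %% 360
}

#' Bin angles into equal radial sectors
#'
#' Sector s covers the half-open arc [(s-1) * 360/nSectors, s * 360/nSectors),
#' so 0 maps to sector 1, 22.5 to sector 2 (for 16 sectors), and angles just
#' below 360 to sector nSectors; boundary angles always belong to the
#' higher-numbered sector.
#'
#' @param angles numeric angles in degrees, each in [0, 360).
#' @param nSectors number of sectors.
#' @return integer sector indices in 1..nSectors.
#' @export
binToSectors <- function(angles, nSectors = 16L) {
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles >= 360))
    stopDomain("angles must lie in [0, 360)")
  s <- floor(angles * nSectors / 360) + 1L
  as.integer(pmin(s, nSectors))
}

# Eligible focal cells of a mosaic under a StarConfig: target-row cells of
# the focal type, minus edge-margin exclusions, minus cells with < k
# candidates.
focalCells <- function(mosaic, config) {
  df <- mosaic@cells
  focalType <- config@candidateTypes[1L]
  foc <- df[df$cell_type == focalType & df$row_index == config@targetRow, ,
            drop = FALSE]
  if (config@edgePolicy == "exclude_margin" && nrow(foc)) {
    bb <- list(x = range(df$x), y = range(df$y))
    m <- config@margin
    keep <- foc$x >= bb$x[1L] + m & foc$x <= bb$x[2L] - m &
            foc$y >= bb$y[1L] + m & foc$y <= bb$y[2L] - m
    foc <- foc[keep, , drop = FALSE]
  }
  foc
}

#' Compute the sector-occupancy profile of one mosaic
#'
#' For every eligible focal cell of the target row, arms are drawn to its k
#' nearest neighbors among cells of the candidate types, arm directions are
#' measured against the reference axis, binned into the radial sectors, and
#' accumulated into one per-sample count vector. Frequencies are the counts
#' normalized to sum to 1.
#'
#' Eligibility: focal cells are target-row cells of the focal type
#' (first `candidateTypes` entry), optionally excluding a bounding-box
#' margin, and must have at least k candidate neighbors. At least
#' `minFocalCells` eligible cells are required.
#'
#' @param mosaic a [Mosaic-class] object.
#' @param config a [StarConfig-class] object.
#' @return a [SectorProfile-class] object.
#' @examples
#' m <- generateLattice(generatorConfig(cellsPerRow = 15, jitterSD = 0))
#' computeProfile(m, starConfig(axisMode = "given", givenAxisAngle = 0))
#' @export
computeProfile <- function(mosaic, config = starConfig()) {
  stopifnot(is(mosaic, "Mosaic"), is(config, "StarConfig"))
  validObject(config)
  df <- mosaic@cells
  cand <- df[df$cell_type %in% config@candidateTypes, , drop = FALSE]
  foc <- focalCells(mosaic, config)
  k <- config@k

  axis <- if (config@axisMode == "given") config@givenAxisAngle
          else estimateAxis(mosaic, config@targetRow)

  counts <- integer(config@nSectors)
  nf <- 0L
  for (idx in seq_len(nrow(foc))) {
    f <- foc[idx, ]
    others <- cand[cand$cell_id != f$cell_id, , drop = FALSE]
    if (nrow(others) < k) next  # ineligible under the inclusion policy
    ids <- findKNearest(f, others, k)
    nb <- others[match(ids, others$cell_id), , drop = FALSE]
    ang <- armAngles(f, nb, axis)
    counts <- counts + tabulate(binToSectors(ang, config@nSectors),
                                nbins = config@nSectors)
    nf <- nf + 1L
  }
  if (nf < config@minFocalCells)
    stopData("sample '%s': %d eligible focal cells found, %d required",
             mosaic@sampleId, nf, config@minFocalCells)
  new("SectorProfile", sampleId = mosaic@sampleId, genotype = mosaic@genotype,
      region = mosaic@region, counts = counts,
      frequencies = counts / sum(counts), nFocal = nf)
}

#' Mean sector frequency across samples
#'
#' Unweighted mean of the per-sample frequency vectors (each sample is one
#' cochlea and counts equally, regardless of its number of focal cells).
#'
#' @param profiles list of [SectorProfile-class] objects sharing nSectors.
#' @return numeric vector of mean frequencies (sums to 1).
#' @export
aggregateGroup <- function(profiles) {
  if (!length(profiles)) stopData("cannot aggregate an empty profile set")
  ns <- vapply(profiles, function(p) length(p@counts), integer(1))
  if (length(unique(ns)) != 1L)
    stopDomain("profiles disagree on the number of sectors: %s",
               paste(unique(ns), collapse = ", "))
  colMeans(do.call(rbind, lapply(profiles, sectorFrequencies)))
}

#' Tabulate sector profiles
#'
#' @param profiles list of [SectorProfile-class] objects.
#' @return data.frame with one row per sample: annotations, n_focal and
#'   count_/freq_ columns per sector.
#' @export
profilesToTable <- function(profiles) {
  stopifnot(length(profiles) > 0)
  ns <- length(profiles[[1L]]@counts)
  rows <- lapply(profiles, function(p) {
    out <- data.frame(sample_id = p@sampleId, genotype = p@genotype,
                      region = p@region, n_focal = p@nFocal,
                      stringsAsFactors = FALSE)
    cn <- as.data.frame(as.list(p@counts))
    names(cn) <- sprintf("count_%d", seq_len(ns))
    fr <- as.data.frame(as.list(p@frequencies))
    names(fr) <- sprintf("freq_%d", seq_len(ns))
    cbind(out, cn, fr)
  })
  do.call(rbind, rows)
}
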