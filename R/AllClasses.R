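#' @import methods
NULL

#' Configuration for the synthetic epithelium generator
#'
#' Describes an offset-row ("brick"/near-hexagonal) lattice of cell centroids
#' with optional positional jitter, random cell loss, and ectopic-cell
#' insertion in the pillar-cell region, emulating confocal surface views of
#' the outer hair cell (OHC) rows of the embryonic organ of Corti.
#'
#' @slot nRows integer, number of cell rows (default 3, the OHC rows).
#' @slot cellsPerRow integer, cells per row (>= 2).
#' @slot colSpacing numeric, within-row centroid spacing d_c in micrometers.
#' @slot rowSpacing numeric, between-row spacing d_r in micrometers. The
#'   default d_c * sqrt(3)/2 makes the noiseless lattice hexagonal, so every
#'   interior cell has six equidistant nearest neighbors.
#' @slot rowOffsetFraction numeric, fraction of d_c by which alternate rows
#'   are shifted (0.5 = near-hexagonal packing).
#' @slot jitterSD numeric, isotropic Gaussian positional noise sd (um).
#' @slot missingRate numeric in [0,1], per-site probability of cell absence.
#' @slot ectopicRate numeric in [0,1], per-column probability of inserting an
#'   ectopic cell between row 1 and the pillar-cell position.
#' @slot seed integer seed; identical configurations reproduce bit-identical
#'   mosaics.
#' @slot genotypeLabel,regionLabel character sample annotations
#'   (region one of base/mid/apex by convention).
#' @seealso [generatorConfig()], [presetConfig()], [generateLattice()]
#' @export
setClass("GeneratorConfig",
  representation(
    nRows = "integer",
    cellsPerRow = "integer",
    colSpacing = "numeric",
    rowSpacing = "numeric",
    rowOffsetFraction = "numeric",
    jitterSD = "numeric",
    missingRate = "numeric",
    ectopicRate = "numeric",
    seed = "integer",
    genotypeLabel = "character",
    regionLabel = "character"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  scalarNum <- function(x) length(x) == 1L && is.finite(x)
  if (!scalarNum(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (!scalarNum(object@cellsPerRow) || object@cellsPerRow < 2L)
    msg <- c(msg, "cellsPerRow must be a single integer >= 2")
  for (s in c("colSpacing", "rowSpacing")) {
    v <- slot(object, s)
    if (!scalarNum(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single finite value > 0", s))
  }
  if (!scalarNum(object@rowOffsetFraction))
    msg <- c(msg, "rowOffsetFraction must be a single finite value")
  if (!scalarNum(object@jitterSD) || object@jitterSD < 0)
    msg <- c(msg, "jitterSD must be a single finite value >= 0")
  for (s in c("missingRate", "ectopicRate")) {
    v <- slot(object, s)
    if (!scalarNum(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A cell mosaic: one imaged field of the organ of Corti
#'
#' Holds the digitized cell centroids of one sample/field together with its
#' annotations and the longitudinal length of the sensory epithelium in the
#' image (the denominator of the density statistic).
#'
#' @slot cells data.frame with columns `cell_id` (integer, unique),
#'   `cell_type` (IHC/OHC/IPC/OPC/DC/ectopic), `row_index` (integer >= 1,
#'   1 = medial-most row of its type), `x`, `y` (um; x runs along the
#'   longitudinal basal-to-apical axis, y medial-to-lateral).
#' @slot sampleId,genotype,region character annotations.
#' @slot length numeric, epithelium length L in um (> 0).
#' @seealso [Mosaic()], [cells()], [epitheliumLength()]
#' @export
setClass("Mosaic",
  representation(
    cells = "data.frame",
    sampleId = "character",
    genotype = "character",
    region = "character",
    length = "numeric"
  )
)

setValidity("Mosaic", function(object) {
  msg <- character()
  df <- object@cells
  need <- c("cell_id", "cell_type", "row_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("cells is missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (anyDuplicated(df$cell_id))
      msg <- c(msg, "cell_id values must be unique within a Mosaic")
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
      msg <- c(msg, "cell coordinates must be finite")
    if (any(df$row_index < 1L))
      msg <- c(msg, "row_index must be >= 1")
  }
  if (length(object@length) != 1L || !is.finite(object@length) ||
      object@length <= 0)
    msg <- c(msg, "epithelium length must be a single finite value > 0")
  for (s in c("sampleId", "genotype", "region"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("%s must be a single string", s))
  if (length(msg)) msg else TRUE
})

#' Configuration of the six-arm angular-sector statistic
#'
#' For each focal cell in the target row, arms are drawn to its k nearest
#' same-type neighbors and the arm directions are binned into `nSectors`
#' equal radial sectors (default 16 sectors of 22.5 degrees, numbered 1-16
#' counter-clockwise from the longitudinal axis).
#'
#' @slot k integer, number of nearest neighbors per star (default 6).
#' @slot nSectors integer, number of radial sectors (default 16).
#' @slot targetRow integer, focal row (default 2: second-row OHCs; use 4 for
#'   the PROX1+ fourth-row analysis).
#' @slot minFocalCells integer, minimum eligible focal cells per sample
#'   (default 10).
#' @slot candidateTypes character, cell types forming the neighbor candidate
#'   pool; the first element is the focal cell type (default "OHC").
#' @slot axisMode "estimated" (principal axis of the focal row) or "given".
#' @slot givenAxisAngle numeric degrees, used when axisMode = "given".
#' @slot edgePolicy "include" (all focal cells with >= k candidates) or
#'   "exclude_margin" (drop focal cells within `margin` um of the mosaic
#'   bounding box).
#' @slot margin numeric, um, for edgePolicy = "exclude_margin".
#' @seealso [starConfig()], [computeProfile()]
#' @export
setClass("StarConfig",
  representation(
    k = "integer",
    nSectors = "integer",
    targetRow = "integer",
    minFocalCells = "integer",
    candidateTypes = "character",
    axisMode = "character",
    givenAxisAngle = "numeric",
    edgePolicy = "character",
    margin = "numeric"
  )
)

setValidity("StarConfig", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@nSectors) != 1L || object@nSectors < 2L)
    msg <- c(msg, "nSectors must be a single integer >= 2")
  if (length(object@targetRow) != 1L || object@targetRow < 1L)
    msg <- c(msg, "targetRow must be a single integer >= 1")
  if (length(object@minFocalCells) != 1L || object@minFocalCells < 1L)
    msg <- c(msg, "minFocalCells must be a single integer >= 1")
  if (!length(object@candidateTypes))
    msg <- c(msg, "candidateTypes must name at least one cell type")
  if (!object@axisMode %in% c("estimated", "given"))
    msg <- c(msg, "axisMode must be 'estimated' or 'given'")
  if (!object@edgePolicy %in% c("include", "exclude_margin"))
    msg <- c(msg, "edgePolicy must be 'include' or 'exclude_margin'")
  if (length(object@margin) != 1L || !is.finite(object@margin) ||
      object@margin < 0)
    msg <- c(msg, "margin must be a single finite value >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-sample sector-occupancy profile
#'
#' Counts and frequencies of star-arm directions over the radial sectors for
#' one sample, as accumulated by [computeProfile()]. `sum(counts)` equals
#' k * nFocal, and frequencies sum to 1.
#'
#' @slot sampleId,genotype,region character annotations.
#' @slot counts integer vector of per-sector arm counts.
#' @slot frequencies numeric vector, counts / sum(counts).
#' @slot nFocal integer, number of focal cells used.
#' @export
setClass("SectorProfile",
  representation(
    sampleId = "character",
    genotype = "character",
    region = "character",
    counts = "integer",
    frequencies = "numeric",
    nFocal = "integer"
  )
)

setValidity("SectorProfile", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@frequencies))
    msg <- c(msg, "counts and frequencies must have equal length")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (object@nFocal > 0L) {
    if (sum(object@counts) == 0L)
      msg <- c(msg, "counts must be positive when nFocal > 0")
    else if (abs(sum(object@frequencies) - 1) > 1e-9)
      msg <- c(msg, "frequencies must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
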