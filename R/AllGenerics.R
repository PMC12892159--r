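#' @rdname Mosaic-class
#' @param x a `Mosaic` or `SectorProfile` object.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname Mosaic-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname Mosaic-class
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname Mosaic-class
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname Mosaic-class
#' @export
setGeneric("epitheliumLength", function(x) standardGeneric("epitheliumLength"))

#' @rdname Mosaic-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname SectorProfile-class
#' @param x a `SectorProfile` object.
#' @export
setGeneric("sectorCounts", function(x) standardGeneric("sectorCounts"))

#' @rdname SectorProfile-class
#' @export
setGeneric("sectorFrequencies", function(x) standardGeneric("sectorFrequencies"))

#' @rdname SectorProfile-class
#' @export
setGeneric("nFocal", function(x) standardGeneric("nFocal"))

setMethod("cells", "Mosaic", function(x) x@cells)
setMethod("sampleId", "Mosaic", function(x) x@sampleId)
setMethod("genotype", "Mosaic", function(x) x@genotype)
setMethod("region", "Mosaic", function(x) x@region)
setMethod("epitheliumLength", "Mosaic", function(x) x@length)
setMethod("nCells", "Mosaic", function(x) nrow(x@cells))

setMethod("sampleId", "SectorProfile", function(x) x@sampleId)
setMethod("genotype", "SectorProfile", function(x) x@genotype)
setMethod("region", "SectorProfile", function(x) x@region)
setMethod("sectorCounts", "SectorProfile", function(x) x@counts)
setMethod("sectorFrequencies", "SectorProfile", function(x) x@frequencies)
setMethod("nFocal", "SectorProfile", function(x) x@nFocal)

setMethod("show", "Mosaic", function(object) {
  cat(sprintf(
    "Mosaic '%s' (%s, %s): %d cells, L = %.2f um\n",
    object@sampleId, object@genotype, object@region,
    nrow(object@cells), object@length))
  tab <- table(object@cells$cell_type)
  if (length(tab))
    cat("  cell types:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  invisible(NULL)
})

setMethod("show", "SectorProfile", function(object) {
  cat(sprintf(
    "SectorProfile '%s' (%s, %s): %d sectors, %d focal cells, %d arms\n",
    object@sampleId, object@genotype, object@region,
    length(object@counts), object@nFocal, sum(object@counts)))
  cat("  counts:", paste(object@counts, collapse = " "), "\n")
  invisible(NULL)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    paste0("GeneratorConfig: %d x %d lattice, d_c = %.2f um, d_r = %.2f um,",
           " jitter sd = %.3f um\n"),
    object@nRows, object@cellsPerRow, object@colSpacing, object@rowSpacing,
    object@jitterSD))
  cat(sprintf("  missing = %.3f, ectopic = %.3f, seed = %d, %s / %s\n",
              object@missingRate, object@ectopicRate, object@seed,
              object@genotypeLabel, object@regionLabel))
  invisible(NULL)
})

setMethod("show", "StarConfig", function(object) {
  cat(sprintf(
    "StarConfig: k = %d, %d sectors (%.2f deg), target row %d, axis %s\n",
    object@k, object@nSectors, 360 / object@nSectors, object@targetRow,
    if (object@axisMode == "given")
      sprintf("given (%.1f deg)", object@givenAxisAngle) else "estimated"))
  invisible(NULL)
})
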