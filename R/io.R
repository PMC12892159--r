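# CSV dialect: comma-separated, UTF-8, "." decimal, header required.
# Coordinates are um in an image-local frame; angles in output tables are
# degrees.

mosaicColumns <- c("sample_id", "genotype", "region", "cell_type",
                   "row_index", "x_um", "y_um")

writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write mosaics to a cell-centroid CSV table
#'
#' One row per cell with columns sample_id, genotype, region, cell_type,
#' row_index, cell_id, x_um, y_um, length_um (the per-sample epithelium
#' length, repeated on each row of its sample).
#'
#' @param mosaics a [Mosaic-class] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMosaics <- function(mosaics, path) {
  if (is(mosaics, "Mosaic")) mosaics <- list(mosaics)
  rows <- lapply(mosaics, function(m) {
    df <- m@cells
    data.frame(sample_id = m@sampleId, genotype = m@genotype,
               region = m@region, cell_type = df$cell_type,
               row_index = df$row_index, cell_id = df$cell_id,
               x_um = df$x, y_um = df$y, length_um = m@length,
               stringsAsFactors = FALSE)
  })
  writeCsv(do.call(rbind, rows), path)
}

#' Read mosaics from a cell-centroid CSV table
#'
#' Expects the header columns sample_id, genotype, region, cell_type,
#' row_index, x_um, y_um in any order, plus optional cell_id and length_um
#' columns. Malformed coordinates are reported with their line numbers;
#' duplicate (sample_id, cell_id) pairs are an integrity error. When
#' length_um is absent the longitudinal (x) extent of each sample is used as
#' its epithelium length.
#'
#' @param path CSV path.
#' @return named list of [Mosaic-class] objects, one per sample_id in order
#'   of first appearance.
#' @export
readMosaics <- function(path) {
  if (!file.exists(path)) stopDomain("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  miss <- setdiff(mosaicColumns, names(raw))
  if (length(miss))
    stopDomain("mosaic table is missing required column(s): %s",
               paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopDomain("non-numeric or non-finite %s at line(s) %s", col,
                 paste(utils::head(bad + 1L, 5L), collapse = ", "))
    v
  }
  raw$x <- num("x_um")
  raw$y <- num("y_um")
  ri <- num("row_index")
  if (any(ri != round(ri) | ri < 1))
    stopDomain("row_index must be integers >= 1")
  raw$row_index <- as.integer(ri)
  hasId <- "cell_id" %in% names(raw)
  if (hasId) {
    raw$cell_id <- as.integer(num("cell_id"))
    dup <- duplicated(paste(raw$sample_id, raw$cell_id))
    if (any(dup))
      stopDomain("duplicate (sample_id, cell_id) at line(s) %s",
                 paste(utils::head(which(dup) + 1L, 5L), collapse = ", "))
  }
  hasLen <- "length_um" %in% names(raw)
  if (hasLen) raw$length_um <- num("length_um")

  ids <- unique(raw$sample_id)
  out <- lapply(ids, function(sid) {
    sub <- raw[raw$sample_id == sid, , drop = FALSE]
    for (col in c("genotype", "region"))
      if (length(unique(sub[[col]])) != 1L)
        stopDomain("sample '%s' has conflicting %s values", sid, col)
    L <- if (hasLen) {
      u <- unique(sub$length_um)
      if (length(u) != 1L)
        stopDomain("sample '%s' has conflicting length_um values", sid)
      u
    } else NULL
    cellsDf <- data.frame(
      cell_id = if (hasId) sub$cell_id else seq_len(nrow(sub)),
      cell_type = sub$cell_type, row_index = sub$row_index,
      x = sub$x, y = sub$y, stringsAsFactors = FALSE)
    Mosaic(cellsDf, sampleId = sid, genotype = sub$genotype[1L],
           region = sub$region[1L], length = L)
  })
  names(out) <- ids
  out
}

defaultRunConfig <- function() {
  list(
    preset = "control-vs-tko",
    n_samples = 3L,
    seed = 1L,
    out_dir = ".",
    generator = list(
      n_rows = 3L, cells_per_row = 20L, col_spacing = 8,
      row_offset_fraction = 0.5),
    star = list(
      k = 6L, n_sectors = 16L, target_row = 2L, min_focal_cells = 10L,
      candidate_types = "OHC", axis_mode = "estimated",
      given_axis_angle = 0, edge_policy = "include", margin = 0),
    tests = list(welch = FALSE, alpha = 0.05, alpha2 = 0.01,
                 label_on = "p_raw"))
}

mergeConfig <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stopConfig("unknown configuration key: %s", full)
    if (is.list(base[[key]]))
      base[[key]] <- mergeConfig(base[[key]],
                                 as.list(override[[key]]), full)
    else base[[key]] <- override[[key]]
  }
  base
}

#' Read a JSON run configuration
#'
#' Unknown keys are rejected; omitted keys take their documented defaults.
#' A resolved copy of the configuration is written next to the outputs of
#' every run so that re-running it reproduces identical tables.
#'
#' @param path JSON file path, or NULL for the defaults.
#' @return nested named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stopDomain("config file not found: %s", path)
    cfg <- mergeConfig(cfg, jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  cfg
}

writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

starConfigFromRun <- function(cfg) {
  s <- cfg$star
  starConfig(k = s$k, nSectors = s$n_sectors, targetRow = s$target_row,
             minFocalCells = s$min_focal_cells,
             candidateTypes = s$candidate_types, axisMode = s$axis_mode,
             givenAxisAngle = s$given_axis_angle, edgePolicy = s$edge_policy,
             margin = s$margin)
}

# Cheap deterministic fingerprint of a resolved configuration.
configFingerprint <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
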