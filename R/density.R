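#' Count cells of a given type in a mosaic
#'
#' Ectopic hair cells sit outside the normal rows but are still hair cells;
#' by default they are counted together with the row-1-adjacent hair-cell
#' type (`ectopicAs = "OHC"`), matching how OHC density is scored in fields
#' that contain a partial fourth row. Set `ectopicAs = NA` to count them only
#' under their own "ectopic" label.
#'
#' @param mosaic a [Mosaic-class] object.
#' @param cellType label to count (one of the types present, or
#'   IHC/OHC/IPC/OPC/DC/ectopic).
#' @param ectopicAs type under which ectopic cells are also counted
#'   (default "OHC"), or NA for none.
#' @return integer count.
#' @export
countCells <- function(mosaic, cellType = "OHC", ectopicAs = "OHC") {
  stopifnot(is(mosaic, "Mosaic"))
  known <- union(c("IHC", "OHC", "IPC", "OPC", "DC", "ectopic"),
                 unique(mosaic@cells$cell_type))
  if (length(cellType) != 1L || !cellType %in% known)
    stopDomain("unknown cell_type '%s'; known labels: %s", cellType,
               paste(sort(known), collapse = ", "))
  types <- cellType
  if (!is.na(ectopicAs) && identical(cellType, ectopicAs))
    types <- c(types, "ectopic")
  sum(mosaic@cells$cell_type %in% types)
}

#' Cell density per 100 um of sensory epithelium
#'
#' The study's density statistic: the cell count divided by the length of
#' the sensory epithelium in the image, multiplied by 100.
#'
#' @param nCells non-negative cell count.
#' @param length epithelium length L in um, > 0.
#' @return cells per 100 um.
#' @examples
#' computeDensity(30, 200)  # 15 cells per 100 um
#' @export
computeDensity <- function(nCells, length) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0))
    stopDomain("epithelium length must be > 0 (got %s)",
               paste(format(length), collapse = ", "))
  if (any(nCells < 0)) stopDomain("cell count must be >= 0")
  nCells / length * 100
}

#' Tabulate per-sample cell densities
#'
#' @param mosaics list of [Mosaic-class] objects.
#' @param cellType label counted (see [countCells()]).
#' @param ectopicAs ectopic-counting policy (see [countCells()]).
#' @return data.frame with columns sample_id, genotype, region, cell_type,
#'   n_cells, length_um, density (cells per 100 um).
#' @export
densityTable <- function(mosaics, cellType = "OHC", ectopicAs = "OHC") {
  if (is(mosaics, "Mosaic")) mosaics <- list(mosaics)
  rows <- lapply(mosaics, function(m) {
    n <- countCells(m, cellType, ectopicAs)
    data.frame(sample_id = m@sampleId, genotype = m@genotype,
               region = m@region, cell_type = cellType, n_cells = n,
               length_um = m@length, density = computeDensity(n, m@length),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way ANOVA with Tukey post-hoc on cell densities
#'
#' Fixed-effects two-way ANOVA of density on genotype, region and their
#' interaction (type-II sums of squares, which coincide with the classical
#' balanced-design decomposition when the design is balanced), followed by
#' Tukey HSD pairwise comparisons of genotype within each region.
#'
#' @param records data.frame with columns genotype, region, density (e.g.
#'   from [densityTable()]).
#' @return list with elements `anova` (data.frame: effect, sum_sq, df,
#'   f_value, p_value) and `tukey` (data.frame: region, contrast, estimate,
#'   t_ratio, p_raw, p_tukey).
#' @export
compareDensity <- function(records) {
  records <- as.data.frame(records)
  need <- c("genotype", "region", "density")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopDomain("density records are missing column(s): %s",
               paste(miss, collapse = ", "))
  records$genotype <- factor(records$genotype)
  records$region <- factor(records$region)
  if (nlevels(records$genotype) < 2L || nlevels(records$region) < 2L)
    stopData("need >= 2 genotypes and >= 2 regions (found %d x %d)",
             nlevels(records$genotype), nlevels(records$region))
  tab <- table(records$genotype, records$region)
  if (any(tab < 2L))
    stopData("every genotype x region cell needs >= 2 replicates (min found: %d)",
             min(tab))
  cellVar <- tapply(records$density,
                    list(records$genotype, records$region), stats::var)
  if (all(cellVar == 0, na.rm = TRUE))
    stopData("degenerate design: zero within-group variance in every cell")

  fit <- stats::lm(density ~ genotype * region, data = records)
  an <- car::Anova(fit, type = 2)
  anova <- data.frame(effect = rownames(an), sum_sq = an[["Sum Sq"]],
                      df = an[["Df"]], f_value = an[["F value"]],
                      p_value = an[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(anova) <- NULL

  em <- emmeans::emmeans(fit, ~ genotype | region)
  tk <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  rw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "none"))
  tukey <- data.frame(region = as.character(tk$region),
                      contrast = as.character(tk$contrast),
                      estimate = tk$estimate, t_ratio = tk$t.ratio,
                      p_raw = rw$p.value, p_tukey = tk$p.value,
                      stringsAsFactors = FALSE)
  list(anova = anova, tukey = tukey)
}
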