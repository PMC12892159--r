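#' Per-sector two-sample t-tests between genotype groups
#'
#' For each radial sector, compares the per-sample occupancy frequencies of
#' the two groups with a two-sided two-sample t-test (pooled-variance Student
#' by default, Welch with `welch = TRUE`); the unit of replication is the
#' cochlea/sample. Raw p values are reported alongside Benjamini-Hochberg
#' adjusted p values across the sectors; significance labels (default
#' `*` p < 0.05, `**` p < 0.01) are applied to the configured p column
#' (raw by default). Sectors where both groups have zero variance yield an
#' undefined t; they are flagged degenerate and reported not-significant.
#'
#' @param group1,group2 lists of [SectorProfile-class] objects (>= 2 each),
#'   all sharing the same number of sectors.
#' @param welch logical, use the Welch unequal-variance test.
#' @param alpha,alpha2 thresholds for `*` and `**` labels.
#' @param labelOn "p_raw" or "p_bh": the column driving the labels.
#' @return data.frame with one row per sector: sector, mean_freq_group1,
#'   mean_freq_group2, t_stat, p_raw, p_bh, label, degenerate.
#' @export
sectorTTest <- function(group1, group2, welch = FALSE, alpha = 0.05,
                        alpha2 = 0.01, labelOn = c("p_raw", "p_bh")) {
  labelOn <- match.arg(labelOn)
  if (length(group1) < 2L || length(group2) < 2L)
    stopData("each group needs >= 2 samples (found %d and %d)",
             length(group1), length(group2))
  f1 <- do.call(rbind, lapply(group1, sectorFrequencies))
  f2 <- do.call(rbind, lapply(group2, sectorFrequencies))
  if (ncol(f1) != ncol(f2))
    stopDomain("groups disagree on the number of sectors (%d vs %d)",
               ncol(f1), ncol(f2))
  ns <- ncol(f1)
  t_stat <- p_raw <- rep(NA_real_, ns)
  degenerate <- logical(ns)
  for (s in seq_len(ns)) {
    x <- f1[, s]; y <- f2[, s]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      degenerate[s] <- TRUE
      next
    }
    tt <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                   error = function(e) NULL)
    if (is.null(tt)) { degenerate[s] <- TRUE; next }
    t_stat[s] <- unname(tt$statistic)
    p_raw[s] <- tt$p.value
  }
  p_bh <- stats::p.adjust(p_raw, method = "BH")
  p_lab <- if (labelOn == "p_raw") p_raw else p_bh
  label <- ifelse(is.na(p_lab), "",
                  ifelse(p_lab < alpha2, "**", ifelse(p_lab < alpha, "*", "")))
  data.frame(sector = seq_len(ns),
             mean_freq_group1 = colMeans(f1),
             mean_freq_group2 = colMeans(f2),
             t_stat = t_stat, p_raw = p_raw, p_bh = p_bh,
             label = label, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Disorder summary of a sector profile
#'
#' Shannon entropy (base 2, with 0 log 0 = 0) of the sector frequency vector
#' and the number of occupied sectors. A perfect hexagonal mosaic
#' concentrates all arms in six sectors (entropy log2(6) = 2.585 bits);
#' disordered mosaics spread mass toward the uniform maximum of
#' log2(nSectors) bits.
#'
#' @param profile a [SectorProfile-class] object with nFocal > 0.
#' @return data.frame with sample_id, entropy (bits), occupied_sectors.
#' @export
disorderSummary <- function(profile) {
  stopifnot(is(profile, "SectorProfile"))
  if (profile@nFocal <= 0L)
    stopData("profile '%s' has no focal cells", profile@sampleId)
  f <- profile@frequencies
  nz <- f > 0
  data.frame(sample_id = profile@sampleId,
             entropy = -sum(f[nz] * log2(f[nz])),
             occupied_sectors = sum(nz),
             stringsAsFactors = FALSE)
}

#' End-to-end patterning comparison of two genotype groups
#'
#' Runs the full analysis of a control-vs-mutant experiment: per-sample
#' sector profiles, group radar means, per-sector t-tests, per-sample
#' disorder summaries, and -- when the mosaics span at least two regions
#' with replication -- the density ANOVA/Tukey comparison.
#'
#' @param control,mutant lists of [Mosaic-class] objects.
#' @param config a [StarConfig-class] object.
#' @param welch logical, Welch flavor for the sector t-tests.
#' @param densityCellType cell type counted for density (see [countCells()]).
#' @return list with elements `profiles` (list control/mutant),
#'   `radar` (data.frame group, sector, mean_frequency), `sector_tests`,
#'   `disorder` (with group column), `density_records`, and
#'   `density_comparison` (NULL unless the density design supports ANOVA).
#' @export
runExperimentComparison <- function(control, mutant, config = starConfig(),
                                    welch = FALSE, densityCellType = "OHC") {
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] sample '%s': %s", what, id, conditionMessage(e)),
           call. = FALSE)
    })
  }
  profs <- function(ms) lapply(ms, function(m)
    stage("profile", m@sampleId, computeProfile(m, config)))
  pc <- profs(control)
  pm <- profs(mutant)

  ns <- config@nSectors
  radar <- rbind(
    data.frame(group = "control", sector = seq_len(ns),
               mean_frequency = aggregateGroup(pc)),
    data.frame(group = "mutant", sector = seq_len(ns),
               mean_frequency = aggregateGroup(pm)))

  tests <- sectorTTest(pc, pm, welch = welch)

  dis <- rbind(
    cbind(do.call(rbind, lapply(pc, disorderSummary)), group = "control"),
    cbind(do.call(rbind, lapply(pm, disorderSummary)), group = "mutant"))
  rownames(dis) <- NULL

  dens <- densityTable(c(control, mutant), cellType = densityCellType)
  cmp <- NULL
  tab <- table(dens$genotype, dens$region)
  if (nrow(tab) >= 2L && ncol(tab) >= 2L && all(tab >= 2L))
    cmp <- compareDensity(dens)

  list(profiles = list(control = pc, mutant = pm), radar = radar,
       sector_tests = tests, disorder = dis, density_records = dens,
       density_comparison = cmp, config = config)
}
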