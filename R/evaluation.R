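## DVH computation and the quantitative plan-quality panel.

#' Cumulative dose-volume histogram of a structure
#'
#' Volume-weighted cumulative histogram over the mask voxels: the curve value
#' at dose edge d is the fraction of the structure volume receiving at least
#' d. Starts at 1.0 at dose 0 and is monotone non-increasing.
#'
#' @param dose a dose [VoxelVolume-class].
#' @param mask logical array on the same grid (non-empty).
#' @param bin_width_gy histogram bin width (default 0.1 Gy).
#' @return data.frame with columns `dose_gy` (bin edges) and `fraction`.
#' @export
computeDVH <- function(dose, mask, bin_width_gy = 0.1) {
  if (!any(mask)) stop("cannot compute a DVH over an empty mask")
  d <- dose@voxels[mask]
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  data.frame(dose_gy = edges, fraction = frac)
}

#' V at a dose level, from a DVH curve
#'
#' Percentage of the structure volume receiving at least `dose_gy`, read
#' from the curve (step lookup at the largest edge not exceeding the query).
#'
#' @param dvh data.frame from [computeDVH()].
#' @param dose_gy query dose (Gy).
#' @return percentage in \[0, 100\].
#' @export
vAt <- function(dvh, dose_gy) {
  i <- findInterval(dose_gy, dvh$dose_gy)
  if (i < 1) return(100)
  if (i > nrow(dvh)) return(0)
  100 * dvh$fraction[i]
}

#' Direct volume-at-dose, maximum and mean dose over a mask
#'
#' `vAtDirect` counts voxels with dose at or above the threshold (inclusive,
#' so a structure uniformly at the threshold scores 100%).
#'
#' @param dose a dose [VoxelVolume-class].
#' @param mask logical array (non-empty).
#' @param threshold_gy dose threshold (Gy).
#' @return percentage / Gy.
#' @export
vAtDirect <- function(dose, mask, threshold_gy) {
  if (!any(mask)) stop("empty structure mask")
  100 * mean(dose@voxels[mask] >= threshold_gy)
}

#' @rdname vAtDirect
#' @export
dMax <- function(dose, mask) {
  if (!any(mask)) stop("empty structure mask")
  max(dose@voxels[mask])
}

#' @rdname vAtDirect
#' @export
dMean <- function(dose, mask) {
  if (!any(mask)) stop("empty structure mask")
  mean(dose@voxels[mask])
}

#' Hotspot volume at a percentage of the prescription
#'
#' Body volume receiving at least `level_pct` % of the prescription dose, in
#' cc (107% is the conventional hotspot level for CSI review).
#'
#' @param dose a dose [VoxelVolume-class].
#' @param body logical body mask (NULL evaluates the whole grid).
#' @param rx_gy prescription dose (Gy).
#' @param level_pct hotspot level (default 107).
#' @return volume in cc.
#' @export
hotspotVolume <- function(dose, body = NULL, rx_gy = 23.4, level_pct = 107) {
  thr <- rx_gy * level_pct / 100
  d <- dose@voxels
  n <- if (is.null(body)) sum(d >= thr) else sum(d[body] >= thr)
  n * voxelVolumeCC(dose)
}

## the evaluation panel: which metric applies to which structure
.v95Structures <- c("brain", "spinal_canal", "cribriform_plate")
.dmaxStructures <- c("brain", "spinal_canal", "brainstem", "cochleae", "eyes",
                     "lenses", "optic_nerves")
.dmeanStructures <- c("cochleae", "heart", "kidneys", "lacrimal_glands",
                      "lungs", "pituitary", "thyroid")

#' Evaluate a composite plan
#'
#' Computes the quantitative panel: V95 of the prescription for the targets
#' (brain, spinal canal, cribriform plate), maximum dose for the serial
#' structures, mean dose for the parallel structures (Gy and % of the
#' prescription), and the 107% hotspot volume. Dmax is the maximum voxel
#' dose (no small-volume smoothing). Structures missing from the set are
#' marked absent with a warning.
#'
#' @param plan a [CompositePlan-class] (or any dose [VoxelVolume-class]).
#' @param sv the [LabeledVolume-class] evaluated against.
#' @param rx a [Prescription-class].
#' @return a [PlanReport-class].
#' @export
evaluatePlan <- function(plan, sv, rx = prescription()) {
  dose <- if (is(plan, "CompositePlan")) compositeDose(plan) else plan
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  rxGy <- rx@total_dose_gy
  rows <- list()
  addRow <- function(structure, metric, value_gy = NA, value_pct = NA, present = TRUE) {
    rows[[length(rows) + 1]] <<- data.frame(
      structure = structure, metric = metric, value_gy = value_gy,
      value_pct_rx = if (is.na(value_gy)) NA else 100 * value_gy / rxGy,
      value_pct = value_pct, present = present)
  }
  metric1 <- function(structs, metric, fun) {
    for (s in structs) {
      m <- getMask(sv, s, required = FALSE)
      if (is.null(m) || !any(m)) {
        warning(sprintf("structure '%s' absent; %s not evaluated", s, metric))
        addRow(s, metric, present = FALSE)
      } else if (metric == "V95") {
        addRow(s, metric, value_pct = vAtDirect(dose, m, 0.95 * rxGy))
      } else {
        addRow(s, metric, value_gy = fun(dose, m))
      }
    }
  }
  metric1(.v95Structures, "V95", NULL)
  metric1(.dmaxStructures, "Dmax", dMax)
  metric1(.dmeanStructures, "Dmean", dMean)
  body <- getMask(sv, "body", required = FALSE)
  new("PlanReport", metrics = do.call(rbind, rows),
      hotspot_cc = hotspotVolume(dose, body, rxGy), rx_gy = rxGy)
}

#' Render a plan report as a Markdown table
#'
#' @param report a [PlanReport-class].
#' @return character vector of Markdown lines.
#' @export
planReportMarkdown <- function(report) {
  m <- report@metrics
  fmt <- function(x, d = 1) ifelse(is.na(x), "-", sprintf(paste0("%.", d, "f"), x))
  lines <- c("| Structure | Metric | Gy | % Rx | V95 (%) |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %s |", m$structure, m$metric,
                     fmt(m$value_gy, 2), fmt(m$value_pct_rx), fmt(m$value_pct)),
             sprintf("| body | hotspot V107 | - | - | %.2f cc |", report@hotspot_cc))
  lines
}

#' DVH curves for a set of structures
#'
#' @param dose a dose [VoxelVolume-class] (or [CompositePlan-class]).
#' @param sv a [LabeledVolume-class].
#' @param structures structure names (default: all non-body masks present).
#' @param bin_width_gy DVH bin width.
#' @return long data.frame (structure, dose_gy, fraction).
#' @export
dvhTable <- function(dose, sv, structures = NULL, bin_width_gy = 0.1) {
  if (is(dose, "CompositePlan")) dose <- compositeDose(dose)
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  if (is.null(structures))
    structures <- setdiff(names(sv@masks), "body")
  do.call(rbind, lapply(structures, function(s) {
    m <- getMask(sv, s, required = FALSE)
    if (is.null(m) || !any(m)) return(NULL)
    cbind(structure = s, computeDVH(dose, m, bin_width_gy))
  }))
}

#' Plot DVH curves
#'
#' @param dvh long data.frame from [dvhTable()].
#' @param rx_gy optional prescription dose to mark.
#' @return invisibly, the input.
#' @export
plotDVH <- function(dvh, rx_gy = NULL) {
  structs <- unique(dvh$structure)
  cols <- grDevices::hcl.colors(max(3, length(structs)), "Dark 3")
  graphics::plot(NA, xlim = range(dvh$dose_gy), ylim = c(0, 100),
                 xlab = "Dose (Gy)", ylab = "Volume (%)", main = "DVH")
  for (i in seq_along(structs)) {
    d <- dvh[dvh$structure == structs[i], ]
    graphics::lines(d$dose_gy, 100 * d$fraction, col = cols[i], lwd = 2)
  }
  if (!is.null(rx_gy)) graphics::abline(v = rx_gy, lty = 2)
  graphics::legend("bottomleft", legend = structs, col = cols[seq_along(structs)],
                   lwd = 2, cex = 0.7, bty = "n")
  invisible(dvh)
}
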