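# Spatial statistics of Notch activation: the per-cell table, binned
# percent-positive gradients with peak and pool boundary, DTC drift and
# distances, nearest-neighbour distances, region centers and extents, and
# the progenitor-zone extent.

#' Build the per-cell analysis table
#'
#' Joins nuclei and classified spots into one row per germ cell (the DTC is
#' excluded): axial distance from the distal tip along the gonad axis (arc
#' length; identical to x for the straight synthetic gonad), Euclidean
#' distance to the DTC nucleus center, ATS count and summed ATS intensity,
#' and cytoplasmic mRNA count.
#'
#' @param nuclei segmented, classified nuclei
#' @param spots classified spot table (needs spot_class, cell_id,
#'   nucleus_id, intensity_au)
#' @param dtcId nucleus_id of the DTC, or NA (DTC-relative fields absent)
#' @return data.frame, one row per cell
#' @examples
#' nuc <- data.frame(nucleus_id = 1:2, x = c(1, 5), y = 0, z = 0,
#'                   r = 1.5, morphology = "mitotic")
#' sp <- data.frame(spot_class = "true_ats", cell_id = 1, nucleus_id = 1,
#'                  intensity_au = c(1.2, 0.9))
#' buildCellTable(nuc, sp, dtcId = NA)
#' @export
buildCellTable <- function(nuclei, spots, dtcId = NA) {
  cells <- nuclei[is.na(dtcId) | nuclei$nucleus_id != dtcId, , drop = FALSE]
  dtc_center <- if (!is.na(dtcId)) {
    k <- which(nuclei$nucleus_id == dtcId)
    unlist(nuclei[k, c("x", "y", "z")])
  } else NULL
  n <- nrow(cells)
  out <- data.frame(
    cell_id = cells$nucleus_id,
    nucleus_id = cells$nucleus_id,
    x = cells$x, y = cells$y, z = cells$z, r = cells$r,
    morphology = if ("morphology" %in% names(cells)) cells$morphology
                 else rep("unknown", n),
    axial_distance = pmax(0, cells$x),
    dtc_distance = if (!is.null(dtc_center))
      sqrt((cells$x - dtc_center[1])^2 + (cells$y - dtc_center[2])^2 +
           (cells$z - dtc_center[3])^2) else rep(NA_real_, n),
    n_ats = 0L, summed_ats_au = 0, n_mrna = 0L)
  if (!is.null(spots) && nrow(spots) > 0) {
    ats <- spots[spots$spot_class == "true_ats" & !is.na(spots$cell_id), ,
                 drop = FALSE]
    if (nrow(ats)) {
      cnt <- table(ats$cell_id)
      sm <- tapply(ats$intensity_au, ats$cell_id, sum)
      i <- match(as.integer(names(cnt)), out$cell_id)
      ok <- !is.na(i)
      out$n_ats[i[ok]] <- as.integer(cnt)[ok]
      out$summed_ats_au[i[ok]] <- as.numeric(sm)[ok]
    }
    mr <- spots[spots$spot_class == "mrna_cyto" & !is.na(spots$cell_id), ,
                drop = FALSE]
    if (nrow(mr)) {
      cnt <- table(mr$cell_id)
      i <- match(as.integer(names(cnt)), out$cell_id)
      ok <- !is.na(i)
      out$n_mrna[i[ok]] <- as.integer(cnt)[ok]
    }
  }
  rownames(out) <- NULL
  out
}

#' Binned percent-positive spatial profile
#'
#' Percentage of cells satisfying \code{predicate} per half-open axial
#' distance bin \code{[lo, hi)}; the profile of Notch transcriptional
#' activation probability along the gonad axis.  Empty bins carry NA.
#'
#' @param cells cell table
#' @param binWidth bin width (um)
#' @param predicate function of the cell table returning a logical vector;
#'   default: at least one ATS
#' @param maxDistance profile range (um); defaults to the data maximum
#' @return data.frame: bin_lo, bin_hi, bin_mid, n_cells, n_positive,
#'   percent
#' @export
percentProfile <- function(cells, binWidth = 2.5,
                           predicate = function(df) df$n_ats >= 1,
                           maxDistance = NULL) {
  stopifnot(nrow(cells) >= 1)
  pos <- predicate(cells)
  if (is.null(maxDistance)) maxDistance <- max(cells$axial_distance)
  nb <- max(1L, ceiling(maxDistance / binWidth - 1e-9))
  edges <- seq(0, nb * binWidth, by = binWidth)
  bin <- findInterval(cells$axial_distance, edges,
                      rightmost.closed = FALSE)
  bin[bin < 1] <- 1
  bin[bin > nb] <- nb   # a cell exactly at the top edge joins the last bin
  ncell <- tabulate(bin, nb)
  npos <- tabulate(bin[pos], nb)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             n_cells = ncell, n_positive = npos,
             percent = ifelse(ncell > 0, 100 * npos / ncell, NA_real_))
}

#' Average percent profiles across gonads with equal weight
#'
#' Per-gonad profiles are computed first and averaged bin-wise with equal
#' weight per gonad (bins missing in a gonad are skipped for that gonad).
#'
#' @param profiles list of profiles from \code{\link{percentProfile}}
#' @return a profile data.frame with percent = cross-gonad mean and
#'   n_gonads per bin
#' @export
averageProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  nb <- max(vapply(profiles, nrow, 1L))
  ref <- profiles[[which.max(vapply(profiles, nrow, 1L))]]
  pc <- sapply(profiles, function(p) {
    v <- rep(NA_real_, nb); v[seq_len(nrow(p))] <- p$percent; v
  })
  pc <- matrix(pc, nrow = nb)
  data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi, bin_mid = ref$bin_mid,
             n_cells = rowSums(sapply(profiles, function(p) {
               v <- rep(0, nb); v[seq_len(nrow(p))] <- p$n_cells; v
             })),
             n_gonads = rowSums(!is.na(pc)),
             percent = rowMeans(pc, na.rm = TRUE))
}

#' Proximal boundary of the stem-cell pool
#'
#' Left edge of the first bin at or after the profile peak whose percent
#' falls below \code{threshold} and is not immediately followed by a bin at
#' or above it (a single above-threshold bin beyond the crossing does not
#' reset the boundary).  NA if the profile never crosses the threshold.
#'
#' @param profile a percent profile
#' @param threshold percent threshold (default 2.5)
#' @return boundary position (um) or NA
#' @export
poolBoundary <- function(profile, threshold = 2.5) {
  stopifnot(nrow(profile) >= 1)
  pc <- profile$percent
  occ <- which(!is.na(pc))
  if (!length(occ)) return(NA_real_)
  if (all(pc[occ] < threshold)) return(profile$bin_lo[1])
  pk <- occ[which.max(pc[occ])]
  for (i in seq(pk, nrow(profile))) {
    if (is.na(pc[i]) || pc[i] >= threshold) next
    nxt <- if (i + 1 <= nrow(profile)) pc[i + 1] else NA
    if (!is.na(nxt) && nxt >= threshold) {
      # single above-threshold bin beyond the crossing does not reset it,
      # but two consecutive ones do
      nxt2 <- if (i + 2 <= nrow(profile)) pc[i + 2] else NA
      if (!is.na(nxt2) && nxt2 >= threshold) next
    }
    return(profile$bin_lo[i])
  }
  NA_real_
}

#' Position of the profile peak
#'
#' Center of the occupied bin with the maximum percent; ties are broken
#' toward the more distal (smaller-distance) bin.
#'
#' @param profile a percent profile
#' @return peak position (um)
#' @export
profilePeak <- function(profile) {
  occ <- which(!is.na(profile$percent))
  if (!length(occ)) stop("profile has no occupied bin")
  profile$bin_mid[occ[which.max(profile$percent[occ])]]
}

#' Nearest-neighbour distances among qualifying cells
#'
#' For each cell satisfying \code{predicate}, the 3D Euclidean distance
#' (nucleus centers) to its nearest qualifying neighbour.
#'
#' @param cells cell table
#' @param predicate function of the cell table returning a logical vector
#' @return numeric vector of NNDs (um), one per qualifying cell
#' @export
nndDistances <- function(cells, predicate = function(df) df$n_ats >= 1) {
  sel <- cells[predicate(cells), , drop = FALSE]
  if (nrow(sel) < 2)
    stop("need at least 2 qualifying cells for nearest-neighbour distances")
  m <- as.matrix(sel[, c("x", "y", "z")])
  d <- as.matrix(dist(m))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' DTC nuclear shift (drift) from the distal tip
#'
#' 3D Euclidean distance (not arc length) from the most distal point of the
#' gonad (the origin of the coordinate frame) to the DTC nucleus center.
#'
#' @param dtcCenter numeric length-3 (um), DTC nucleus center
#' @param tip the distal tip reference point (defaults to the origin)
#' @return drift (um)
#' @examples
#' dtcShift(c(3, 4, 0))  # 5
#' @export
dtcShift <- function(dtcCenter, tip = c(0, 0, 0)) {
  sqrt(sum((as.numeric(dtcCenter) - tip)^2))
}

#' Mean distance of qualifying cells to the DTC nucleus
#'
#' Mean Euclidean distance between cells satisfying \code{predicate}
#' (default: ATS-containing) and the DTC nucleus center; the clustering of
#' Notch activation around the niche nucleus.
#'
#' @param cells cell table with dtc_distance
#' @param predicate qualifying predicate
#' @return mean distance (um)
#' @export
meanDtcDistance <- function(cells, predicate = function(df) df$n_ats >= 1) {
  sel <- cells[predicate(cells), , drop = FALSE]
  if (nrow(sel) == 0) stop("no qualifying cells")
  if (all(is.na(sel$dtc_distance))) stop("dtc_distance absent (no DTC)")
  mean(sel$dtc_distance)
}

#' Correlation of a per-cell response with distance to the DTC nucleus
#'
#' Pearson correlation and least-squares line of a response (summed ATS
#' intensity or mRNA count) on the distance to the DTC nucleus.  For the
#' ATS response only ATS-containing cells enter; for the mRNA response all
#' cells do.
#'
#' @param cells cell table
#' @param response "summed_ats_au" or "n_mrna"
#' @return list: r, slope, intercept, n
#' @export
corrVsDistance <- function(cells,
                           response = c("summed_ats_au", "n_mrna")) {
  response <- match.arg(response)
  sel <- if (response == "summed_ats_au")
    cells[cells$n_ats >= 1, , drop = FALSE] else cells
  sel <- sel[!is.na(sel$dtc_distance), , drop = FALSE]
  if (nrow(sel) < 3) stop("need at least 3 cells with response and distance")
  x <- sel$dtc_distance; y <- sel[[response]]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  fit <- lm(y ~ x)
  list(r = unname(cor(x, y)), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = nrow(sel))
}

#' Center of the mRNA-rich region
#'
#' Unweighted centroid of the centers of cells with more than
#' \code{threshold} mRNAs; NA centroid if no cell qualifies.
#'
#' @param cells cell table
#' @param threshold minimum mRNA count (exclusive)
#' @return numeric length-3 centroid (um) or c(NA, NA, NA)
#' @export
mrnaRegionCenter <- function(cells, threshold = 10) {
  sel <- cells[cells$n_mrna > threshold, , drop = FALSE]
  if (nrow(sel) == 0) return(c(x = NA_real_, y = NA_real_, z = NA_real_))
  c(x = mean(sel$x), y = mean(sel$y), z = mean(sel$z))
}

#' Euclidean distance between two region centers
#'
#' @param centerA,centerB length-3 centroids (um)
#' @return distance (um), NA if either center is absent
#' @export
regionCenterDistance <- function(centerA, centerB) {
  if (any(is.na(centerA)) || any(is.na(centerB))) return(NA_real_)
  sqrt(sum((as.numeric(centerA) - as.numeric(centerB))^2))
}

#' Progenitor-zone extent
#'
#' Arc length along the gonad axis from the distal tip to the most distal
#' position where more than one crescent-class cell falls within one
#' cell-diameter axial window; the onset of meiotic-entry morphology.  With
#' no crescent cells the full window length is returned, flagged.
#'
#' @param cells cell table with morphology
#' @param windowLength full analysis window length (um)
#' @param cellDiameter axial window for the >1-crescent rule (um)
#' @return extent (um) with attribute \code{flagged} = TRUE when no
#'   crescent boundary was found
#' @export
pzExtent <- function(cells, windowLength = 60, cellDiameter = 3.8) {
  cre <- sort(cells$axial_distance[cells$morphology == "crescent"])
  if (length(cre) >= 2) {
    for (i in seq_len(length(cre) - 1)) {
      if (cre[i + 1] - cre[i] <= cellDiameter) {
        out <- cre[i]
        attr(out, "flagged") <- FALSE
        return(out)
      }
    }
  }
  out <- windowLength
  attr(out, "flagged") <- TRUE
  out
}

#' Axial extent of a qualifying cell region
#'
#' Axial span (max minus min axial distance) of cells satisfying
#' \code{predicate}.
#'
#' @param cells cell table
#' @param predicate qualifying predicate
#' @return extent (um)
#' @export
regionExtent <- function(cells, predicate = function(df) df$n_ats >= 1) {
  sel <- cells[predicate(cells), , drop = FALSE]
  if (nrow(sel) == 0) stop("no qualifying cells")
  max(sel$axial_distance) - min(sel$axial_distance)
}
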