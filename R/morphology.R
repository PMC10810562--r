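# DTC/niche membrane morphology from the membrane-GFP channel: cap gaps,
# detached fragments, and the extents of long external processes (LEPs) and
# short intercalating processes (SIPs).

#' Segment the DTC membrane channel
#'
#' Otsu threshold, 3D 26-connectivity labeling, and extraction of the main
#' membrane body (largest connected component).  A light medial
#' representation of the main body (mean voxel position per axial slab and
#' angular sector) is returned as the skeleton used by process
#' measurements.
#'
#' @param arr membrane channel (3D array, photons)
#' @param stack the source \linkS4class{GonadStack}
#' @return list: mask (logical array), labels (integer array), main_id,
#'   main (data.frame of main-body voxel world coordinates x, y, z, rho,
#'   phi), skeleton (data.frame of medial points)
#' @export
segmentMembrane <- function(arr, stack) {
  v <- as.numeric(arr)
  thr <- .otsu(v[seq(1, length(v), by = 4)])
  mask <- arr > thr
  if (!any(mask)) stop("empty membrane mask: no signal above threshold")
  d <- dim(arr)
  lab <- .cpp_label3d(mask, d)
  pos <- which(lab > 0)
  sizes <- tabulate(lab[pos])
  main_id <- which.max(sizes)
  ix <- ((pos - 1) %% d[1]) + 1
  iy <- (((pos - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((pos - 1) %/% (d[1] * d[2])) + 1
  w <- .stack_world(stack, cbind(ix - 1, iy - 1, iz - 1))
  sel <- lab[pos] == main_id
  main <- data.frame(x = w[sel, 1], y = w[sel, 2], z = w[sel, 3])
  main$rho <- sqrt(main$y^2 + main$z^2)
  main$phi <- atan2(main$z, main$y) %% (2 * pi)
  # medial grid: mean position per (1 um axial slab, 10 deg sector)
  slab <- floor(main$x)
  sector <- floor(main$phi / (10 * pi / 180))
  key <- interaction(slab, sector, drop = TRUE)
  skeleton <- data.frame(
    x = tapply(main$x, key, mean),
    y = tapply(main$y, key, mean),
    z = tapply(main$z, key, mean),
    rho = tapply(main$rho, key, mean))
  rownames(skeleton) <- NULL
  list(mask = mask, labels = lab, main_id = main_id, main = main,
       skeleton = skeleton)
}

#' Count and measure gaps in the DTC cap
#'
#' The cap surface (distal membrane shell) is parameterized on an angular
#' grid around the gonad axis; maximal connected runs of uncovered sectors
#' are gaps, and each gap length is the geodesic arc length of its run at
#' the cap radius.  Wrap-around runs are handled.
#'
#' @param main main-body voxel table from \code{\link{segmentMembrane}}
#' @param geometry the \linkS4class{GonadGeometry}
#' @param capWindow axial window over which the cap is assessed (um)
#' @param angStepDeg angular grid resolution (degrees)
#' @param shellHalf radial half-thickness of the cap shell (um)
#' @return list: gap_count, gap_lengths (um), cap_radius
#' @export
findGaps <- function(main, geometry, capWindow = 5, angStepDeg = 2,
                     shellHalf = 0.6) {
  Rm <- .membrane_radius(geometry)
  cap <- main[main$x >= 0.5 & main$x <= capWindow &
                abs(main$rho - Rm) <= shellHalf, , drop = FALSE]
  nb <- ceiling(360 / angStepDeg)
  covered <- rep(FALSE, nb)
  if (nrow(cap) > 0) {
    b <- 1 + floor(cap$phi / (2 * pi) * nb)
    b[b > nb] <- nb
    cnt <- tabulate(b, nb)
    # count-based coverage: PSF blur bleeds a thin skirt of signal into gap
    # edges, so a sector counts as covered only with at least half the
    # typical voxel support
    covered <- cnt >= 0.5 * median(cnt[cnt > 0])
  }
  if (all(covered))
    return(list(gap_count = 0L, gap_lengths = numeric(0), cap_radius = Rm))
  if (!any(covered))
    return(list(gap_count = 1L, gap_lengths = 2 * pi * Rm, cap_radius = Rm))
  # uncovered runs with wrap-around: rotate so position 1 is covered
  shift <- which(covered)[1] - 1L
  cv <- covered[((seq_len(nb) - 1 + shift) %% nb) + 1]
  r <- rle(cv)
  runs <- r$lengths[!r$values]
  lens <- runs * (2 * pi / nb) * Rm
  list(gap_count = length(lens), gap_lengths = as.numeric(lens),
       cap_radius = Rm)
}

#' Detect detached membrane fragments
#'
#' Connected components disjoint from the main membrane body whose longest
#' axis exceeds \code{minLength}; each length is measured longwise as the
#' maximum pairwise distance between the component's voxel centers.
#'
#' @param seg result of \code{\link{segmentMembrane}}
#' @param stack the source \linkS4class{GonadStack}
#' @param minLength minimum longest-axis length (um, exclusive)
#' @return list: fragment_count, fragment_lengths (um)
#' @export
findFragments <- function(seg, stack, minLength = 0.5) {
  lab <- seg$labels
  d <- dim(lab)
  pos <- which(lab > 0 & lab != seg$main_id)
  if (!length(pos))
    return(list(fragment_count = 0L, fragment_lengths = numeric(0)))
  comp <- lab[pos]
  ix <- ((pos - 1) %% d[1]) + 1
  iy <- (((pos - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((pos - 1) %/% (d[1] * d[2])) + 1
  w <- .stack_world(stack, cbind(ix - 1, iy - 1, iz - 1))
  lens <- c()
  for (k in unique(comp)) {
    pw <- w[comp == k, , drop = FALSE]
    if (nrow(pw) > 1500) pw <- pw[seq(1, nrow(pw), by = 4), , drop = FALSE]
    len <- if (nrow(pw) == 1) 0 else max(dist(pw))
    if (len > minLength) lens <- c(lens, len)
  }
  list(fragment_count = length(lens),
       fragment_lengths = as.numeric(sort(lens)))
}

#' Measure LEP and SIP extents
#'
#' Process voxels are the main-body voxels proximal to the cap window.
#' Voxels within \code{surfaceDepth} of the tube surface are external
#' (LEP), deeper voxels are intercalating (SIP).  Each extent is the axial
#' distance from the distal-most point of the cap to the most proximal
#' voxel of the class; absent (NA) when a class has no voxels.
#'
#' @param main main-body voxel table from \code{\link{segmentMembrane}}
#' @param geometry the \linkS4class{GonadGeometry}
#' @param capWindow axial end of the cap region (um)
#' @param surfaceDepth depth below the tube surface separating external
#'   from intercalating voxels (um)
#' @return list: lep_extent, sip_extent (um, NA when absent)
#' @export
processExtents <- function(main, geometry, capWindow = 5,
                           surfaceDepth = 1.5) {
  tip <- min(main$x)
  proc <- main[main$x > capWindow, , drop = FALSE]
  lep <- proc$x[proc$rho >= geometry@tubeRadius - surfaceDepth]
  sip <- proc$x[proc$rho < geometry@tubeRadius - surfaceDepth]
  list(lep_extent = if (length(lep)) max(lep) - tip else NA_real_,
       sip_extent = if (length(sip)) max(sip) - tip else NA_real_)
}

#' Quantify DTC membrane morphology of a gonad stack
#'
#' Full membrane pipeline: segmentation of the membrane channel, cap gap
#' census, detached fragment census, and LEP/SIP extents.
#'
#' @param stack a \linkS4class{GonadStack} with a membrane channel
#' @param geometry the \linkS4class{GonadGeometry}
#' @param ... passed to the measurement functions
#' @return list: gap_count, gap_lengths, fragment_count, fragment_lengths,
#'   lep_extent, sip_extent
#' @export
dtcMorphology <- function(stack, geometry, ...) {
  arr <- getChannel(stack, "membrane")
  seg <- segmentMembrane(arr, stack)
  gaps <- findGaps(seg$main, geometry, ...)
  frags <- findFragments(seg, stack)
  ext <- processExtents(seg$main, geometry)
  c(gaps[c("gap_count", "gap_lengths")],
    frags, ext)
}
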