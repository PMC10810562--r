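# smFISH spot detection: Gaussian local peak finding, the two background
# ratio filters, intron-exon colocalization, ATS calling, single-mRNA
# normalization and capped-Voronoi assignment of spots to cells.

# logical germline mask (voxels inside the gonad tube) for a stack
.germline_mask <- function(stack, geometry) {
  d <- dim(stack@img)
  xs <- (seq_len(d[1]) - 0.5) * stack@pixelSizeXY - .X_MARGIN
  ys <- (seq_len(d[2]) - 0.5 - d[2] / 2) * stack@pixelSizeXY
  zs <- (seq_len(d[3]) - 0.5 - d[3] / 2) * stack@zStep
  rho2 <- outer(ys^2, zs^2, "+")
  inside_yz <- rho2 <= geometry@tubeRadius^2
  mask <- array(FALSE, d[1:3])
  xok <- xs <= geometry@tubeLength
  idx <- which(inside_yz) - 1L
  if (length(idx))
    mask[as.vector(outer(which(xok), idx * d[1], "+"))] <- TRUE
  mask
}

# mean of arr in the ellipsoidal shell between inner and outer radii around
# continuous voxel center v (0-based); used for local background
.shell_mean <- function(arr, v, r1xy, r3xy, r1z, r3z) {
  d <- dim(arr)
  x0 <- max(1, floor(v[1] + 1 - r3xy)); x1 <- min(d[1], ceiling(v[1] + 1 + r3xy))
  y0 <- max(1, floor(v[2] + 1 - r3xy)); y1 <- min(d[2], ceiling(v[2] + 1 + r3xy))
  z0 <- max(1, floor(v[3] + 1 - r3z)); z1 <- min(d[3], ceiling(v[3] + 1 + r3z))
  xs <- (x0:x1) - (v[1] + 1); ys <- (y0:y1) - (v[2] + 1); zs <- (z0:z1) - (v[3] + 1)
  q1 <- outer(outer(xs^2 / r1xy^2, ys^2 / r1xy^2, "+"), zs^2 / r1z^2, "+")
  q3 <- outer(outer(xs^2 / r3xy^2, ys^2 / r3xy^2, "+"), zs^2 / r3z^2, "+")
  w <- arr[x0:x1, y0:y1, z0:z1]
  sel <- q3 <= 1 & q1 > 1
  if (!any(sel)) return(NA_real_)
  mean(w[sel])
}

#' Detect candidate RNA spots as 3D local intensity maxima
#'
#' Matched-filter peak detection: the channel is smoothed with the Gaussian
#' PSF, 3D local maxima above an adaptive floor (median plus
#' \code{nMads} MADs of the smoothed germline signal) are kept, spot centers
#' are refined per axis by a 3-point parabolic fit, and the raw intensity is
#' the local-background-subtracted integral over an ellipsoidal ball of
#' 2 PSF sigmas.  The local background is the mean in the 1-3 spot-radius
#' shell.
#'
#' @param arr channel array (3D, photons)
#' @param stack the source \linkS4class{GonadStack}
#' @param mask logical array marking the germline (spots outside are
#'   dropped; also defines the background statistics)
#' @param psfSigmaXY,psfSigmaZ PSF sigmas (um)
#' @param nMads adaptive floor in MADs above the median
#' @return data.frame: x, y, z (um), peak_value (photons, raw channel),
#'   raw_intensity (integrated photons), local_bg
#' @export
localPeaks <- function(arr, stack, mask, psfSigmaXY = 0.15,
                       psfSigmaZ = 0.45, nMads = 6) {
  stopifnot(any(mask))
  d <- dim(arr)
  sxy <- psfSigmaXY / stack@pixelSizeXY
  sz <- psfSigmaZ / stack@zStep
  sm <- .cpp_blur3d(arr, d, sxy, sxy, sz)
  bgv <- sm[mask]
  floorVal <- median(bgv) + nMads * mad(bgv)
  pk <- .cpp_local_maxima3d(sm, d, floorVal)
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      peak_value = numeric(0), raw_intensity = numeric(0),
                      local_bg = numeric(0)))
  keep <- mask[pk[, 1:3, drop = FALSE]]
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      peak_value = numeric(0), raw_intensity = numeric(0),
                      local_bg = numeric(0)))
  rxy <- 2 * sxy; rz <- 2 * sz
  out <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    ix <- pk[i, 1]; iy <- pk[i, 2]; iz <- pk[i, 3]
    v0 <- c(ix, iy, iz) - 1   # 0-based
    # 3-point parabolic sub-voxel refinement on the smoothed stack
    sub <- v0
    for (axis in 1:3) {
      idx <- c(ix, iy, iz)
      vm <- idx; vm[axis] <- vm[axis] - 1L
      vp <- idx; vp[axis] <- vp[axis] + 1L
      a <- sm[matrix(vm, 1)]; b <- sm[matrix(idx, 1)]; cc <- sm[matrix(vp, 1)]
      den <- a - 2 * b + cc
      if (is.finite(den) && den < 0) sub[axis] <- sub[axis] + 0.5 * (a - cc) / den
    }
    lb <- .shell_mean(arr, sub, rxy, 3 * rxy, rz, 3 * rz)
    if (!is.finite(lb)) lb <- median(bgv)
    bs <- .cpp_ball_sum(arr, d, matrix(sub, 1), rxy, rz)
    raw <- bs[1, 1] - lb * bs[1, 2]
    w <- .stack_world(stack, matrix(sub, 1))
    out[[i]] <- c(w[1], w[2], w[3], arr[ix, iy, iz], raw, lb)
  }
  m <- do.call(rbind, out)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], peak_value = m[, 4],
             raw_intensity = m[, 5], local_bg = m[, 6])
}

#' Apply the two background-ratio candidate filters
#'
#' Keeps candidates whose peak intensity exceeds the mean overall germline
#' background by the factor \code{overallMin} (> 1.0) and the local
#' background (the 1-3 spot-radius shell) by \code{localMin} (> 1.05).
#'
#' @param cands data.frame from \code{\link{localPeaks}}
#' @param arr channel array
#' @param mask germline mask (defines the overall background)
#' @param overallMin signal-to-overall-background threshold
#' @param localMin signal-to-local-background threshold
#' @return filtered data.frame with columns overall_ratio, local_ratio added
#' @export
scoreCandidates <- function(cands, arr, mask, overallMin = 1.0,
                            localMin = 1.05) {
  if (nrow(cands) == 0) {
    cands$overall_ratio <- numeric(0); cands$local_ratio <- numeric(0)
    return(cands)
  }
  overall <- mean(arr[mask])
  cands$overall_ratio <- cands$peak_value / overall
  cands$local_ratio <- cands$peak_value / cands$local_bg
  out <- cands[cands$overall_ratio > overallMin &
                 cands$local_ratio > localMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutual-nearest-neighbour colocalization of two spot lists
#'
#' Pairs spots from two channels when each is the other's nearest neighbour
#' and their distance is within \code{tol}; every spot joins at most one
#' pair.
#'
#' @param a,b data.frames with x, y, z columns (um)
#' @param tol pairing tolerance (um)
#' @return data.frame with columns ia, ib (row indices into a and b) and
#'   dist
#' @export
colocalizeSpots <- function(a, b, tol = 0.4) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(ia = integer(0), ib = integer(0), dist = numeric(0)))
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rep(1, nrow(bm))) +
    outer(rep(1, nrow(am)), rowSums(bm^2)) - 2 * am %*% t(bm)
  nn_a <- max.col(-d2)                     # nearest b for each a
  nn_b <- max.col(-t(d2))                  # nearest a for each b
  ia <- which(nn_b[nn_a] == seq_len(nrow(am)))
  ib <- nn_a[ia]
  dd <- sqrt(pmax(0, d2[cbind(ia, ib)]))
  keep <- dd <= tol
  data.frame(ia = ia[keep], ib = ib[keep], dist = dd[keep])
}

#' Classify exon-channel spots as cytoplasmic or nuclear mRNA and compute
#' the single-mRNA intensity unit
#'
#' Exon candidates inside a nuclear sphere are nuclear; the rest are
#' cytoplasmic mRNAs.  The mean raw intensity of cytoplasmic mRNAs defines
#' 1 a.u. (the single-mRNA unit) per gonad, so the cytoplasmic mean in a.u.
#' is exactly 1.
#'
#' @param exonCands scored exon candidates
#' @param nuclei segmented nuclei (x, y, z, r)
#' @return list: \code{spots} (with spot_class, nucleus_id, intensity_au)
#'   and \code{single_mrna_intensity}
#' @export
callMrna <- function(exonCands, nuclei) {
  n <- nrow(exonCands)
  if (n == 0) stop("no exon candidates: single-mRNA unit undefined")
  nuc_id <- rep(NA_integer_, n)
  if (nrow(nuclei) > 0) {
    nm <- as.matrix(nuclei[, c("x", "y", "z")])
    sm <- as.matrix(exonCands[, c("x", "y", "z")])
    for (i in seq_len(n)) {
      dd <- sqrt(colSums((t(nm) - sm[i, ])^2))
      j <- which(dd <= nuclei$r)
      if (length(j)) nuc_id[i] <- nuclei$nucleus_id[j[which.min(dd[j])]]
    }
  }
  cls <- ifelse(is.na(nuc_id), "mrna_cyto", "mrna_nuclear")
  cyto <- which(cls == "mrna_cyto" & exonCands$raw_intensity > 0)
  if (length(cyto) == 0)
    stop("no cytoplasmic mRNA spots: normalization undefined")
  unit <- mean(exonCands$raw_intensity[cyto])
  out <- exonCands
  out$spot_class <- cls
  out$nucleus_id <- nuc_id
  out$intensity_au <- out$raw_intensity / unit
  list(spots = out, single_mrna_intensity = unit)
}

#' Call true active transcription sites
#'
#' An intron-channel candidate is a true ATS when (1) it lies inside a
#' nuclear sphere, (2) it colocalizes with an exon-channel nuclear spot, and
#' (3) both the intron and the exon intensity are at least as bright as a
#' single mRNA (1 a.u.).  The reported ATS intensity is the exon-channel
#' intensity in a.u.
#'
#' @param intronCands scored intron candidates
#' @param exonSpots exon spots as returned by \code{\link{callMrna}}
#' @param nuclei segmented nuclei
#' @param singleMrna single-mRNA intensity unit (raw photons)
#' @param tol colocalization tolerance (um)
#' @return data.frame of true ATS (spot_class "true_ats"), with nucleus_id
#'   and intensity_au (exon-based)
#' @export
callAts <- function(intronCands, exonSpots, nuclei, singleMrna, tol = 0.4) {
  if (is.null(nuclei) || nrow(nuclei) == 0)
    stop("nuclei are required to call ATS")
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      raw_intensity = numeric(0), intensity_au = numeric(0),
                      intron_au = numeric(0), nucleus_id = integer(0),
                      spot_class = character(0))
  if (nrow(intronCands) == 0) return(empty)
  # (1) localized to a nucleus
  nm <- as.matrix(nuclei[, c("x", "y", "z")])
  im <- as.matrix(intronCands[, c("x", "y", "z")])
  nuc_id <- rep(NA_integer_, nrow(intronCands))
  for (i in seq_len(nrow(intronCands))) {
    dd <- sqrt(colSums((t(nm) - im[i, ])^2))
    j <- which(dd <= nuclei$r)
    if (length(j)) nuc_id[i] <- nuclei$nucleus_id[j[which.min(dd[j])]]
  }
  sel <- which(!is.na(nuc_id))
  if (!length(sel)) return(empty)
  # (2) colocalized with an exon nuclear spot
  exo <- exonSpots[exonSpots$spot_class == "mrna_nuclear", , drop = FALSE]
  prs <- colocalizeSpots(intronCands[sel, , drop = FALSE], exo, tol)
  if (!nrow(prs)) return(empty)
  # (3) both at least as bright as one mRNA
  intron_au <- intronCands$raw_intensity[sel[prs$ia]] / singleMrna
  exon_au <- exo$intensity_au[prs$ib]
  keep <- intron_au >= 1 & exon_au >= 1
  if (!any(keep)) return(empty)
  i_idx <- sel[prs$ia[keep]]
  data.frame(x = intronCands$x[i_idx], y = intronCands$y[i_idx],
             z = intronCands$z[i_idx],
             raw_intensity = exo$raw_intensity[prs$ib[keep]],
             intensity_au = exon_au[keep],
             intron_au = intron_au[keep],
             nucleus_id = nuc_id[i_idx],
             spot_class = "true_ats")
}

#' Assign spots to germ cells by the radius-capped Voronoi rule
#'
#' Each spot is assigned to the nucleus with the nearest center, provided
#' that distance does not exceed \code{capRadius}; this capped
#' nearest-center partition is the bounded 3D Voronoi cell model of germ
#' cell boundaries.  Ties go to the lower nucleus_id.
#'
#' @param spots data.frame with x, y, z
#' @param nuclei data.frame with nucleus_id, x, y, z
#' @param capRadius maximum distance from the nucleus center (um)
#' @return spots with cell_id column (NA when unassigned)
#' @export
assignToCells <- function(spots, nuclei, capRadius = 3) {
  spots$cell_id <- rep(NA_integer_, nrow(spots))
  if (nrow(spots) == 0 || nrow(nuclei) == 0) return(spots)
  nm <- as.matrix(nuclei[, c("x", "y", "z")])
  sm <- as.matrix(spots[, c("x", "y", "z")])
  ord <- order(nuclei$nucleus_id)
  nm <- nm[ord, , drop = FALSE]
  ids <- nuclei$nucleus_id[ord]
  for (i in seq_len(nrow(spots))) {
    dd <- sqrt(colSums((t(nm) - sm[i, ])^2))
    j <- which.min(dd)   # first minimum = lowest nucleus_id on ties
    if (dd[j] <= capRadius) spots$cell_id[i] <- ids[j]
  }
  spots
}

#' Detect and classify all RNA spots of a gonad stack
#'
#' Full smFISH pipeline for one gonad: independent peak detection in the
#' intron and exon channels, the two background-ratio filters, cytoplasmic
#' single-mRNA normalization, ATS calling with intron-exon colocalization,
#' and capped-Voronoi assignment of cytoplasmic mRNAs to cells.
#'
#' @param stack a \linkS4class{GonadStack} with intron and exon channels
#' @param nuclei segmented nuclei (from \code{\link{segmentNuclei}})
#' @param geometry the \linkS4class{GonadGeometry} (germline mask)
#' @param psfSigmaXY,psfSigmaZ PSF sigmas (um)
#' @param colocTol intron-exon pairing tolerance (um)
#' @param capRadius Voronoi cap radius (um)
#' @return list: \code{spots} (all classified spots), \code{ats} (true
#'   ATS), \code{single_mrna_intensity}
#' @export
detectSpots <- function(stack, nuclei, geometry, psfSigmaXY = 0.15,
                        psfSigmaZ = 0.45, colocTol = 0.4, capRadius = 3) {
  mask <- .germline_mask(stack, geometry)
  intron <- getChannel(stack, "intron")
  exon <- getChannel(stack, "exon")
  ic <- scoreCandidates(localPeaks(intron, stack, mask, psfSigmaXY,
                                   psfSigmaZ), intron, mask)
  ec <- scoreCandidates(localPeaks(exon, stack, mask, psfSigmaXY,
                                   psfSigmaZ), exon, mask)
  mr <- callMrna(ec, nuclei)
  ats <- callAts(ic, mr$spots, nuclei, mr$single_mrna_intensity, colocTol)
  cyto <- mr$spots[mr$spots$spot_class == "mrna_cyto", , drop = FALSE]
  cyto <- assignToCells(cyto, nuclei, capRadius)
  if (nrow(ats) > 0) ats$cell_id <- ats$nucleus_id
  spots <- rbind(
    cbind(channel = "exon", cyto[, c("x", "y", "z", "raw_intensity",
                                     "intensity_au", "spot_class",
                                     "nucleus_id", "cell_id")]),
    if (nrow(ats) > 0)
      cbind(channel = "intron",
            ats[, c("x", "y", "z", "raw_intensity", "intensity_au",
                    "spot_class", "nucleus_id", "cell_id")]))
  spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
  rownames(spots) <- NULL
  list(spots = spots, ats = ats,
       single_mrna_intensity = mr$single_mrna_intensity)
}
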