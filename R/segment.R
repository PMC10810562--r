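# Nucleus reconstruction from the DAPI channel: per-plane normalization and
# circular Hough detection, cross-plane chain assembly into best-fit spheres,
# DAPI summation, morphology classification and DTC localization.

# Otsu threshold of a numeric vector (256-bin histogram split maximising
# between-class variance).
.otsu <- function(v, nbins = 256L) {
  r <- range(v, finite = TRUE)
  if (diff(r) == 0) return(r[1])
  h <- as.numeric(
    tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)), nbins))
  w <- cumsum(h); m <- cumsum(h * seq_len(nbins))
  mt <- m[nbins]; wt <- w[nbins]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  r[1] + k / nbins * diff(r)
}

# binary erosion of a logical matrix by a square of half-width `n`
.erode <- function(mask, n = 2L) {
  out <- mask
  for (d in seq_len(n)) {
    nr <- nrow(out); nc <- ncol(out)
    sh <- out
    sh[-1, ] <- sh[-1, ] & out[-nr, ]; sh[-nr, ] <- sh[-nr, ] & out[-1, ]
    sh[, -1] <- sh[, -1] & out[, -nc]; sh[, -nc] <- sh[, -nc] & out[, -1]
    sh[c(1, nr), ] <- FALSE; sh[, c(1, nc)] <- FALSE
    out <- sh
  }
  out
}

#' Normalize a DAPI plane to its nucleus-free background
#'
#' Divides a z-plane by the mean intensity of its background region, so
#' nucleus-free areas average 1.0.  The background mask is the set of pixels
#' below the plane's Otsu split, eroded by 2 pixels to keep nuclear rims out
#' of the estimate.
#'
#' @param plane numeric matrix (one z-plane)
#' @return normalized plane with attribute \code{background} (the divisor)
#' @examples
#' p <- matrix(10, 40, 40); p[15:25, 15:25] <- 100
#' b <- attr(normalizeDapiPlane(p), "background")  # 10
#' @export
normalizeDapiPlane <- function(plane) {
  v <- as.numeric(plane)
  if (length(v) > 20000) v <- v[seq(1, length(v), by = 4)]  # otsu subsample
  thr <- .otsu(v)
  mask <- .erode(plane < thr, 2L)
  if (!any(mask)) mask <- plane < thr      # speckle background: skip erosion
  if (!any(mask)) {
    # uniform plane: everything is background
    if (diff(range(plane)) < 1e-9 && mean(plane) > 0) {
      out <- plane / mean(plane)
      attr(out, "background") <- mean(plane)
      return(out)
    }
    stop("empty background mask: plane has no nucleus-free region")
  }
  bg <- mean(plane[mask])
  if (bg <= 0) stop("non-positive background mean")
  out <- plane / bg
  attr(out, "background") <- bg
  out
}

#' Detect candidate nuclear circles in one plane
#'
#' Circular Hough transform with Sobel gradient voting over the radius range,
#' the per-plane primitive of nucleus reconstruction.  Detections are scored
#' by normalized accumulator votes (fraction of the circumference supported),
#' sorted by score, and greedily suppressed so no two kept circles have
#' centers closer than \code{rMin}.
#'
#' @param plane normalized DAPI plane (matrix, x by y)
#' @param pixelSize lateral pixel size (um)
#' @param rMin,rMax radius search range (um)
#' @param sensitivity minimum normalized vote score in (0, 1]
#' @param gradThresh Sobel gradient magnitude threshold (normalized units)
#' @return data.frame x, y (um, plane coordinates), r (um), score
#' @export
detectPlaneCircles <- function(plane, pixelSize, rMin = 1.0, rMax = 3.5,
                               sensitivity = 0.12, gradThresh = 1.0) {
  stopifnot(rMin < rMax)
  cand <- .cpp_hough_circles(plane, rMin / pixelSize, rMax / pixelSize,
                             gradThresh, sensitivity)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      score = numeric(0)))
  df <- data.frame(x = (cand[, "x"] + 0.5) * pixelSize,
                   y = (cand[, "y"] + 0.5) * pixelSize,
                   r = cand[, "r"] * pixelSize,
                   score = cand[, "score"])
  df <- df[order(-df$score, df$x, df$y), , drop = FALSE]
  supp <- 0.8 * rMin   # suppression radius; softer than rMin so that packed
  keep <- logical(nrow(df))   # neighbours do not erase each other
  for (i in seq_len(nrow(df))) {
    if (i == 1) { keep[1] <- TRUE; next }
    k <- which(keep)
    d2 <- (df$x[k] - df$x[i])^2 + (df$y[k] - df$y[i])^2
    keep[i] <- all(d2 >= supp^2)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best-fit sphere through a stack of circles: r_i^2 = R^2 - (z_i - z0)^2
# is linear in (z0, R^2); returns center z and radius
.fit_sphere_z <- function(z, r) {
  if (length(z) < 2 || diff(range(z)) == 0)
    return(c(z0 = mean(z), R = max(r)))
  fit <- lm.fit(cbind(1, z), r^2 + z^2)   # r^2 + z^2 = (R^2 - z0^2) + 2 z0 z
  b <- fit$coefficients[2]; a <- fit$coefficients[1]
  z0 <- b / 2
  R2 <- a + z0^2
  if (!is.finite(R2) || R2 <= 0) return(c(z0 = mean(z), R = max(r)))
  # clamp: center must lie within one z-step of the observed span
  z0 <- min(max(z0, min(z) - 1), max(z) + 1)
  c(z0 = z0, R = sqrt(R2))
}

#' Assemble per-plane circles into 3D spherical nuclei
#'
#' Greedy chaining of circles across consecutive z-planes: a circle joins the
#' chain whose running mean center is nearest (within \code{maxSpread} in XY)
#' among chains last extended in the previous plane.  Chains qualify as
#' nuclei when (1) they span at least \code{minPlanes} consecutive planes and
#' (2) the maximum XY deviation of their circle centers from the chain
#' centroid stays below \code{maxSpread}.  The nuclear sphere is the best
#' fit through the circle stack (score-weighted XY center; z-center and
#' radius from the circle-radius profile).  Chains whose fitted spheres
#' overlap by more than a quarter of the smaller radius are merged (the
#' higher-scoring one is kept).
#'
#' @param circles data.frame with columns z_index (integer plane), x, y, r
#'   (um) and score; plane coordinates as from
#'   \code{\link{detectPlaneCircles}}
#' @param zStep axial step (um)
#' @param minPlanes minimum number of consecutive planes
#' @param maxSpread maximum XY center spread (um)
#' @return data.frame of nuclei: nucleus_id, x, y, z (um), r (um), n_planes,
#'   spread, score
#' @export
assembleNuclei <- function(circles, zStep, minPlanes = 4L, maxSpread = 0.5) {
  empty <- data.frame(nucleus_id = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), r = numeric(0),
                      n_planes = integer(0), spread = numeric(0),
                      score = numeric(0))
  if (nrow(circles) == 0) return(empty)
  # canonical order: permutation invariance of the input
  circles <- circles[order(circles$z_index, circles$x, circles$y), ,
                     drop = FALSE]
  chains <- list()   # each: list(idx, last_z, mx, my)
  open <- integer(0) # chains extendable into the current plane
  for (zi in sort(unique(circles$z_index))) {
    rows <- which(circles$z_index == zi)
    open <- open[vapply(chains[open], function(ch) ch$last_z == zi - 1L, TRUE)]
    assigned <- integer(length(rows))
    if (length(open) && length(rows)) {
      cand <- expand.grid(ri = seq_along(rows), ci = seq_along(open))
      cand$d <- sqrt((circles$x[rows[cand$ri]] -
                        vapply(chains[open[cand$ci]], `[[`, 0, "mx"))^2 +
                     (circles$y[rows[cand$ri]] -
                        vapply(chains[open[cand$ci]], `[[`, 0, "my"))^2)
      cand <- cand[cand$d <= maxSpread, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_c <- logical(length(open))
      for (k in seq_len(nrow(cand))) {
        ri <- cand$ri[k]; ci <- cand$ci[k]
        if (assigned[ri] || used_c[ci]) next
        assigned[ri] <- open[ci]; used_c[ci] <- TRUE
      }
    }
    for (j in seq_along(rows)) {
      row <- rows[j]
      if (assigned[j]) {
        ch <- chains[[assigned[j]]]
        ch$idx <- c(ch$idx, row)
        ch$last_z <- zi
        n <- length(ch$idx)
        ch$mx <- mean(circles$x[ch$idx]); ch$my <- mean(circles$y[ch$idx])
        chains[[assigned[j]]] <- ch
      } else {
        chains[[length(chains) + 1L]] <- list(idx = row, last_z = zi,
                                              mx = circles$x[row],
                                              my = circles$y[row])
        assigned[j] <- length(chains)
      }
    }
    open <- unique(c(open[!open %in% assigned], assigned))
    open <- open[vapply(chains[open], function(ch) ch$last_z == zi, TRUE)]
  }
  recs <- NULL
  for (ch in chains) {
    idx <- ch$idx
    if (length(idx) < minPlanes) next
    cx <- circles$x[idx]; cy <- circles$y[idx]
    spread <- max(sqrt((cx - mean(cx))^2 + (cy - mean(cy))^2))
    if (spread >= maxSpread) next
    w <- circles$score[idx]
    zw <- (circles$z_index[idx] - 0.5) * zStep
    fit <- .fit_sphere_z(zw, circles$r[idx])
    recs <- rbind(recs, data.frame(
      x = sum(cx * w) / sum(w), y = sum(cy * w) / sum(w),
      z = unname(fit["z0"]), r = unname(fit["R"]),
      n_planes = length(idx), spread = spread, score = mean(w)))
  }
  if (is.null(recs)) return(empty)
  recs <- .merge_overlaps(recs)
  recs <- recs[order(recs$x, recs$y, recs$z), , drop = FALSE]
  recs <- cbind(nucleus_id = seq_len(nrow(recs)), recs)
  rownames(recs) <- NULL
  recs
}

# merge rule: no two nuclei may overlap by > 25% of the smaller radius;
# the higher-scoring record survives (rescued records score last)
.merge_overlaps <- function(recs) {
  recs <- recs[order(-ifelse(is.na(recs$score), -Inf, recs$score)), ,
               drop = FALSE]
  keep <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    if (i == 1) { keep[1] <- TRUE; next }
    k <- which(keep)
    d <- sqrt((recs$x[k] - recs$x[i])^2 + (recs$y[k] - recs$y[i])^2 +
              (recs$z[k] - recs$z[i])^2)
    ovl <- recs$r[k] + recs$r[i] - d
    keep[i] <- all(ovl <= 0.25 * pmin(recs$r[k], recs$r[i]))
  }
  recs[keep, , drop = FALSE]
}

# --- voxel geometry helpers for world-coordinate measurements ---------------

.stack_vox <- function(stack, p) {
  d <- dim(stack@img)
  cbind((p[, 1] + .X_MARGIN) / stack@pixelSizeXY - 0.5,
        p[, 2] / stack@pixelSizeXY + d[2] / 2 - 0.5,
        p[, 3] / stack@zStep + d[3] / 2 - 0.5)
}

.stack_world <- function(stack, v) {
  d <- dim(stack@img)
  cbind((v[, 1] + 0.5) * stack@pixelSizeXY - .X_MARGIN,
        (v[, 2] + 0.5 - d[2] / 2) * stack@pixelSizeXY,
        (v[, 3] + 0.5 - d[3] / 2) * stack@zStep)
}

.ball_sum <- function(arr, stack, centers, r_um, rz_um = r_um) {
  v <- .stack_vox(stack, centers)
  res <- .cpp_ball_sum(arr, dim(arr), v, r_um / stack@pixelSizeXY,
                       rz_um / stack@zStep)
  list(sum = res[, 1], n = res[, 2])
}

#' Sum the DAPI signal inside a nuclear sphere
#'
#' Sums normalized-channel voxels whose centers lie inside the nuclear
#' sphere; spheres clipped by the stack boundary are summed over the
#' in-bounds part and flagged.
#'
#' @param nuclei data.frame with x, y, z, r (um)
#' @param arr normalized DAPI channel (3D array)
#' @param stack the \linkS4class{GonadStack} the channel came from (voxel
#'   calibration)
#' @return input with columns dapi_sum, n_voxels, clipped
#' @export
sumDapi <- function(nuclei, arr, stack) {
  if (nrow(nuclei) == 0) {
    nuclei$dapi_sum <- numeric(0); nuclei$n_voxels <- numeric(0)
    nuclei$clipped <- logical(0)
    return(nuclei)
  }
  d <- dim(arr)
  out <- numeric(nrow(nuclei)); nv <- numeric(nrow(nuclei))
  clip <- logical(nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    ctr <- as.matrix(nuclei[i, c("x", "y", "z")])
    bs <- .ball_sum(arr, stack, ctr, nuclei$r[i])
    out[i] <- bs$sum; nv[i] <- bs$n
    v <- .stack_vox(stack, ctr)
    rv <- nuclei$r[i] / c(stack@pixelSizeXY, stack@pixelSizeXY, stack@zStep)
    clip[i] <- any(v - rv < -0.5) || any(v + rv > d[1:3] - 0.5)
  }
  nuclei$dapi_sum <- out; nuclei$n_voxels <- nv; nuclei$clipped <- clip
  nuclei
}

# mid-plane mask statistics: eccentricity of the bright nuclear mask from
# second moments, plus the geometry of the dark sub-region (area and offset
# of its centroid from the nucleus center, in radius units).  The dark
# region separates the three morphologies: germ "donut" nuclei have a
# centered dark nucleolar core, crescents an offset dark lune, the DTC none.
.midplane_shape <- function(arr, stack, nucleus, thr = 1.8,
                            darkFrac = 0.62) {
  d <- dim(arr)
  v <- .stack_vox(stack, as.matrix(nucleus[, c("x", "y", "z")]))
  zi <- min(max(1L, round(v[3] + 1)), d[3])
  rpx <- nucleus$r / stack@pixelSizeXY
  half <- ceiling(1.8 * rpx)
  x0 <- max(1, round(v[1] + 1) - half); x1 <- min(d[1], round(v[1] + 1) + half)
  y0 <- max(1, round(v[2] + 1) - half); y1 <- min(d[2], round(v[2] + 1) + half)
  win <- arr[x0:x1, y0:y1, zi]
  xs <- seq(x0, x1) - (v[1] + 1); ys <- seq(y0, y1) - (v[2] + 1)
  r2 <- outer(xs^2, ys^2, "+")
  own <- r2 <= (1.35 * rpx)^2          # exclude packed neighbours
  bright <- win > thr
  mask <- bright & own
  if (sum(mask) < 8)
    return(list(ecc = 0, solidity = 1, dark_off = NA_real_, dark_area = 0))
  idx <- which(mask, arr.ind = TRUE)
  cv <- stats::cov(idx)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  hull <- grDevices::chull(idx)
  hp <- idx[hull, , drop = FALSE]
  harea <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                   c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
  solidity <- if (harea > 0) min(1, nrow(idx) / harea) else 1
  # dark sub-region: below darkFrac of the rim level, inside the nucleus and
  # enclosed by bright pixels in all four axis directions (a true core, not
  # background beyond an elliptical rim)
  ring <- (r2 <= (0.95 * rpx)^2) & (r2 >= (0.60 * rpx)^2)
  rim <- if (any(ring & bright)) mean(win[ring & bright]) else NA_real_
  if (!is.finite(rim)) rim <- mean(win[own])
  encl_l <- apply(bright, 2, cummax)
  encl_r <- apply(bright[rev(seq_len(nrow(bright))), , drop = FALSE], 2,
                  cummax)[rev(seq_len(nrow(bright))), , drop = FALSE]
  encl_u <- t(apply(bright, 1, cummax))
  encl_d <- t(apply(bright[, rev(seq_len(ncol(bright))), drop = FALSE], 1,
                    cummax))[, rev(seq_len(ncol(bright))), drop = FALSE]
  enclosed <- (encl_l > 0) & (encl_r > 0) & (encl_u > 0) & (encl_d > 0)
  dark <- (r2 <= (0.85 * rpx)^2) & (win < darkFrac * rim) & enclosed
  if (sum(dark) < 5)
    return(list(ecc = ecc, solidity = solidity, dark_off = NA_real_,
                dark_area = 0))
  di <- which(dark, arr.ind = TRUE)
  cx <- mean(xs[di[, 1]]); cy <- mean(ys[di[, 2]])
  list(ecc = ecc, solidity = solidity,
       dark_off = sqrt(cx^2 + cy^2) / rpx, dark_area = sum(dark))
}

# central-to-rim intensity ratio inside the sphere
.core_rim_ratio <- function(arr, stack, nucleus) {
  ctr <- as.matrix(nucleus[, c("x", "y", "z")])
  core <- .ball_sum(arr, stack, ctr, 0.35 * nucleus$r)
  outer_ <- .ball_sum(arr, stack, ctr, 0.95 * nucleus$r)
  inner_ <- .ball_sum(arr, stack, ctr, 0.70 * nucleus$r)
  rim_sum <- outer_$sum - inner_$sum
  rim_n <- outer_$n - inner_$n
  if (rim_n <= 0 || core$n <= 0) return(NA_real_)
  (core$sum / core$n) / (rim_sum / rim_n)
}

#' Classify nuclear morphology from DAPI appearance
#'
#' Decision tree on three mid-plane/3D features: germ (mitotic) nuclei show
#' the round "donut" look (dark nucleolar center, low eccentricity); the DTC
#' nucleus lacks the dark center and is elliptical; meiotic-entry nuclei are
#' crescent-shaped (low mask solidity).  Thresholds are recorded tuning
#' decisions of this implementation.
#'
#' @param nuclei data.frame of assembled nuclei
#' @param arr normalized DAPI channel
#' @param stack the source \linkS4class{GonadStack}
#' @param eccMin minimum mid-plane eccentricity for a DTC candidate
#' @param darkOffsetMax dark regions whose centroid sits farther than this
#'   (in radius units) from the nucleus center mark a crescent
#' @param solidityMin bright masks less solid (convex) than this mark a
#'   crescent
#' @param coreRatioBright minimum central-to-rim ratio for a DTC candidate
#'   (the DTC center is at least as bright as its rim)
#' @return input with columns core_ratio, eccentricity, solidity,
#'   dark_offset, morphology (mitotic / crescent / dtc_candidate / unknown)
#'   and dtc_score
#' @export
classifyMorphology <- function(nuclei, arr, stack, eccMin = 0.60,
                               darkOffsetMax = 0.40, solidityMin = 0.80,
                               coreRatioBright = 1.08) {
  n <- nrow(nuclei)
  nuclei$core_ratio <- rep(NA_real_, n)
  nuclei$eccentricity <- rep(NA_real_, n)
  nuclei$solidity <- rep(NA_real_, n)
  nuclei$dark_offset <- rep(NA_real_, n)
  nuclei$morphology <- rep("unknown", n)
  nuclei$dtc_score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nuc <- nuclei[i, ]
    ratio <- .core_rim_ratio(arr, stack, nuc)
    shp <- .midplane_shape(arr, stack, nuc)
    nuclei$core_ratio[i] <- ratio
    nuclei$eccentricity[i] <- shp$ecc
    nuclei$solidity[i] <- shp$solidity
    nuclei$dark_offset[i] <- shp$dark_off
    nuclei$dtc_score[i] <- ifelse(is.na(ratio), 0, ratio) * shp$ecc *
      shp$solidity   # the DTC mask is convex; fused clusters are not
    if (is.na(ratio)) next
    has_dark <- shp$dark_area >= 5
    if (has_dark && !is.na(shp$dark_off) && shp$dark_off <= darkOffsetMax) {
      nuclei$morphology[i] <- "mitotic"        # centered dark core: donut
    } else if (has_dark) {
      nuclei$morphology[i] <- "crescent"       # offset dark lune
    } else if (shp$solidity < solidityMin) {
      nuclei$morphology[i] <- "crescent"       # concave bright mask
    } else if (shp$ecc >= eccMin && ratio >= coreRatioBright) {
      nuclei$morphology[i] <- "dtc_candidate"  # bright center, elliptical
    } else {
      nuclei$morphology[i] <- "mitotic"        # round, core unresolved
    }
  }
  nuclei
}

#' Locate the DTC/niche nucleus among classified nuclei
#'
#' Picks the dtc_candidate with the highest DTC score (mid-plane
#' eccentricity times central-to-rim intensity ratio); ties are broken
#' toward the distal tip.
#'
#' @param nuclei classified nuclei (from \code{\link{classifyMorphology}})
#' @return the nucleus_id of the DTC nucleus
#' @export
identifyDtc <- function(nuclei) {
  cand <- nuclei[nuclei$morphology == "dtc_candidate", , drop = FALSE]
  if (nrow(cand) == 0)
    stop("DTC not found: no dtc_candidate among ", nrow(nuclei), " nuclei")
  tip_d <- sqrt(cand$x^2 + cand$y^2 + cand$z^2)
  cand <- cand[order(-cand$dtc_score, tip_d), , drop = FALSE]
  cand$nucleus_id[1]
}

#' Measure the nucleolar (dark-core) diameter of a nucleus
#'
#' A nucleus has a detectable dark core when the darkest decile of its
#' mid-plane interior falls below \code{darkFrac} of the rim intensity.
#' The core diameter is then estimated from the second moment of the
#' darkness deficit (rim level minus intensity), corrected for the PSF
#' variance and mapped to microns with an affine calibration against the
#' forward optical model.  Nuclei without a detectable dark core yield NA.
#'
#' @param nuclei data.frame of nuclei
#' @param arr normalized DAPI channel
#' @param stack the source \linkS4class{GonadStack}
#' @param darkFrac fraction of the rim intensity defining "dark"
#' @param psfSigmaXY lateral PSF sigma used for the variance correction (um)
#' @return input with column nucleolus_diameter (um, NA if absent)
#' @export
measureNucleolus <- function(nuclei, arr, stack, darkFrac = 0.98,
                             psfSigmaXY = 0.15) {
  d <- dim(arr)
  px <- stack@pixelSizeXY
  out <- rep(NA_real_, nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    nuc <- nuclei[i, ]
    v <- .stack_vox(stack, as.matrix(nuc[, c("x", "y", "z")]))
    zi <- min(max(2L, round(v[3] + 1)), d[3] - 1L)
    rpx <- nuc$r / px
    half <- ceiling(rpx)
    x0 <- max(1, round(v[1] + 1) - half); x1 <- min(d[1], round(v[1] + 1) + half)
    y0 <- max(1, round(v[2] + 1) - half); y1 <- min(d[2], round(v[2] + 1) + half)
    # average the three central planes: the core spans them, the noise
    # averages down
    win <- (arr[x0:x1, y0:y1, zi - 1] + arr[x0:x1, y0:y1, zi] +
            arr[x0:x1, y0:y1, zi + 1]) / 3
    xs <- seq(x0, x1) - (v[1] + 1); ys <- seq(y0, y1) - (v[2] + 1)
    r2 <- outer(xs^2, ys^2, "+")
    inside <- r2 <= (0.8 * rpx)^2
    ring <- r2 <= rpx^2 & r2 >= (0.65 * rpx)^2
    if (!any(ring) || !any(inside)) next
    rim <- mean(win[ring])
    q10 <- quantile(win[inside], 0.1, names = FALSE)
    # detectable core: the darkest decile clearly below the rim level;
    # cores below the axial resolution (~1.1 um FWHM) stay undetected
    if (!is.finite(rim) || q10 > darkFrac * rim) next
    # size from the second moment of the darkness deficit relative to the
    # rim level (which sits below the interior plateau and so doubles as a
    # noise floor), corrected for the PSF variance; the affine constants
    # are calibrated against the forward optical model
    def <- pmax(0, rim - win)
    def[!inside] <- 0
    W <- sum(def)
    if (W <= 0) next
    vx <- sum(def * outer(xs^2, rep(1, length(ys)))) / W
    vy <- sum(def * outer(rep(1, length(xs)), ys^2)) / W
    var_um <- (vx + vy) / 2 * px^2
    s_um <- sqrt(max(0, var_um - psfSigmaXY^2))
    if (s_um <= 0) next
    out[i] <- 2.70 * s_um + 0.80
  }
  nuclei$nucleolus_diameter <- out
  nuclei
}

# Rescue pass: bright 3D components not claimed by any chained sphere are
# re-admitted as nucleus records.  This recovers (a) nuclei whose circle
# chains were broken by packing-induced suppression and (b) the DTC nucleus,
# whose elliptical cross-sections defeat circular-Hough chaining (gradient
# votes smear along the major axis).  Components are gated by volume and
# classified downstream like any other nucleus.
# deterministic farthest-point-seeded Lloyd clustering (no RNG use)
.split_points <- function(pw, k, iters = 12L) {
  ctrs <- pw[1, , drop = FALSE]
  while (nrow(ctrs) < k) {
    dmin <- rep(Inf, nrow(pw))
    for (j in seq_len(nrow(ctrs)))
      dmin <- pmin(dmin, rowSums(sweep(pw, 2, ctrs[j, ])^2))
    ctrs <- rbind(ctrs, pw[which.max(dmin), ])
  }
  for (it in seq_len(iters)) {
    d2 <- sapply(seq_len(k), function(j) rowSums(sweep(pw, 2, ctrs[j, ])^2))
    grp <- max.col(-d2)
    for (j in seq_len(k))
      if (any(grp == j)) ctrs[j, ] <- colMeans(pw[grp == j, , drop = FALSE])
  }
  split.data.frame(as.data.frame(pw), grp)
}

.rescue_nuclei <- function(sm, stack, nuclei, thr = 1.8,
                           volRange = c(6, 300), splitVol = 38) {
  d <- dim(sm)
  px <- stack@pixelSizeXY; zs <- stack@zStep
  claimed <- array(0, d)
  if (nrow(nuclei) > 0) {
    v <- .stack_vox(stack, as.matrix(nuclei[, c("x", "y", "z")]))
    obj <- cbind(0, v, 1.15 * nuclei$r / px, 1.15 * nuclei$r / px,
                 1.15 * nuclei$r / zs, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0)
    claimed <- .cpp_raster_objects(claimed, d, obj)
  }
  residual <- (sm > thr) & (claimed < 0.5)
  lab <- .cpp_label3d(residual, d)
  pos <- which(lab > 0)
  if (!length(pos)) return(NULL)
  comp <- lab[pos]
  voxvol <- px * px * zs
  sizes <- tabulate(comp)
  keep <- which(sizes * voxvol >= volRange[1] & sizes * voxvol <= volRange[2])
  if (!length(keep)) return(NULL)
  ix <- ((pos - 1) %% d[1]) + 1
  iy <- (((pos - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((pos - 1) %/% (d[1] * d[2])) + 1
  w <- .stack_world(stack, cbind(ix - 1, iy - 1, iz - 1))
  recs <- NULL
  for (k in keep) {
    sel <- comp == k
    pw <- w[sel, , drop = FALSE]
    vol <- sizes[k] * voxvol
    parts <- if (vol > splitVol) {
      .split_points(pw, max(2L, round(vol / 22)))
    } else list(as.data.frame(pw))
    for (pp in parts) {
      pvol <- nrow(pp) * voxvol
      if (pvol < volRange[1]) next
      r_eff <- (3 * pvol / (4 * pi))^(1 / 3)
      recs <- rbind(recs, data.frame(
        x = mean(pp[, 1]), y = mean(pp[, 2]), z = mean(pp[, 3]),
        r = min(max(r_eff, 1.0), 3.5),
        n_planes = length(unique(round(pp[, 3] / stack@zStep))),
        spread = 0,
        score = NA_real_))
    }
  }
  recs
}

#' Segment all nuclei of a gonad stack
#'
#' Full DAPI pipeline: per-plane background normalization, light lateral
#' smoothing, per-plane circular Hough detection, cross-plane assembly into
#' spheres, a residual-blob rescue pass (which also captures the elliptical
#' DTC nucleus), DAPI summation, morphology classification and nucleolus
#' measurement.
#'
#' @param stack a \linkS4class{GonadStack} containing a dapi channel
#' @param rMin,rMax Hough radius range (um)
#' @param sensitivity Hough vote threshold
#' @param gradThresh Sobel gradient threshold (normalized units)
#' @param minPlanes,maxSpread chain acceptance criteria
#' @param minRadius smallest credible nuclear radius (um); smaller chain
#'   fits are discarded as slicing artifacts
#' @return list with elements \code{nuclei} (data.frame, one row per
#'   nucleus) and \code{norm} (the normalized DAPI array, reused by later
#'   stages)
#' @export
segmentNuclei <- function(stack, rMin = 1.0, rMax = 3.5, sensitivity = 0.12,
                          gradThresh = 1.0, minPlanes = 4L, maxSpread = 0.5,
                          minRadius = 1.3) {
  arr <- getChannel(stack, "dapi")
  d <- dim(arr)
  for (z in seq_len(d[3]))
    arr[, , z] <- normalizeDapiPlane(arr[, , z])
  sm <- .cpp_blur3d(arr, d, 1.0, 1.0, 0)   # lateral denoise for the Hough
  circles <- NULL
  for (z in seq_len(d[3])) {
    cc <- detectPlaneCircles(sm[, , z], stack@pixelSizeXY, rMin, rMax,
                             sensitivity, gradThresh)
    if (nrow(cc)) circles <- rbind(circles, cbind(z_index = z, cc))
  }
  if (is.null(circles))
    circles <- data.frame(z_index = integer(0), x = numeric(0),
                          y = numeric(0), r = numeric(0), score = numeric(0))
  # plane coordinates -> axis-centered world coordinates
  circles$x <- circles$x - .X_MARGIN
  circles$y <- circles$y - d[2] / 2 * stack@pixelSizeXY
  nuclei <- assembleNuclei(circles, stack@zStep, minPlanes, maxSpread)
  nuclei$z <- nuclei$z - d[3] / 2 * stack@zStep
  # germ nuclei are never this small; sub-minRadius chains are slicing
  # artifacts (typically central circles of the elliptical DTC) and are
  # dropped so the rescue pass can rebuild the full object
  nuclei <- nuclei[nuclei$r >= minRadius, , drop = FALSE]
  # a single sphere cannot span more planes than its diameter allows;
  # taller chains are stacked neighbours fused end-to-end
  nuclei <- nuclei[nuclei$n_planes <=
                     ceiling(2 * nuclei$r / stack@zStep) + 3, , drop = FALSE]
  rescue <- .rescue_nuclei(sm, stack, nuclei)
  if (!is.null(rescue) && nrow(rescue) > 0) {
    nuclei <- rbind(nuclei[, c("x", "y", "z", "r", "n_planes", "spread",
                               "score")], rescue)
    nuclei <- .merge_overlaps(nuclei)
    nuclei <- nuclei[order(nuclei$x, nuclei$y, nuclei$z), , drop = FALSE]
    nuclei <- cbind(nucleus_id = seq_len(nrow(nuclei)), nuclei)
    rownames(nuclei) <- NULL
  }
  nuclei <- sumDapi(nuclei, arr, stack)
  nuclei <- classifyMorphology(nuclei, arr, stack)
  nuclei <- measureNucleolus(nuclei, arr, stack)
  list(nuclei = nuclei, norm = arr)
}
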