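# Forward optical model: truth -> rendered multi-channel 3D stack, plus the
# TIFF + sidecar / CSV + JSON serialization of stacks and truth tables.

.membrane_radius <- function(geometry) geometry@tubeRadius + 0.4

# The grid extends .X_MARGIN um distal of the tip (x < 0), as a real crop
# does, so tip-hugging nuclei (typically the DTC) are imaged unclipped.
.X_MARGIN <- 2.5

# Grid dimensions for a geometry under an optics model.  The lateral field
# adds a 1.5 um margin around the tube so the membrane shell fits.
.grid_dims <- function(geometry, optics) {
  ext <- 2 * (geometry@tubeRadius + 1.5)
  c(nx = ceiling((geometry@tubeLength + .X_MARGIN) / optics@pixelSizeXY),
    ny = ceiling(ext / optics@pixelSizeXY),
    nz = ceiling(ext / optics@zStep))
}

# world (um) -> continuous 0-based voxel coordinates
.world_to_vox <- function(p, optics, ny, nz) {
  cbind((p[, 1] + .X_MARGIN) / optics@pixelSizeXY - 0.5,
        p[, 2] / optics@pixelSizeXY + ny / 2 - 0.5,
        p[, 3] / optics@zStep + nz / 2 - 0.5)
}

# 1-based voxel indices -> world coordinates of voxel centers
.vox_to_world <- function(v, optics, ny, nz) {
  cbind((v[, 1] - 0.5) * optics@pixelSizeXY - .X_MARGIN,
        (v[, 2] - 0.5 - ny / 2) * optics@pixelSizeXY,
        (v[, 3] - 0.5 - nz / 2) * optics@zStep)
}

# world coordinates of the plane/pixel axes of a stack
.axis_coords <- function(dims, optics) {
  list(x = (seq_len(dims[1]) - 0.5) * optics@pixelSizeXY - .X_MARGIN,
       y = (seq_len(dims[2]) - 0.5 - dims[2] / 2) * optics@pixelSizeXY,
       z = (seq_len(dims[3]) - 0.5 - dims[3] / 2) * optics@zStep)
}

# spot channels render the PSF analytically per spot (sparse, exact mass)
.spot_gaussians <- function(arr, vox, intens, optics) {
  .cpp_add_gaussians(arr, dim(arr), vox, intens,
                     optics@psfSigmaXY / optics@pixelSizeXY,
                     optics@psfSigmaXY / optics@pixelSizeXY,
                     optics@psfSigmaZ / optics@zStep)
}

.blur <- function(arr, optics) {
  .cpp_blur3d(arr, dim(arr),
              optics@psfSigmaXY / optics@pixelSizeXY,
              optics@psfSigmaXY / optics@pixelSizeXY,
              optics@psfSigmaZ / optics@zStep)
}

.apply_noise <- function(arr, optics) {
  if (!optics@shotNoise) return(arr)
  .cpp_apply_noise(arr, optics@readNoiseSd)
}

# nuclei (germ + DTC) as rows for the C++ rasterizer
.nucleus_objects <- function(truth, optics, ny, nz) {
  px <- optics@pixelSizeXY; zs <- optics@zStep
  cells <- truth@cells
  rows <- NULL
  if (nrow(cells) > 0) {
    v <- .world_to_vox(as.matrix(cells[, c("x", "y", "z")]), optics, ny, nz)
    for (i in seq_len(nrow(cells))) {
      r <- cells$r[i]
      if (cells$morphology[i] == "crescent") {
        # lune: sphere minus an offset sphere -> high 2D eccentricity
        ang <- runif(1, 0, 2 * pi)
        off <- 0.65 * r
        rows <- rbind(rows, c(2, v[i, ], r / px, r / px, r / zs, 0, 1,
                              0, 0, 0.12,
                              off * cos(ang) / px, off * sin(ang) / px, 0,
                              0.85 * r / px, 0.85 * r / zs))
      } else {
        cr <- cells$nucleolus_diameter[i] / 2
        if (is.na(cr)) cr <- 0
        rows <- rbind(rows, c(0, v[i, ], r / px, r / px, r / zs, 0, 1,
                              cr / px, cr / zs,
                              optics@nucleolusDarkFraction, 0, 0, 0, 0, 0))
      }
    }
  }
  d <- truth@dtc
  vd <- .world_to_vox(matrix(d$center, 1, 3), optics, ny, nz)
  rows <- rbind(rows, c(1, vd[1, ], d$semiAxes[1] / px, d$semiAxes[2] / px,
                        d$semiAxes[3] / zs, d$angle, 1.05,
                        0, 0, 1, 0, 0, 0, 0, 0))
  rows
}

# membrane channel: cap shell with gap sectors, LEP ribbons, SIP spokes,
# detached fragments
.render_membrane <- function(truth, optics, dims, amp = 80) {
  geom <- truth@geometry
  mem <- truth@scalars$membrane
  Rm <- .membrane_radius(geom)
  ax <- .axis_coords(dims, optics)
  rho <- sqrt(outer(ax$y^2, ax$z^2, "+"))
  phi <- atan2(matrix(ax$z, dims[2], dims[3], byrow = TRUE),
               matrix(ax$y, dims[2], dims[3])) %% (2 * pi)
  half_sh <- 0.28
  ring <- abs(rho - Rm) <= half_sh
  in_gap <- matrix(FALSE, dims[2], dims[3])
  if (!is.null(mem$gaps) && nrow(mem$gaps) > 0) {
    for (g in seq_len(nrow(mem$gaps))) {
      dphi <- mem$gaps$arc_len[g] / Rm
      in_gap <- in_gap |
        (((phi - mem$gaps$phi_start[g]) %% (2 * pi)) < dphi)
    }
  }
  img <- array(0, dims)
  # cap cylinder shell (with gaps carved out)
  xin <- which(ax$x >= -0.05 & ax$x <= mem$capExtent)
  ring_cap <- ring & !in_gap
  idx_yz <- which(ring_cap) - 1L
  if (length(xin) && length(idx_yz))
    img[as.vector(outer(xin, idx_yz * dims[1], "+"))] <- amp
  # distal face disc
  if (geom@distalCap) {
    xin <- which(ax$x >= -0.05 & ax$x <= 0.35)
    face <- (rho <= Rm + half_sh) & !in_gap
    idx_yz <- which(face) - 1L
    if (length(xin) && length(idx_yz))
      img[as.vector(outer(xin, idx_yz * dims[1], "+"))] <- amp
  }
  # LEP ribbons along the outer shell (none when the truth has no process
  # beyond the cap)
  wphi <- 0.9 / Rm
  lepEnds <- c(mem$lepExtent, max(mem$capExtent, mem$lepExtent - 5))
  for (k in 1:2) {
    if (lepEnds[k] <= mem$capExtent) next
    sector <- ring & (((phi - mem$lepPhi[k]) %% (2 * pi)) < wphi)
    xin <- which(ax$x > mem$capExtent & ax$x <= lepEnds[k])
    idx_yz <- which(sector) - 1L
    if (length(xin) && length(idx_yz))
      img[as.vector(outer(xin, idx_yz * dims[1], "+"))] <- amp
  }
  # SIP spokes: thin radial sheets reaching into the tube interior, each
  # attached to the cap by a narrow surface ribbon (SIPs extend from the
  # DTC membrane, they are not free-floating)
  for (xs in mem$sipX) {
    xin <- which(abs(ax$x - xs) <= 0.25)
    psi <- runif(1, 0, 2 * pi)
    spoke <- (rho <= Rm + half_sh) & (rho >= 2.5) &
      (abs(((phi - psi + pi) %% (2 * pi)) - pi) < (0.45 / pmax(rho, 1)))
    idx_yz <- which(spoke) - 1L
    if (length(xin) && length(idx_yz))
      img[as.vector(outer(xin, idx_yz * dims[1], "+"))] <- amp
    ribbon <- ring & (abs(((phi - psi + pi) %% (2 * pi)) - pi) < (0.3 / Rm))
    xrib <- which(ax$x > mem$capExtent & ax$x <= xs)
    idx_yz <- which(ribbon) - 1L
    if (length(xrib) && length(idx_yz))
      img[as.vector(outer(xrib, idx_yz * dims[1], "+"))] <- amp
  }
  # detached fragments: small prolate ellipsoids in the interior
  if (!is.null(mem$fragments) && nrow(mem$fragments) > 0) {
    fr <- mem$fragments
    w <- cbind(fr$x, fr$rho * cos(fr$phi), fr$rho * sin(fr$phi))
    v <- .world_to_vox(w, optics, dims[2], dims[3])
    obj <- cbind(1, v,
                 (fr$length / 2) / optics@pixelSizeXY,
                 pmin(0.35, fr$length / 2) / optics@pixelSizeXY,
                 pmin(0.45, pmax(fr$length / 2, 0.3)) / optics@zStep,
                 fr$theta, amp, 0, 0, 1, 0, 0, 0, 0, 0)
    img <- .cpp_raster_objects(img, dim(img), obj)
  }
  img
}

#' Render a synthetic gonad truth into a multi-channel image stack
#'
#' Forward optical model: nuclei are rasterized as DAPI-bright spheres with
#' dark nucleolar cores (the DTC as a bright ellipsoid without a core,
#' crescents as lunes), RNA spots are deposited with trilinear sub-voxel
#' placement into the intron channel (ATS only) and exon channel (ATS plus
#' cytoplasmic mRNAs), and an optional membrane channel renders the DTC cap
#' shell with gaps, LEP/SIP processes and detached fragments.  Each channel
#' is convolved with a separable Gaussian PSF, offset by its background, and
#' degraded with Poisson shot noise plus Gaussian read noise.  A fixed seed
#' gives a bit-identical stack.
#'
#' @param truth a \linkS4class{GonadTruth}
#' @param optics an \linkS4class{OpticsModel}
#' @param seed integer seed for the noise
#' @param channels channels to render (subset of dapi, intron, exon,
#'   membrane)
#' @return a \linkS4class{GonadStack}
#' @examples
#' tr <- generateTruth(GonadGeometry(nCells = 10, tubeLength = 20),
#'                     BiologyModel(1), seed = 1)
#' st <- renderStack(tr, OpticsModel(shotNoise = FALSE), seed = 1,
#'                   channels = "dapi")
#' st
#' @export
renderStack <- function(truth, optics = OpticsModel(), seed,
                        channels = c("dapi", "intron", "exon")) {
  stopifnot(is(truth, "GonadTruth"), is(optics, "OpticsModel"))
  channels <- match.arg(channels,
                        c("dapi", "intron", "exon", "membrane"),
                        several.ok = TRUE)
  dims <- .grid_dims(truth@geometry, optics)
  if (prod(dims) * length(channels) > optics@maxVoxels)
    stop("rendered grid would have ", prod(dims) * length(channels),
         " voxels, above the maxVoxels guard (", optics@maxVoxels, ")")
  .with_seed(seed, {
    img <- array(0, c(unname(dims), length(channels)))
    photons <- optics@photonsPerAu
    for (k in seq_along(channels)) {
      ch <- channels[k]
      bg <- if (ch %in% names(optics@background))
        optics@background[[ch]] else 0
      plane <- array(0, dims)
      if (ch == "dapi") {
        obj <- .nucleus_objects(truth, optics, dims[2], dims[3])
        plane <- .cpp_raster_objects(plane, dims, obj) * optics@nuclearAmp
      } else if (ch == "intron") {
        if (nrow(truth@ats) > 0) {
          v <- .world_to_vox(as.matrix(truth@ats[, c("x", "y", "z")]),
                             optics, dims[2], dims[3])
          plane <- .spot_gaussians(plane, v, truth@ats$intensity_au * photons,
                                   optics)
        }
      } else if (ch == "exon") {
        pos <- rbind(as.matrix(truth@ats[, c("x", "y", "z")]),
                     as.matrix(truth@mrna[, c("x", "y", "z")]))
        ints <- c(truth@ats$intensity_au, truth@mrna$intensity_au) * photons
        if (nrow(pos) > 0) {
          v <- .world_to_vox(pos, optics, dims[2], dims[3])
          plane <- .spot_gaussians(plane, v, ints, optics)
        }
      } else if (ch == "membrane") {
        plane <- .blur(.render_membrane(truth, optics, dims), optics)
      }
      if (ch == "dapi") plane <- .blur(plane, optics)
      plane <- plane + bg
      img[, , , k] <- .apply_noise(plane, optics)
    }
    new("GonadStack", img = img, channels = channels,
        pixelSizeXY = optics@pixelSizeXY, zStep = optics@zStep)
  })
}

#' Generate a seeded cohort of synthetic gonads
#'
#' Derives one sub-seed per gonad from \code{masterSeed}, generates truth
#' and renders the stack for each.  With \code{out} set, stacks and truth
#' tables are written to disk (TIFF + JSON sidecar, CSV + JSON truth) and a
#' manifest is returned; otherwise the pairs are returned in memory (use
#' small \code{nGonads}: a full-size rendered gonad is ~40 MB per channel).
#'
#' @param nGonads number of gonads (>= 1)
#' @param geometry,biology,optics model configuration
#' @param masterSeed integer master seed
#' @param channels channels to render
#' @param out optional output directory
#' @return with \code{out}: data.frame manifest (gonad, seed, prefix);
#'   otherwise a list of \code{list(stack =, truth =)} pairs
#' @export
generateCohort <- function(nGonads, geometry = GonadGeometry(),
                           biology = BiologyModel(1),
                           optics = OpticsModel(), masterSeed,
                           channels = c("dapi", "intron", "exon"),
                           out = NULL) {
  stopifnot(nGonads >= 1)
  seeds <- gonadSeeds(masterSeed, nGonads)
  res <- vector("list", nGonads)
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  for (i in seq_len(nGonads)) {
    tr <- generateTruth(geometry, biology, seed = seeds[i])
    st <- renderStack(tr, optics, seed = seeds[i] + 1L, channels = channels)
    if (is.null(out)) {
      res[[i]] <- list(stack = st, truth = tr)
    } else {
      prefix <- file.path(out, sprintf("gonad_%03d", i))
      writeGonadStack(st, prefix)
      writeTruthTable(tr, prefix)
      res[[i]] <- data.frame(gonad = i, seed = seeds[i], prefix = prefix)
    }
  }
  if (is.null(out)) res else do.call(rbind, res)
}

#' Deterministic per-gonad seeds from a master seed
#'
#' @param masterSeed integer master seed
#' @param n number of gonads
#' @return integer vector of n sub-seeds (< 2^31)
#' @export
gonadSeeds <- function(masterSeed, n) {
  as.integer((as.double(masterSeed) * 10007 + 7919 * seq_len(n)) %%
               2147483629)
}

# ---------------------------------------------------------------------------
# Serialization
# ---------------------------------------------------------------------------

#' Write / read a stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-major (all z-planes of channel 1, then channel 2, ...);
#' voxel values are stored as 16-bit integers (photon counts; values are
#' rounded and clipped at 65535) with the layout recorded in
#' \code{<prefix>.json}.
#'
#' @param stack a \linkS4class{GonadStack}
#' @param prefix path prefix; writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}
#' @return \code{writeGonadStack}: the prefix, invisibly;
#'   \code{readGonadStack}: a \linkS4class{GonadStack}
#' @export
writeGonadStack <- function(stack, prefix) {
  stopifnot(is(stack, "GonadStack"))
  d <- dim(stack@img)
  pages <- vector("list", d[3] * d[4])
  n <- 0L
  for (k in seq_len(d[4])) for (z in seq_len(d[3])) {
    n <- n + 1L
    # TIFF pages are row-major (y = rows); transpose x/y
    pages[[n]] <- t(pmin(round(stack@img[, , z, k]), 65535)) / 65535
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L,
                  compression = "none")
  meta <- list(channels = stack@channels,
               dim = d[1:3],
               pixel_size_xy = stack@pixelSizeXY,
               z_step = stack@zStep,
               page_order = "channel_major",
               value_scale = 65535)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeGonadStack
#' @export
readGonadStack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  d <- as.integer(meta$dim)
  nch <- length(meta$channels)
  img <- array(0, c(d, nch))
  n <- 0L
  for (k in seq_len(nch)) for (z in seq_len(d[3])) {
    n <- n + 1L
    img[, , z, k] <- t(pages[[n]]) * meta$value_scale
  }
  new("GonadStack", img = img, channels = meta$channels,
      pixelSizeXY = meta$pixel_size_xy, zStep = meta$z_step)
}

#' Write / read a ground-truth table as CSV plus JSON scalars
#'
#' \code{<prefix>_cells.csv} holds one row per germ cell with list-valued
#' fields (locus states, ATS and mRNA positions/intensities) JSON-encoded;
#' \code{<prefix>_gonad.json} holds the per-gonad scalars, DTC record,
#' membrane truth and geometry.
#'
#' @param truth a \linkS4class{GonadTruth}
#' @param prefix path prefix
#' @return \code{writeTruthTable}: the prefix, invisibly;
#'   \code{readTruthTable}: a \linkS4class{GonadTruth}
#' @export
writeTruthTable <- function(truth, prefix) {
  stopifnot(is(truth, "GonadTruth"))
  cells <- truth@cells
  enc <- function(x) vapply(x, function(v)
    as.character(jsonlite::toJSON(v, digits = NA)), "")
  flat <- cells[, c("cell_id", "x", "y", "z", "r", "nucleolus_diameter",
                    "morphology", "axial_distance", "n_ats", "n_mrna")]
  flat$locus_states <- enc(cells$locus_states)
  by_cell <- function(df) {
    sp <- split(df[, c("x", "y", "z", "intensity_au")], df$cell_id)
    out <- rep("[]", nrow(cells))
    idx <- match(as.integer(names(sp)), cells$cell_id)
    out[idx] <- vapply(sp, function(v)
      as.character(jsonlite::toJSON(unname(as.matrix(v)), digits = NA)), "")
    out
  }
  flat$ats <- by_cell(truth@ats)
  flat$mrna <- by_cell(truth@mrna)
  write.csv(flat, paste0(prefix, "_cells.csv"), row.names = FALSE)
  g <- truth@geometry
  gon <- list(dtc = truth@dtc, scalars = truth@scalars,
              geometry = list(tubeLength = g@tubeLength,
                              tubeRadius = g@tubeRadius,
                              cellDiameterMean = g@cellDiameterMean,
                              cellDiameterSd = g@cellDiameterSd,
                              nCells = g@nCells, distalCap = g@distalCap))
  jsonlite::write_json(gon, paste0(prefix, "_gonad.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(prefix) {
  flat <- read.csv(paste0(prefix, "_cells.csv"), stringsAsFactors = FALSE)
  gon <- jsonlite::read_json(paste0(prefix, "_gonad.json"),
                             simplifyVector = TRUE)
  geom <- do.call(GonadGeometry, gon$geometry)
  dec_spots <- function(col, id_name) {
    rows <- NULL
    for (i in seq_len(nrow(flat))) {
      m <- jsonlite::fromJSON(col[i])
      if (length(m) == 0) next
      m <- matrix(m, ncol = 4)
      rows <- rbind(rows, data.frame(cell_id = flat$cell_id[i],
                                     x = m[, 1], y = m[, 2], z = m[, 3],
                                     intensity_au = m[, 4]))
    }
    if (is.null(rows))
      rows <- data.frame(cell_id = integer(0), x = numeric(0),
                         y = numeric(0), z = numeric(0),
                         intensity_au = numeric(0))
    cbind(setNames(data.frame(seq_len(nrow(rows))), id_name), rows)
  }
  cells <- flat[, c("cell_id", "x", "y", "z", "r", "nucleolus_diameter",
                    "morphology", "axial_distance", "n_ats", "n_mrna")]
  cells$locus_states <- lapply(flat$locus_states, function(s)
    as.logical(jsonlite::fromJSON(s)))
  dtc <- gon$dtc
  dtc$center <- unlist(dtc$center)
  dtc$semiAxes <- unlist(dtc$semiAxes)
  scal <- gon$scalars
  if (!is.null(scal$membrane$gaps))
    scal$membrane$gaps <- as.data.frame(scal$membrane$gaps)
  if (!is.null(scal$membrane$fragments))
    scal$membrane$fragments <- as.data.frame(scal$membrane$fragments)
  new("GonadTruth", cells = cells,
      ats = dec_spots(flat$ats, "ats_id"),
      mrna = dec_spots(flat$mrna, "mrna_id"),
      dtc = dtc, scalars = scal, geometry = geom)
}
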