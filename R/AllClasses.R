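#' @useDynLib nicheQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx coef cor cov lm lm.fit median qlnorm rbinom
#'   rlnorm rnbinom rnorm rpois runif sd setNames plnorm aov anova t.test
#'   ks.test mad quantile
#' @importFrom grDevices chull
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Geometry of the modeled distal gonad
#'
#' The distal gonad is modeled as a straight cylindrical tube: the distal tip
#' sits at the origin, the gonad axis is +x, and units are microns
#' throughout.  Only the distal analysis window (~60 um, the region the
#' imaging protocol crops to) is modeled, not the full U-shaped gonad arm.
#'
#' @slot tubeLength axial length of the analysis window (um)
#' @slot tubeRadius radius of the gonad tube (um)
#' @slot cellDiameterMean mean germ-cell nuclear diameter (um)
#' @slot cellDiameterSd standard deviation of the nuclear diameter (um)
#' @slot nCells number of germ cells packed into the window
#' @slot distalCap whether the distal face is closed by a hemispherical cap
#'   (affects only the membrane channel; nuclei are packed in the cylinder)
#' @name GonadGeometry-class
#' @aliases GonadGeometry-class
#' @exportClass GonadGeometry
setClass("GonadGeometry",
  representation(tubeLength = "numeric", tubeRadius = "numeric",
                 cellDiameterMean = "numeric", cellDiameterSd = "numeric",
                 nCells = "numeric", distalCap = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@tubeLength <= 0) msg <- c(msg, "tubeLength must be > 0")
    if (object@tubeRadius <= 0) msg <- c(msg, "tubeRadius must be > 0")
    if (object@cellDiameterMean >= object@tubeRadius)
      msg <- c(msg, "cellDiameterMean must be smaller than tubeRadius")
    if (object@cellDiameterMean <= 0) msg <- c(msg, "cellDiameterMean must be > 0")
    if (object@cellDiameterSd < 0) msg <- c(msg, "cellDiameterSd must be >= 0")
    if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a gonad geometry
#'
#' Defaults describe the distal analysis window of an adult hermaphrodite
#' gonad: a 60 um window of a 20-um-diameter tube holding ~200 packed germ
#' cells of ~3.8 um nuclear diameter.
#'
#' @param tubeLength,tubeRadius window length and tube radius (um)
#' @param cellDiameterMean,cellDiameterSd nuclear diameter law (um)
#' @param nCells number of germ cells
#' @param distalCap close the distal face with a hemispherical cap
#' @return a \linkS4class{GonadGeometry} object
#' @examples
#' GonadGeometry(nCells = 50)
#' @export
GonadGeometry <- function(tubeLength = 60, tubeRadius = 10,
                          cellDiameterMean = 3.8, cellDiameterSd = 0.3,
                          nCells = 200, distalCap = TRUE) {
  new("GonadGeometry", tubeLength = tubeLength, tubeRadius = tubeRadius,
      cellDiameterMean = cellDiameterMean, cellDiameterSd = cellDiameterSd,
      nCells = nCells, distalCap = distalCap)
}

#' Biology of an aging gonad: activation gradient, spot laws, niche drift
#'
#' Encodes the age-dependent generative laws of the simulator: the spatial
#' probability profile of Notch-dependent transcriptional activation, the
#' number of Notch-responsive gene loci per nucleus, intensity laws for
#' active transcription sites (ATS) and cytoplasmic mRNAs, the mRNA count
#' law, the lognormal drift law of the DTC/niche nucleus, and the onset of
#' meiotic (crescent) morphology.
#'
#' @slot ageDay adult age in days (1-4)
#' @slot activationAnchors two-column matrix (distance um, probability) of
#'   the per-cell activation profile p(d); interpolated piecewise-linearly
#' @slot nLoci number of independently activatable loci per nucleus
#' @slot atsMeanlog,atsSdlog lognormal law of single-ATS intensity (a.u.)
#' @slot mrnaPeakMean mean mRNA count per cell at the profile peak
#' @slot mrnaDispersion negative-binomial size parameter of the count law
#' @slot mrnaIntensityCv coefficient of variation of single-mRNA intensity
#' @slot driftMeanlog,driftSdlog lognormal law of the DTC nuclear drift (um)
#' @slot driftCap upper truncation of drift samples (um; resampled above)
#' @slot driftRef reference drift of the age day (um; the drift-law
#'   mean); the activation profile of a gonad is shifted by
#'   activationCoupling * (drift - driftRef), so Notch activation tracks
#'   the niche nucleus
#' @slot activationCoupling strength of the profile-to-DTC coupling (1 =
#'   the activation pattern moves with the niche nucleus, 0 = independent)
#' @slot meioticOnset axial distance beyond which crescents appear (um)
#' @slot crescentProb probability a cell beyond meioticOnset is a crescent
#' @slot nucleolusDiameterMean,nucleolusDiameterSd germ nucleolus size (um)
#' @slot membrane named list of DTC membrane morphology parameters (cap
#'   extent, gap count/length laws, fragment laws, LEP/SIP extents, um)
#' @name BiologyModel-class
#' @aliases BiologyModel-class
#' @exportClass BiologyModel
setClass("BiologyModel",
  representation(ageDay = "numeric", activationAnchors = "matrix",
                 nLoci = "numeric", atsMeanlog = "numeric", atsSdlog = "numeric",
                 mrnaPeakMean = "numeric", mrnaDispersion = "numeric",
                 mrnaIntensityCv = "numeric",
                 driftMeanlog = "numeric", driftSdlog = "numeric",
                 driftCap = "numeric", driftRef = "numeric",
                 activationCoupling = "numeric", meioticOnset = "numeric",
                 crescentProb = "numeric",
                 nucleolusDiameterMean = "numeric",
                 nucleolusDiameterSd = "numeric",
                 membrane = "list"),
  validity = function(object) {
    msg <- NULL
    p <- object@activationAnchors[, 2]
    if (any(p < 0 | p > 1)) msg <- c(msg, "activation probabilities must lie in [0,1]")
    if (is.unsorted(object@activationAnchors[, 1]))
      msg <- c(msg, "activation anchor distances must be increasing")
    pk <- which.max(p)
    if (pk > 1 && is.unsorted(p[seq_len(pk)]))
      msg <- c(msg, "activation profile must be unimodal (rising limb)")
    if (pk < length(p) && is.unsorted(rev(p[pk:length(p)])))
      msg <- c(msg, "activation profile must be unimodal (falling limb)")
    if (object@nLoci < 1) msg <- c(msg, "nLoci must be >= 1")
    if (!(object@ageDay %in% 1:4)) msg <- c(msg, "ageDay must be 1, 2, 3 or 4")
    if (is.null(msg)) TRUE else msg
  })

# Per-day anchor tables for the activation profile p(d).  Day 1 and Day 4
# were calibrated by Monte Carlo against the published spatial anchors
# (distal-most ~70%, peak ~5 um, <2.5% beyond ~25 um at Day 1; peak ~15 um
# and a flattened gradient at Day 4); Days 2-3 interpolate the progression.
.activation_anchor_tables <- list(
  `1` = cbind(d = c(0, 2.5, 5, 7.5, 10, 15, 20, 23, 24, 26, 30, 35, 60),
              p = c(0.70, 0.76, 0.82, 0.72, 0.52, 0.25, 0.085, 0.060,
                    0.025, 0.003, 0.002, 0.0015, 0.001)),
  `2` = cbind(d = c(0, 4, 8, 12, 16, 22, 28, 33, 38, 60),
              p = c(0.55, 0.60, 0.64, 0.52, 0.33, 0.12, 0.035, 0.012,
                    0.004, 0.001)),
  `3` = cbind(d = c(0, 4, 8, 11, 14, 18, 24, 30, 36, 42, 60),
              p = c(0.40, 0.45, 0.50, 0.53, 0.48, 0.32, 0.13, 0.04,
                    0.012, 0.004, 0.001)),
  `4` = cbind(d = c(0, 6, 11, 15, 18, 21, 25, 30, 36, 44, 60),
              p = c(0.12, 0.18, 0.28, 0.42, 0.55, 0.42, 0.26, 0.12,
                    0.04, 0.008, 0.001)))

# Lognormal drift-law parameters per day.  Day 1: mean 2 um with ~97% of
# mass below 5 um.  Day 4: calibrated (truncated at driftCap) to mean ~12 um
# with P(drift <= 5 um) ~ 0.38 and samples reaching ~40+ um.
.drift_params <- list(
  `1` = c(meanlog = log(2) - 0.18, sdlog = 0.60),
  `2` = c(meanlog = log(5) - 0.32, sdlog = 0.80),
  `3` = c(meanlog = log(8) - 0.50, sdlog = 1.00),
  `4` = c(meanlog = 2.13, sdlog = 1.35))

.membrane_defaults <- function(ageDay) {
  list(capExtent = 6,
       gapCountMean = 2.5,
       gapLenMean = c(2.0, 2.6, 3.4, 4.4)[ageDay],
       gapLenSd = 0.6,
       fragCountMean = c(4, 3, 2, 1.5)[ageDay],
       fragLenMean = 1.6, fragLenSd = 0.5,
       lepExtent = c(35, 38, 42, 46)[ageDay],
       sipExtent = 15)
}

#' Construct the biology model for a given adult age
#'
#' Returns the age-day defaults of the generative model.  Day-1 and Day-4
#' defaults are calibrated so that statistics computed directly on simulated
#' ground truth reproduce the published spatial anchors of niche aging
#' (distal activation ~70% and peak ~5 um at Day 1 shifting to ~15 um at
#' Day 4; DTC nuclear drift mean ~2 um at Day 1 vs ~12 um at Day 4 with 38%
#' of gonads within 5 um).
#'
#' @param ageDay adult age in days (1, 2, 3 or 4)
#' @param ... override any slot default by name
#' @return a \linkS4class{BiologyModel} object
#' @examples
#' BiologyModel(ageDay = 4)
#' @export
BiologyModel <- function(ageDay = 1, ...) {
  stopifnot(ageDay %in% 1:4)
  dp <- .drift_params[[as.character(ageDay)]]
  args <- list(ageDay = ageDay,
    activationAnchors = .activation_anchor_tables[[as.character(ageDay)]],
    nLoci = 4, atsMeanlog = log(3.0), atsSdlog = 0.55,
    mrnaPeakMean = 20, mrnaDispersion = 5, mrnaIntensityCv = 0.15,
    driftMeanlog = unname(dp["meanlog"]), driftSdlog = unname(dp["sdlog"]),
    driftCap = 55, driftRef = c(2, 5, 8, 11)[ageDay],
    activationCoupling = 0.7, meioticOnset = c(35, 33, 30, 27)[ageDay],
    crescentProb = 0.35,
    nucleolusDiameterMean = 1.5, nucleolusDiameterSd = 0.15,
    membrane = .membrane_defaults(ageDay))
  args[names(list(...))] <- list(...)
  do.call(new, c("BiologyModel", args))
}

#' Optical model of the widefield acquisition
#'
#' Voxel calibration, Gaussian point-spread function, per-channel
#' backgrounds, photon conversion and noise of the rendering model.
#'
#' @slot pixelSizeXY lateral pixel size (um)
#' @slot zStep axial step between planes (um)
#' @slot psfSigmaXY,psfSigmaZ Gaussian PSF sigmas (um)
#' @slot background named per-channel background level (photons)
#' @slot photonsPerAu integrated photons emitted by a 1 a.u. spot
#' @slot nuclearAmp added DAPI signal inside a nucleus (photons)
#' @slot shotNoise apply Poisson shot noise
#' @slot readNoiseSd Gaussian read noise (photons)
#' @slot nucleolusDarkFraction DAPI attenuation inside the nucleolar core
#' @slot maxVoxels guard on the rendered grid size (voxels)
#' @name OpticsModel-class
#' @aliases OpticsModel-class
#' @exportClass OpticsModel
setClass("OpticsModel",
  representation(pixelSizeXY = "numeric", zStep = "numeric",
                 psfSigmaXY = "numeric", psfSigmaZ = "numeric",
                 background = "numeric", photonsPerAu = "numeric",
                 nuclearAmp = "numeric", shotNoise = "logical",
                 readNoiseSd = "numeric", nucleolusDarkFraction = "numeric",
                 maxVoxels = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@zStep <= 0) msg <- c(msg, "zStep must be > 0")
    if (object@pixelSizeXY <= 0) msg <- c(msg, "pixelSizeXY must be > 0")
    if (any(object@background < 0)) msg <- c(msg, "background must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct the optics model
#'
#' Defaults mirror the acquisition geometry of a 63x/1.4 NA widefield stack
#' (0.13 um pixels, 0.3 um z-step) with a Gaussian PSF.
#'
#' @param pixelSizeXY,zStep voxel calibration (um)
#' @param psfSigmaXY,psfSigmaZ Gaussian PSF sigmas (um)
#' @param background named per-channel background (photons)
#' @param photonsPerAu integrated photons of a 1 a.u. spot
#' @param nuclearAmp DAPI amplitude added inside nuclei (photons)
#' @param shotNoise apply Poisson shot noise
#' @param readNoiseSd Gaussian read noise sd (photons)
#' @param nucleolusDarkFraction DAPI attenuation of the nucleolar core
#' @param maxVoxels refuse to render grids larger than this
#' @return an \linkS4class{OpticsModel} object
#' @examples
#' OpticsModel(shotNoise = FALSE)
#' @export
OpticsModel <- function(pixelSizeXY = 0.13, zStep = 0.3,
                        psfSigmaXY = 0.15, psfSigmaZ = 0.45,
                        background = c(dapi = 50, intron = 10, exon = 10,
                                       membrane = 10),
                        photonsPerAu = 500, nuclearAmp = 100,
                        shotNoise = TRUE, readNoiseSd = 2,
                        nucleolusDarkFraction = 0.25,
                        maxVoxels = 2.5e8) {
  new("OpticsModel", pixelSizeXY = pixelSizeXY, zStep = zStep,
      psfSigmaXY = psfSigmaXY, psfSigmaZ = psfSigmaZ,
      background = background, photonsPerAu = photonsPerAu,
      nuclearAmp = nuclearAmp, shotNoise = shotNoise,
      readNoiseSd = readNoiseSd,
      nucleolusDarkFraction = nucleolusDarkFraction, maxVoxels = maxVoxels)
}

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Multi-channel 3D image stack with physical calibration
#'
#' The raw input of the analysis pipeline and the output of the renderer.
#' Voxel data are a 4D array (x, y, z, channel) in photons; world
#' coordinates are microns with the distal tip at the origin, the gonad axis
#' along +x, and the tube axis passing through the y/z center of the grid.
#'
#' @slot img 4D numeric array (nx, ny, nz, nChannels)
#' @slot channels channel names, e.g. dapi / intron / exon / membrane
#' @slot pixelSizeXY lateral pixel size (um)
#' @slot zStep axial step (um)
#' @name GonadStack-class
#' @aliases GonadStack-class
#' @exportClass GonadStack
setClass("GonadStack",
  representation(img = "array", channels = "character",
                 pixelSizeXY = "numeric", zStep = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@img)) != 4) msg <- c(msg, "img must be a 4D array")
    else if (dim(object@img)[4] != length(object@channels))
      msg <- c(msg, "length(channels) must equal dim(img)[4]")
    if (is.null(msg)) TRUE else msg
  })

#' Simulator ground truth for one gonad
#'
#' Mirrors every quantity the detection pipeline estimates: per-cell nuclear
#' geometry, morphology and locus activation states; ATS and mRNA spot
#' tables; the DTC nucleus (center, shape, drift); and per-gonad scalars
#' including membrane morphology truth.
#'
#' @slot cells data.frame, one row per germ cell (cell_id, x, y, z, radius,
#'   nucleolus_diameter, morphology, axial_distance, n_ats, n_mrna,
#'   locus_states as a list column)
#' @slot ats data.frame of true ATS (ats_id, cell_id, x, y, z, intensity_au)
#' @slot mrna data.frame of cytoplasmic mRNAs (mrna_id, cell_id, x, y, z,
#'   intensity_au)
#' @slot dtc list describing the DTC nucleus (center, semi-axes, xy angle,
#'   drift)
#' @slot scalars list of per-gonad scalars (age day, seed, membrane truth)
#' @slot geometry the \linkS4class{GonadGeometry} used
#' @name GonadTruth-class
#' @aliases GonadTruth-class
#' @exportClass GonadTruth
setClass("GonadTruth",
  representation(cells = "data.frame", ats = "data.frame",
                 mrna = "data.frame", dtc = "list", scalars = "list",
                 geometry = "GonadGeometry"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@cells) > 0) {
      nA <- sum(object@cells$n_ats)
      if (nA != nrow(object@ats))
        msg <- c(msg, "sum(cells$n_ats) must equal nrow(ats)")
      if (any(object@cells$axial_distance < 0))
        msg <- c(msg, "axial distances must be >= 0")
    }
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Show methods and accessors
# ---------------------------------------------------------------------------

setMethod("show", "GonadGeometry", function(object) {
  cat("GonadGeometry: tube", object@tubeLength, "x r", object@tubeRadius,
      "um,", object@nCells, "cells (d ~",
      object@cellDiameterMean, "um)\n")
})

setMethod("show", "BiologyModel", function(object) {
  cat("BiologyModel: Day", object@ageDay, "|", object@nLoci,
      "loci | drift lognormal(", round(object@driftMeanlog, 3), ",",
      round(object@driftSdlog, 3), ") um\n")
})

setMethod("show", "OpticsModel", function(object) {
  cat("OpticsModel:", object@pixelSizeXY, "um px,", object@zStep,
      "um z-step, PSF sigma", object@psfSigmaXY, "/", object@psfSigmaZ,
      "um, noise", if (object@shotNoise) "on" else "off", "\n")
})

setMethod("show", "GonadStack", function(object) {
  d <- dim(object@img)
  cat("GonadStack:", d[1], "x", d[2], "x", d[3], "voxels,",
      d[4], "channel(s) [", paste(object@channels, collapse = ", "),
      "],", object@pixelSizeXY, "um px /", object@zStep, "um z\n")
})

setMethod("show", "GonadTruth", function(object) {
  cat("GonadTruth: Day", object@scalars$ageDay, "|",
      nrow(object@cells), "cells,", nrow(object@ats), "ATS,",
      nrow(object@mrna), "mRNAs | DTC drift",
      round(object@dtc$drift, 2), "um\n")
})

#' @describeIn GonadStack-class channel names of a stack
#' @param x a GonadStack
#' @export
channelNames <- function(x) x@channels

#' Extract one channel of a stack as a 3D array
#' @param x a \linkS4class{GonadStack}
#' @param channel channel name
#' @return 3D numeric array (nx, ny, nz)
#' @export
getChannel <- function(x, channel) {
  stopifnot(is(x, "GonadStack"))
  i <- match(channel, x@channels)
  if (is.na(i)) stop("channel '", channel, "' not present")
  d <- dim(x@img)
  n <- prod(d[1:3])
  out <- x@img[((i - 1) * n + 1):(i * n)]   # contiguous channel block
  dim(out) <- d[1:3]
  out
}

#' Voxel calibration of a stack
#' @param x a \linkS4class{GonadStack}
#' @return named numeric: pixelSizeXY and zStep (um)
#' @export
voxelSize <- function(x) c(pixelSizeXY = x@pixelSizeXY, zStep = x@zStep)

#' @rdname GonadTruth-class
#' @param x a GonadTruth
#' @export
truthCells <- function(x) x@cells

#' @rdname GonadTruth-class
#' @export
truthAts <- function(x) x@ats

#' @rdname GonadTruth-class
#' @export
truthMrna <- function(x) x@mrna

#' @rdname GonadTruth-class
#' @export
truthDtc <- function(x) x@dtc

#' @rdname GonadTruth-class
#' @export
gonadScalars <- function(x) x@scalars
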