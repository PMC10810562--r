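# Generative model of an aging distal gonad: ground truth layer.
# Coordinates: microns, right-handed, distal tip at the origin, gonad axis
# along +x, tube axis through (y, z) = (0, 0).

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Probability of Notch activation at a given axial distance
#'
#' Piecewise-linear interpolation of the age-specific anchor table; this is
#' the per-cell probability that at least one locus is transcriptionally
#' active at axial distance \code{d} from the distal tip.
#'
#' @param d axial distances (um)
#' @param biology a \linkS4class{BiologyModel}
#' @return probabilities in [0, 1]
#' @examples
#' activationProbability(c(0, 5, 25), BiologyModel(1))
#' @export
activationProbability <- function(d, biology) {
  a <- biology@activationAnchors
  approx(a[, 1], a[, 2], xout = pmin(pmax(d, min(a[, 1])), max(a[, 1])),
         rule = 2)$y
}

# profile shifted along the axis by `shift` um; positions that would map
# distal of the tip decay exponentially toward zero (the vacated distal
# region loses activation rather than inheriting the distal-most level)
.activation_prob_shifted <- function(d, biology, shift = 0) {
  dp <- d - shift
  p <- activationProbability(pmax(dp, 0), biology)
  neg <- dp < 0
  if (any(neg)) p[neg] <- p[neg] * exp(dp[neg] / 2)
  p
}

.per_locus_prob_shifted <- function(d, biology, shift = 0) {
  p <- .activation_prob_shifted(d, biology, shift)
  1 - (1 - p)^(1 / biology@nLoci)
}

#' Per-locus activation probability
#'
#' Solves \code{1 - (1 - q)^nLoci = p(d)} so that a cell with
#' \code{nLoci} i.i.d. Bernoulli(q) loci has overall activation
#' probability \code{p(d)}.
#'
#' @inheritParams activationProbability
#' @return per-locus probabilities q(d)
#' @export
perLocusProbability <- function(d, biology) {
  p <- activationProbability(d, biology)
  1 - (1 - p)^(1 / biology@nLoci)
}

#' Sample DTC nuclear drift distances
#'
#' Draws from the age-specific lognormal drift law, resampling values above
#' the truncation cap so every sample fits inside the analysis window.
#'
#' @param n number of samples
#' @param biology a \linkS4class{BiologyModel}
#' @return nonnegative drift distances (um)
#' @export
sampleDrift <- function(n, biology) {
  out <- rlnorm(n, biology@driftMeanlog, biology@driftSdlog)
  bad <- out > biology@driftCap
  while (any(bad)) {
    out[bad] <- rlnorm(sum(bad), biology@driftMeanlog, biology@driftSdlog)
    bad <- out > biology@driftCap
  }
  out
}

# Dart-throwing sphere packing inside the tube.  Returns matrix x,y,z,r.
# Centers keep >= 0.9 * (ri + rj) from each other and >= clearance from
# `avoid` points (the DTC).  Errors if the target count is unreachable.
.pack_nuclei <- function(n, geom, radii, avoid = NULL, avoid_r = 0,
                         max_tries = 2000L * max(n, 1L)) {
  if (n == 0) return(matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, c("x", "y", "z", "r"))))
  L <- geom@tubeLength; R <- geom@tubeRadius
  xs <- ys <- zs <- rs <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    r <- radii[placed + 1L]
    x <- runif(1, 0.35 * r, L - r)
    rho <- (R - r) * sqrt(runif(1))
    phi <- runif(1, 0, 2 * pi)
    y <- rho * cos(phi); z <- rho * sin(phi)
    if (placed > 0) {
      d2 <- (xs[1:placed] - x)^2 + (ys[1:placed] - y)^2 + (zs[1:placed] - z)^2
      if (any(d2 < (0.9 * (rs[1:placed] + r))^2)) next
    }
    if (!is.null(avoid)) {
      d2a <- (avoid[1] - x)^2 + (avoid[2] - y)^2 + (avoid[3] - z)^2
      if (d2a < (avoid_r + r)^2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y; zs[placed] <- z; rs[placed] <- r
  }
  if (placed < n)
    stop("nucleus packing failed: only ", placed, " of ", n,
         " nuclei fit this tube; reduce nCells to at most ~", placed)
  cbind(x = xs, y = ys, z = zs, r = rs)
}

# Sample k points inside a ball of radius `rad` around `center` with a
# minimum pairwise separation (chromosomal locus territories).
.sample_loci_positions <- function(k, center, rad, min_sep = 0.8) {
  pts <- matrix(numeric(0), 0, 3)
  guard <- 0
  while (nrow(pts) < k && guard < 2000) {
    guard <- guard + 1
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- center + rad * runif(1)^(1 / 3) * u
    if (nrow(pts) == 0 ||
        all(colSums((t(pts) - p)^2) >= min_sep^2))
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < k) {   # relax separation rather than fail
    while (nrow(pts) < k) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      pts <- rbind(pts, center + rad * runif(1)^(1 / 3) * u)
    }
  }
  pts
}

# Cytoplasmic mRNA positions: uniform in a shell around the owning nucleus,
# inside the tube and outside every nuclear sphere.
.sample_mrna_positions <- function(k, center, own_r, nuclei, geom,
                                   reach = 2.8) {
  if (k == 0) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, k, 3)
  filled <- 0L; guard <- 0L
  R <- geom@tubeRadius; L <- geom@tubeLength
  while (filled < k && guard < 500L) {
    guard <- guard + 1L
    m <- 4L * (k - filled)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    rr <- (own_r + 0.15) + (reach - own_r - 0.15) * runif(m)^(1 / 3)
    p <- sweep(u * rr, 2, center, "+")
    ok <- p[, 1] >= 0.2 & p[, 1] <= L - 0.2 &
      (p[, 2]^2 + p[, 3]^2) <= (R - 0.2)^2
    if (nrow(nuclei) > 0 && any(ok)) {
      for (i in which(ok)) {
        d2 <- (nuclei[, "x"] - p[i, 1])^2 + (nuclei[, "y"] - p[i, 2])^2 +
          (nuclei[, "z"] - p[i, 3])^2
        if (any(d2 < (nuclei[, "r"] + 0.12)^2)) ok[i] <- FALSE
      }
    }
    p <- p[ok, , drop = FALSE]
    take <- min(nrow(p), k - filled)
    if (take > 0) {
      out[(filled + 1):(filled + take), ] <- p[seq_len(take), , drop = FALSE]
      filled <- filled + take
    }
  }
  out[seq_len(filled), , drop = FALSE]
}

# Membrane morphology truth: angular gap sectors, fragments, process extents.
.sample_membrane_truth <- function(biology, geom) {
  m <- biology@membrane
  R <- geom@tubeRadius + 0.4   # membrane shell sits just outside the tube
  n_gaps <- rpois(1, m$gapCountMean)
  gaps <- NULL
  if (n_gaps > 0) {
    lens <- pmax(0.6, rnorm(n_gaps, m$gapLenMean, m$gapLenSd))
    dphi <- lens / R
    starts <- numeric(0)
    for (dp in dphi) {   # non-overlapping angular sectors
      for (try in 1:50) {
        s <- runif(1, 0, 2 * pi)
        if (length(starts) == 0 ||
            all(abs(((s - starts + pi) %% (2 * pi)) - pi) >
                (dp + dphi[seq_along(starts)]) / 2 + 0.15))
          break
      }
      starts <- c(starts, s)
    }
    gaps <- data.frame(phi_start = starts, arc_len = dphi[seq_along(starts)] * R)
    n_gaps <- nrow(gaps)
  }
  n_frag <- rpois(1, m$fragCountMean)
  frags <- NULL
  if (n_frag > 0) {
    lens <- pmax(0.7, rnorm(n_frag, m$fragLenMean, m$fragLenSd))
    frags <- data.frame(
      x = runif(n_frag, m$capExtent + 3, min(geom@tubeLength - 2, 40)),
      rho = runif(n_frag, 2, R - 2),
      phi = runif(n_frag, 0, 2 * pi),
      length = lens,
      theta = runif(n_frag, 0, pi))
  }
  list(capExtent = m$capExtent, gaps = gaps, fragments = frags,
       lepExtent = m$lepExtent, sipExtent = m$sipExtent,
       lepPhi = runif(2, 0, 2 * pi),
       sipX = sort(runif(4, m$capExtent + 1, m$sipExtent)))
}

#' Generate the ground truth of one synthetic gonad
#'
#' Samples the full generative model for one distal gonad: a drifted DTC
#' nucleus (ellipsoidal, no dark core), packed spherical germ-cell nuclei,
#' per-cell locus activation states following the age-specific spatial
#' profile, ATS positions and intensities, distance-dependent cytoplasmic
#' mRNA counts and positions, crescent (meiotic-entry) morphology beyond the
#' meiotic onset, and DTC membrane morphology truth.
#'
#' @param geometry a \linkS4class{GonadGeometry}
#' @param biology a \linkS4class{BiologyModel}
#' @param seed integer seed; the result is deterministic given
#'   (geometry, biology, seed)
#' @return a \linkS4class{GonadTruth}
#' @examples
#' tr <- generateTruth(GonadGeometry(nCells = 40), BiologyModel(1), seed = 1)
#' head(truthCells(tr))
#' @export
generateTruth <- function(geometry = GonadGeometry(),
                          biology = BiologyModel(1), seed) {
  stopifnot(is(geometry, "GonadGeometry"), is(biology, "BiologyModel"))
  validObject(geometry); validObject(biology)
  .with_seed(seed, {
    R <- geometry@tubeRadius
    # --- DTC nucleus ---
    drift <- sampleDrift(1, biology)
    theta_max <- asin(min(1, (R - 2) / max(drift, 1e-9)))
    th <- runif(1, 0, theta_max)
    phi <- runif(1, 0, 2 * pi)
    rho <- drift * sin(th)
    dtc_center <- c(x = drift * cos(th), y = rho * cos(phi),
                    z = rho * sin(phi))
    dtc <- list(center = dtc_center,
                semiAxes = c(3.0, 1.5, 1.5),  # axis ratio 2, xy-plane long axis
                angle = runif(1, 0, pi),
                drift = drift)
    # --- germ nuclei ---
    n <- as.integer(geometry@nCells)
    radii <- pmax(1.0, rnorm(n, geometry@cellDiameterMean / 2,
                             geometry@cellDiameterSd / 2))
    pk <- .pack_nuclei(n, geometry, radii, avoid = dtc_center, avoid_r = 3.2)
    ax <- pk[, "x"]
    morph <- rep("mitotic", n)
    if (n > 0) {
      mei <- ax > biology@meioticOnset & runif(n) < biology@crescentProb
      morph[mei] <- "crescent"
    }
    nucleolus <- pmax(0.8, rnorm(n, biology@nucleolusDiameterMean,
                                 biology@nucleolusDiameterSd))
    nucleolus[morph == "crescent"] <- NA_real_
    # --- locus activation and ATS ---
    # the activation pattern is tethered to the niche nucleus: a drifted
    # DTC drags the profile proximally by the same amount (scaled by the
    # coupling strength), and the vacated distal region decays
    shift <- biology@activationCoupling * (drift - biology@driftRef)
    q <- .per_locus_prob_shifted(ax, biology, shift)
    locus_states <- lapply(seq_len(n), function(i)
      as.logical(rbinom(biology@nLoci, 1, q[i])))
    n_ats <- vapply(locus_states, sum, 1L)
    ats <- NULL
    for (i in which(n_ats > 0)) {
      pos <- .sample_loci_positions(n_ats[i], pk[i, 1:3], 0.62 * pk[i, "r"])
      ats <- rbind(ats, data.frame(
        cell_id = i, x = pos[, 1], y = pos[, 2], z = pos[, 3],
        intensity_au = rlnorm(n_ats[i], biology@atsMeanlog,
                              biology@atsSdlog)))
    }
    if (is.null(ats))
      ats <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), intensity_au = numeric(0))
    ats <- cbind(ats_id = seq_len(nrow(ats)), ats)
    # --- cytoplasmic mRNAs ---
    pmax_prof <- max(biology@activationAnchors[, 2])
    mu <- biology@mrnaPeakMean *
      .activation_prob_shifted(ax, biology, shift) / pmax_prof
    n_mrna_target <- if (n > 0)
      rnbinom(n, size = biology@mrnaDispersion, mu = mu) else integer(0)
    cv <- biology@mrnaIntensityCv
    mrna <- NULL
    n_mrna <- integer(n)
    for (i in which(n_mrna_target > 0)) {
      pos <- .sample_mrna_positions(n_mrna_target[i], pk[i, 1:3],
                                    pk[i, "r"], pk, geometry)
      if (nrow(pos) == 0) next
      n_mrna[i] <- nrow(pos)
      mrna <- rbind(mrna, data.frame(
        cell_id = i, x = pos[, 1], y = pos[, 2], z = pos[, 3],
        intensity_au = pmax(0.3, rnorm(nrow(pos), 1, cv))))
    }
    if (is.null(mrna))
      mrna <- data.frame(cell_id = integer(0), x = numeric(0),
                         y = numeric(0), z = numeric(0),
                         intensity_au = numeric(0))
    mrna <- cbind(mrna_id = seq_len(nrow(mrna)), mrna)
    cells <- data.frame(
      cell_id = seq_len(n),
      x = pk[, "x"], y = pk[, "y"], z = pk[, "z"], r = pk[, "r"],
      nucleolus_diameter = nucleolus,
      morphology = morph,
      axial_distance = ax,
      n_ats = as.integer(n_ats),
      n_mrna = n_mrna)
    cells$locus_states <- locus_states
    membrane <- .sample_membrane_truth(biology, geometry)
    new("GonadTruth", cells = cells, ats = ats, mrna = mrna, dtc = dtc,
        scalars = list(ageDay = biology@ageDay, seed = seed,
                       membrane = membrane),
        geometry = geometry)
  })
}
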