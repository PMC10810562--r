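# Nucleus reconstruction: normalization, per-plane circle detection, chain
# assembly criteria, DAPI summation, morphology and DTC identification.

disc_plane <- function(nx, ny, centers, radius_px, bg = 1, amp = 3) {
  m <- matrix(bg, nx, ny)
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(nx)) {
      dx2 <- (i - centers[k, 1])^2
      sel <- which(dx2 + (seq_len(ny) - centers[k, 2])^2 <= radius_px^2)
      m[i, sel] <- amp
    }
  }
  # PSF-like lateral blur so the disc has realistic soft edges
  nicheQuant:::.cpp_blur3d(array(m, c(nx, ny, 1)),
                           c(nx, ny, 1L), 1.2, 1.2, 0)[, , 1]
}

test_that("DAPI normalization maps the background to 1.0", {
  p <- matrix(7, 50, 50)
  out <- normalizeDapiPlane(p)
  expect_equal(as.numeric(out), rep(1, 2500))
  expect_equal(attr(out, "background"), 7)
  p2 <- matrix(10, 60, 60); p2[20:35, 20:35] <- 100
  out2 <- normalizeDapiPlane(p2)
  mask <- p2 < 50
  expect_equal(mean(out2[nicheQuant:::.erode(mask, 2)]), 1.0,
               tolerance = 1e-12)
  expect_error(normalizeDapiPlane(matrix(0, 5, 5)), "background")
})

test_that("normalization holds plane-wise on a rendered stack", {
  tr <- generateTruth(smallGeometry(12), BiologyModel(1), seed = 51)
  st <- renderStack(tr, OpticsModel(), seed = 52, channels = "dapi")
  arr <- getChannel(st, "dapi")
  bg_means <- vapply(seq_len(dim(arr)[3]), function(z) {
    out <- normalizeDapiPlane(arr[, , z])
    thr <- nicheQuant:::.otsu(as.numeric(arr[, , z]))
    mean(out[nicheQuant:::.erode(arr[, , z] < thr, 2)])
  }, 0)
  expect_true(all(bg_means > 0.98 & bg_means < 1.02))
})

test_that("plane circle detection finds discs and nothing in blank planes", {
  expect_equal(nrow(detectPlaneCircles(matrix(1, 80, 80), 0.13)), 0)
  px <- 0.13
  r_px <- 1.8 / px
  one <- disc_plane(120, 120, cbind(60, 60), r_px)
  cc <- detectPlaneCircles(one, px)
  expect_equal(nrow(cc), 1)
  expect_lt(abs(cc$r - 1.8), 0.3)
  expect_lt(abs(cc$x - 60 * px + px / 2), 0.2)
  expect_lt(abs(cc$y - 60 * px + px / 2), 0.2)
  two <- disc_plane(200, 120, cbind(c(50, 50 + 10 / px), c(60, 60)), r_px)
  cc2 <- detectPlaneCircles(two, px)
  expect_equal(nrow(cc2), 2)
})

test_that("chain criteria are enforced bit-exactly", {
  mk_chain <- function(zs, x, y, jitter = 0) {
    data.frame(z_index = zs,
               x = x + jitter * rep_len(c(1, -1), length(zs)),
               y = y, r = 1.5, score = 0.5)
  }
  # 3 consecutive planes: rejected (needs >= 4)
  expect_equal(nrow(assembleNuclei(mk_chain(1:3, 5, 5), 0.3)), 0)
  # 4 consecutive planes: accepted
  expect_equal(nrow(assembleNuclei(mk_chain(1:4, 5, 5), 0.3)), 1)
  # 4 planes with a gap (non-consecutive): rejected
  expect_equal(nrow(assembleNuclei(mk_chain(c(1, 2, 4, 5), 5, 5), 0.3)), 0)
  # 5-plane chain with XY spread 0.6 um: rejected (< 0.5 um required)
  spread <- mk_chain(1:5, 5, 5)
  spread$x <- 5 + c(-0.3, 0.3, -0.3, 0.3, -0.3)  # max dev from centroid 0.36
  spread$x[1] <- 5 - 0.62                        # one outlier: spread > 0.5
  expect_equal(nrow(assembleNuclei(spread, 0.3, maxSpread = 0.5)), 0)
  # same chain with spread < 0.5: accepted
  tight <- mk_chain(1:5, 5, 5, jitter = 0.1)
  expect_equal(nrow(assembleNuclei(tight, 0.3)), 1)
})

test_that("chain assembly is invariant to circle order within planes", {
  set.seed(8)
  circles <- do.call(rbind, lapply(1:8, function(z)
    data.frame(z_index = z,
               x = c(5, 9, 13) + rnorm(3, 0, 0.05),
               y = c(5, 5, 5) + rnorm(3, 0, 0.05),
               r = 1.5, score = runif(3, 0.3, 0.6))))
  a <- assembleNuclei(circles, 0.3)
  perm <- circles[sample(nrow(circles)), ]
  b <- assembleNuclei(perm, 0.3)
  expect_equal(a, b)
})

test_that("sphere fit recovers center and radius from a circle stack", {
  z0 <- 1.65; R <- 1.8
  zi <- 1:11
  zw <- (zi - 0.5) * 0.3
  rr <- sqrt(pmax(0, R^2 - (zw - z0)^2))
  keep <- rr > 0.3
  circles <- data.frame(z_index = zi[keep], x = 5, y = 5, r = rr[keep],
                        score = 1)
  nuc <- assembleNuclei(circles, 0.3)
  expect_equal(nrow(nuc), 1)
  expect_lt(abs(nuc$z - z0), 0.12)
  expect_lt(abs(nuc$r - R), 0.1)
})

test_that("sumDapi equals a brute-force voxel scan and is linear", {
  geo <- smallGeometry(0)
  st <- new("GonadStack", img = array(1, c(40, 40, 20, 1)),
            channels = "dapi", pixelSizeXY = 0.13, zStep = 0.3)
  arr <- getChannel(st, "dapi")
  nuc <- data.frame(nucleus_id = 1L, x = 2.6, y = 0, z = 0, r = 1.2)
  out <- sumDapi(nuc, arr, st)
  # brute force: voxel centers inside the sphere
  d <- dim(arr)
  cnt <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- nicheQuant:::.stack_world(st, cbind(i - 1, j - 1, k - 1))
    if (((w[1] - 2.6)^2 + w[2]^2) / 1.2^2 + w[3]^2 / 1.2^2 <= 1)
      cnt <- cnt + 1
  }
  expect_equal(out$dapi_sum, cnt)
  # degenerate radius: still at least the containing voxel
  tiny <- sumDapi(data.frame(nucleus_id = 1L, x = 2.6, y = 0, z = 0,
                             r = 0.01), arr, st)
  expect_gte(tiny$n_voxels, 1)
  # linearity
  out2 <- sumDapi(nuc, arr * 2, st)
  expect_equal(out2$dapi_sum, 2 * out$dapi_sum)
})

test_that("morphology classes are recovered from rendered nuclei", {
  geo <- GonadGeometry(tubeLength = 30, tubeRadius = 6, nCells = 0)
  cells <- data.frame(cell_id = 1:2, x = c(6, 14), y = 0, z = 0, r = 1.9,
                      nucleolus_diameter = c(1.5, NA),
                      morphology = c("mitotic", "crescent"))
  tr <- makeTruthFixture(cells = cells, geometry = geo,
                         dtc = list(center = c(x = 23, y = 0, z = 0),
                                    semiAxes = c(3, 1.5, 1.5),
                                    angle = 0.5, drift = 23))
  st <- renderStack(tr, OpticsModel(), seed = 61, channels = "dapi")
  nuc <- segmentNuclei(st)$nuclei
  near <- function(x0) nuc[which.min(abs(nuc$x - x0)), ]
  expect_equal(near(6)$morphology, "mitotic")
  expect_equal(near(14)$morphology, "crescent")
  expect_equal(near(23)$morphology, "dtc_candidate")
  # DTC axis-ratio-2 ellipsoid: high eccentricity, no dark core
  expect_gte(near(23)$eccentricity, 0.6)
  # a uniform sphere is never classified crescent
  expect_false(near(23)$morphology == "crescent")
  expect_equal(identifyDtc(nuc), near(23)$nucleus_id)
})

test_that("identifyDtc follows score then distal tie-break and errors cleanly", {
  nuc <- data.frame(nucleus_id = 1:3, x = c(8, 3, 20), y = 0, z = 0,
                    r = 2, morphology = c("dtc_candidate", "dtc_candidate",
                                          "mitotic"),
                    dtc_score = c(0.9, 0.9, 2))
  expect_equal(identifyDtc(nuc), 2)     # tie -> closer to the tip
  nuc$dtc_score[1] <- 1.5
  expect_equal(identifyDtc(nuc), 1)     # higher score wins
  one <- nuc[1, ]
  expect_equal(identifyDtc(one), 1)
  expect_error(identifyDtc(nuc[nuc$morphology == "mitotic", ]),
               "DTC not found")
})

test_that("nucleolus diameters are recovered in the resolvable range", {
  geo <- GonadGeometry(tubeLength = 36, tubeRadius = 6, nCells = 0)
  diams <- c(1.5, 1.75, 2.0)
  cells <- data.frame(cell_id = 1:3, x = seq(4, by = 5, length.out = 3),
                      y = 0, z = 0, r = 1.9, nucleolus_diameter = diams,
                      morphology = "mitotic")
  tr <- makeTruthFixture(cells = cells, geometry = geo,
                         dtc = list(center = c(x = 1, y = 0, z = 5),
                                    semiAxes = c(3, 1.5, 1.5), angle = 0,
                                    drift = 1))
  st <- renderStack(tr, OpticsModel(), seed = 71, channels = "dapi")
  nuc <- segmentNuclei(st)$nuclei
  nuc <- nuc[nuc$morphology == "mitotic", ]
  nuc <- nuc[order(nuc$x), ]
  expect_equal(sum(is.na(nuc$nucleolus_diameter)), 0)
  expect_lt(abs(nuc$nucleolus_diameter[1] - 1.5), 0.3)
  fit <- lm(nuc$nucleolus_diameter ~ diams)
  expect_gt(coef(fit)[2], 0.6); expect_lt(coef(fit)[2], 1.4)
  # a core-free nucleus yields an absent value
  cells2 <- data.frame(cell_id = 1L, x = 6, y = 0, z = 0, r = 1.9,
                       nucleolus_diameter = NA_real_,
                       morphology = "mitotic")
  tr2 <- makeTruthFixture(cells = cells2, geometry = geo,
                          dtc = list(center = c(x = 1, y = 0, z = 5),
                                     semiAxes = c(3, 1.5, 1.5), angle = 0,
                                     drift = 1))
  st2 <- renderStack(tr2, OpticsModel(), seed = 72, channels = "dapi")
  nuc2 <- segmentNuclei(st2)$nuclei
  expect_true(is.na(nuc2$nucleolus_diameter[which.min(abs(nuc2$x - 6))]))
})

test_that("segmentation recovers a packed gonad at high recall/precision", {
  tr <- generateTruth(GonadGeometry(), BiologyModel(1), seed = 42)
  st <- renderStack(tr, OpticsModel(), seed = 43, channels = "dapi")
  nuc <- segmentNuclei(st)$nuclei
  rs <- recovery_stats(nuc, tr, tol = 2)
  expect_gte(rs$recall, 0.95)
  expect_gte(rs$precision, 0.95)
  expect_lt(median(rs$center_err), 0.5)
  # emitted records satisfy their own invariants
  expect_true(all(nuc$r > 0))
  expect_true(all(nuc$n_planes >= 4))
  expect_true(all(nuc$spread < 0.5))
  # merge rule: no two nuclei overlap by more than 25% of the smaller radius
  m <- as.matrix(nuc[, c("x", "y", "z")])
  d <- as.matrix(dist(m)); diag(d) <- Inf
  ovl <- outer(nuc$r, nuc$r, "+") - d
  lim <- 0.25 * outer(nuc$r, nuc$r, pmin)
  expect_true(all(ovl <= lim + 1e-9))
})
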