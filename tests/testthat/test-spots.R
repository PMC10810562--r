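# Spot detection: peak finding, the two ratio filters, colocalization, ATS
# calling, single-mRNA normalization and capped-Voronoi assignment.

test_that("local peak detection: empty on constant, exact on one spot", {
  geo <- smallGeometry(0)
  st0 <- new("GonadStack", img = array(5, c(60, 60, 20, 1)),
             channels = "exon", pixelSizeXY = 0.13, zStep = 0.3)
  mask <- array(TRUE, c(60, 60, 20))
  expect_equal(nrow(localPeaks(getChannel(st0, "exon"), st0, mask)), 0)
  mrna <- data.frame(mrna_id = 1L, cell_id = 1L, x = 9.7, y = -1.1, z = 0.8,
                     intensity_au = 1)
  tr <- makeTruthFixture(mrna = mrna, geometry = geo)
  st <- renderStack(tr, OpticsModel(shotNoise = FALSE), seed = 1,
                    channels = "exon")
  m2 <- nicheQuant:::.germline_mask(st, geo)
  pk <- localPeaks(getChannel(st, "exon"), st, m2)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x - 9.7), 0.13)
  expect_lt(abs(pk$y + 1.1), 0.13)
  expect_lt(abs(pk$z - 0.8), 0.3)
})

test_that("well-separated mRNAs are recovered at >= 95% under default noise", {
  geo <- GonadGeometry(tubeLength = 40, tubeRadius = 8, nCells = 0)
  set.seed(123)
  # 100 spots with pairwise separation >= 1 um
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < 100) {
    p <- c(runif(1, 1, 39), runif(1, -5, 5), runif(1, -5, 5))
    if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) >= 1)
      pts <- rbind(pts, p)
  }
  mrna <- data.frame(mrna_id = seq_len(100), cell_id = 1L,
                     x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     intensity_au = pmax(0.3, rnorm(100, 1, 0.15)))
  tr <- makeTruthFixture(mrna = mrna, geometry = geo)
  st <- renderStack(tr, OpticsModel(), seed = 5, channels = "exon")
  mask <- nicheQuant:::.germline_mask(st, geo)
  arr <- getChannel(st, "exon")
  cand <- scoreCandidates(localPeaks(arr, st, mask), arr, mask)
  hit <- vapply(seq_len(100), function(i)
    min(sqrt((cand$x - pts[i, 1])^2 + (cand$y - pts[i, 2])^2 +
             (cand$z - pts[i, 3])^2)) < 0.5, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("candidate filters enforce the two background ratios", {
  cands <- data.frame(x = 1:3, y = 0, z = 0,
                      peak_value = c(10.4, 9.9, 15),
                      raw_intensity = 1, local_bg = c(10, 5, 10))
  arr <- array(10, c(4, 4, 4)); mask <- array(TRUE, c(4, 4, 4))
  out <- scoreCandidates(cands, arr, mask)
  # local ratio 1.04 -> dropped; overall ratio 0.99 -> dropped; (1.5,1.5) kept
  expect_equal(nrow(out), 1)
  expect_equal(out$peak_value, 15)
  expect_gt(out$local_ratio, 1.05)
  expect_gt(out$overall_ratio, 1.0)
  # monotonicity: relaxing the local threshold never loses candidates
  n_strict <- nrow(scoreCandidates(cands, arr, mask, localMin = 1.05))
  n_loose <- nrow(scoreCandidates(cands, arr, mask, localMin = 1.01))
  expect_gte(n_loose, n_strict)
})

test_that("colocalization is mutual-nearest within tolerance", {
  a <- data.frame(x = c(1, 5, 9), y = 0, z = 0)
  prs <- colocalizeSpots(a, a, tol = 0.4)
  expect_equal(nrow(prs), 3)
  expect_equal(prs$ia, prs$ib)
  expect_equal(prs$dist, rep(0, 3))
  b <- data.frame(x = 1.6, y = 0, z = 0)   # 0.6 um away, tol 0.4
  expect_equal(nrow(colocalizeSpots(a[1, ], b, tol = 0.4)), 0)
})

test_that("colocalization matches optimal assignment on small instances", {
  set.seed(6)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    base <- cbind(runif(n, 0, 20), runif(n, -3, 3), runif(n, -3, 3))
    # paired instance: partner spots jittered within tolerance, spots apart
    keep <- oracle_nnd(base) > 1.2
    a <- base[keep, , drop = FALSE]
    b <- a + matrix(rnorm(3 * nrow(a), 0, 0.08), ncol = 3)
    drop_b <- runif(nrow(b)) < 0.3
    b2 <- b[!drop_b, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b2) == 0) next
    prs <- colocalizeSpots(as.data.frame(`colnames<-`(a, c("x", "y", "z"))),
                           as.data.frame(`colnames<-`(b2, c("x", "y", "z"))),
                           tol = 0.4)
    opt <- oracle_matching(a, b2, tol = 0.4)
    expect_equal(nrow(prs), opt$npairs)
    expect_equal(sum(prs$dist), opt$cost, tolerance = 1e-9)
  }
})

test_that("single-mRNA normalization forces a cytoplasmic mean of exactly 1", {
  nuclei <- data.frame(nucleus_id = 1L, x = 50, y = 0, z = 0, r = 2)
  cands <- data.frame(x = c(1, 2, 50.5), y = 0, z = 0,
                      peak_value = 5, raw_intensity = c(2, 4, 9),
                      local_bg = 1)
  mr <- callMrna(cands, nuclei)
  cyto <- mr$spots[mr$spots$spot_class == "mrna_cyto", ]
  expect_equal(cyto$intensity_au, c(2 / 3, 4 / 3))
  expect_equal(mean(cyto$intensity_au), 1, tolerance = 1e-15)
  expect_equal(mr$single_mrna_intensity, 3)
  expect_equal(mr$spots$spot_class[3], "mrna_nuclear")
  # all spots nuclear: normalization undefined
  allnuc <- data.frame(x = 50.2, y = 0, z = 0, peak_value = 5,
                       raw_intensity = 3, local_bg = 1)
  expect_error(callMrna(allnuc, nuclei), "no cytoplasmic")
})

test_that("ATS calling enforces nuclear position, pairing and brightness", {
  nuclei <- data.frame(nucleus_id = 1:2, x = c(5, 12), y = 0, z = 0, r = 2)
  exon <- data.frame(x = c(5.2, 12.1, 30), y = 0, z = 0, peak_value = 9,
                     raw_intensity = c(6, 1.6, 2), local_bg = 1)
  mr <- callMrna(exon, nuclei)        # unit = 2 (the cytoplasmic spot)
  expect_equal(mr$single_mrna_intensity, 2)
  intron <- data.frame(x = c(5.2, 12.1, 7.3), y = 0, z = 0,
                       peak_value = 9, raw_intensity = c(4, 1.4, 5),
                       local_bg = 1)
  ats <- callAts(intron, mr$spots, nuclei, mr$single_mrna_intensity)
  # spot at x=5.2: in nucleus 1, paired, intron 2 a.u. & exon 3 a.u. -> kept
  # spot at x=12.1: exon 0.8 a.u. < 1 -> rejected
  # spot at x=7.3: 0.3 um outside nucleus 1 -> rejected
  expect_equal(nrow(ats), 1)
  expect_equal(ats$nucleus_id, 1L)
  expect_equal(ats$intensity_au, 3)   # exon-channel a.u. is reported
  expect_error(callAts(intron, mr$spots, nuclei[0, ], 2), "nuclei")
})

test_that("capped-Voronoi assignment matches brute force and its cap", {
  nuclei <- data.frame(nucleus_id = c(4L, 9L), x = c(5, 10), y = 0, z = 0)
  spots <- data.frame(x = c(8.2, 7.5, 5.1), y = c(0, 0, 3.19), z = 0)
  out <- assignToCells(spots, nuclei, capRadius = 3)
  expect_equal(out$cell_id[1], 9L)              # nearest center
  expect_equal(out$cell_id[2], 4L)              # tie -> lower nucleus_id
  expect_true(is.na(out$cell_id[3]))            # 3.19 um > 3 um cap
  set.seed(14)
  ns <- 200
  sp <- data.frame(x = runif(ns, 0, 30), y = runif(ns, -5, 5),
                   z = runif(ns, -5, 5))
  nu <- data.frame(nucleus_id = sample(1000, 40),
                   x = runif(40, 0, 30), y = runif(40, -5, 5),
                   z = runif(40, -5, 5))
  got <- assignToCells(sp, nu, capRadius = 3)$cell_id
  want <- oracle_assign(as.matrix(sp), as.matrix(nu[, c("x", "y", "z")]),
                        nu$nucleus_id, cap = 3)
  expect_identical(got, want)
})

test_that("rendered gonad: ATS recovery, a.u. normalization and CV", {
  geo <- GonadGeometry()
  tr <- generateTruth(geo, BiologyModel(1), seed = 42)
  st <- renderStack(tr, OpticsModel(), seed = 43)
  nuc <- segmentNuclei(st)$nuclei
  det <- detectSpots(st, nuc, geo)
  cyto <- det$spots[det$spots$spot_class == "mrna_cyto", ]
  # normalization identity at machine precision
  expect_equal(mean(cyto$intensity_au), 1, tolerance = 1e-12)
  # per-cell ATS counts stay within the locus budget
  cnt <- table(det$ats$nucleus_id)
  expect_true(all(cnt <= 4))
  # cell-level sensitivity vs truth
  tc <- truthCells(tr)
  pos_cells <- tc[tc$n_ats > 0, ]
  hit <- vapply(seq_len(nrow(pos_cells)), function(i) {
    dd <- sqrt((nuc$x - pos_cells$x[i])^2 + (nuc$y - pos_cells$y[i])^2 +
               (nuc$z - pos_cells$z[i])^2)
    j <- nuc$nucleus_id[which.min(dd)]
    min(dd) < 2 && j %in% det$ats$nucleus_id
  }, TRUE)
  expect_gte(mean(hit), 0.9)
  # detected cytoplasmic a.u. spread tracks the generator's narrow law:
  # photon/background noise and unresolved proximate pairs can only widen
  # it, and the robust spread stays within the predicted measurement noise
  rcv <- mad(cyto$intensity_au) / median(cyto$intensity_au)
  truth_cv <- sd(truthMrna(tr)$intensity_au) / mean(truthMrna(tr)$intensity_au)
  expect_gte(rcv, 0.8 * truth_cv)
  expect_lte(rcv, truth_cv + 0.12)
  expect_lt(abs(median(cyto$intensity_au) - 1), 0.1)
  # every called ATS lies inside its nucleus sphere
  i <- match(det$ats$nucleus_id, nuc$nucleus_id)
  dd <- sqrt((det$ats$x - nuc$x[i])^2 + (det$ats$y - nuc$y[i])^2 +
             (det$ats$z - nuc$z[i])^2)
  expect_true(all(dd <= nuc$r[i]))
})
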