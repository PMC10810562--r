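# Shared fixtures and independent brute-force oracles for the test suite.
# Fixtures are built in code at test time; no binary data ship with the
# package.

# small gonad geometry so unit-test renders stay fast
smallGeometry <- function(nCells = 15, tubeLength = 20, tubeRadius = 6) {
  GonadGeometry(tubeLength = tubeLength, tubeRadius = tubeRadius,
                nCells = nCells)
}

empty_spots_df <- function(id = "ats_id") {
  setNames(data.frame(integer(0), integer(0), numeric(0), numeric(0),
                      numeric(0), numeric(0)),
           c(id, "cell_id", "x", "y", "z", "intensity_au"))
}

# hand-built GonadTruth with full control over cells / spots / membrane
makeTruthFixture <- function(cells = NULL, ats = NULL, mrna = NULL,
                             dtc = NULL, membrane = NULL,
                             geometry = smallGeometry(0)) {
  if (is.null(cells)) {
    cells <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), r = numeric(0),
                        nucleolus_diameter = numeric(0),
                        morphology = character(0),
                        axial_distance = numeric(0),
                        n_ats = integer(0), n_mrna = integer(0))
    cells$locus_states <- list()
  } else {
    if (is.null(cells$nucleolus_diameter))
      cells$nucleolus_diameter <- rep(1.5, nrow(cells))
    if (is.null(cells$morphology))
      cells$morphology <- rep("mitotic", nrow(cells))
    if (is.null(cells$axial_distance)) cells$axial_distance <- cells$x
    if (is.null(cells$n_ats)) cells$n_ats <- 0L
    if (is.null(cells$n_mrna)) cells$n_mrna <- 0L
    if (is.null(cells$locus_states))
      cells$locus_states <- lapply(cells$n_ats, function(k)
        c(rep(TRUE, k), rep(FALSE, 4 - k)))
  }
  if (is.null(ats)) ats <- empty_spots_df("ats_id")
  if (is.null(mrna)) mrna <- empty_spots_df("mrna_id")
  if (is.null(dtc))
    dtc <- list(center = c(x = 1, y = 0, z = geometry@tubeRadius - 1.2),
                semiAxes = c(3, 1.5, 1.5), angle = 0, drift = 1)
  if (is.null(membrane))
    membrane <- list(capExtent = 5, gaps = NULL, fragments = NULL,
                     lepExtent = min(18, geometry@tubeLength - 2),
                     sipExtent = 12, lepPhi = c(0, pi), sipX = c(7, 9))
  new("GonadTruth", cells = cells, ats = ats, mrna = mrna, dtc = dtc,
      scalars = list(ageDay = 1, seed = 0, membrane = membrane),
      geometry = geometry)
}

# ---- brute-force oracles ---------------------------------------------------

# all-pairs nearest-neighbour distances, O(n^2)
oracle_nnd <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    dd <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- min(dd, sqrt(sum((m[i, ] - m[j, ])^2)))
    }
    out[i] <- dd
  }
  out
}

# capped nearest-center assignment, O(n*m), lowest-id tie-break
oracle_assign <- function(spots, centers, ids, cap) {
  out <- rep(NA_integer_, nrow(spots))
  ord <- order(ids)
  centers <- centers[ord, , drop = FALSE]; ids <- ids[ord]
  for (i in seq_len(nrow(spots))) {
    best <- Inf; bid <- NA_integer_
    for (j in seq_len(nrow(centers))) {
      dd <- sqrt(sum((spots[i, ] - centers[j, ])^2))
      if (dd < best - 1e-12) { best <- dd; bid <- ids[j] }
    }
    if (is.finite(best) && best <= cap) out[i] <- bid
  }
  out
}

# hand binning of a percent profile
oracle_profile <- function(d, pos, binWidth, maxD) {
  edges <- seq(0, binWidth * ceiling(maxD / binWidth + 1e-9), by = binWidth)
  pc <- nn <- numeric(length(edges) - 1)
  for (b in seq_len(length(edges) - 1)) {
    sel <- d >= edges[b] & d < edges[b + 1]
    nn[b] <- sum(sel)
    pc[b] <- if (nn[b] > 0) 100 * sum(pos[sel]) / nn[b] else NA_real_
  }
  list(percent = pc, n = nn)
}

# exact min-cost bipartite matching within tolerance, by enumeration
# (instances <= 7 x 7); returns number of pairs and total cost
oracle_matching <- function(a, b, tol) {
  na <- nrow(a); nb <- nrow(b)
  d <- matrix(Inf, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  d[d > tol] <- Inf
  best <- list(npairs = 0, cost = 0)
  # enumerate all injective partial assignments greedily via recursion
  rec <- function(i, used, npairs, cost) {
    if (i > na) {
      if (npairs > best$npairs ||
          (npairs == best$npairs && cost < best$cost - 1e-12))
        best <<- list(npairs = npairs, cost = cost)
      return(invisible())
    }
    rec(i + 1, used, npairs, cost)            # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (used[j] || !is.finite(d[i, j])) next
      used[j] <- TRUE
      rec(i + 1, used, npairs + 1, cost + d[i, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, nb), 0, 0)
  best
}

# nuclei recovery against truth: recall / precision matched within `tol` um
recovery_stats <- function(nuclei, truth, tol = 2) {
  tc <- truthCells(truth)
  allt <- rbind(as.matrix(tc[, c("x", "y", "z")]),
                matrix(truthDtc(truth)$center, 1))
  if (nrow(tc) == 0) return(list(recall = NA, precision = NA))
  derr <- vapply(seq_len(nrow(tc)), function(i)
    min(sqrt((nuclei$x - tc$x[i])^2 + (nuclei$y - tc$y[i])^2 +
             (nuclei$z - tc$z[i])^2)), 0)
  perr <- vapply(seq_len(nrow(nuclei)), function(i)
    min(sqrt((allt[, 1] - nuclei$x[i])^2 + (allt[, 2] - nuclei$y[i])^2 +
             (allt[, 3] - nuclei$z[i])^2)), 0)
  list(recall = mean(derr < tol), precision = mean(perr < tol),
       center_err = derr)
}
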