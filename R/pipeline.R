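# End-to-end orchestration: render -> segment -> detect -> quantify for
# single gonads and cohorts.

#' Analyze one gonad stack end to end
#'
#' Runs nucleus segmentation, DTC localization, RNA spot detection and the
#' per-cell table on a rendered (or real, same layout) stack.
#'
#' @param stack a \linkS4class{GonadStack} with dapi, intron, exon channels
#' @param geometry the \linkS4class{GonadGeometry} of the sample
#' @param ... tuning parameters passed to \code{\link{segmentNuclei}}
#' @return list: nuclei, spots, cells (per-cell table), dtc_id (NA if not
#'   found), dtc_shift (um), single_mrna_intensity
#' @export
analyzeGonad <- function(stack, geometry, ...) {
  seg <- segmentNuclei(stack, ...)
  nuclei <- seg$nuclei
  dtc_id <- tryCatch(identifyDtc(nuclei), error = function(e) NA_integer_)
  det <- detectSpots(stack, nuclei, geometry)
  cells <- buildCellTable(nuclei, det$spots, dtc_id)
  shift <- if (!is.na(dtc_id)) {
    k <- which(nuclei$nucleus_id == dtc_id)
    dtcShift(unlist(nuclei[k, c("x", "y", "z")]))
  } else NA_real_
  list(nuclei = nuclei, spots = det$spots, cells = cells,
       dtc_id = dtc_id, dtc_shift = shift,
       single_mrna_intensity = det$single_mrna_intensity)
}

#' Simulate and analyze a cohort of synthetic gonads
#'
#' For each gonad: generate truth, render the stack, run the full detection
#' pipeline, and collect the per-gonad summaries.  Stacks are discarded
#' after analysis so memory stays flat; truth objects are kept for
#' recovery checks.
#'
#' @param nGonads cohort size
#' @param geometry,biology,optics model configuration
#' @param masterSeed integer master seed (per-gonad seeds derive from it)
#' @param binWidth profile bin width (um)
#' @param keepTruth keep the GonadTruth objects in the result
#' @return list with per-gonad \code{results} (cells, dtc_shift, profile,
#'   ...), \code{profiles} (list of per-gonad percent profiles) and
#'   \code{truths} (if kept)
#' @export
analyzeCohort <- function(nGonads, geometry = GonadGeometry(),
                          biology = BiologyModel(1), optics = OpticsModel(),
                          masterSeed, binWidth = 2.5, keepTruth = TRUE) {
  seeds <- gonadSeeds(masterSeed, nGonads)
  results <- vector("list", nGonads)
  truths <- vector("list", nGonads)
  profiles <- vector("list", nGonads)
  for (i in seq_len(nGonads)) {
    tr <- generateTruth(geometry, biology, seed = seeds[i])
    st <- renderStack(tr, optics, seed = seeds[i] + 1L)
    res <- analyzeGonad(st, geometry)
    profiles[[i]] <- percentProfile(res$cells, binWidth = binWidth,
                                    maxDistance = geometry@tubeLength)
    results[[i]] <- list(cells = res$cells, dtc_id = res$dtc_id,
                         dtc_shift = res$dtc_shift,
                         single_mrna_intensity = res$single_mrna_intensity,
                         n_nuclei = nrow(res$nuclei))
    truths[[i]] <- if (keepTruth) tr else NULL
    rm(st); gc(FALSE)
  }
  list(results = results, profiles = profiles,
       truths = if (keepTruth) truths else NULL, seeds = seeds)
}
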