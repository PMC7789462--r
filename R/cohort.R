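#' @include AllClasses.R phantom.R outcomes.R
NULL

#' Construct a cohort specification
#'
#' Defaults reproduce the three-group study structure: 22 patients with
#' decreased supine spirometry, 13 patients with normal spirometry and 18
#' healthy controls. Between-subject variability is driven by a latent
#' severity term shared by the CC and DH ratios (more severe weakness means
#' less motion and more paradoxical curvature) plus independent noise; the
#' published group means only constrain the centres, so the sds are
#' documented simulation choices.
#'
#' @param groups data.frame with columns `label`, `n`, `preset`.
#' @param betweenSubjectSd named numeric sds: `latent` (severity term),
#'   `cc`, `ap`, `dh`, `area` (independent parts) and `postDisp` (mm).
#' @param pftNoiseSd named numeric residual sds for `fvc_supine`,
#'   `fvc_upright`, `mip`, `mep` (% predicted).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(groups = data.frame(
                         label = c("decreased_spiro_pompe",
                                   "normal_spiro_pompe", "healthy"),
                         n = c(22L, 13L, 18L),
                         preset = c("decreased_spiro_pompe",
                                    "normal_spiro_pompe", "healthy"),
                         stringsAsFactors = FALSE),
                       betweenSubjectSd = c(latent = 0.10, cc = 0.05,
                                            ap = 0.05, dh = 0.06,
                                            area = 0.05, postDisp = 6),
                       pftNoiseSd = c(fvc_supine = 5, fvc_upright = 4,
                                      mip = 12, mep = 20)) {
  new("CohortSpec", groups = groups, betweenSubjectSd = betweenSubjectSd,
      pftNoiseSd = pftNoiseSd)
}

## Linear links from the true CC ratio to pulmonary function (% predicted),
## calibrated so the preset CC means map to the published group means of
## FVC supine (102/60), FVC upright (106/81) and MIP (106/72); MEP is
## deliberately only weakly linked. Simulation assumptions, not claims.
pftFromCC <- function(ccTrue, noiseSd, nse) {
  fvcSup <- -78.6 + 105 * ccTrue + nse(noiseSd["fvc_supine"])
  fvcUp <- -1.5 + 62.5 * ccTrue + nse(noiseSd["fvc_upright"])
  fvcUp <- pmax(fvcUp, fvcSup - 3)     # upright FVC rarely below supine
  mip <- -40.2 + 85 * ccTrue + nse(noiseSd["mip"])
  mep <- 95 + 10 * (ccTrue - 1.5) + nse(noiseSd["mep"])
  fvcUp <- round(fvcUp, 1); fvcSup <- round(fvcSup, 1)
  data.frame(fvc_upright_pct = fvcUp, fvc_supine_pct = fvcSup,
             delta_fvc_pct = deltaFVC(fvcUp, fvcSup),
             mip_pct = round(mip, 1), mep_pct = round(mep, 1))
}

ageMeanByGroup <- c(decreased_spiro_pompe = 45, normal_spiro_pompe = 31,
                    healthy = 43, severe = 50)
ageSdByGroup <- c(decreased_spiro_pompe = 16, normal_spiro_pompe = 14,
                  healthy = 14, severe = 14)

#' Generate a synthetic cohort
#'
#' Draws per-subject true outcome ratios around the group preset means,
#' builds each subject's phantom frame series, and simulates the subject
#' metadata (age, sex, pulmonary function as monotone functions of the
#' true CC ratio plus noise, so correlation structure between MRI and
#' pulmonary-function outcomes is recoverable by design). Fully
#' reproducible from the seed. Draws that would be geometrically
#' inconsistent are clamped to the feasible range before the phantom is
#' built; the truth table always records the realized analytic values.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @param output `"polygon"` (exact contours, fast) or `"mask"`.
#' @param nFrames,verticesPerContour,rasterSpacingMM forwarded to
#'   [phantomParams()].
#' @return list with `series` (list of [FrameSeries-class]), `metadata`
#'   (data.frame, one row per subject) and `truth` (data.frame of analytic
#'   outcomes).
#' @export
generateCohort <- function(spec = cohortSpec(), seed = 1L,
                           output = c("polygon", "mask"), nFrames = 15L,
                           verticesPerContour = 200L, rasterSpacingMM = 1) {
  output <- match.arg(output)
  set.seed(seed)
  sd <- spec@betweenSubjectSd
  rows <- list(); truths <- list(); series <- list()
  k <- 0L
  for (gi in seq_len(nrow(spec@groups))) {
    grp <- spec@groups[gi, ]
    base <- phantomPreset(grp$preset)
    for (si in seq_len(grp$n)) {
      k <- k + 1L
      id <- sprintf("S%03d", k)
      z <- stats::rnorm(1)
      ccR <- max(1.01, base@ccRatio + sd["latent"] * z +
                   stats::rnorm(1, 0, sd["cc"]))
      apBase <- base@ccRatio / base@ccApRatio
      apR <- max(1.0, apBase + stats::rnorm(1, 0, sd["ap"]))
      dhR <- max(0.3, base@dhRatio - 1.5 * sd["latent"] * z +
                   stats::rnorm(1, 0, sd["dh"]))
      ## keep the dome fullness at the preset's expiration-to-inspiration
      ## shift so the quartic family always covers the draw
      fullShift <- base@daRatio / (apBase * base@dhRatio)
      daR <- fullShift * apR * dhR
      areaR <- base@areaRatio * (ccR * apR) / (base@ccRatio * apBase) +
        stats::rnorm(1, 0, sd["area"])
      areaR <- clampAreaRatio(base, ccR, apR, dhR, daR, areaR)
      postD <- max(abs(base@apExpMM * (apR - 1)) + 2,
                   base@postDisplacementMM + stats::rnorm(1, 0, sd["postDisp"]))
      params <- phantomParams(
        ccExpMM = base@ccExpMM, apExpMM = base@apExpMM,
        domeHeightExpMM = base@domeHeightExpMM, capFracExp = base@capFracExp,
        ccRatio = ccR, ccApRatio = ccR / apR, areaRatio = areaR,
        daRatio = daR, dhRatio = dhR, postDisplacementMM = postD,
        nFrames = nFrames, verticesPerContour = verticesPerContour,
        rasterSpacingMM = rasterSpacingMM, seed = seed + k)
      ph <- generatePhantomSeries(params, output = output, subjectId = id)
      series[[k]] <- ph$series
      truths[[k]] <- cbind(ph$truth, data.frame(group = grp$label))
      nse <- function(s) stats::rnorm(1, 0, s)
      pft <- pftFromCC(ccR, spec@pftNoiseSd, nse)
      rows[[k]] <- cbind(
        data.frame(
          subject_id = id, group = grp$label,
          age = round(min(70, max(15, stats::rnorm(
            1, ageMeanByGroup[[grp$preset]], ageSdByGroup[[grp$preset]])))),
          sex = sample(c("m", "f"), 1)),
        pft,
        data.frame(z_fvc_supine = round((pft$fvc_supine_pct - 100) / 12, 2)))
    }
  }
  list(series = series, metadata = do.call(rbind, rows),
       truth = do.call(rbind, truths))
}

## Restrict a drawn lung-area ratio to the band the cap fraction can
## realize (fI in [0.03, 0.97]) for the drawn extents.
clampAreaRatio <- function(base, ccR, apR, dhR, daR, areaR) {
  apE <- base@apExpMM; ccE <- base@ccExpMM; hE <- base@domeHeightExpMM
  fullE <- base@domeFullnessExp
  areaE <- lungPolygonArea(apE, ccE + hE, hE, fullE, base@capFracExp)
  apI <- apE * apR; ccI <- ccE * ccR; hI <- hE * dhR
  fullI <- fullE * daR / (apR * dhR)
  TI <- ccI + hI
  areaAt <- function(f) (apI * TI * (1 - f * (1 - pi / 4)) - fullI * apI * hI) / areaE
  min(max(areaR, areaAt(0.97) + 1e-3), areaAt(0.03) - 1e-3)
}

#' Measure every subject of a cohort
#'
#' Convenience wrapper running [measureSeries()] over a list of series and
#' binding the per-subject records.
#'
#' @param seriesList list of [FrameSeries-class].
#' @param dhThresholdMM passed to [measureSeries()].
#' @return data.frame with one row per subject.
#' @export
measureCohort <- function(seriesList, dhThresholdMM = 0.5) {
  do.call(rbind, lapply(seriesList, function(s)
    measureSeries(s, dhThresholdMM = dhThresholdMM)$record))
}
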