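#' Construct a protease panel
#'
#' @param proteases character vector of biomarker names (panel order matters:
#'   it fixes feature order everywhere downstream).
#' @param consensus named character vector of consensus substrate sequences;
#'   metadata only, never used numerically.
#' @param groupMeans,groupSds numeric matrices (proteases x groups, group
#'   columns healthy/localized/metastatic) of net activity means and sds in
#'   arbitrary fluorescence units.
#' @param controlBaselineMean,controlBaselineSd baseline level and
#'   between-well variability of the SC/AC control wells (a.u.).
#' @return A [ProteasePanel-class].
#' @export
ProteasePanel <- function(proteases, consensus = setNames(rep("", length(proteases)), proteases),
                          groupMeans, groupSds,
                          controlBaselineMean = 50, controlBaselineSd = 5) {
  groupMeans <- as.matrix(groupMeans)
  groupSds <- as.matrix(groupSds)
  rownames(groupMeans) <- rownames(groupSds) <- proteases
  colnames(groupMeans) <- colnames(groupSds) <- CLASS_LEVELS
  new("ProteasePanel", proteases = proteases, consensus = consensus,
      groupMeans = groupMeans, groupSds = groupSds,
      controlBaselineMean = controlBaselineMean,
      controlBaselineSd = controlBaselineSd)
}

#' Default 7-protease ovarian-cancer panel
#'
#' The shipped synthetic panel: MMP3, MMP28, CTSK, MMP24, ADAM15, ADAM10/12
#' and ADAM17, with consensus substrate sequences as metadata and synthetic
#' per-group activity parameters. The parameters are free choices of this
#' package (they are not measurements); they encode the qualitative group
#' structure the analysis assumes:
#' healthy > localized > metastatic mean activity for MMP3, MMP28, CTSK,
#' MMP24 and ADAM10/12; for ADAM15 the metastatic mean sits near the healthy
#' mean, well above localized; ADAM17 group means are within 5% of each other
#' (a designed null biomarker). ADAM10 and ADAM12 are one feature because
#' their active centres are too similar for the substrate to distinguish.
#'
#' @param nProteases 7 (default) or 6 to drop ADAM17 and work with the
#'   six-biomarker panel variant.
#' @return A [ProteasePanel-class].
#' @export
#' @examples
#' defaultPanel()
defaultPanel <- function(nProteases = 7L) {
  stopifnot(nProteases %in% c(6L, 7L))
  proteases <- c("MMP3", "MMP28", "CTSK", "MMP24", "ADAM15", "ADAM10/12", "ADAM17")
  consensus <- c(
    "MMP3"      = "GAGRPFS-MIMGAG",
    "MMP28"     = "GAGMAPK-HKEMAG",
    "CTSK"      = "GAGAKLK-AENNAG",
    "MMP24"     = "GAGNSFG-LRFGAG",
    "ADAM15"    = "GAGAGSH-TTHGAG",
    "ADAM10/12" = "GAGHSQA-VKSQAG",
    "ADAM17"    = "GAGLAQA-VRSSAG"
  )
  means <- rbind(
    #           healthy localized metastatic
    "MMP3"      = c(1000, 700, 450),
    "MMP28"     = c( 900, 640, 430),
    "CTSK"      = c(1100, 760, 420),
    "MMP24"     = c( 800, 610, 450),
    "ADAM15"    = c( 850, 560, 830),
    "ADAM10/12" = c( 950, 680, 440),
    "ADAM17"    = c( 595, 595, 595) # designed null biomarker
  )
  sds <- rbind(
    "MMP3"      = c(220, 155, 100),
    "MMP28"     = c(200, 140,  95),
    "CTSK"      = c(240, 170,  95),
    "MMP24"     = c(175, 135, 100),
    "ADAM15"    = c(190, 125, 185),
    "ADAM10/12" = c(210, 150, 100),
    "ADAM17"    = c(130, 130, 130)
  )
  keep <- seq_len(nProteases)
  ProteasePanel(proteases[keep], consensus[keep],
                means[keep, , drop = FALSE], sds[keep, , drop = FALSE],
                controlBaselineMean = 50, controlBaselineSd = 5)
}

#' Rescale between-group separation of a panel
#'
#' Shrinks (or amplifies) each protease's group means toward/away from its
#' grand mean: `m' = grand + factor * (m - grand)`. `factor = 0` yields a
#' null panel (all group means equal — the type-I-error reference condition);
#' `factor = 1` is the panel unchanged. Standard deviations are untouched.
#'
#' @param panel a [ProteasePanel-class].
#' @param factor non-negative separation multiplier.
#' @return A [ProteasePanel-class].
#' @export
scaleSeparation <- function(panel, factor) {
  stopifnot(is(panel, "ProteasePanel"), factor >= 0)
  m <- groupMeans(panel)
  grand <- rowMeans(m)
  m2 <- grand + factor * (m - grand)
  ProteasePanel(panelProteases(panel), consensusSequences(panel),
                m2, groupSds(panel),
                panel@controlBaselineMean, panel@controlBaselineSd)
}

#' Panel accessors
#'
#' @param x a [ProteasePanel-class].
#' @return `panelProteases`: ordered character vector of names;
#'   `consensusSequences`: named character vector; `groupMeans`/`groupSds`:
#'   proteases x groups numeric matrices.
#' @name panelAccessors
NULL

#' @rdname panelAccessors
#' @export
setMethod("panelProteases", "ProteasePanel", function(x) x@proteases)

#' @rdname panelAccessors
#' @export
setMethod("consensusSequences", "ProteasePanel", function(x) x@consensus)

#' @rdname panelAccessors
#' @export
setMethod("groupMeans", "ProteasePanel", function(x) x@groupMeans)

#' @rdname panelAccessors
#' @export
setMethod("groupSds", "ProteasePanel", function(x) x@groupSds)

setMethod("show", "ProteasePanel", function(object) {
  cat(sprintf("ProteasePanel with %d proteases: %s\n",
              length(object@proteases),
              paste(object@proteases, collapse = ", ")))
  cat(sprintf("control baseline %.1f +/- %.1f a.u.\n",
              object@controlBaselineMean, object@controlBaselineSd))
})
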