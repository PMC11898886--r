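#' Protease panel definition
#'
#' Metadata and generative parameters for a panel of protease nanobiosensors.
#' Each protease carries its consensus substrate sequence (metadata only) and,
#' for the synthetic-cohort generator, a mean and standard deviation of net
#' fluorescence activity (arbitrary units, a.u.) per diagnostic group, plus
#' the shared baseline level of the control wells.
#'
#' @slot proteases ordered character vector of biomarker names.
#' @slot consensus named character vector of consensus oligopeptide sequences.
#' @slot groupMeans numeric matrix, proteases x groups, mean net activity (a.u.).
#' @slot groupSds numeric matrix, proteases x groups, standard deviation (a.u.).
#' @slot controlBaselineMean,controlBaselineSd baseline fluorescence of
#'   sample-control and assay-control wells (a.u.).
#'
#' @export
setClass("ProteasePanel",
  representation(
    proteases = "character",
    consensus = "character",
    groupMeans = "matrix",
    groupSds = "matrix",
    controlBaselineMean = "numeric",
    controlBaselineSd = "numeric"
  )
)

setValidity("ProteasePanel", function(object) {
  msg <- character()
  p <- object@proteases
  if (length(p) < 1L || anyDuplicated(p))
    msg <- c(msg, "proteases must be a non-empty set of unique names")
  for (nm in c("groupMeans", "groupSds")) {
    m <- slot(object, nm)
    if (!identical(rownames(m), p))
      msg <- c(msg, sprintf("rownames(%s) must equal the protease vector", nm))
    if (!identical(colnames(m), CLASS_LEVELS))
      msg <- c(msg, sprintf("colnames(%s) must be %s", nm,
                            paste(CLASS_LEVELS, collapse = "/")))
  }
  if (any(!is.finite(object@groupMeans)) || any(object@groupMeans < 0))
    msg <- c(msg, "all group means must be finite and >= 0")
  if (any(!is.finite(object@groupSds)) || any(object@groupSds < 0))
    msg <- c(msg, "all group sds must be finite and >= 0")
  if (length(object@controlBaselineMean) != 1L || object@controlBaselineMean < 0)
    msg <- c(msg, "controlBaselineMean must be a single value >= 0")
  if (length(object@controlBaselineSd) != 1L || object@controlBaselineSd < 0)
    msg <- c(msg, "controlBaselineSd must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Cohort simulation configuration
#'
#' Sample counts per diagnostic group, the activity noise model and the root
#' seed for a synthetic cohort draw. Defaults mirror the study design the
#' package emulates: 50 healthy controls, 46 localized (stage I-II) and 50
#' metastatic (stage III-IV) ovarian-cancer samples.
#'
#' @slot nHealthy,nLocalized,nMetastatic integer sample counts.
#' @slot noiseModel `"lognormal"` (default; activities are positive and
#'   right-skewed) or `"normal"` (floored at zero).
#' @slot seed integer seed for the cohort random stream.
#' @slot panel a [ProteasePanel-class].
#'
#' @export
setClass("CohortConfig",
  representation(
    nHealthy = "integer",
    nLocalized = "integer",
    nMetastatic = "integer",
    noiseModel = "character",
    seed = "integer",
    panel = "ProteasePanel"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  n <- c(object@nHealthy, object@nLocalized, object@nMetastatic)
  if (any(is.na(n)) || any(n < 0L))
    msg <- c(msg, "group sample counts must be non-negative integers")
  if (!(object@noiseModel %in% c("lognormal", "normal")))
    msg <- c(msg, sprintf("unknown noise model '%s' (use lognormal or normal)",
                          object@noiseModel))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Per-sample protease activity container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' one `"activity"` assay (proteases as rows, samples as columns, net
#' fluorescence a.u.) and a `group` column in `colData` with the three-class
#' diagnostic label (possibly `NA` when labels are not yet attached).
#'
#' @export
#' @import SummarizedExperiment
setClass("ActivitySet", contains = "SummarizedExperiment")

setValidity("ActivitySet", function(object) {
  msg <- character()
  if (!("activity" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "an 'activity' assay is required")
  else {
    a <- SummarizedExperiment::assay(object, "activity")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "activities must be finite and non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!("group" %in% colnames(cd)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- cd$group
    bad <- !is.na(g) & !(as.character(g) %in% CLASS_LEVELS)
    if (any(bad))
      msg <- c(msg, sprintf("unknown group labels: %s",
                            paste(unique(as.character(g)[bad]), collapse = ", ")))
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Triplicate plate readout container
#'
#' Long-format well intensities for the three plate solutions: sample control
#' (`SC`, buffer + serum), assay control (`AC`, nanobiosensor + buffer) and
#' `ASSAY` (nanobiosensor + serum), each in triplicate per sample x protease.
#'
#' @slot wells data.frame with columns `sample_id`, `protease`, `solution`,
#'   `replicate`, `intensity`.
#' @slot instrument free-text excitation/emission descriptor.
#'
#' @export
setClass("PlateSet",
  representation(wells = "data.frame", instrument = "character")
)

SOLUTIONS <- c("SC", "AC", "ASSAY")

setValidity("PlateSet", function(object) {
  w <- object@wells
  need <- c("sample_id", "protease", "solution", "replicate", "intensity")
  if (!all(need %in% colnames(w)))
    return(sprintf("wells must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(w$solution %in% SOLUTIONS))
    msg <- c(msg, "solution must be one of SC, AC, ASSAY")
  if (!all(w$replicate %in% 1:3))
    msg <- c(msg, "replicate must be 1, 2 or 3")
  if (any(!is.finite(w$intensity)) || any(w$intensity < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  cnt <- table(w$sample_id, w$protease, w$solution)
  if (length(cnt) && !all(cnt == 3L)) {
    bad <- which(cnt != 3L, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "exactly 3 replicates required; offending sample '%s', protease '%s', solution %s",
      rownames(cnt)[bad[1L]], colnames(cnt)[bad[2L]], dimnames(cnt)[[3L]][bad[3L]]))
  }
  if (length(msg)) msg else TRUE
})

#' Hierarchical two-stage kNN classifier
#'
#' Stage 1 votes healthy vs non-healthy over the standardized labeled set;
#' stage 2, trained on the non-healthy labeled samples only, votes localized
#' vs metastatic. Posteriors multiply through the hierarchy.
#'
#' @slot k requested neighbour count (odd); `k1`/`k2` are the per-stage counts
#'   after clipping to the available training rows.
#' @slot center,scale per-feature standardization fit on the labeled set.
#' @slot features feature names retained in the distance (zero-variance
#'   features are dropped with a warning).
#' @export
setClass("HierarchicalKnnModel",
  representation(
    k = "integer", k1 = "integer", k2 = "integer",
    trainX = "matrix", stage1Labels = "character",
    stage2X = "matrix", stage2Labels = "character",
    center = "numeric", scale = "numeric",
    features = "character", panel = "character"
  )
)

setValidity("HierarchicalKnnModel", function(object) {
  msg <- character()
  if (object@k < 1L || object@k %% 2L == 0L)
    msg <- c(msg, "k must be odd and >= 1")
  if (any(object@scale <= 0))
    msg <- c(msg, "standardization sds must be > 0")
  if (length(msg)) msg else TRUE
})

#' Two-layer linear-activation network
#'
#' An input -> hidden -> output network whose hidden activation is the
#' identity; class posteriors are the normalized-exponential (softmax) of the
#' output layer, so the model is an affine map followed by a simplex
#' transform.
#'
#' @slot W1,b1 input-to-hidden weights/biases; @slot W2,b2 hidden-to-output.
#' @slot hyper list of training hyperparameters (hidden, lr, epochs, seed).
#' @export
setClass("TwoLayerNetModel",
  representation(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    center = "numeric", scale = "numeric",
    classes = "character", features = "character", hyper = "list"
  )
)

#' Active-learning state
#'
#' The labeled / query-pool / held-out-test partition of a dataset, plus the
#' query history accumulated by uncertainty sampling.
#'
#' @slot labeledIds,poolIds,testIds disjoint sample-id sets partitioning the
#'   dataset.
#' @slot queryHistory data.frame of (iteration, sample_id, confidence), where
#'   confidence is the top-class posterior probability of the queried sample
#'   at selection time (the minimized quantity of least-confidence sampling).
#' @slot redraws number of initial-labeled-set redraws needed to obtain at
#'   least one healthy and one non-healthy labeled sample.
#' @export
setClass("ALState",
  representation(
    labeledIds = "character", poolIds = "character", testIds = "character",
    model = "ANY", queryHistory = "data.frame",
    seed = "integer", redraws = "integer"
  )
)

setValidity("ALState", function(object) {
  ids <- c(object@labeledIds, object@poolIds, object@testIds)
  if (anyDuplicated(ids))
    return("labeled, pool and test id sets must be disjoint")
  TRUE
})

#' Shapley feature-relevance explanation
#'
#' Signed per-feature attributions of a model's class probability at one
#' sample, relative to a background expectation. For the exact method the
#' efficiency axiom holds: `baseValue + sum(phi)` equals the model output at
#' the sample to numerical precision.
#'
#' @slot phi named numeric vector, one Shapley value per panel feature
#'   (units of model probability).
#' @slot baseValue mean model output over the background set.
#' @slot method `"exact"` (coalition enumeration) or `"sampling"`
#'   (Monte-Carlo permutation estimate).
#' @slot nEval number of coalitions (exact) or permutation draws (sampling).
#' @export
setClass("ShapExplanation",
  representation(
    sampleId = "character", explainedClass = "character",
    baseValue = "numeric", phi = "numeric",
    method = "character", nEval = "numeric"
  )
)

setValidity("ShapExplanation", function(object) {
  msg <- character()
  if (!(object@method %in% c("exact", "sampling")))
    msg <- c(msg, "method must be 'exact' or 'sampling'")
  if (is.null(names(object@phi)))
    msg <- c(msg, "phi must be named by feature")
  if (length(msg)) msg else TRUE
})
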