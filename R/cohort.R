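#' Construct a cohort configuration
#'
#' @param nHealthy,nLocalized,nMetastatic group sample counts; defaults are
#'   the 50 / 46 / 50 design the package emulates (146 samples total).
#' @param noiseModel `"lognormal"` (default) or `"normal"`.
#' @param seed integer seed for the cohort stream.
#' @param panel a [ProteasePanel-class]; default [defaultPanel()].
#' @return A [CohortConfig-class].
#' @export
#' @examples
#' cohortConfig(seed = 1L)
cohortConfig <- function(nHealthy = 50L, nLocalized = 46L, nMetastatic = 50L,
                         noiseModel = c("lognormal", "normal"), seed = 1L,
                         panel = defaultPanel()) {
  if (is.character(noiseModel) && length(noiseModel) > 1L)
    noiseModel <- noiseModel[1L]
  new("CohortConfig",
      nHealthy = as.integer(nHealthy), nLocalized = as.integer(nLocalized),
      nMetastatic = as.integer(nMetastatic), noiseModel = noiseModel,
      seed = as.integer(seed), panel = panel)
}

#' Build an ActivitySet from a sample x protease matrix
#'
#' @param activities numeric matrix, samples as rows, panel proteases as
#'   columns (column order fixes feature order).
#' @param groups character/factor of group labels per sample, or `NULL`.
#' @param sampleIds sample identifiers; defaults to rownames.
#' @param panel optional [ProteasePanel-class] stored in `metadata()`.
#' @return An [ActivitySet-class].
#' @export
ActivitySet <- function(activities, groups = NULL, sampleIds = rownames(activities),
                        panel = NULL) {
  activities <- as.matrix(activities)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(nrow(activities)))
  g <- if (is.null(groups)) factor(rep(NA_character_, nrow(activities)),
                                   levels = CLASS_LEVELS)
       else factor(as.character(groups), levels = CLASS_LEVELS)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = t(activities)),
    colData = S4Vectors::DataFrame(group = g, row.names = sampleIds)
  )
  out <- new("ActivitySet", se)
  if (!is.null(panel)) S4Vectors::metadata(out)$panel <- panel
  out
}

#' Activity container accessors
#'
#' @param x an [ActivitySet-class].
#' @return `activityMatrix`: samples x proteases numeric matrix;
#'   `sampleGroups`: factor of group labels (levels
#'   healthy/localized/metastatic, may contain `NA`).
#' @name activityAccessors
NULL

#' @rdname activityAccessors
#' @export
setMethod("activityMatrix", "ActivitySet", function(x)
  t(SummarizedExperiment::assay(x, "activity")))

#' @rdname activityAccessors
#' @export
setMethod("sampleGroups", "ActivitySet", function(x)
  SummarizedExperiment::colData(x)$group)

setMethod("show", "ActivitySet", function(object) {
  g <- sampleGroups(object)
  cat(sprintf("ActivitySet: %d samples x %d proteases\n",
              ncol(object), nrow(object)))
  if (any(!is.na(g))) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else cat("groups: unlabeled\n")
})

## One group x protease block of activity draws.
drawActivities <- function(n, mean, sd, noiseModel) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  if (noiseModel == "lognormal") {
    if (mean <= 0) stop("lognormal noise needs positive means", call. = FALSE)
    sdlog <- sqrt(log1p((sd / mean)^2))
    meanlog <- log(mean) - sdlog^2 / 2
    rlnorm(n, meanlog, sdlog)
  } else {
    pmax(rnorm(n, mean, sd), 0)
  }
}

#' Simulate a diagnostic cohort
#'
#' Draws per-sample net protease activities for the three diagnostic groups
#' from the panel's per-group means and sds, under a lognormal (default) or
#' truncated-normal noise model. The draw is fully determined by
#' `config@seed`: identical configuration and seed give a bit-identical
#' table.
#'
#' @param config a [CohortConfig-class].
#' @param allowZeroSd permit zero group sds (the deterministic zero-noise
#'   limit, useful for separability checks); otherwise a zero sd is a
#'   configuration error.
#' @return An [ActivitySet-class] with `50 + 46 + 50 = 146` samples under the
#'   default configuration, groups in block order healthy, localized,
#'   metastatic, and the generating panel in `metadata()`.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1L))
#' table(sampleGroups(cohort))
generateCohort <- function(config, allowZeroSd = FALSE) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  panel <- config@panel
  if (!allowZeroSd && any(groupSds(panel) <= 0))
    stop("group sds must be > 0 (set allowZeroSd = TRUE for the zero-noise limit)",
         call. = FALSE)
  counts <- c(healthy = config@nHealthy, localized = config@nLocalized,
              metastatic = config@nMetastatic)
  proteases <- panelProteases(panel)
  n <- sum(counts)
  act <- matrix(NA_real_, n, length(proteases),
                dimnames = list(NULL, proteases))
  groups <- rep(CLASS_LEVELS, counts)
  withr::with_seed(config@seed, {
    for (g in CLASS_LEVELS) {
      idx <- which(groups == g)
      for (p in proteases) {
        act[idx, p] <- drawActivities(length(idx), groupMeans(panel)[p, g],
                                      groupSds(panel)[p, g], config@noiseModel)
      }
    }
  })
  ActivitySet(act, groups = groups,
              sampleIds = sprintf("S%03d", seq_len(n)), panel = panel)
}

#' Simulate triplicate plate readouts for a cohort
#'
#' Forward-simulates the 96-well protocol: for every sample x protease, three
#' solutions (sample control SC, assay control AC, assay) in triplicate. Every
#' well in a sample x protease block shares one baseline draw
#' (`Normal(controlBaselineMean, controlBaselineSd)`, floored at 0); assay
#' wells add the sample's true activity; independent well noise with sd
#' `plateNoiseSd` is added on top. Control wells therefore stay low while
#' assay wells carry baseline + signal.
#'
#' @param x an [ActivitySet-class] (the true activities).
#' @param plateNoiseSd well-level noise sd (a.u.), `>= 0`.
#' @param seed integer seed for the plate stream.
#' @param panel panel supplying the control baseline; defaults to the panel
#'   stored in `metadata(x)`, else [defaultPanel()].
#' @return A [PlateSet-class].
#' @export
generatePlateReadings <- function(x, plateNoiseSd = 10, seed = 1L, panel = NULL) {
  stopifnot(is(x, "ActivitySet"))
  if (plateNoiseSd < 0) stop("plateNoiseSd must be >= 0", call. = FALSE)
  if (is.null(panel)) panel <- S4Vectors::metadata(x)$panel
  if (is.null(panel)) panel <- defaultPanel()
  act <- activityMatrix(x)
  samples <- rownames(act)
  proteases <- colnames(act)
  grid <- expand.grid(replicate = 1:3, solution = SOLUTIONS,
                      protease = proteases, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    nBlock <- length(samples) * length(proteases)
    baseline <- pmax(rnorm(nBlock, panel@controlBaselineMean,
                           panel@controlBaselineSd), 0)
    blockIdx <- rep(seq_len(nBlock), each = 9L) # 3 solutions x 3 replicates
    signal <- ifelse(grid$solution == "ASSAY",
                     act[cbind(grid$sample_id, grid$protease)], 0)
    noise <- if (plateNoiseSd > 0) rnorm(nrow(grid), 0, plateNoiseSd) else 0
    intensity <- pmax(baseline[blockIdx] + signal + noise, 0)
  })
  wells <- data.frame(sample_id = grid$sample_id, protease = grid$protease,
                      solution = grid$solution, replicate = grid$replicate,
                      intensity = intensity, stringsAsFactors = FALSE)
  new("PlateSet", wells = wells,
      instrument = "simulated plate reader, ex 425/20 nm, em 650/20 nm")
}

setMethod("show", "PlateSet", function(object) {
  w <- object@wells
  cat(sprintf("PlateSet: %d wells (%d samples x %d proteases, 3 solutions x 3 replicates)\n",
              nrow(w), length(unique(w$sample_id)), length(unique(w$protease))))
  cat("instrument:", object@instrument, "\n")
})
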