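#' Build a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in the fixed order
#' healthy, localized, metastatic.
#'
#' @param truth,predicted character/factor vectors of class labels.
#' @return integer matrix of counts.
#' @export
confusionMatrix <- function(truth, predicted) {
  t1 <- factor(as.character(truth), levels = CLASS_LEVELS)
  p1 <- factor(as.character(predicted), levels = CLASS_LEVELS)
  cm <- table(truth = t1, predicted = p1)
  matrix(as.integer(cm), 3L, 3L, dimnames = list(CLASS_LEVELS, CLASS_LEVELS))
}

checkCm <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0) || any(cm != round(cm)))
    stop("confusion matrix must hold non-negative integer counts", call. = FALSE)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  cm
}

#' Classification accuracy of a confusion matrix
#'
#' `100 * trace / total`, reported as a percentage truncated (not rounded)
#' to `digits` decimals; truncation is the package's conservative reporting
#' convention — a reported accuracy never over-states the realized one. Set
#' `digits = NULL` for the full-precision value.
#'
#' @param cm square count matrix (true x predicted).
#' @param digits decimals to truncate to; default 2.
#' @return accuracy in percent.
#' @export
#' @examples
#' accuracy(rbind(c(47, 1, 2), c(3, 42, 1), c(0, 2, 48))) # 93.83
accuracy <- function(cm, digits = 2L) {
  cm <- checkCm(cm)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  if (is.null(digits)) acc else truncateDecimals(acc, digits)
}

#' Macro-averaged sensitivity and specificity
#'
#' Per-class recall (`diagonal / row sum`) and one-vs-rest specificity
#' (`TN / (TN + FP)`), macro-averaged as the unweighted mean over classes.
#' Classes with an all-zero row are excluded from the macro mean with a
#' warning. The macro convention is a documented package choice; other
#' averaging conventions give different numbers.
#'
#' @param cm square count matrix (true x predicted).
#' @return list with `perClassSensitivity`, `perClassSpecificity`,
#'   `macroSensitivity`, `macroSpecificity`.
#' @export
macroMetrics <- function(cm) {
  cm <- checkCm(cm)
  k <- nrow(cm)
  total <- sum(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  sens <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  spec <- vapply(seq_len(k), function(i) {
    tn <- total - rs[i] - cs[i] + cm[i, i]
    fp <- cs[i] - cm[i, i]
    tn / (tn + fp)
  }, numeric(1L))
  names(sens) <- names(spec) <- rownames(cm)
  if (any(is.na(sens)))
    warning(sprintf("class(es) with no true samples excluded from macro mean: %s",
                    paste(rownames(cm)[is.na(sens)], collapse = ", ")))
  list(perClassSensitivity = sens, perClassSpecificity = spec,
       macroSensitivity = mean(sens, na.rm = TRUE),
       macroSpecificity = mean(spec[!is.na(sens)]))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a synthetic cohort: simulate activities,
#' forward-simulate and re-process plate readouts, run the group statistics,
#' train both base models under active learning, explain test-set
#' predictions of the hierarchical model with exact Shapley values, and
#' gather everything into a report bundle. All randomness derives from the
#' single root seed via labelled sub-streams, so a fixed (config, seed) pair
#' reproduces the bundle exactly.
#'
#' @param config list of options: `nHealthy`, `nLocalized`, `nMetastatic`,
#'   `noiseModel`, `plateNoiseSd`, `nExplain` (test samples explained per
#'   class, default 5), plus model options as in [runActiveLearning()].
#' @param seed root integer seed.
#' @param outDir optional directory; when given, all artifacts (feature CSV,
#'   plate CSV, comparison CSV, confusions, learning curves, query logs,
#'   shap CSV, `report.json`) are written there.
#' @return list with `cohort`, `plates`, `processed`, `comparison`,
#'   `hknn`, `nn2`, `explanations`, `topFeatures`, `report`.
#' @export
runPipeline <- function(config = list(), seed = 1L, outDir = NULL) {
  cfg <- cohortConfig(
    nHealthy = config$nHealthy %||% 50L,
    nLocalized = config$nLocalized %||% 46L,
    nMetastatic = config$nMetastatic %||% 50L,
    noiseModel = config$noiseModel %||% "lognormal",
    seed = deriveSeed(seed, "cohort"),
    panel = config$panel %||% defaultPanel()
  )
  cohort <- generateCohort(cfg)
  plates <- generatePlateReadings(cohort,
                                  plateNoiseSd = config$plateNoiseSd %||% 10,
                                  seed = deriveSeed(seed, "plate"))
  processed <- summarizeWells(plates,
                              groups = setNames(as.character(sampleGroups(cohort)),
                                                colnames(cohort)))
  comparison <- compareGroups(processed)

  hknn <- runActiveLearning(processed, "hierarchical_knn", config, seed)
  nn2 <- runActiveLearning(processed, "two_layer_nn", config, seed)

  ## explain a few test samples per class with the hierarchical model
  nExplain <- config$nExplain %||% 5L
  truth <- setNames(as.character(sampleGroups(processed)), colnames(processed))
  act <- activityMatrix(processed)
  bg <- act[labeledIds(hknn$state), , drop = FALSE]
  explanations <- list()
  for (cls in CLASS_LEVELS) {
    ids <- head(testIds(hknn$state)[truth[testIds(hknn$state)] == cls], nExplain)
    for (id in ids) {
      explanations[[id]] <- shapleyExact(hknn$model, act[id, ], bg,
                                         class = cls, sampleId = id)
    }
  }
  tops <- lapply(setNames(CLASS_LEVELS, CLASS_LEVELS),
                 function(cls) topFeatures(explanations, cls))

  n <- ncol(processed)
  report <- list(
    seed = seed,
    config_hash = hashObject(config),
    n_samples = n,
    split = list(labeled = floor(0.20 * n), pool = floor(0.30 * n),
                 test = n - floor(0.20 * n) - floor(0.30 * n)),
    comparison = comparison,
    hknn = list(accuracy = accuracy(hknn$confusion),
                confusion = hknn$confusion,
                macro = macroMetrics(hknn$confusion)),
    nn2 = list(accuracy = accuracy(nn2$confusion),
               confusion = nn2$confusion,
               macro = macroMetrics(nn2$confusion)),
    top_features = lapply(tops, function(tf) tf$top3)
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureCsv(processed, file.path(outDir, "features.csv"))
    writeComparisonCsv(comparison, file.path(outDir, "comparison.csv"))
    for (tag in c("hknn", "nn2")) {
      res <- if (tag == "hknn") hknn else nn2
      write.csv(as.data.frame(res$confusion),
                file.path(outDir, sprintf("confusion_%s.csv", tag)))
      write.csv(res$learningCurve,
                file.path(outDir, sprintf("learning_curve_%s.csv", tag)),
                row.names = FALSE)
      write.csv(res$history, file.path(outDir, sprintf("queries_%s.csv", tag)),
                row.names = FALSE)
      writeModelJson(res$model, file.path(outDir, sprintf("model_%s.json", tag)))
    }
    writeShapCsv(explanations, file.path(outDir, "shap.csv"))
    jsonlite::write_json(reportToJson(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, plates = plates, processed = processed,
       comparison = comparison, hknn = hknn, nn2 = nn2,
       explanations = explanations, topFeatures = tops, report = report)
}

## Flatten the report list into JSON-friendly structures.
reportToJson <- function(report) {
  r <- report
  r$comparison <- report$comparison
  r$hknn$confusion <- as.data.frame(report$hknn$confusion)
  r$nn2$confusion <- as.data.frame(report$nn2$confusion)
  r
}
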