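#' Read and write per-sample feature tables
#'
#' The feature-table CSV schema is
#' `sample_id,group,<one column per protease>`, UTF-8, decimal point, with
#' `/` in protease names mapped to `_` in column headers (so `ADAM10/12`
#' becomes `ADAM10_12`). An empty `group` field reads back as `NA`.
#'
#' @param x an [ActivitySet-class].
#' @param path CSV file path.
#' @param proteases optional panel order for reading; defaults to all
#'   non-id columns in file order.
#' @return `writeFeatureCsv` returns `path` invisibly; `readFeatureCsv`
#'   returns an [ActivitySet-class].
#' @export
writeFeatureCsv <- function(x, path) {
  stopifnot(is(x, "ActivitySet"))
  act <- activityMatrix(x)
  df <- data.frame(sample_id = rownames(act),
                   group = as.character(sampleGroups(x)),
                   act, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", "group", proteaseColumn(colnames(act)))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @export
readFeatureCsv <- function(path, proteases = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("feature CSV needs 'sample_id' and 'group' columns", call. = FALSE)
  featCols <- setdiff(colnames(df), c("sample_id", "group"))
  act <- as.matrix(df[, featCols, drop = FALSE])
  if (!is.null(proteases)) {
    want <- proteaseColumn(proteases)
    if (!all(want %in% featCols))
      stop(sprintf("missing protease columns: %s",
                   paste(setdiff(want, featCols), collapse = ", ")),
           call. = FALSE)
    act <- act[, want, drop = FALSE]
    colnames(act) <- proteases
  } else {
    # undo the "/" -> "_" mapping for the shared ADAM10/12 feature
    colnames(act) <- sub("^ADAM10_12$", "ADAM10/12", colnames(act))
  }
  g <- df$group
  g[!is.na(g) & g == ""] <- NA_character_
  ActivitySet(act, groups = g, sampleIds = df$sample_id)
}

#' Read and write plate-well tables
#'
#' Long-format plate CSV: `sample_id,protease,solution,replicate,intensity`
#' with `solution` one of `SC`, `AC`, `ASSAY` and `replicate` 1-3.
#'
#' @param plates a [PlateSet-class].
#' @param path CSV file path.
#' @export
writePlateCsv <- function(plates, path) {
  stopifnot(is(plates, "PlateSet"))
  write.csv(plates@wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePlateCsv
#' @export
readPlateCsv <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE)
  new("PlateSet", wells = w, instrument = "imported")
}

#' Write QC flags to a sidecar CSV
#'
#' @param x an [ActivitySet-class] produced by [summarizeWells()].
#' @param path CSV file path (`sample_id,protease,flag`).
#' @export
writeQcCsv <- function(x, path) {
  flags <- S4Vectors::metadata(x)$qcFlags
  if (is.null(flags))
    flags <- data.frame(sample_id = character(), protease = character(),
                        flag = character())
  write.csv(flags, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort configuration from JSON
#'
#' Recognized keys: `nHealthy`, `nLocalized`, `nMetastatic`, `noiseModel`,
#' `seed`, `nProteases`. Unknown keys are rejected rather than ignored, so a
#' typo cannot silently fall back to a default.
#'
#' @param path JSON file path.
#' @return A [CohortConfig-class].
#' @export
readCohortConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("nHealthy", "nLocalized", "nMetastatic", "noiseModel", "seed",
             "nProteases")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  panel <- defaultPanel(nProteases = as.integer(raw$nProteases %||% 7L))
  cohortConfig(nHealthy = raw$nHealthy %||% 50L,
               nLocalized = raw$nLocalized %||% 46L,
               nMetastatic = raw$nMetastatic %||% 50L,
               noiseModel = raw$noiseModel %||% "lognormal",
               seed = raw$seed %||% 1L,
               panel = panel)
}

#' Serialize a fitted model to JSON and back
#'
#' Stores weights or training matrices, standardization parameters, the
#' panel feature order and training hyperparameters, so a model reloads into
#' an identical predictor.
#'
#' @param model a [HierarchicalKnnModel-class] or [TwoLayerNetModel-class].
#' @param path JSON file path.
#' @export
writeModelJson <- function(model, path) {
  obj <- if (is(model, "HierarchicalKnnModel")) {
    list(type = "hierarchical_knn", k = model@k, k1 = model@k1, k2 = model@k2,
         trainX = model@trainX, stage1Labels = model@stage1Labels,
         stage2X = model@stage2X, stage2Labels = model@stage2Labels,
         center = model@center, scale = model@scale,
         features = model@features, panel = model@panel)
  } else if (is(model, "TwoLayerNetModel")) {
    list(type = "two_layer_nn", W1 = model@W1, b1 = model@b1,
         W2 = model@W2, b2 = model@b2, center = model@center,
         scale = model@scale, classes = model@classes,
         features = model@features, hyper = model@hyper)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m, cols) {
    m <- as.matrix(m)
    if (length(m) == 0L) m <- matrix(numeric(0), 0L, length(cols))
    colnames(m) <- cols
    m
  }
  if (obj$type == "hierarchical_knn") {
    new("HierarchicalKnnModel",
        k = as.integer(obj$k), k1 = as.integer(obj$k1), k2 = as.integer(obj$k2),
        trainX = asMat(obj$trainX, obj$features),
        stage1Labels = as.character(obj$stage1Labels),
        stage2X = asMat(obj$stage2X, obj$features),
        stage2Labels = as.character(obj$stage2Labels),
        center = setNames(as.numeric(obj$center), obj$features),
        scale = setNames(as.numeric(obj$scale), obj$features),
        features = obj$features, panel = obj$panel)
  } else if (obj$type == "two_layer_nn") {
    new("TwoLayerNetModel",
        W1 = asMat(obj$W1, NULL), b1 = as.numeric(obj$b1),
        W2 = asMat(obj$W2, obj$classes), b2 = setNames(as.numeric(obj$b2), obj$classes),
        center = setNames(as.numeric(obj$center), obj$features),
        scale = setNames(as.numeric(obj$scale), obj$features),
        classes = obj$classes, features = obj$features,
        hyper = as.list(obj$hyper))
  } else stop(sprintf("unknown model type '%s'", obj$type), call. = FALSE)
}

#' Write Shapley explanations to CSV
#'
#' Schema: `sample_id,explained_class,base_value,phi_<feature...>,method`.
#'
#' @param explanations list of [ShapExplanation-class].
#' @param path CSV file path.
#' @export
writeShapCsv <- function(explanations, path) {
  rows <- lapply(explanations, function(e) {
    phi <- as.list(e@phi)
    names(phi) <- paste0("phi_", proteaseColumn(names(e@phi)))
    c(list(sample_id = e@sampleId, explained_class = e@explainedClass,
           base_value = e@baseValue), phi, list(method = e@method))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
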