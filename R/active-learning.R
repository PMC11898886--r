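#' Split a dataset into labeled / pool / test partitions
#'
#' Draws the initial active-learning partition: `floor(0.20 n)` samples form
#' the initial labeled set, `floor(0.30 n)` the query pool, and the remainder
#' the held-out test set on which confusion matrices are computed. Selection
#' is uniform from the seeded sub-stream; the labeled draw is repeated (a
#' fresh draw from the same stream) until it contains at least one healthy
#' and one non-healthy sample so that stage 1 of the hierarchical model is
#' trainable, and the number of redraws is recorded.
#'
#' @param x a labeled [ActivitySet-class] with >= 10 samples and all three
#'   classes present.
#' @param seed integer seed for the split stream.
#' @return An [ALState-class] (with no model fitted yet).
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1L))
#' state <- splitDataset(cohort, seed = 1L)
#' lengths(list(labeledIds(state), poolIds(state), testIds(state)))
splitDataset <- function(x, seed = 1L) {
  stopifnot(is(x, "ActivitySet"))
  ids <- colnames(x)
  n <- length(ids)
  if (n < 10L) stop("need at least 10 samples to split", call. = FALSE)
  grp <- as.character(sampleGroups(x))
  missing <- setdiff(CLASS_LEVELS, unique(grp[!is.na(grp)]))
  if (length(missing))
    stop(sprintf("missing groups: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  nl <- floor(0.20 * n)
  np <- floor(0.30 * n)
  names(grp) <- ids
  redraws <- 0L
  withr::with_seed(as.integer(seed), {
    repeat {
      perm <- sample(ids)
      lab <- perm[seq_len(nl)]
      gl <- grp[lab]
      if (any(gl == "healthy") && any(gl != "healthy")) break
      redraws <- redraws + 1L
    }
  })
  labeled <- ids[ids %in% perm[seq_len(nl)]]
  pool <- ids[ids %in% perm[nl + seq_len(np)]]
  test <- setdiff(ids, c(labeled, pool))
  if (redraws > 0L)
    message(sprintf("initial labeled set redrawn %d time(s)", redraws))
  new("ALState", labeledIds = labeled, poolIds = pool, testIds = test,
      model = NULL, queryHistory = data.frame(iteration = integer(),
                                              sample_id = character(),
                                              confidence = numeric(),
                                              stringsAsFactors = FALSE),
      seed = as.integer(seed), redraws = redraws)
}

#' ALState accessors
#' @param x an [ALState-class].
#' @name ALState-accessors
NULL

#' @rdname ALState-accessors
#' @export
setMethod("labeledIds", "ALState", function(x) x@labeledIds)
#' @rdname ALState-accessors
#' @export
setMethod("poolIds", "ALState", function(x) x@poolIds)
#' @rdname ALState-accessors
#' @export
setMethod("testIds", "ALState", function(x) x@testIds)
#' @rdname ALState-accessors
#' @export
setMethod("queryHistory", "ALState", function(x) x@queryHistory)

setMethod("show", "ALState", function(object) {
  cat(sprintf("ALState: %d labeled / %d pool / %d test (seed %d, %d redraws)\n",
              length(object@labeledIds), length(object@poolIds),
              length(object@testIds), object@seed, object@redraws))
  if (nrow(object@queryHistory))
    cat(sprintf("%d queries made\n", nrow(object@queryHistory)))
})

## Per-sample uncertainty score to MINIMIZE under each strategy.
uncertaintyScore <- function(posterior, strategy) {
  switch(strategy,
    least_confidence = confidence(posterior),
    margin = apply(posterior, 1L, function(p) {
      s <- sort(p, decreasing = TRUE); s[1L] - s[2L]
    }),
    entropy = -apply(posterior, 1L, function(p) {
      p <- p[p > 0]; -sum(p * log(p))
    }),
    stop(sprintf("unknown query strategy '%s'", strategy), call. = FALSE)
  )
}

#' Select the next query by uncertainty sampling
#'
#' The default strategy is least-confidence sampling: the pool sample whose
#' top-class posterior probability `P(yhat | x)` is smallest is selected for
#' annotation. `margin` (smallest top-two gap) and `entropy` (largest
#' posterior entropy) are available as alternatives but are off by default.
#' Ties are broken by the smallest sample index (pool order).
#'
#' @param model a fitted classifier accepted by [predictPosterior()].
#' @param pool an [ActivitySet-class] or matrix of the pool samples, in
#'   dataset order.
#' @param strategy query strategy; default `"least_confidence"`.
#' @return list with `sample_id` (character), `index` (position in the
#'   pool), and `confidence` (the queried sample's top-class posterior).
#' @export
selectQuery <- function(model, pool, strategy = "least_confidence") {
  X <- if (is(pool, "ActivitySet")) activityMatrix(pool) else as.matrix(pool)
  if (nrow(X) == 0L) stop("empty query pool", call. = FALSE)
  post <- predictPosterior(model, X)
  score <- uncertaintyScore(post, strategy)
  idx <- which.min(score) # first minimum = smallest sample index on ties
  list(sample_id = rownames(X)[idx], index = idx,
       confidence = unname(confidence(post)[idx]))
}

fitModelSpec <- function(labeled, modelSpec, config, initSeed) {
  switch(modelSpec,
    hierarchical_knn = fitHierarchicalKnn(labeled,
                                          k = config$k %||% 5L),
    two_layer_nn = fitLinearNet(labeled,
                                hidden = config$hidden %||% 8L,
                                lr = config$lr %||% 0.2,
                                epochs = config$epochs %||% 300L,
                                seed = initSeed),
    stop(sprintf("unknown model spec '%s'", modelSpec), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pool-based active-learning protocol
#'
#' Splits the dataset (20% labeled / 30% pool / 50% test), fits the chosen
#' base model on the initial labeled set, then iterates: select the
#' least-confident pool sample, move it with its true label into the labeled
#' set (oracle annotator), and refit the model from scratch with a fresh
#' seeded initialization. Iteration stops when the pool is exhausted or
#' after `budget` queries. Test accuracy is recorded after every refit.
#'
#' @param x a labeled [ActivitySet-class].
#' @param modelSpec `"hierarchical_knn"` or `"two_layer_nn"`.
#' @param config optional list of model options (`k`, `hidden`, `lr`,
#'   `epochs`), `strategy`, and `budget` (max queries, default pool size).
#' @param seed root integer seed; split and per-iteration initialization
#'   seeds are derived from it.
#' @return list with `model` (final fitted model), `state` (final
#'   [ALState-class]), `confusion` (3x3 test confusion matrix),
#'   `learningCurve` (data.frame iteration/nLabeled/accuracy, accuracy in
#'   percent), and `history` (the query log).
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(nHealthy = 15L, nLocalized = 15L,
#'                                       nMetastatic = 15L, seed = 1L))
#' res <- runActiveLearning(cohort, "hierarchical_knn", seed = 1L,
#'                          config = list(budget = 3L))
#' res$confusion
runActiveLearning <- function(x, modelSpec = c("hierarchical_knn", "two_layer_nn"),
                              config = list(), seed = 1L) {
  modelSpec <- match.arg(modelSpec)
  strategy <- config$strategy %||% "least_confidence"
  state <- splitDataset(x, seed = deriveSeed(seed, "split"))
  budget <- min(config$budget %||% length(state@poolIds),
                length(state@poolIds))

  truth <- setNames(as.character(sampleGroups(x)), colnames(x))
  act <- activityMatrix(x)

  refit <- function(labeled, iter)
    fitModelSpec(x[, labeled], modelSpec, config,
                 initSeed = deriveSeed(seed, paste0("init", iter)))
  testAcc <- function(model) {
    post <- predictPosterior(model, act[state@testIds, , drop = FALSE])
    mean(as.character(predictedClass(post)) == truth[state@testIds]) * 100
  }

  model <- refit(state@labeledIds, 0L)
  curve <- data.frame(iteration = 0L, nLabeled = length(state@labeledIds),
                      accuracy = testAcc(model))
  history <- state@queryHistory

  iter <- 0L
  pool <- state@poolIds
  labeled <- state@labeledIds
  while (iter < budget && length(pool) > 0L) {
    iter <- iter + 1L
    q <- selectQuery(model, act[pool, , drop = FALSE], strategy = strategy)
    history <- rbind(history,
                     data.frame(iteration = iter, sample_id = q$sample_id,
                                confidence = q$confidence,
                                stringsAsFactors = FALSE))
    pool <- setdiff(pool, q$sample_id)
    labeled <- c(labeled, q$sample_id)
    model <- refit(labeled, iter)
    curve <- rbind(curve,
                   data.frame(iteration = iter, nLabeled = length(labeled),
                              accuracy = testAcc(model)))
  }

  state@labeledIds <- labeled
  state@poolIds <- pool
  state@queryHistory <- history
  state@model <- model

  post <- predictPosterior(model, act[state@testIds, , drop = FALSE])
  cm <- confusionMatrix(truth[state@testIds],
                        as.character(predictedClass(post)))
  list(model = model, state = state, confusion = cm,
       learningCurve = curve, history = history)
}
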