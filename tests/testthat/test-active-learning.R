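test_that("the split uses floor arithmetic for labeled and pool fractions", {
  cohort <- generateCohort(cohortConfig(seed = 71L)) # n = 146
  state <- splitDataset(cohort, seed = 1L)
  expect_length(labeledIds(state), 29L) # floor(0.20 * 146)
  expect_length(poolIds(state), 43L)    # floor(0.30 * 146)
  expect_length(testIds(state), 74L)

  smallTen <- generateCohort(cohortConfig(nHealthy = 4L, nLocalized = 3L,
                                          nMetastatic = 3L, seed = 72L))
  st <- splitDataset(smallTen, seed = 2L)
  expect_equal(lengths(list(labeledIds(st), poolIds(st), testIds(st))),
               c(2L, 3L, 5L), ignore_attr = TRUE)
})

test_that("splits partition the dataset and always allow stage-1 training", {
  for (s in 1:25) {
    cohort <- generateCohort(cohortConfig(nHealthy = 5L, nLocalized = 5L,
                                          nMetastatic = 5L, seed = s))
    state <- suppressMessages(splitDataset(cohort, seed = s))
    ids <- c(labeledIds(state), poolIds(state), testIds(state))
    expect_setequal(ids, colnames(cohort))
    expect_equal(anyDuplicated(ids), 0L)
    g <- as.character(sampleGroups(cohort))[match(labeledIds(state), colnames(cohort))]
    expect_true(any(g == "healthy") && any(g != "healthy"))
  }
})

test_that("the split is seed-deterministic and varies across seeds", {
  cohort <- generateCohort(cohortConfig(seed = 73L))
  a <- splitDataset(cohort, seed = 5L)
  b <- splitDataset(cohort, seed = 5L)
  expect_identical(labeledIds(a), labeledIds(b))
  expect_identical(testIds(a), testIds(b))
  distinct <- vapply(1:100, function(s)
    !identical(labeledIds(splitDataset(cohort, seed = s)), labeledIds(a)),
    logical(1L))
  expect_gte(sum(distinct), 98L)
  expect_error(splitDataset(cohort[, 1:5], seed = 1L), "at least 10")
  expect_error(splitDataset(cohort[, sampleGroups(cohort) == "healthy"][, 1:20],
                            seed = 1L), "missing groups")
})

test_that("least-confidence selection is forced by the posterior minimum", {
  posts <- rbind(a = c(0.9, 0.05, 0.05), b = c(0.4, 0.35, 0.25))
  colnames(posts) <- c("healthy", "localized", "metastatic")
  mock <- new("MockPosteriorModel",
              f = function(X) posts[rownames(X), , drop = FALSE])
  pool <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "f1"))
  q <- selectQuery(mock, pool)
  expect_equal(q$sample_id, "b")
  expect_equal(q$confidence, 0.4)

  single <- pool["b", , drop = FALSE]
  expect_equal(selectQuery(mock, single)$sample_id, "b")
  expect_error(selectQuery(mock, pool[0, , drop = FALSE]), "empty")
})

test_that("selection matches an exhaustive min-max-posterior scan", {
  set.seed(83)
  for (rep in 1:5) {
    n <- 20L
    raw <- matrix(runif(n * 3), n, 3)
    posts <- raw / rowSums(raw)
    rownames(posts) <- sprintf("P%02d", seq_len(n))
    colnames(posts) <- c("healthy", "localized", "metastatic")
    mock <- new("MockPosteriorModel",
                f = function(X) posts[rownames(X), , drop = FALSE])
    pool <- matrix(0, n, 1, dimnames = list(rownames(posts), "f1"))
    best <- rownames(posts)[which.min(apply(posts, 1, max))] # brute force
    expect_equal(selectQuery(mock, pool)$sample_id, best)
  }
})

test_that("margin and entropy strategies are available but distinct", {
  posts <- rbind(a = c(0.50, 0.49, 0.01), b = c(0.45, 0.30, 0.25))
  colnames(posts) <- c("healthy", "localized", "metastatic")
  mock <- new("MockPosteriorModel",
              f = function(X) posts[rownames(X), , drop = FALSE])
  pool <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "f1"))
  expect_equal(selectQuery(mock, pool)$sample_id, "b") # least confidence
  expect_equal(selectQuery(mock, pool, strategy = "margin")$sample_id, "a")
  expect_equal(selectQuery(mock, pool, strategy = "entropy")$sample_id, "b")
  expect_error(selectQuery(mock, pool, strategy = "random"), "unknown")
})

test_that("a zero budget returns the initial model and a one-point curve", {
  cohort <- tinyCohort(6L, seed = 89L)
  res <- runActiveLearning(cohort, "hierarchical_knn",
                           config = list(budget = 0L, k = 3L), seed = 3L)
  expect_equal(nrow(res$learningCurve), 1L)
  expect_equal(nrow(res$history), 0L)
  expect_length(labeledIds(res$state), floor(0.2 * ncol(cohort)))
})

test_that("the AL loop conserves the partition and never touches the test set", {
  cohort <- tinyCohort(8L, seed = 97L)
  init <- splitDataset(cohort, seed = deriveSeed(5L, "split"))
  res <- runActiveLearning(cohort, "hierarchical_knn",
                           config = list(k = 3L), seed = 5L)
  expect_identical(testIds(res$state), testIds(init))
  expect_setequal(labeledIds(res$state),
                  c(labeledIds(init), poolIds(init))) # pool exhausted
  expect_length(poolIds(res$state), 0L)
  expect_equal(nrow(res$history), length(poolIds(init)))
  expect_setequal(res$history$sample_id, poolIds(init))
  ## one query per iteration, so the labeled set grows by exactly 1 each time
  expect_equal(res$learningCurve$nLabeled,
               seq(length(labeledIds(init)), length.out = nrow(res$learningCurve)))
})

test_that("query-history confidences replay exactly", {
  cohort <- tinyCohort(8L, seed = 101L)
  res <- runActiveLearning(cohort, "hierarchical_knn",
                           config = list(k = 3L), seed = 7L)
  h <- res$history
  expect_true(all(h$confidence >= 0 & h$confidence <= 1))
  ## replay: refit at each iteration and recompute the queried confidence
  init <- splitDataset(cohort, seed = deriveSeed(7L, "split"))
  labeled <- labeledIds(init); pool <- poolIds(init)
  act <- activityMatrix(cohort)
  for (i in seq_len(nrow(h))) {
    model <- fitHierarchicalKnn(cohort[, labeled], k = 3L)
    q <- selectQuery(model, act[pool, , drop = FALSE])
    expect_identical(q$sample_id, h$sample_id[i])
    expect_equal(q$confidence, h$confidence[i])
    labeled <- c(labeled, q$sample_id)
    pool <- setdiff(pool, q$sample_id)
  }
})

test_that("runs are reproducible from the seed and differ across seeds", {
  cohort <- tinyCohort(8L, seed = 103L)
  a <- runActiveLearning(cohort, "two_layer_nn", seed = 11L)
  b <- runActiveLearning(cohort, "two_layer_nn", seed = 11L)
  expect_identical(a$history, b$history)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$learningCurve, b$learningCurve)
})

test_that("zero-noise separable cohorts reach perfect test accuracy", {
  cohort <- zeroNoiseCohort(10L, seed = 107L)
  for (spec in c("hierarchical_knn", "two_layer_nn")) {
    ## constant ADAM17 triggers the zero-variance-feature warning by design
    res <- suppressWarnings(runActiveLearning(cohort, spec, seed = 13L))
    expect_equal(accuracy(res$confusion), 100)
  }
})
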