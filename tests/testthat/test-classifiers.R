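test_that("1-NN memorizes a one-sample-per-class labeled set", {
  X <- rbind(c(0, 0), c(5, 0), c(0, 5))
  labeled <- asActivity(X, groups = c("healthy", "localized", "metastatic"))
  fit <- fitHierarchicalKnn(labeled, k = 1L)
  post <- predictPosterior(fit, X)
  expect_equal(as.character(predictedClass(post)),
               c("healthy", "localized", "metastatic"))
  expect_true(all(confidence(post) == 1))
})

test_that("zero-variance features are dropped from the distance with a warning", {
  set.seed(2)
  X <- cbind(runif(9, 1, 5), 7) # second feature constant
  colnames(X) <- c("a", "b")
  labeled <- asActivity(X, groups = rep(c("healthy", "localized", "metastatic"), 3))
  expect_warning(fit <- fitHierarchicalKnn(labeled, k = 3L), "zero-variance.*b")
  expect_equal(fit@features, "a")
  expect_silent(predictPosterior(fit, X))
})

test_that("k is validated and clipped to the labeled size", {
  set.seed(4)
  X <- matrix(runif(12, 0, 5), 6, 2, dimnames = list(NULL, c("a", "b")))
  labeled <- asActivity(X, groups = rep(c("healthy", "localized", "metastatic"), 2))
  expect_error(fitHierarchicalKnn(labeled, k = 4L), "odd")
  expect_warning(fit <- fitHierarchicalKnn(labeled, k = 11L), "clipped")
  expect_equal(fit@k1, 5L) # largest odd <= 6
  expect_error(fitHierarchicalKnn(labeled[, 0], k = 1L), "empty|label")
})

test_that("with k equal to the labeled size stage 1 returns the class prior", {
  set.seed(3)
  X <- matrix(runif(18, 0, 5), 9, 2, dimnames = list(NULL, c("a", "b")))
  g <- c(rep("healthy", 4), rep("localized", 3), rep("metastatic", 2))
  labeled <- asActivity(X, groups = g)
  fit <- fitHierarchicalKnn(labeled, k = 9L)
  post <- predictPosterior(fit, c(100, 100)) # far away: neighbors = everyone
  expect_equal(unname(post[1, "healthy"]), 4 / 9)
})

test_that("hierarchical posteriors follow the two-stage product rule", {
  ## geometry forcing stage-1 vote 2/5 healthy and stage-2 vote 3/5 localized
  x1 <- 20 + c(-0.1, -0.2, 10, 11, 12,    0.1, 0.2, 5.5,   0.3, 0.4)
  g <- c(rep("healthy", 5), rep("localized", 3), rep("metastatic", 2))
  X <- cbind(v = x1)
  fit <- fitHierarchicalKnn(asActivity(X, groups = g), k = 5L)
  post <- predictPosterior(fit, 20)
  expect_equal(unname(post[1, ]), c(0.4, 0.6 * 0.6, 0.6 * 0.4),
               ignore_attr = TRUE)
  ## hierarchy consistency is exact
  expect_equal(unname(post[1, "localized"] + post[1, "metastatic"]),
               unname(1 - post[1, "healthy"]))
  ## repeated calls are identical (deterministic tie handling)
  expect_identical(post, predictPosterior(fit, 20))
})

test_that("a unanimous stage-1 vote yields a degenerate posterior", {
  X <- cbind(a = c(0, 0.1, 0.2, 9, 9.1, 9.2, 9.3))
  g <- c(rep("healthy", 3), rep("localized", 2), rep("metastatic", 2))
  fit <- fitHierarchicalKnn(asActivity(X, groups = g), k = 3L)
  post <- predictPosterior(fit, 0.1)
  expect_equal(unname(post[1, ]), c(1, 0, 0), ignore_attr = TRUE)
})

test_that("stage 2 is absent without two non-healthy classes", {
  set.seed(6)
  X <- matrix(runif(12, 0, 5), 6, 2, dimnames = list(NULL, c("a", "b")))
  labeled <- asActivity(X, groups = c(rep("healthy", 4), "localized", "localized"))
  fit <- fitHierarchicalKnn(labeled, k = 3L)
  expect_equal(nrow(fit@stage2X), 0L)
  post <- predictPosterior(fit, c(100, 100))
  expect_equal(unname(post[1, "localized"]), unname(post[1, "metastatic"]))
})

test_that("both models emit valid simplex posteriors on random inputs", {
  cohort <- tinyCohort(10L, seed = 41L)
  hk <- fitHierarchicalKnn(cohort, k = 5L)
  nn <- fitLinearNet(cohort, seed = 41L)
  set.seed(5)
  X <- matrix(abs(rnorm(1000 * 7, 600, 300)), 1000, 7,
              dimnames = list(NULL, panelProteases(defaultPanel())))
  for (model in list(hk, nn)) {
    post <- predictPosterior(model, X)
    expect_true(all(post >= 0))
    expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  }
  expect_error(predictPosterior(hk, c(1, 2)), "panel|length")
})

test_that("zero-noise cohorts are learned perfectly by both models", {
  cohort <- zeroNoiseCohort(8L, seed = 43L)
  truth <- as.character(sampleGroups(cohort))
  ## ADAM17 has equal group means, so it is constant at zero noise and is
  ## dropped from the kNN distance with a warning
  hk <- suppressWarnings(fitHierarchicalKnn(cohort, k = 5L))
  expect_equal(as.character(predictedClass(predictPosterior(hk, cohort))), truth)
  nn <- fitLinearNet(cohort, seed = 43L)
  expect_equal(as.character(predictedClass(predictPosterior(nn, cohort))), truth)
})

test_that("an all-zero network is the uniform posterior", {
  pan <- panelProteases(defaultPanel())
  model <- new("TwoLayerNetModel",
               W1 = matrix(0, 7, 8, dimnames = list(pan, NULL)), b1 = rep(0, 8),
               W2 = matrix(0, 8, 3), b2 = rep(0, 3),
               center = setNames(rep(0, 7), pan), scale = setNames(rep(1, 7), pan),
               classes = c("healthy", "localized", "metastatic"),
               features = pan, hyper = list())
  post <- predictPosterior(model, setNames(rnorm(7), pan))
  expect_equal(unname(post[1, ]), rep(1 / 3, 3), ignore_attr = TRUE)
})

test_that("network training is deterministic in seed and data", {
  cohort <- tinyCohort(8L, seed = 47L)
  a <- fitLinearNet(cohort, seed = 7L)
  b <- fitLinearNet(cohort, seed = 7L)
  expect_identical(a@W1, b@W1)
  expect_identical(a@b2, b@b2)
  c2 <- fitLinearNet(cohort, seed = 8L)
  expect_false(identical(a@W1, c2@W1))
})

test_that("a single-class labeled set predicts that class with near certainty", {
  set.seed(8)
  X <- matrix(abs(rnorm(10 * 7, 500, 50)), 10, 7,
              dimnames = list(NULL, panelProteases(defaultPanel())))
  labeled <- asActivity(X, groups = rep("localized", 10))
  nn <- fitLinearNet(labeled, seed = 1L)
  post <- predictPosterior(nn, X)
  expect_true(all(post[, "localized"] >= 1 - 1e-6))
})

test_that("the composed linear map is affine with rank at most the class count", {
  cohort <- tinyCohort(8L, seed = 53L)
  wide <- fitLinearNet(cohort, hidden = 16L, seed = 9L)
  narrow <- fitLinearNet(cohort, hidden = 8L, seed = 9L)
  expect_false(identical(dim(wide@W1), dim(narrow@W1)))
  composed <- wide@W1 %*% wide@W2 # input -> logits, before the simplex map
  expect_lte(qr(composed)$rank, 3L)
})

test_that("input translation is absorbed by standardization", {
  cohort <- tinyCohort(8L, seed = 59L)
  act <- activityMatrix(cohort)
  shift <- seq_len(7) * 100
  shifted <- ActivitySet(sweep(act, 2, -shift), groups = sampleGroups(cohort),
                         sampleIds = colnames(cohort))
  a <- fitLinearNet(cohort, seed = 11L)
  b <- fitLinearNet(shifted, seed = 11L)
  q <- act[3, ]
  expect_equal(predictPosterior(a, q), predictPosterior(b, q + shift),
               tolerance = 1e-12)
})

test_that("divergent training surfaces as an explicit error", {
  cohort <- tinyCohort(8L, seed = 61L)
  expect_error(fitLinearNet(cohort, lr = 1e12, epochs = 50L, seed = 1L),
               "non-finite")
})
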