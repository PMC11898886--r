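## Resolve (matrix | vector | ActivitySet) predictor input to a matrix whose
## columns match the model's full panel order.
resolveInput <- function(x, panelFeatures) {
  if (is(x, "ActivitySet")) x <- activityMatrix(x)
  if (is.null(dim(x))) {
    if (length(x) != length(panelFeatures))
      stop(sprintf("expected an activity vector of length %d, got %d",
                   length(panelFeatures), length(x)), call. = FALSE)
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, panelFeatures))
  }
  x <- as.matrix(x)
  if (ncol(x) != length(panelFeatures))
    stop(sprintf("expected %d panel features, got %d columns",
                 length(panelFeatures), ncol(x)), call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- panelFeatures
  else if (!identical(colnames(x), panelFeatures))
    x <- x[, panelFeatures, drop = FALSE]
  x
}

## Largest odd k that is <= k and <= n (>= 1).
clipOdd <- function(k, n) {
  k <- min(k, n)
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 1L)
}

labeledMatrix <- function(labeled) {
  stopifnot(is(labeled, "ActivitySet"))
  g <- as.character(sampleGroups(labeled))
  if (any(is.na(g)))
    stop("all training samples must carry a group label", call. = FALSE)
  list(X = activityMatrix(labeled), g = g)
}

#' Fit the hierarchical two-stage kNN classifier
#'
#' Stage 1 is a k-nearest-neighbour vote separating healthy from non-healthy;
#' stage 2, trained only on the non-healthy labeled samples, separates
#' localized from metastatic. Distances are Euclidean on per-feature z-scores
#' computed from the labeled set; zero-variance features are dropped from the
#' distance with a warning. `k` larger than a stage's training size is
#' clipped down to the largest feasible odd value with a warning. When fewer
#' than two non-healthy classes are present, stage 2 is absent and the model
#' predicts a uniform split between localized and metastatic conditional on
#' non-healthy.
#'
#' @param labeled a labeled [ActivitySet-class].
#' @param k neighbour count; odd, default 5.
#' @return A [HierarchicalKnnModel-class].
#' @export
fitHierarchicalKnn <- function(labeled, k = 5L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1", call. = FALSE)
  lm <- labeledMatrix(labeled)
  X <- lm$X; g <- lm$g
  if (nrow(X) == 0L) stop("empty labeled set", call. = FALSE)
  panelFeatures <- colnames(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (nrow(X) == 1L) scl[] <- 0
  keep <- scl > 0
  if (!all(keep)) {
    warning(sprintf("dropping zero-variance feature(s) from the distance: %s",
                    paste(panelFeatures[!keep], collapse = ", ")))
    if (!any(keep))
      stop("no feature with positive variance in the labeled set", call. = FALSE)
  }
  features <- panelFeatures[keep]
  Z <- scale(X[, keep, drop = FALSE], ctr[keep], scl[keep])

  k1 <- clipOdd(k, nrow(Z))
  if (k1 < k) warning(sprintf("k clipped from %d to %d (labeled size %d)",
                              k, k1, nrow(Z)))
  s1 <- ifelse(g == "healthy", "healthy", "non-healthy")

  nh <- g != "healthy"
  stage2X <- Z[nh, , drop = FALSE]
  stage2Labels <- g[nh]
  if (length(unique(stage2Labels)) < 2L) {
    # stage 2 untrainable with fewer than two non-healthy classes:
    # absent, predicts uniform over localized/metastatic
    stage2X <- matrix(numeric(0), 0L, ncol(Z), dimnames = list(NULL, features))
    stage2Labels <- character(0)
    k2 <- 1L
  } else {
    k2 <- clipOdd(k, nrow(stage2X))
  }

  new("HierarchicalKnnModel",
      k = k, k1 = k1, k2 = k2,
      trainX = unclass(Z), stage1Labels = s1,
      stage2X = unclass(stage2X), stage2Labels = stage2Labels,
      center = ctr[keep], scale = scl[keep],
      features = features, panel = panelFeatures)
}

## Vote fraction for `positive` among the k nearest rows of trainZ to z.
## Ties at the k-th distance resolve to the smallest training-row index:
## neighbours are ordered by (distance, index), first k taken.
knnVote <- function(trainZ, labels, z, k, positive) {
  d <- sqrt(colSums((t(trainZ) - z)^2))
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(min(k, length(ord)))]
  mean(labels[nb] == positive)
}

#' @rdname predictPosterior
#' @export
setMethod("predictPosterior", "HierarchicalKnnModel", function(model, x) {
  X <- resolveInput(x, model@panel)
  Z <- scale(X[, model@features, drop = FALSE], model@center, model@scale)
  n <- nrow(Z)
  post <- matrix(NA_real_, n, 3L,
                 dimnames = list(rownames(X), CLASS_LEVELS))
  for (i in seq_len(n)) {
    pH <- knnVote(model@trainX, model@stage1Labels, Z[i, ], model@k1, "healthy")
    pLgivenNH <- if (nrow(model@stage2X) == 0L) 0.5
                 else knnVote(model@stage2X, model@stage2Labels, Z[i, ],
                              model@k2, "localized")
    post[i, ] <- c(pH, (1 - pH) * pLgivenNH, (1 - pH) * (1 - pLgivenNH))
  }
  post
})

#' Predicted class and confidence of a posterior matrix
#'
#' @param posterior matrix from [predictPosterior()].
#' @return `predictedClass`: factor of argmax classes (ties broken by the
#'   fixed class order healthy < localized < metastatic); `confidence`: the
#'   top-class posterior probability per sample.
#' @export
predictedClass <- function(posterior) {
  idx <- apply(posterior, 1L, which.max) # which.max takes the first maximum
  factor(CLASS_LEVELS[idx], levels = CLASS_LEVELS)
}

#' @rdname predictedClass
#' @export
confidence <- function(posterior) apply(posterior, 1L, max)

setMethod("show", "HierarchicalKnnModel", function(object) {
  cat(sprintf("HierarchicalKnnModel: k=%d (stage1 k=%d on %d samples, stage2 k=%d on %d)\n",
              object@k, object@k1, nrow(object@trainX), object@k2,
              nrow(object@stage2X)))
  cat(sprintf("features: %s\n", paste(object@features, collapse = ", ")))
})
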