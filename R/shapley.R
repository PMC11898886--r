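## Resolve the model argument of the Shapley functions into a plain
## prediction function f(matrix) -> numeric vector of the explained-class
## probability. Fitted package models dispatch through predictPosterior.
classProbFun <- function(model, class) {
  if (is.function(model)) return(model)
  class <- match.arg(class, CLASS_LEVELS)
  function(X) predictPosterior(model, X)[, class]
}

shapBackground <- function(background) {
  B <- if (is(background, "ActivitySet")) activityMatrix(background)
       else as.matrix(background)
  if (nrow(B) == 0L) stop("empty background set", call. = FALSE)
  B
}

#' Exact Shapley feature attributions by coalition enumeration
#'
#' Computes interventional Shapley values of a model's class probability at
#' one sample. The value of a coalition `S` is the mean model output over
#' the background rows with the features in `S` replaced by the sample's
#' values (marginal-replacement expectation). Attributions are assembled by
#' full enumeration of all `2^p` coalitions with the Shapley kernel weights
#' `|S|! (p - |S| - 1)! / p!`, so the efficiency, symmetry, dummy and
#' linearity axioms hold to numerical precision.
#'
#' @param model a fitted [HierarchicalKnnModel-class] /
#'   [TwoLayerNetModel-class], or any function mapping a numeric matrix to a
#'   numeric vector of outputs.
#' @param x numeric activity vector (one sample, panel order).
#' @param background an [ActivitySet-class] or matrix of background samples
#'   (typically the labeled training set; capped deterministically at
#'   `maxBackground` rows).
#' @param class explained class; required when `model` is a fitted
#'   classifier, ignored for plain functions.
#' @param sampleId identifier stored in the explanation.
#' @param maxBackground cap on background rows (first rows kept); default 50.
#' @return A [ShapExplanation-class].
#' @export
shapleyExact <- function(model, x, background, class = NULL,
                         sampleId = "sample", maxBackground = 50L) {
  p <- length(x)
  if (p > 12L)
    stop("exact enumeration is guarded at p <= 12; use shapleySampling()",
         call. = FALSE)
  B <- shapBackground(background)
  if (nrow(B) > maxBackground) B <- B[seq_len(maxBackground), , drop = FALSE]
  f <- classProbFun(model, class)
  featureNames <- colnames(B)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(p))

  nb <- nrow(B)
  nMask <- 2L^p
  ## v[mask + 1] = mean_b f(hybrid(x, b, S = mask))
  v <- numeric(nMask)
  bits <- function(mask) which(bitwAnd(mask, 2L^(seq_len(p) - 1L)) > 0L)
  for (mask in 0:(nMask - 1L)) {
    S <- bits(mask)
    H <- B
    if (length(S)) H[, S] <- matrix(x[S], nb, length(S), byrow = TRUE)
    v[mask + 1L] <- mean(f(H))
  }

  wt <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) / factorial(p)
  phi <- numeric(p)
  sizes <- vapply(0:(nMask - 1L), function(m) length(bits(m)), integer(1L))
  for (i in seq_len(p)) {
    bit <- 2L^(i - 1L)
    without <- which(bitwAnd(0:(nMask - 1L), bit) == 0L) - 1L
    s <- sizes[without + 1L]
    phi[i] <- sum(wt[s + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  names(phi) <- featureNames
  new("ShapExplanation", sampleId = sampleId,
      explainedClass = if (is.null(class)) NA_character_ else class,
      baseValue = v[1L], phi = phi, method = "exact", nEval = nMask)
}

#' Monte-Carlo Shapley attributions by permutation sampling
#'
#' Unbiased permutation estimator of the exact interventional Shapley values
#' of [shapleyExact()], for panels too large to enumerate: each draw picks a
#' random feature ordering and one background row, walks features into the
#' sample one by one and accumulates the marginal output changes. Standard
#' error shrinks as `nSamples^(-1/2)`.
#'
#' @inheritParams shapleyExact
#' @param nSamples number of permutation draws, >= 1.
#' @param seed integer seed.
#' @return A [ShapExplanation-class].
#' @export
shapleySampling <- function(model, x, background, class = NULL,
                            nSamples = 1000L, seed = 1L,
                            sampleId = "sample", maxBackground = 50L) {
  if (nSamples < 1L) stop("nSamples must be >= 1", call. = FALSE)
  B <- shapBackground(background)
  if (nrow(B) > maxBackground) B <- B[seq_len(maxBackground), , drop = FALSE]
  f <- classProbFun(model, class)
  p <- length(x)
  featureNames <- colnames(B)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(p))

  phi <- numeric(p)
  base <- 0
  withr::with_seed(as.integer(seed), {
    for (m in seq_len(nSamples)) {
      perm <- sample.int(p)
      b <- B[sample.int(nrow(B), 1L), ]
      ## rows: background row, then cumulative replacement along perm
      H <- matrix(b, p + 1L, p, byrow = TRUE)
      for (j in seq_len(p)) H[(j + 1L):(p + 1L), perm[j]] <- x[perm[j]]
      out <- f(H)
      phi[perm] <- phi[perm] + diff(out)
      base <- base + out[1L]
    }
  })
  phi <- phi / nSamples
  names(phi) <- featureNames
  new("ShapExplanation", sampleId = sampleId,
      explainedClass = if (is.null(class)) NA_character_ else class,
      baseValue = base / nSamples, phi = phi, method = "sampling",
      nEval = nSamples)
}

#' ShapExplanation accessors
#' @param x a [ShapExplanation-class].
#' @name ShapExplanation-accessors
NULL

#' @rdname ShapExplanation-accessors
#' @export
setMethod("shapValues", "ShapExplanation", function(x) x@phi)

#' @rdname ShapExplanation-accessors
#' @export
setMethod("baseValue", "ShapExplanation", function(x) x@baseValue)

setMethod("show", "ShapExplanation", function(object) {
  cat(sprintf("ShapExplanation (%s, %g evaluations) for sample '%s', class '%s'\n",
              object@method, object@nEval, object@sampleId,
              object@explainedClass))
  cat(sprintf("base value %.4f; phi:\n", object@baseValue))
  print(round(object@phi, 4))
})

#' Rank features by mean absolute Shapley value
#'
#' Aggregates explanations of one class into a global feature ranking by
#' mean `|phi|`; ties resolve to panel order. The per-sample top-3 sets are
#' also returned so their class-wise consistency can be inspected.
#'
#' @param explanations list of [ShapExplanation-class] objects.
#' @param class explained class to aggregate over.
#' @return list with `ranking` (data.frame feature/meanAbsPhi in rank
#'   order), `top3` (character vector), and `perSampleTop3` (list of
#'   per-explanation top-3 character vectors).
#' @export
topFeatures <- function(explanations, class) {
  cls <- vapply(explanations, function(e) e@explainedClass, character(1L))
  sel <- explanations[cls == class]
  if (!length(sel))
    stop(sprintf("no explanations for class '%s'", class), call. = FALSE)
  phis <- do.call(rbind, lapply(sel, function(e) abs(e@phi)))
  meanAbs <- colMeans(phis)
  ord <- order(-meanAbs, seq_along(meanAbs))
  ranking <- data.frame(feature = names(meanAbs)[ord],
                        meanAbsPhi = unname(meanAbs[ord]),
                        stringsAsFactors = FALSE)
  perSampleTop3 <- lapply(sel, function(e) {
    a <- abs(e@phi)
    names(a)[order(-a, seq_along(a))][1:3]
  })
  list(ranking = ranking, top3 = ranking$feature[1:3],
       perSampleTop3 = perSampleTop3)
}
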