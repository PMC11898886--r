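#' Fit the two-layer linear-activation network
#'
#' A literal two-layer network whose hidden activation is the identity, so
#' the input-to-output map is affine; class posteriors are the
#' normalized-exponential (softmax) of the output layer. Inputs are
#' standardized with the labeled set's per-feature mean and sd (constant
#' features get unit scale). Training is full-batch gradient descent on the
#' multinomial cross-entropy for a fixed epoch count, with weights
#' initialized from the seeded sub-stream, so identical seed and data give
#' identical weights.
#'
#' When the labeled set contains a single class, the cross-entropy optimum
#' diverges toward certainty on that class; the fitted model returns the
#' limit directly (a large fixed output bias on the observed class).
#'
#' @param labeled a labeled [ActivitySet-class].
#' @param hidden hidden width; default 8. The hidden layer does not enlarge
#'   the model class (the composed map is affine) but is retained as the
#'   stated architecture.
#' @param lr learning rate; default 0.2.
#' @param epochs full-batch epochs; default 300.
#' @param seed integer seed for weight initialization.
#' @return A [TwoLayerNetModel-class].
#' @export
fitLinearNet <- function(labeled, hidden = 8L, lr = 0.2, epochs = 300L,
                         seed = 1L) {
  lm <- labeledMatrix(labeled)
  X <- lm$X; g <- lm$g
  if (nrow(X) == 0L) stop("empty labeled set", call. = FALSE)
  features <- colnames(X)
  p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (nrow(X) == 1L) scl[] <- 1
  scl[scl <= 0] <- 1
  Z <- scale(X, ctr, scl)

  hyper <- list(hidden = as.integer(hidden), lr = lr,
                epochs = as.integer(epochs), seed = as.integer(seed))

  classes <- CLASS_LEVELS
  present <- unique(g)
  if (length(present) == 1L) {
    # degenerate one-class limit: certainty on the observed class
    W1 <- matrix(0, p, hidden, dimnames = list(features, NULL))
    W2 <- matrix(0, hidden, 3L, dimnames = list(NULL, classes))
    b2 <- setNames(rep(0, 3L), classes)
    b2[present] <- 50
    return(new("TwoLayerNetModel", W1 = W1, b1 = rep(0, hidden),
               W2 = W2, b2 = b2, center = ctr, scale = scl,
               classes = classes, features = features, hyper = hyper))
  }

  Y <- matrix(0, nrow(Z), 3L, dimnames = list(NULL, classes))
  Y[cbind(seq_len(nrow(Z)), match(g, classes))] <- 1

  withr::with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, sd = 0.1), p, hidden,
                 dimnames = list(features, NULL))
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden * 3L, sd = 0.1), hidden, 3L,
                 dimnames = list(NULL, classes))
    b2 <- setNames(rep(0, 3L), classes)
  })

  n <- nrow(Z)
  for (e in seq_len(epochs)) {
    H <- Z %*% W1 + matrix(b1, n, hidden, byrow = TRUE) # identity activation
    O <- H %*% W2 + matrix(b2, n, 3L, byrow = TRUE)
    P <- softmaxRows(O)
    loss <- -mean(log(pmax(rowSums(P * Y), 1e-300)))
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d (lr too large?)", e),
           call. = FALSE)
    dO <- (P - Y) / n
    dW2 <- crossprod(H, dO); db2 <- colSums(dO)
    dH <- dO %*% t(W2)
    dW1 <- crossprod(Z, dH); db1 <- colSums(dH)
    W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
    W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
  }

  new("TwoLayerNetModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      center = ctr, scale = scl, classes = classes, features = features,
      hyper = hyper)
}

#' @rdname predictPosterior
#' @export
setMethod("predictPosterior", "TwoLayerNetModel", function(model, x) {
  X <- resolveInput(x, model@features)
  Z <- scale(X, model@center, model@scale)
  n <- nrow(Z)
  h <- length(model@b1)
  H <- Z %*% model@W1 + matrix(model@b1, n, h, byrow = TRUE)
  O <- H %*% model@W2 + matrix(model@b2, n, 3L, byrow = TRUE)
  post <- softmaxRows(O)
  dimnames(post) <- list(rownames(X), model@classes)
  post
})

setMethod("show", "TwoLayerNetModel", function(object) {
  cat(sprintf("TwoLayerNetModel: %d -> %d -> 3 (identity hidden activation, softmax output)\n",
              nrow(object@W1), ncol(object@W1)))
  cat(sprintf("trained %d epochs, lr %g, seed %d\n",
              object@hyper$epochs, object@hyper$lr, object@hyper$seed))
})
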