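## Shared fixtures: everything is generated in code, no stored data.

## A small labeled cohort for classifier tests.
tinyCohort <- function(nPerGroup = 15L, seed = 1L, sep = 1, noise = "lognormal") {
  cohortConfig(nHealthy = nPerGroup, nLocalized = nPerGroup,
               nMetastatic = nPerGroup, noiseModel = noise, seed = seed,
               panel = scaleSeparation(defaultPanel(), sep)) |>
    generateCohort()
}

## Zero-noise cohort: every sample sits exactly on its group mean.
zeroNoiseCohort <- function(nPerGroup = 15L, seed = 1L) {
  pan <- defaultPanel()
  pan0 <- ProteasePanel(panelProteases(pan), consensusSequences(pan),
                        groupMeans(pan), groupSds(pan) * 0)
  generateCohort(cohortConfig(nHealthy = nPerGroup, nLocalized = nPerGroup,
                              nMetastatic = nPerGroup, seed = seed,
                              panel = pan0),
                 allowZeroSd = TRUE)
}

## An ActivitySet built directly from a matrix of activities.
asActivity <- function(X, groups = NULL) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  ActivitySet(X, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Mock posterior model: wraps a plain function returning a posterior matrix,
## so query-selection logic can be tested against forced posteriors.
setClass("MockPosteriorModel", representation(f = "function"))
setMethod("predictPosterior", "MockPosteriorModel",
          function(model, x) model@f(as.matrix(x)))

## Independent Shapley oracle: average marginal contribution over all p!
## feature orderings, with its own hybrid-point evaluation loop.
shapleyPermutationOracle <- function(f, x, B) {
  p <- length(x)
  perms <- permuteAll(p)
  phi <- numeric(p)
  for (rowi in seq_len(nrow(perms))) {
    perm <- perms[rowi, ]
    z <- B
    prev <- mean(f(z))
    for (j in perm) {
      z[, j] <- x[j]
      cur <- mean(f(z))
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

## All permutations of 1..n (n small).
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}
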