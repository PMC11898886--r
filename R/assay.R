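#' Summarize triplicate wells into net activities
#'
#' Converts plate readouts into one net activity per sample x protease:
#' `activity = mean(ASSAY triplicate) - mean(AC triplicate)`, floored at 0.
#' The assay control (nanobiosensor + buffer) is the subtracted baseline
#' because it shares the fluorophore source with the assay wells; the sample
#' control (serum autofluorescence) is used for quality control only.
#'
#' QC flags are attached, never dropped silently:
#' \describe{
#'   \item{`high_cv_<SOLUTION>`}{a triplicate's coefficient of variation
#'     exceeds `cvThreshold` (CV is computed only when the triplicate mean is
#'     positive).}
#'   \item{`below_baseline`}{the raw net signal was negative before
#'     flooring.}
#' }
#'
#' @param plates a [PlateSet-class].
#' @param cvThreshold triplicate CV flag threshold, in `(0, 1]`; default 0.2.
#' @param groups optional named vector of group labels (names = sample ids)
#'   passed through to the output.
#' @return An [ActivitySet-class]; QC flags are in
#'   `metadata(result)$qcFlags`, a data.frame with columns
#'   `sample_id`, `protease`, `flag`.
#' @export
summarizeWells <- function(plates, cvThreshold = 0.2, groups = NULL) {
  stopifnot(is(plates, "PlateSet"))
  if (!(cvThreshold > 0 && cvThreshold <= 1))
    stop("cvThreshold must be in (0, 1]", call. = FALSE)
  w <- plates@wells
  if (any(w$intensity < 0)) stop("negative well intensity", call. = FALSE)
  samples <- unique(w$sample_id)
  proteases <- unique(w$protease)

  ## structural completeness check, naming the offender
  cnt <- table(factor(w$sample_id, samples), factor(w$protease, proteases),
               factor(w$solution, SOLUTIONS))
  if (!all(cnt == 3L)) {
    bad <- which(cnt != 3L, arr.ind = TRUE)[1L, ]
    stop(sprintf("incomplete triplicate for sample '%s', protease '%s', solution %s",
                 samples[bad[1L]], proteases[bad[2L]], SOLUTIONS[bad[3L]]),
         call. = FALSE)
  }

  key <- interaction(w$sample_id, w$protease, w$solution, drop = FALSE)
  mu <- tapply(w$intensity, key, mean)
  s  <- tapply(w$intensity, key, sd)

  getStat <- function(stat, sol)
    matrix(stat[paste(rep(samples, each = length(proteases)), proteases, sol,
                      sep = ".")],
           nrow = length(samples), byrow = TRUE,
           dimnames = list(samples, proteases))
  mAssay <- getStat(mu, "ASSAY"); sAssay <- getStat(s, "ASSAY")
  mAC <- getStat(mu, "AC"); sAC <- getStat(s, "AC")
  mSC <- getStat(mu, "SC"); sSC <- getStat(s, "SC")

  net <- mAssay - mAC
  act <- pmax(net, 0)

  flags <- data.frame(sample_id = character(), protease = character(),
                      flag = character(), stringsAsFactors = FALSE)
  addFlag <- function(mask, flag) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx))
      flags <<- rbind(flags, data.frame(sample_id = samples[idx[, 1L]],
                                        protease = proteases[idx[, 2L]],
                                        flag = flag, stringsAsFactors = FALSE))
  }
  cvOf <- function(m, sdm) ifelse(m > 0, sdm / m, 0)
  addFlag(cvOf(mAssay, sAssay) > cvThreshold, "high_cv_ASSAY")
  addFlag(cvOf(mAC, sAC) > cvThreshold, "high_cv_AC")
  addFlag(cvOf(mSC, sSC) > cvThreshold, "high_cv_SC")
  addFlag(net < 0, "below_baseline")
  flags <- flags[order(flags$sample_id, flags$protease, flags$flag), ,
                 drop = FALSE]
  rownames(flags) <- NULL

  g <- if (!is.null(groups)) unname(groups[samples]) else NULL
  out <- ActivitySet(act, groups = g, sampleIds = samples)
  S4Vectors::metadata(out)$qcFlags <- flags
  out
}
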