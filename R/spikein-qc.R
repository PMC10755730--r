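# Spike-in QC: conversion-rate estimation from contigs of known uniform
# modification state. Rates are pooled read-level proportions (sum of
# T-readouts over sum of C+T readouts), matching how average conversion
# rates are reported; per-site medians are a diagnostic only.

#' Estimate conversion rates from spike-in counts
#'
#' For each spike-in class, pools N_T and N_C over all labeled rows and
#' reports the C-to-T conversion rate sum(N_T) / sum(N_C + N_T). The
#' caller's non-conversion error `epsilon` is the larger of the unmodified
#' and all-5mC non-conversion rates: the binomial null must cover residual
#' unconverted 5mC as well as unconverted C, and the conservative maximum
#' of the two calibrations is used (see the methods vignette).
#'
#' @param counts a [SiteCountTable-class].
#' @param labels named character mapping spike-in contig names to classes
#'   (unmodified / all-5mC / all-5hmC), e.g. `spikeInClasses(ref)`.
#' @return A [SpikeInReport-class] with pooled rates, epsilon, per-site
#'   median diagnostic and a per-5'-context breakdown.
#' @export
estimateConversion <- function(counts, labels) {
  if (!length(labels) || is.null(names(labels)))
    stop("labels must be a named character vector (contig -> class)")
  if (!all(labels %in% .SPIKE_CLASSES))
    stop("spike-in classes must be unmodified / all-5mC / all-5hmC")
  df <- siteCounts(counts)
  df <- df[df$contig %in% names(labels), , drop = FALSE]
  df$class <- unname(labels[df$contig])

  classes <- unique(unname(labels))
  rates <- data.frame(class = classes, n_T = NA_real_, n_C = NA_real_,
                      rate = NA_real_, median_site_rate = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    sub <- df[df$class == classes[i], , drop = FALSE]
    nT <- sum(sub$N_T); nC <- sum(sub$N_C)
    if (nT + nC == 0)
      stop(sprintf("spike-in class '%s' has zero depth", classes[i]))
    rates$n_T[i] <- nT
    rates$n_C[i] <- nC
    rates$rate[i] <- nT / (nT + nC)
    rates$median_site_rate[i] <-
      stats::median(sub$N_T / (sub$N_C + sub$N_T))
  }

  nonconv <- 1 - rates$rate[rates$class %in% c("unmodified", "all-5mC")]
  eps <- if (length(nonconv)) max(nonconv) else NA_real_
  ctx <- stats::aggregate(cbind(n_T = N_T, n_C = N_C) ~ class + context5p,
                          data = df, FUN = sum)
  ctx$rate <- ctx$n_T / (ctx$n_T + ctx$n_C)
  new("SpikeInReport", rates = rates, epsilon = eps, context = ctx)
}
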