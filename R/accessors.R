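#' @rdname ReferenceSet-class
setMethod("refSequences", "ReferenceSet", function(x) x@sequences)

#' @rdname ReferenceSet-class
setMethod("spikeInClasses", "ReferenceSet", function(x) x@spikeClass)

#' @rdname ReferenceSet-class
setMethod("contigClass", "ReferenceSet", function(x, contig) {
  stopifnot(all(contig %in% names(x@sequences)))
  cl <- x@spikeClass[contig]
  cl[is.na(cl)] <- "genomic"
  setNames(unname(cl), contig)
})

#' @rdname ModificationMap-class
setMethod("modSites", "ModificationMap", function(x) x@sites)

#' @rdname ReadSet-class
setMethod("readSequences", "ReadSet", function(x) x@sequences)

#' @rdname ReadSet-class
setMethod("readQualities", "ReadSet", function(x) x@qualities)

#' @rdname ReadSet-class
setMethod("readTruth", "ReadSet", function(x) x@truth)

#' @rdname ReadSet-class
setMethod("length", "ReadSet", function(x) length(x@sequences))

#' @rdname SiteCountTable-class
setMethod("siteCounts", "SiteCountTable", function(x) x@counts)

#' @rdname SpikeInReport-class
setMethod("conversionRates", "SpikeInReport", function(x) x@rates)

#' @rdname SpikeInReport-class
setMethod("nonConversionError", "SpikeInReport", function(x) x@epsilon)

#' @rdname HmcCallSet-class
setMethod("hmcCalls", "HmcCallSet", function(x) x@calls)

#' @rdname HmcCallSet-class
setMethod("highConfidenceSites", "HmcCallSet",
          function(x) x@calls[x@calls$high_confidence, , drop = FALSE])

#' @rdname KineticFit-class
setMethod("kcat", "KineticFit", function(x) x@k_cat)

#' @rdname KineticFit-class
setMethod("Km", "KineticFit", function(x) x@K_M)

#' @rdname KineticFit-class
setMethod("efficiency", "KineticFit", function(x) x@efficiency)

setMethod("show", "DeaminationModel", function(object) {
  cat("DeaminationModel:", object@enzyme, "\n")
  cat("P(deaminate | state, 5' neighbor):\n")
  print(round(object@prob, 4))
})

setMethod("show", "ReferenceSet", function(object) {
  n <- length(object@sequences)
  cat("ReferenceSet with", n, "contig(s),",
      sum(Biostrings::width(object@sequences)), "bp total\n")
  cl <- contigClass(object, names(object@sequences))
  for (i in seq_len(min(n, 8L)))
    cat(sprintf("  %s (%d bp, %s)\n", names(object@sequences)[i],
                Biostrings::width(object@sequences)[i], cl[i]))
  if (n > 8L) cat("  ...\n")
})

setMethod("show", "ModificationMap", function(object) {
  st <- S4Vectors::mcols(object@sites)$state
  cat("ModificationMap:", length(object@sites), "site(s)",
      sprintf("(%d 5mC, %d 5hmC)\n", sum(st == "5mC"), sum(st == "5hmC")))
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet with", length(object@sequences), "read(s)\n")
  if (length(object@sequences))
    cat("  widths:", paste(range(Biostrings::width(object@sequences)),
                           collapse = "-"), "bp\n")
})

setMethod("show", "SiteCountTable", function(object) {
  cat("SiteCountTable:", nrow(object@counts), "covered cytosine site(s)\n")
  if (nrow(object@counts)) print(head(object@counts, 5L))
})

setMethod("show", "SpikeInReport", function(object) {
  cat("SpikeInReport (pooled read-level conversion rates)\n")
  print(object@rates)
  cat(sprintf("epsilon (caller null): %.6f\n", object@epsilon))
})

setMethod("show", "HmcCallSet", function(object) {
  cat(sprintf(
    "HmcCallSet: %d site(s), %d high-confidence (depth >= %d, q < %g, epsilon = %g, %s)\n",
    nrow(object@calls), sum(object@calls$high_confidence),
    object@minDepth, object@qCutoff, object@epsilon, object@method))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit (%s): k_cat = %.4g min^-1, K_M = %.4g uM, k_cat/K_M = %.4g uM^-1 min^-1\n",
    object@method, object@k_cat, object@K_M, object@efficiency))
  cat(sprintf("  linearization: slope %.4g, intercept %.4g, R^2 %.6f%s\n",
              object@slope, object@intercept, object@r_squared,
              if (object@valid) "" else "  [fit invalid: intercept <= 0]"))
})

setMethod("show", "MixtureRegression", function(object) {
  cat(sprintf(
    "MixtureRegression: slope %.4f, intercept %.4f, R^2 %.5f (n = %d)\n",
    object@slope, object@intercept, object@r_squared, object@n))
})
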