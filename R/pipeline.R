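#' Run the full simulation-to-calls pipeline
#'
#' Convenience wrapper chaining [simulateReads()], [alignReads()] (or the
#' truth alignments, bypassing the aligner), [pileup()],
#' [estimateConversion()] on the reference's spike-in contigs, and
#' [callHmc()] on the genomic contigs with the spike-in-derived epsilon.
#'
#' @param ref a [ReferenceSet-class] (with spike-in contigs if epsilon is
#'   to be estimated).
#' @param mods a [ModificationMap-class].
#' @param model a [DeaminationModel-class].
#' @param mean_depth per-strand mean coverage.
#' @param read_len read length.
#' @param seed integer seed.
#' @param aligner "seed" (the converted-space aligner) or "truth"
#'   (alignments taken from the simulator's truth sidecar).
#' @param max_mismatch aligner mismatch bound.
#' @param epsilon override the spike-in-derived non-conversion error.
#' @param min_depth,q_cutoff caller thresholds.
#' @param error_rate optional substitution error rate for the simulator.
#' @return list(reads, alignments, counts, spikein, calls); `spikein` is
#'   NULL when the reference has no spike-in contigs and `epsilon` was
#'   supplied.
#' @export
hmcPipeline <- function(ref, mods, model, mean_depth = 10, read_len = 100L,
                        seed = 1L, aligner = c("seed", "truth"),
                        max_mismatch = 2L, epsilon = NULL,
                        min_depth = 5L, q_cutoff = 0.01, error_rate = 0) {
  aligner <- match.arg(aligner)
  reads <- simulateReads(ref, mods, model, mean_depth = mean_depth,
                         read_len = read_len, seed = seed,
                         error_rate = error_rate)
  aln <- if (aligner == "seed") alignReads(reads, ref, max_mismatch)
         else truthAlignments(reads)
  counts <- pileup(aln, reads, ref)

  spikein <- NULL
  labels <- spikeInClasses(ref)
  if (length(labels))
    spikein <- estimateConversion(counts, labels)
  if (is.null(epsilon)) {
    if (is.null(spikein))
      stop("no spike-in contigs: supply epsilon explicitly")
    epsilon <- nonConversionError(spikein)
  }

  genomic <- setdiff(names(refSequences(ref)), names(labels))
  df <- siteCounts(counts)
  gcounts <- new("SiteCountTable",
                 counts = df[df$contig %in% genomic, , drop = FALSE])
  calls <- callHmc(gcounts, epsilon, min_depth = min_depth,
                   q_cutoff = q_cutoff)
  list(reads = reads, alignments = aln, counts = counts,
       spikein = spikein, calls = calls)
}
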