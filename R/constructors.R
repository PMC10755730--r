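#' Construct a ReferenceSet from sequences
#'
#' @param sequences named character vector or named DNAStringSet.
#' @param spike_class named character mapping spike-in contigs to classes.
#' @return A [ReferenceSet-class].
#' @export
referenceSet <- function(sequences, spike_class = character(0)) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("ReferenceSet", sequences = sequences, spikeClass = spike_class)
}

#' Construct a SiteCountTable from a data.frame
#'
#' @param counts data.frame with columns contig, pos0, strand, context5p,
#'   context3p, N_C, N_T, N_other.
#' @return A [SiteCountTable-class].
#' @export
siteCountTable <- function(counts) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  missing <- setdiff(.COUNT_COLS, names(counts))
  for (col in missing) {
    if (col %in% c("context5p", "context3p")) counts[[col]] <- "N"
    else if (col == "N_other") counts[[col]] <- 0L
    else stop(sprintf("missing column: %s", col))
  }
  new("SiteCountTable", counts = counts[, .COUNT_COLS])
}

#' Construct a ModificationMap from a data.frame
#'
#' @param entries data.frame(contig, pos0, strand, state); pos0 is
#'   0-based.
#' @param ref optional [ReferenceSet-class]; when supplied, each entry is
#'   checked to address a base that is C on its strand.
#' @return A [ModificationMap-class].
#' @export
modificationMap <- function(entries, ref = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  gr <- if (nrow(entries))
    GenomicRanges::GRanges(entries$contig,
                           IRanges::IRanges(start = entries$pos0 + 1L,
                                            width = 1L),
                           strand = entries$strand, state = entries$state)
  else GenomicRanges::GRanges(state = character(0))
  if (!is.null(ref) && nrow(entries)) {
    seqs <- refSequences(ref)
    for (ct in unique(entries$contig)) {
      s <- .explode(as.character(seqs[[ct]]))
      sel <- entries$contig == ct
      base <- s[entries$pos0[sel] + 1L]
      want <- ifelse(entries$strand[sel] == "+", "C", "G")
      if (any(base != want))
        stop("modification entry does not address a cytosine on its strand")
    }
  }
  new("ModificationMap", sites = gr)
}
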