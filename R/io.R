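# Readers and writers for the standard interchange formats: FASTA
# (reference), FASTQ (reads), BED (truth maps and calls), TSV (site
# counts), bedGraph (fractions) and JSON (models and reports).
# Coordinates are 0-based half-open in all BED/bedGraph/TSV output.

#' @rdname deamhmcIO
#' @param ref a [ReferenceSet-class].
#' @param path output file path.
#' @export
writeReferenceFasta <- function(ref, path) {
  Biostrings::writeXStringSet(refSequences(ref), path)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param spike_class named character of spike-in classes for
#'   [readReferenceFasta()].
#' @export
readReferenceFasta <- function(path, spike_class = character(0)) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new("ReferenceSet", sequences = seqs, spikeClass = spike_class)
}

#' @rdname deamhmcIO
#' @param reads a [ReadSet-class].
#' @export
writeReadsFastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(readQualities(reads))
  x <- Biostrings::QualityScaledDNAStringSet(readSequences(reads), q)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param mods a [ModificationMap-class].
#' @export
writeModificationsBed <- function(mods, path) {
  gr <- modSites(mods)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::start(gr),
                   name = S4Vectors::mcols(gr)$state,
                   score = ".",
                   strand = as.character(GenomicRanges::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param counts a [SiteCountTable-class].
#' @export
writeSiteCounts <- function(counts, path) {
  write.table(siteCounts(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @export
readSiteCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(contig = "character",
                                  strand = "character",
                                  context5p = "character",
                                  context3p = "character"))
  new("SiteCountTable", counts = df[, .COUNT_COLS])
}

#' @rdname deamhmcIO
#' @param x a [SiteCountTable-class] or [HmcCallSet-class]; the bedGraph
#'   value is the raw per-site C fraction (strands written as separate
#'   rows at the same interval).
#' @export
writeBedGraph <- function(x, path) {
  df <- if (is(x, "SiteCountTable")) {
    d <- siteCounts(x)
    d$fraction <- d$N_C / (d$N_C + d$N_T)
    d
  } else hmcCalls(x)
  out <- data.frame(chrom = df$contig, start = df$pos0, end = df$pos0 + 1L,
                    value = round(df$fraction, 6))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param calls an [HmcCallSet-class]; BED rows are the high-confidence
#'   sites with score = round(1000 * fraction).
#' @export
writeCallsBed <- function(calls, path) {
  hc <- highConfidenceSites(calls)
  df <- data.frame(chrom = hc$contig, start = hc$pos0, end = hc$pos0 + 1L,
                   name = "5hmC", score = round(1000 * hc$fraction),
                   strand = hc$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @export
writeCallsTsv <- function(calls, path) {
  write.table(hmcCalls(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param report a [SpikeInReport-class], written as JSON
#'   {class: {n_T, n_C, rate}, ..., epsilon}.
#' @export
writeSpikeInReportJson <- function(report, path) {
  r <- conversionRates(report)
  obj <- setNames(lapply(seq_len(nrow(r)), function(i)
    list(n_T = r$n_T[i], n_C = r$n_C[i], rate = r$rate[i])), r$class)
  obj$epsilon <- nonConversionError(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname deamhmcIO
#' @param model a [DeaminationModel-class].
#' @export
writeDeaminationModelJson <- function(model, path) {
  jsonlite::write_json(list(enzyme = model@enzyme,
                            states = rownames(model@prob),
                            contexts = colnames(model@prob),
                            prob = model@prob),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname deamhmcIO
#' @export
readDeaminationModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prob <- matrix(as.numeric(obj$prob), nrow = 3L,
                 dimnames = list(obj$states, obj$contexts))
  deaminationModel(obj$enzyme, prob = prob)
}

#' @rdname deamhmcIO
#' @param points kinetic points data.frame (S_uM, E_uM, t_min,
#'   frac_deaminated).
#' @export
writeKineticPointsCsv <- function(points, path) {
  write.table(points, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname deamhmcIO
#' @export
readKineticPointsCsv <- function(path) {
  read.table(path, header = TRUE, sep = ",")
}

#' @rdname deamhmcIO
#' @param fit a [KineticFit-class].
#' @export
writeKineticFitJson <- function(fit, path) {
  jsonlite::write_json(list(k_cat = fit@k_cat, K_M = fit@K_M,
                            efficiency = fit@efficiency, slope = fit@slope,
                            intercept = fit@intercept,
                            r_squared = fit@r_squared, valid = fit@valid,
                            method = fit@method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' File readers and writers
#'
#' @name deamhmcIO
#' @param path file path.
NULL
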