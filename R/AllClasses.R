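#' @import methods
#' @importFrom Biostrings DNAStringSet BStringSet DNAString reverseComplement
#'   writeXStringSet PDict matchPDict QualityScaledDNAStringSet
#'   writeQualityScaledXStringSet PhredQuality vcountPattern
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths
#' @importFrom stats pbinom p.adjust lm coef rpois runif rnorm rbinom rgeom
#'   setNames var cor complete.cases
#' @importFrom utils head write.table read.table
#' @importFrom data.table data.table as.data.table rbindlist dcast :=
NULL

.datatable.aware <- TRUE

.MOD_STATES    <- c("C", "5mC", "5hmC")
.CONTEXTS      <- c("A", "C", "G", "T")
.SPIKE_CLASSES <- c("unmodified", "all-5mC", "all-5hmC")

#' DeaminationModel: per-state, per-context deamination probabilities
#'
#' Holds, for one deaminase, the probability that a cytosine in state C,
#' 5mC or 5hmC is deaminated (hence read as T), stratified by the 5'
#' neighboring base on the same strand. The engineered eA3A-v10 deaminase
#' shows no sequence-context bias, so its default cells are uniform across
#' contexts; the context axis is kept so partially biased enzymes can be
#' expressed.
#'
#' @slot enzyme enzyme name.
#' @slot prob 3 x 4 numeric matrix, rows C/5mC/5hmC, columns A/C/G/T
#'   (the 5' neighbor), all entries in [0, 1].
#' @export
setClass("DeaminationModel",
         slots = c(enzyme = "character", prob = "matrix"))

setValidity("DeaminationModel", function(object) {
  p <- object@prob
  if (!identical(rownames(p), .MOD_STATES))
    return("prob rows must be C, 5mC, 5hmC")
  if (!identical(colnames(p), .CONTEXTS))
    return("prob columns must be A, C, G, T")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    return("all 12 probabilities must be present and in [0, 1]")
  if (length(object@enzyme) != 1L)
    return("enzyme must be a single name")
  TRUE
})

#' ReferenceSet: contigs plus spike-in labels
#'
#' A set of reference contigs with an optional map from contig name to
#' spike-in modification class. Contigs absent from the map are "genomic"
#' (their cytosine states come from a [ModificationMap]); spike-in contigs
#' are uniformly unmodified, all-5mC or all-5hmC by construction.
#'
#' @slot sequences named [Biostrings::DNAStringSet] of contigs.
#' @slot spikeClass named character; values among unmodified / all-5mC /
#'   all-5hmC, names a subset of contig names.
#' @export
setClass("ReferenceSet",
         slots = c(sequences = "DNAStringSet", spikeClass = "character"))

setValidity("ReferenceSet", function(object) {
  nm <- names(object@sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("all contigs must be named")
  if (anyDuplicated(nm))
    return(sprintf("duplicate contig name: %s", nm[duplicated(nm)][1L]))
  if (any(Biostrings::width(object@sequences) == 0L))
    return("contig sequences must be non-empty")
  sc <- object@spikeClass
  if (length(sc)) {
    if (!all(names(sc) %in% nm))
      return("spike-in label refers to a missing contig")
    if (!all(sc %in% .SPIKE_CLASSES))
      return(sprintf("spike-in classes must be one of: %s",
                     paste(.SPIKE_CLASSES, collapse = ", ")))
  }
  TRUE
})

#' ModificationMap: planted cytosine modification states
#'
#' Width-1 [GenomicRanges::GRanges] of modified cytosines with a `state`
#' metadata column (5mC or 5hmC). Positions absent from the map are
#' unmodified C. Each range must address a base that is C on its strand
#' (C on plus, G on minus in reference coordinates).
#'
#' @slot sites GRanges with mcol `state`.
#' @export
setClass("ModificationMap", slots = c(sites = "GRanges"))

setValidity("ModificationMap", function(object) {
  gr <- object@sites
  if (length(gr) == 0L) return(TRUE)
  st <- S4Vectors::mcols(gr)$state
  if (is.null(st) || !all(st %in% c("5mC", "5hmC")))
    return("state mcol must be 5mC or 5hmC")
  if (any(GenomicRanges::width(gr) != 1L))
    return("modification sites must have width 1")
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    return("modification sites must be stranded")
  key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
               GenomicRanges::strand(gr))
  if (anyDuplicated(key))
    return("duplicate (contig, pos, strand) in modification map")
  TRUE
})

#' ReadSet: simulated reads with their truth sidecar
#'
#' @slot sequences named DNAStringSet of reads.
#' @slot qualities BStringSet of per-read quality strings (constant Phred 40
#'   by default; the pipeline ignores qualities).
#' @slot truth data.frame with one row per read: read_id, contig, start0
#'   (0-based), strand, and for amplicon simulations the molecule state.
#' @export
setClass("ReadSet",
         slots = c(sequences = "DNAStringSet", qualities = "BStringSet",
                   truth = "data.frame"))

setValidity("ReadSet", function(object) {
  n <- length(object@sequences)
  if (length(object@qualities) != n)
    return("sequences and qualities lengths differ")
  if (nrow(object@truth) != n)
    return("truth sidecar must have one row per read")
  need <- c("read_id", "contig", "start0", "strand")
  if (!all(need %in% names(object@truth)))
    return("truth needs columns read_id, contig, start0, strand")
  if (!identical(names(object@sequences), object@truth$read_id))
    return("read names must match truth read_id, in order")
  TRUE
})

#' SiteCountTable: per-cytosine strand-aware C/T counts
#'
#' One row per covered reference cytosine (C on plus, G on minus), with
#' counts of reads showing C (`N_C`, the 5hmC signal), T (`N_T`, converted
#' C or 5mC) or anything else (`N_other`). Depth is N_C + N_T; N_other is
#' excluded from the binomial test. `context5p`/`context3p` are the 5' and
#' 3' neighbors read on the site's strand.
#'
#' @slot counts data.frame(contig, pos0, strand, context5p, context3p,
#'   N_C, N_T, N_other).
#' @export
setClass("SiteCountTable", slots = c(counts = "data.frame"))

.COUNT_COLS <- c("contig", "pos0", "strand", "context5p", "context3p",
                 "N_C", "N_T", "N_other")

setValidity("SiteCountTable", function(object) {
  df <- object@counts
  if (!all(.COUNT_COLS %in% names(df)))
    return(sprintf("counts needs columns: %s",
                   paste(.COUNT_COLS, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$N_C < 0 | df$N_T < 0 | df$N_other < 0))
      return("counts must be non-negative")
    if (!all(df$strand %in% c("+", "-")))
      return("strand must be + or -")
    if (any(df$pos0 < 0))
      return("pos0 must be >= 0")
  }
  TRUE
})

#' SpikeInReport: conversion rates estimated from spike-in contigs
#'
#' Pooled (read-level) C-to-T conversion rates per spike-in class, the
#' derived non-conversion error `epsilon` fed to the binomial caller, and a
#' per-5'-context diagnostic breakdown.
#'
#' @slot rates data.frame(class, n_T, n_C, rate).
#' @slot epsilon max of the unmodified and all-5mC non-conversion rates.
#' @slot context data.frame(class, context5p, n_T, n_C, rate) diagnostic.
#' @export
setClass("SpikeInReport",
         slots = c(rates = "data.frame", epsilon = "numeric",
                   context = "data.frame"))

#' HmcCallSet: per-site binomial 5hmC calls
#'
#' @slot calls data.frame(contig, pos0, strand, context5p, context3p, N_C,
#'   N_T, fraction, p_value, q_value, high_confidence). q_value is NA for
#'   sites below the depth filter (they are excluded from the BH family).
#' @slot epsilon non-conversion error used as the binomial null.
#' @slot minDepth depth filter for high-confidence calling.
#' @slot qCutoff q-value cutoff for high-confidence calling.
#' @slot method multiple-testing method used ("BH" or "storey").
#' @export
setClass("HmcCallSet",
         slots = c(calls = "data.frame", epsilon = "numeric",
                   minDepth = "integer", qCutoff = "numeric",
                   method = "character"))

#' KineticFit: Michaelis-Menten parameters from linearized regression
#'
#' @slot k_cat turnover number (min^-1 as printed by the rate definition).
#' @slot K_M Michaelis constant (uM).
#' @slot efficiency k_cat / K_M (uM^-1 min^-1), always the exact ratio.
#' @slot slope,intercept,r_squared diagnostics of the double-reciprocal
#'   (or Hanes-Woolf) linear fit.
#' @slot valid FALSE when the linearization intercept is <= 0.
#' @slot method "lineweaver-burk" or "hanes-woolf".
#' @export
setClass("KineticFit",
         slots = c(k_cat = "numeric", K_M = "numeric", efficiency = "numeric",
                   slope = "numeric", intercept = "numeric",
                   r_squared = "numeric", valid = "logical",
                   method = "character"))

setValidity("KineticFit", function(object) {
  if (length(object@efficiency) == 1L && length(object@k_cat) == 1L &&
      length(object@K_M) == 1L && is.finite(object@efficiency) &&
      is.finite(object@k_cat) && is.finite(object@K_M) && object@K_M != 0 &&
      abs(object@efficiency - object@k_cat / object@K_M) >
        1e-9 * max(1, abs(object@efficiency)))
    return("efficiency must equal k_cat / K_M")
  TRUE
})

#' MixtureRegression: OLS of measured C/(C+T) on theoretical 5hmC fraction
#'
#' @slot slope,intercept,r_squared ordinary least-squares fit diagnostics.
#' @slot n number of (measured, theoretical) pairs.
#' @export
setClass("MixtureRegression",
         slots = c(slope = "numeric", intercept = "numeric",
                   r_squared = "numeric", n = "integer"))
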