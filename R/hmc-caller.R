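# Base-resolution 5hmC calling: per-site upper-tail binomial test of the
# C readout count against the spike-in non-conversion error, with a depth
# filter and q-value control over the tested family.

#' Upper-tail binomial p-value for a candidate 5hmC site
#'
#' p = P(X >= N_C) with X ~ Binomial(N_C + N_T, epsilon): the probability
#' of seeing at least the observed number of C readouts if every C at the
#' site were an unconverted (non-5hmC) cytosine with non-conversion error
#' epsilon. Vectorized over sites.
#'
#' @param N_C,N_T per-site counts of C and T readouts; N_C + N_T >= 1.
#' @param epsilon non-conversion error in [0, 1].
#' @return p-value(s) in [0, 1].
#' @examples
#' sitePValue(2, 8, 0.01)
#' @export
sitePValue <- function(N_C, N_T, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  depth <- N_C + N_T
  if (any(depth < 1)) stop("site depth (N_C + N_T) must be >= 1")
  if (any(N_C < 0 | N_T < 0)) stop("counts must be non-negative")
  # P(X >= N_C); pbinom(q, ..., lower.tail = FALSE) is P(X > q)
  stats::pbinom(N_C - 1, depth, epsilon, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment q_(i) = min_{j >= i} p_(j) * m / j on the sorted
#' p-values, clipped to [0, 1] and returned in input order. Ties in p give
#' identical q.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as the input.
#' @export
bhAdjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Storey-style q-values: BH scaled by a pi0 estimate at lambda = 0.5.
.storeyAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Call high-confidence 5hmC sites
#'
#' Computes the 5hmC fraction N_C / (N_C + N_T) and the upper-tail
#' binomial p-value for every covered site, applies multiple-testing
#' adjustment over the family of sites passing the depth filter
#' (depth = N_C + N_T >= `min_depth`), and flags high-confidence sites as
#' those with depth >= `min_depth` and q < `q_cutoff`. Sites below the
#' depth filter keep their p-value but carry q = NA and are never
#' high-confidence. N_other is excluded from the test.
#'
#' @param counts a [SiteCountTable-class] (or its data.frame).
#' @param epsilon non-conversion error (from [estimateConversion()] or
#'   user-supplied); must be < 1.
#' @param min_depth minimum depth for the tested family (default 5).
#' @param q_cutoff q-value threshold for high confidence (default 0.01).
#' @param method "BH" (default) or "storey".
#' @return An [HmcCallSet-class].
#' @export
callHmc <- function(counts, epsilon, min_depth = 5L, q_cutoff = 0.01,
                    method = c("BH", "storey")) {
  method <- match.arg(method)
  if (!is.finite(epsilon)) stop("epsilon must be a finite number")
  if (epsilon >= 1) stop("epsilon must be < 1")
  if (epsilon < 0) stop("epsilon must be >= 0")
  df <- if (is(counts, "SiteCountTable")) siteCounts(counts) else counts
  df <- df[df$N_C + df$N_T >= 1L, , drop = FALSE]
  depth <- df$N_C + df$N_T
  fraction <- ifelse(depth > 0, df$N_C / depth, NA_real_)
  p <- if (nrow(df)) sitePValue(df$N_C, df$N_T, epsilon) else numeric(0)
  q <- rep(NA_real_, nrow(df))
  tested <- which(depth >= min_depth)
  if (length(tested))
    q[tested] <- if (method == "BH") bhAdjust(p[tested])
                 else .storeyAdjust(p[tested])
  hc <- !is.na(q) & q < q_cutoff
  calls <- data.frame(df[, c("contig", "pos0", "strand",
                             "context5p", "context3p", "N_C", "N_T")],
                      fraction = fraction, p_value = p, q_value = q,
                      high_confidence = hc, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  new("HmcCallSet", calls = calls, epsilon = epsilon,
      minDepth = as.integer(min_depth), qCutoff = q_cutoff, method = method)
}

#' Merge symmetric CpG strand counts
#'
#' Optional post-step pooling the two strands of a symmetric CpG: for each
#' plus-strand row whose reference context is CpG, the counts of the
#' minus-strand row at the paired G (pos + 1) are added to it and the
#' minus row is dropped. Per-strand calling is the default convention;
#' merging trades strand resolution for depth.
#'
#' @param counts a [SiteCountTable-class].
#' @return A [SiteCountTable-class] with merged CpG rows.
#' @export
mergeCpGStrands <- function(counts) {
  df <- siteCounts(counts)
  plus <- df[df$strand == "+", , drop = FALSE]
  minus <- df[df$strand == "-", , drop = FALSE]
  is_cpg_plus <- plus$context3p == "G"
  key_minus <- paste(minus$contig, minus$pos0)
  partner <- match(paste(plus$contig, plus$pos0 + 1L), key_minus)
  hit <- which(is_cpg_plus & !is.na(partner))
  if (length(hit)) {
    j <- partner[hit]
    plus$N_C[hit] <- plus$N_C[hit] + minus$N_C[j]
    plus$N_T[hit] <- plus$N_T[hit] + minus$N_T[j]
    plus$N_other[hit] <- plus$N_other[hit] + minus$N_other[j]
    minus <- minus[-j, , drop = FALSE]
  }
  out <- rbind(plus, minus)
  out <- out[order(out$contig, out$pos0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  new("SiteCountTable", counts = out)
}
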