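# Genome-scale summaries of a call set: tiled-bin signal and replicate
# correlation, cytosine sequence context, feature distribution, and TSS
# metaprofiles.

#' Tile the genome and average 5hmC signal per bin
#'
#' Bins tile each contig half-open at fixed width. Every assayed site
#' contributes its 5hmC fraction; with `high_conf_only = TRUE` (default)
#' sites that are not high-confidence contribute a fraction of 0 but stay
#' in the denominator, so the bin mean tracks the density and level of
#' confident 5hmC rather than the stoichiometry of whichever sites passed
#' the filter. Empty bins carry n_sites = 0 and NA mean.
#'
#' @param calls an [HmcCallSet-class].
#' @param bin_width bin width in bp (default 10 kb).
#' @param high_conf_only zero the fraction of non-high-confidence sites.
#' @param seqlengths named contig lengths, or a [ReferenceSet-class];
#'   inferred from the rightmost site per contig when NULL.
#' @return data.frame(contig, bin_start, bin_end, mean_fraction, n_sites).
#' @export
binSignal <- function(calls, bin_width = 10000L, high_conf_only = TRUE,
                      seqlengths = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  df <- hmcCalls(calls)
  if (is(seqlengths, "ReferenceSet"))
    seqlengths <- setNames(Biostrings::width(refSequences(seqlengths)),
                           names(refSequences(seqlengths)))
  contigs <- if (!is.null(seqlengths)) names(seqlengths)
             else unique(df$contig)
  if (!is.null(seqlengths)) df <- df[df$contig %in% contigs, , drop = FALSE]
  sig <- df$fraction
  if (high_conf_only) sig[!df$high_confidence] <- 0
  bin <- df$pos0 %/% as.integer(bin_width)

  out <- list()
  for (ct in contigs) {
    sel <- df$contig == ct
    L <- if (!is.null(seqlengths)) seqlengths[[ct]]
         else if (any(sel)) max(df$pos0[sel]) + 1L else bin_width
    nb <- max(1L, as.integer(ceiling(L / bin_width)))
    msum <- tabulate(bin[sel] + 1L, nbins = nb)
    vsum <- rep(0, nb)
    if (any(sel)) {
      agg <- tapply(sig[sel], bin[sel], sum)
      vsum[as.integer(names(agg)) + 1L] <- agg
    }
    out[[ct]] <- data.frame(
      contig = ct,
      bin_start = (seq_len(nb) - 1L) * as.integer(bin_width),
      bin_end = pmin(seq_len(nb) * as.numeric(bin_width), L),
      mean_fraction = ifelse(msum > 0, vsum / msum, NA_real_),
      n_sites = msum, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation between two binned signals
#'
#' Matches bins by (contig, bin_start), keeps bins non-empty in both
#' signals, and computes the product-moment correlation. Empty bins are
#' excluded pairwise, not zero-filled, so shared emptiness cannot
#' manufacture correlation.
#'
#' @param binsA,binsB outputs of [binSignal()].
#' @return Pearson r.
#' @export
correlateBins <- function(binsA, binsB) {
  key <- function(b) paste(b$contig, b$bin_start)
  m <- match(key(binsA), key(binsB))
  ok <- !is.na(m) & binsA$n_sites > 0 & binsB$n_sites[m] > 0
  x <- binsA$mean_fraction[ok]
  y <- binsB$mean_fraction[m[ok]]
  if (length(x) < 3L) stop("need at least 3 shared non-empty bins")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Classify the sequence context of cytosine sites
#'
#' Context is read 5' to 3' on the site's strand: CpG (C followed by G),
#' CHG (C, non-G, G) or CHH. Minus-strand sites are read on the reverse
#' complement. Sites too close to the contig edge for two 3' bases return
#' NA where the context cannot be resolved.
#'
#' @param ref a [ReferenceSet-class].
#' @param contig,pos0,strand parallel vectors addressing cytosines
#'   (0-based positions; base must be C on plus / G on minus).
#' @return character vector of "CpG", "CHG", "CHH" or NA.
#' @export
classifyContext <- function(ref, contig, pos0, strand) {
  seqs <- refSequences(ref)
  n <- length(pos0)
  stopifnot(length(contig) == n, length(strand) == n)
  out <- rep(NA_character_, n)
  for (ct in unique(contig)) {
    s <- .explode(as.character(seqs[[ct]]))
    L <- length(s)
    sel <- which(contig == ct)
    p1 <- pos0[sel] + 1L
    plus <- strand[sel] == "+"
    base <- s[p1]
    if (any(base[plus] != "C") || any(base[!plus] != "G"))
      stop("site is not a cytosine on its strand")
    n1 <- rep(NA_character_, length(sel))
    n2 <- rep(NA_character_, length(sel))
    n1[plus] <- ifelse(p1[plus] + 1L <= L, s[pmin(p1[plus] + 1L, L)], NA)
    n2[plus] <- ifelse(p1[plus] + 2L <= L, s[pmin(p1[plus] + 2L, L)], NA)
    n1[!plus] <- ifelse(p1[!plus] - 1L >= 1L,
                        .compChar(s[pmax(p1[!plus] - 1L, 1L)]), NA)
    n2[!plus] <- ifelse(p1[!plus] - 2L >= 1L,
                        .compChar(s[pmax(p1[!plus] - 2L, 1L)]), NA)
    ctx <- ifelse(is.na(n1), NA_character_,
           ifelse(n1 == "G", "CpG",
           ifelse(is.na(n2), NA_character_,
           ifelse(n2 == "G", "CHG", "CHH"))))
    out[sel] <- ctx
  }
  out
}

#' Distribution of high-confidence 5hmC sites over genomic features
#'
#' Assigns each high-confidence site to the highest-priority overlapping
#' feature (half-open intervals; a site on a start boundary is inside).
#' Sites overlapping no feature are "intergenic". Proportions sum to 1.
#'
#' @param calls an [HmcCallSet-class].
#' @param features data.frame(contig, start, end, label) with 0-based
#'   half-open intervals, or a GRanges with a `label` mcol.
#' @param priority label order used to resolve overlaps (highest first);
#'   labels absent from `priority` rank after it, in order of appearance.
#' @return named numeric vector of proportions (including "intergenic").
#' @export
featureDistribution <- function(calls, features,
                                priority = c("promoter", "utr5", "exon",
                                             "intron", "utr3")) {
  if (is(features, "GRanges")) {
    features <- data.frame(
      contig = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features) - 1L,
      end = GenomicRanges::end(features),
      label = S4Vectors::mcols(features)$label,
      stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) && any(features$end <= features$start))
    stop("malformed interval: end must be > start (half-open)")
  sites <- highConfidenceSites(calls)
  if (!nrow(sites)) stop("no high-confidence sites to summarize")

  labs <- unique(features$label)
  rank <- match(labs, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  lab_rank <- setNames(rank, labs)

  assigned <- rep("intergenic", nrow(sites))
  if (nrow(features)) {
    fgr <- GenomicRanges::GRanges(
      features$contig,
      IRanges::IRanges(start = features$start + 1L, end = features$end))
    sgr <- GenomicRanges::GRanges(
      sites$contig, IRanges::IRanges(start = sites$pos0 + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(sgr, fgr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov)
      fl <- features$label[S4Vectors::subjectHits(ov)]
      fr <- lab_rank[fl]
      best <- tapply(seq_along(qh), qh, function(ii) fl[ii][which.min(fr[ii])])
      assigned[as.integer(names(best))] <- unlist(best)
    }
  }
  tab <- table(factor(assigned,
                      levels = unique(c(names(sort(lab_rank)), "intergenic"))))
  prop <- as.numeric(tab) / nrow(sites)
  setNames(prop, names(tab))
}

#' Mean 5hmC signal around transcription start sites
#'
#' Offsets are strand-oriented (upstream of a TSS is negative regardless
#' of the TSS strand). The profile covers [-window, window) in bins of
#' `bin` bp; each (TSS, site) pair within the window contributes the
#' site's 5hmC fraction to its offset bin.
#'
#' @param calls an [HmcCallSet-class].
#' @param tss data.frame(contig, pos0, strand), one row per TSS.
#' @param window half-width of the profile in bp; multiple of `bin`.
#' @param bin offset bin width in bp.
#' @param high_conf_only restrict to high-confidence sites (default FALSE:
#'   the profile averages raw fractions of all assayed sites).
#' @return data.frame(offset_start, offset_mid, mean_fraction, n_sites).
#' @export
tssMetaprofile <- function(calls, tss, window = 2000L, bin = 100L,
                           high_conf_only = FALSE) {
  tss <- as.data.frame(tss, stringsAsFactors = FALSE)
  if (!nrow(tss)) stop("tss list must be non-empty")
  if (window %% bin != 0) stop("window must be a multiple of bin")
  df <- hmcCalls(calls)
  if (high_conf_only) df <- df[df$high_confidence, , drop = FALSE]
  nb <- 2L * as.integer(window / bin)
  acc_sum <- rep(0, nb); acc_n <- rep(0L, nb)
  if (nrow(df)) {
    sgr <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(start = df$pos0 + 1L, width = 1L))
    tgr <- GenomicRanges::GRanges(
      tss$contig,
      IRanges::IRanges(start = pmax(tss$pos0 + 1L - window, 1L),
                       end = tss$pos0 + window))
    ov <- GenomicRanges::findOverlaps(sgr, tgr)
    if (length(ov)) {
      si <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
      off <- df$pos0[si] - tss$pos0[ti]
      off[tss$strand[ti] == "-"] <- -off[tss$strand[ti] == "-"]
      keep <- off >= -window & off < window
      si <- si[keep]; off <- off[keep]
      bi <- (off + window) %/% bin + 1L
      acc_sum <- vapply(seq_len(nb), function(b)
        sum(df$fraction[si[bi == b]]), numeric(1))
      acc_n <- tabulate(bi, nbins = nb)
    }
  }
  data.frame(
    offset_start = seq.int(-window, window - bin, by = bin),
    offset_mid = seq.int(-window, window - bin, by = bin) + bin / 2,
    mean_fraction = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
    n_sites = acc_n)
}
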