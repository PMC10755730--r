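# Minimal converted-space aligner and strand-aware per-cytosine pileup.
# Deaminated reads are aligned in the three-letter (C collapsed onto T)
# alphabet: reads converted C->T are matched against the C->T-converted
# plus strand and against C->T(reverse complement) for the minus strand.
# Exact 20 bp seeds (Biostrings PDict) are extended by full-length
# comparison with a bounded mismatch count. This replaces a production
# bisulfite-style aligner at clean synthetic scale; externally produced
# per-site count tables can be imported with readSiteCounts().

#' Collapse a sequence alphabet for converted-space alignment
#'
#' @param sequence character vector, DNAString or DNAStringSet over
#'   A/C/G/T/N.
#' @param mode "C2T" replaces every C with T; "G2A" every G with A.
#' @return the converted sequence(s), same length, same container type.
#' @examples
#' convertForAlignment("ACGT", "C2T")  # "ATGT"
#' @export
convertForAlignment <- function(sequence, mode = c("C2T", "G2A")) {
  mode <- match.arg(mode)
  chr <- if (is.character(sequence)) sequence else as.character(sequence)
  if (any(grepl("[^ACGTN]", chr)))
    stop("invalid symbol: sequences must be over A/C/G/T/N")
  out <- if (mode == "C2T") chartr("C", "T", chr) else chartr("G", "A", chr)
  if (is(sequence, "DNAStringSet")) return(Biostrings::DNAStringSet(out))
  if (is(sequence, "DNAString")) return(Biostrings::DNAString(out))
  out
}

# mismatch counts between fixed-width reads (concatenated raw bytes) and
# reference windows, fully vectorized
.mismatchCounts <- function(read_bytes, read_idx, ref_bytes, starts, W) {
  if (!length(starts)) return(integer(0))
  roff <- as.vector(outer(seq_len(W), (read_idx - 1L) * W, "+"))
  soff <- as.vector(outer(seq_len(W) - 1L, starts, "+"))
  colSums(matrix(read_bytes[roff] != ref_bytes[soff], nrow = W))
}

#' Align converted reads against a reference
#'
#' Reads are converted C->T and matched by exact seed (first `seed_width`
#' bases) plus full-length extension allowing up to `max_mismatch`
#' mismatches, against both converted strand spaces of every contig. Reads
#' with equally good hits at more than one locus are flagged non-unique
#' (and are excluded by [pileup()]); reads with no acceptable hit are
#' flagged unmatched.
#'
#' @param reads a [ReadSet-class] or named DNAStringSet.
#' @param ref a [ReferenceSet-class].
#' @param max_mismatch maximum mismatches over the full read (converted
#'   space).
#' @param seed_width exact-match seed length (default 20 bp, truncated to
#'   the read length).
#' @return data.frame(read_id, contig, start0, strand, matched, unique,
#'   mismatches), one row per read, in input read order. start0 is the
#'   0-based plus-strand coordinate of the leftmost aligned base.
#' @export
alignReads <- function(reads, ref, max_mismatch = 2L, seed_width = 20L) {
  seqs <- if (is(reads, "ReadSet")) readSequences(reads) else reads
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  n_reads <- length(seqs)
  res <- data.frame(read_id = ids, contig = NA_character_,
                    start0 = NA_integer_, strand = NA_character_,
                    matched = FALSE, unique = FALSE,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  if (n_reads == 0L) return(res)

  chr <- as.character(seqs)
  conv <- chartr("C", "T", chr)
  widths <- nchar(conv)
  refseqs <- refSequences(ref)
  contigs <- names(refseqs)
  Lc <- setNames(Biostrings::width(refseqs), contigs)
  fwd_conv <- lapply(seq_along(refseqs), function(i)
    charToRaw(chartr("C", "T", as.character(refseqs[[i]]))))
  rev_conv <- lapply(seq_along(refseqs), function(i)
    charToRaw(chartr("C", "T", as.character(
      Biostrings::reverseComplement(refseqs[[i]])))))

  cand <- list()
  for (W in unique(widths)) {
    grp <- which(widths == W)
    sw <- min(as.integer(seed_width), W)
    seeds <- substr(conv[grp], 1L, sw)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    grp_bytes <- charToRaw(paste(conv[grp], collapse = ""))
    for (ci in seq_along(contigs)) {
      if (W > Lc[ci]) next
      for (space in 1:2) {
        subj <- if (space == 1L) fwd_conv[[ci]] else rev_conv[[ci]]
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(rawToChar(subj)))
        sl <- Biostrings::startIndex(m)
        lens <- lengths(sl)
        if (!sum(lens)) next
        ridx <- rep(seq_along(grp), lens)      # index within grp
        starts <- unlist(sl, use.names = FALSE)
        ok <- starts + W - 1L <= Lc[ci]
        ridx <- ridx[ok]; starts <- starts[ok]
        if (!length(starts)) next
        mm <- .mismatchCounts(grp_bytes, ridx, subj, starts, W)
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        ridx <- ridx[keep]; starts <- starts[keep]; mm <- mm[keep]
        start0 <- if (space == 1L) starts - 1L
                  else Lc[ci] - starts - W + 1L
        cand[[length(cand) + 1L]] <- data.table::data.table(
          read = grp[ridx], contig = contigs[ci],
          strand = if (space == 1L) "+" else "-",
          start0 = start0, mm = mm)
      }
    }
  }
  if (!length(cand)) return(res)
  cd <- data.table::rbindlist(cand)
  # de-duplicate identical loci reached twice (possible when seed hits
  # repeat within one subject are reported once each; keep unique loci)
  cd <- unique(cd, by = c("read", "contig", "strand", "start0"))
  mm <- NULL  # NSE note for R CMD check
  cd[, c("best", "nbest") := list(min(mm), sum(mm == min(mm))), by = "read"]
  top <- cd[cd$mm == cd$best]
  top <- top[!duplicated(top$read)]
  i <- top$read
  res$contig[i] <- top$contig
  res$start0[i] <- top$start0
  res$strand[i] <- top$strand
  res$matched[i] <- TRUE
  res$unique[i] <- top$nbest == 1L
  res$mismatches[i] <- top$mm
  res
}

#' Truth alignments from a simulated read set
#'
#' Converts a [ReadSet-class] truth sidecar into the alignment table
#' consumed by [pileup()] (every read matched and unique at its true
#' origin). Useful for error-free amplicon counting and for isolating the
#' counting stage from the aligner.
#'
#' @param reads a [ReadSet-class].
#' @return alignment data.frame as returned by [alignReads()].
#' @export
truthAlignments <- function(reads) {
  tr <- readTruth(reads)
  data.frame(read_id = tr$read_id, contig = tr$contig, start0 = tr$start0,
             strand = tr$strand, matched = TRUE, unique = TRUE,
             mismatches = 0L, stringsAsFactors = FALSE)
}

#' Wrap a single amplicon as a ReferenceSet
#'
#' @param sequence amplicon sequence.
#' @param name contig name (default "amplicon", matching the simulators).
#' @param class spike-in class label, or NA for a genomic contig.
#' @return A [ReferenceSet-class].
#' @export
ampliconReference <- function(sequence, name = "amplicon", class = NA) {
  sc <- if (is.na(class)) character(0) else setNames(as.character(class), name)
  new("ReferenceSet",
      sequences = Biostrings::DNAStringSet(setNames(.asSeqString(sequence),
                                                    name)),
      spikeClass = sc)
}

#' Per-cytosine strand-aware C/T pileup
#'
#' Consumes matched, unique alignments only. For each reference C on the
#' plus strand, reads aligned to the plus strand contribute: read base C
#' increments N_C, T increments N_T, anything else N_other. Minus-strand
#' rows (reference G) are symmetric, counted from minus-strand reads in
#' plus orientation (G increments N_C, A increments N_T). Reads from the
#' opposite strand carry no information about a site and never contribute.
#' Rows with N_C + N_T = 0 are omitted.
#'
#' @param alignments alignment data.frame from [alignReads()] or
#'   [truthAlignments()].
#' @param reads the [ReadSet-class] (or named DNAStringSet) the alignments
#'   refer to.
#' @param ref a [ReferenceSet-class].
#' @return A [SiteCountTable-class].
#' @export
pileup <- function(alignments, reads, ref) {
  seqs <- if (is(reads, "ReadSet")) readSequences(reads) else reads
  aln <- alignments[alignments$matched & alignments$unique, , drop = FALSE]
  refseqs <- refSequences(ref)
  out <- list()
  for (contig in unique(aln$contig)) {
    sstr <- as.character(refseqs[[contig]])
    L <- nchar(sstr)
    rawref <- charToRaw(sstr)
    s <- .explode(sstr)
    a <- aln[aln$contig == contig, , drop = FALSE]
    rd <- seqs[a$read_id]
    Wv <- Biostrings::width(rd)
    if (any(a$start0 + Wv > L) || any(a$start0 < 0L))
      stop("alignment out of contig bounds")

    for (strand in c("+", "-")) {
      sel <- which(a$strand == strand)
      if (!length(sel)) next
      site_raw <- if (strand == "+") .RAW_C else .RAW_G
      c_raw <- if (strand == "+") .RAW_C else .RAW_G
      t_raw <- if (strand == "+") .RAW_T else .RAW_A
      # plus-oriented read sequences
      rs <- rd[sel]
      if (strand == "-") rs <- Biostrings::reverseComplement(rs)
      for (W in unique(Wv[sel])) {
        g <- sel[Wv[sel] == W]
        rsg <- rs[Wv[sel] == W]
        bytes <- charToRaw(paste(as.character(rsg), collapse = ""))
        posv <- as.vector(outer(seq_len(W), a$start0[g], "+"))  # 1-based
        keep <- which(rawref[posv] == site_raw)
        if (!length(keep)) next
        pv <- posv[keep]
        bv <- bytes[as.vector(outer(seq_len(W),
                                    (seq_along(g) - 1L) * W, "+"))][keep]
        dt <- data.table::data.table(
          pos = pv,
          cls = ifelse(bv == c_raw, "C", ifelse(bv == t_raw, "T", "O")))
        pos <- cls <- NULL
        agg <- dt[, list(n = .N), by = list(pos, cls)]
        wide <- data.table::dcast(agg, pos ~ cls, value.var = "n", fill = 0L)
        for (col in c("C", "T", "O"))
          if (is.null(wide[[col]])) wide[[col]] <- 0L
        p1 <- wide$pos  # 1-based site position
        if (strand == "+") {
          c5 <- ifelse(p1 > 1L, s[pmax(p1 - 1L, 1L)], "N")
          c3 <- ifelse(p1 < L, s[pmin(p1 + 1L, L)], "N")
        } else {
          c5 <- ifelse(p1 < L, .compChar(s[pmin(p1 + 1L, L)]), "N")
          c3 <- ifelse(p1 > 1L, .compChar(s[pmax(p1 - 1L, 1L)]), "N")
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, pos0 = p1 - 1L, strand = strand,
          context5p = c5, context3p = c3,
          N_C = wide$C, N_T = wide$T, N_other = wide$O,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out)
        else data.frame(contig = character(0), pos0 = integer(0),
                        strand = character(0), context5p = character(0),
                        context3p = character(0), N_C = integer(0),
                        N_T = integer(0), N_other = integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(df)) {
    dtm <- data.table::as.data.table(df)
    contig <- pos0 <- strand <- context5p <- context3p <- NULL
    dtm <- dtm[, list(N_C = sum(N_C), N_T = sum(N_T), N_other = sum(N_other)),
               by = list(contig, pos0, strand, context5p, context3p)]
    df <- as.data.frame(dtm[order(contig, pos0, strand)])
    df <- df[, .COUNT_COLS]
    df <- df[df$N_C + df$N_T > 0L, , drop = FALSE]
    rownames(df) <- NULL
  }
  new("SiteCountTable", counts = df)
}
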