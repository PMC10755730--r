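# Synthetic-data generators: references with tunable CpG structure, planted
# modification maps, deamination-converted reads, colony/mixture read sets
# and Michaelis-Menten rate data. All generators are deterministic for a
# fixed seed (they call set.seed internally on a derived sub-seed).

# First-order base sampler in which the only non-iid transition is C -> G,
# scaled by `cpg` and renormalized. The run-length structure of the binary
# "previous base is C" chain is geometric, so the chain is simulated by
# alternating rgeom run lengths (fully vectorized) instead of a per-base
# loop.
.genSequence <- function(L, gc, cpg) {
  pC <- gc / 2; pG <- gc / 2; pA <- (1 - gc) / 2; pT <- (1 - gc) / 2
  z <- pA + pC + cpg * pG + pT           # normalizer of the prev-C row
  p11 <- pC / z                          # P(C | prev C)
  p01 <- pC                              # P(C | prev not C)

  # Alternating runs: a non-C run ends with prob p01 per step, a C run
  # continues with prob p11 per step.
  zvec <- logical(0)
  first <- runif(1) < pC
  need <- L
  while (length(zvec) < L) {
    npairs <- max(64L, ceiling(1.3 * need * 1 /
                                 (1 / p01 + 1 / max(1 - p11, 1e-12))))
    run0 <- 1L + rgeom(npairs, p01)
    run1 <- 1L + rgeom(npairs, 1 - p11)
    lens <- as.vector(rbind(run0, run1))
    vals <- rep(c(FALSE, TRUE), npairs)
    if (first) { lens <- c(1L + rgeom(1L, 1 - p11), lens)
                 vals <- c(TRUE, vals); first <- FALSE }
    zvec <- c(zvec, rep(vals, lens))
    need <- L - length(zvec)
  }
  zvec <- zvec[seq_len(L)]

  out <- rep(.RAW_C, L)
  non <- which(!zvec)
  if (length(non)) {
    prevC <- non > 1L & zvec[pmax(non - 1L, 1L)]
    u <- runif(length(non))
    # conditional distribution over A/G/T given previous state
    pick <- function(w) cumsum(w / sum(w))[1:2]
    thrN <- pick(c(pA, pG, pT))
    thrC <- pick(c(pA, cpg * pG, pT))
    bases <- c(.RAW_A, .RAW_G, .RAW_T)
    idx <- integer(length(non))
    idx[!prevC] <- findInterval(u[!prevC], thrN) + 1L
    idx[prevC]  <- findInterval(u[prevC],  thrC) + 1L
    out[non] <- bases[idx]
  }
  rawToChar(out)
}

#' Build a synthetic reference with spike-in contigs
#'
#' Generates random chromosome sequences with a target GC fraction and a
#' tunable CpG dinucleotide enrichment (values below 1 give the CpG
#' depletion typical of mammalian genomes), then appends user-supplied
#' spike-in contigs of known uniform modification class.
#'
#' @param seed integer seed; output is deterministic given the seed.
#' @param chrom_specs named integer vector of chromosome lengths, e.g.
#'   `c(chr1 = 1e6)`, or a data.frame with columns `name` and `length`.
#' @param gc_fraction target GC content in (0, 1).
#' @param cpg_enrichment multiplicative factor on the C->G transition
#'   (1 = independent bases; > 1 enriches CpG, < 1 depletes).
#' @param spike_ins data.frame with columns `name`, `sequence`, `class`
#'   (unmodified / all-5mC / all-5hmC), or NULL.
#' @return A [ReferenceSet-class].
#' @examples
#' ref <- buildReference(1L, c(chr1 = 5000))
#' @export
buildReference <- function(seed, chrom_specs, gc_fraction = 0.42,
                           cpg_enrichment = 1, spike_ins = NULL) {
  if (is.data.frame(chrom_specs))
    chrom_specs <- setNames(chrom_specs$length, chrom_specs$name)
  lens <- as.integer(chrom_specs)
  nms <- names(chrom_specs)
  if (is.null(nms) || any(nms == "")) stop("chromosomes must be named")
  if (any(lens <= 0L)) stop("chromosome lengths must be > 0")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (cpg_enrichment <= 0) stop("cpg_enrichment must be > 0")

  spike_names <- character(0); spike_seqs <- character(0)
  spike_class <- character(0)
  if (!is.null(spike_ins) && nrow(as.data.frame(spike_ins))) {
    spike_ins <- as.data.frame(spike_ins, stringsAsFactors = FALSE)
    spike_names <- as.character(spike_ins$name)
    spike_seqs <- toupper(as.character(spike_ins$sequence))
    spike_class <- setNames(as.character(spike_ins$class), spike_names)
  }
  all_names <- c(nms, spike_names)
  if (anyDuplicated(all_names))
    stop(sprintf("duplicate contig name: %s",
                 all_names[duplicated(all_names)][1L]))

  set.seed(.deriveSeed(seed, 101L))
  chrom_seqs <- vapply(lens, .genSequence, character(1),
                       gc = gc_fraction, cpg = cpg_enrichment)
  seqs <- Biostrings::DNAStringSet(setNames(c(chrom_seqs, spike_seqs),
                                            all_names))
  new("ReferenceSet", sequences = seqs, spikeClass = spike_class)
}

#' Generate the default spike-in set
#'
#' A lambda-like fully unmodified contig plus one all-5mC and one all-5hmC
#' amplicon (367 bp, the length of the colony-sequencing substrates). The
#' unmodified contig is shortened from true lambda scale (48.5 kb) to keep
#' desk-scale simulations fast; rates depend only on observation counts.
#'
#' @param seed integer seed.
#' @param unmod_length length of the unmodified lambda-like contig.
#' @param amplicon_length length of the two amplicon spike-ins.
#' @return data.frame(name, sequence, class) suitable for
#'   [buildReference()]'s `spike_ins` argument.
#' @export
syntheticSpikeIns <- function(seed, unmod_length = 5000L,
                              amplicon_length = 367L) {
  set.seed(.deriveSeed(seed, 211L))
  data.frame(
    name = c("spike_lambda", "spike_5mC", "spike_5hmC"),
    sequence = c(.genSequence(unmod_length, 0.5, 1),
                 .genSequence(amplicon_length, 0.5, 1),
                 .genSequence(amplicon_length, 0.5, 1)),
    class = c("unmodified", "all-5mC", "all-5hmC"),
    stringsAsFactors = FALSE)
}

#' Plant cytosine modifications on a reference
#'
#' Each CpG cytosine (on both strands; the C of a plus-strand CG and the G
#' it pairs with) is independently assigned 5mC with probability
#' `p_5mC_cpg`, 5hmC with probability `p_5hmC_cpg`, and left unmodified
#' otherwise. Non-CpG cytosines are assigned 5hmC with probability
#' `p_5hmC_noncpg` (genomic 5hmC occurs almost exclusively in CpG
#' context). Spike-in contigs are skipped: their state is their label.
#'
#' @param ref a [ReferenceSet-class].
#' @param p_5mC_cpg,p_5hmC_cpg,p_5hmC_noncpg probabilities in [0, 1];
#'   `p_5mC_cpg + p_5hmC_cpg` must not exceed 1.
#' @param seed integer seed.
#' @return A [ModificationMap-class].
#' @export
plantModifications <- function(ref, p_5mC_cpg = 0.70, p_5hmC_cpg = 0.05,
                               p_5hmC_noncpg = 1e-4, seed = 1L) {
  p <- c(p_5mC_cpg, p_5hmC_cpg, p_5hmC_noncpg)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (p_5mC_cpg + p_5hmC_cpg > 1)
    stop("p_5mC_cpg + p_5hmC_cpg must be <= 1")
  set.seed(.deriveSeed(seed, 307L))

  seqs <- refSequences(ref)
  cls <- contigClass(ref, names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (cls[i] != "genomic") next
    s <- .explode(as.character(seqs[[i]]))
    L <- length(s)
    plusC <- which(s == "C")
    minusC <- which(s == "G")
    cpgP <- plusC[plusC < L & s[pmin(plusC + 1L, L)] == "G"]
    cpgM <- minusC[minusC > 1L & s[pmax(minusC - 1L, 1L)] == "C"]
    nonP <- setdiff(plusC, cpgP)
    nonM <- setdiff(minusC, cpgM)

    cpg_pos <- c(cpgP, cpgM)
    cpg_str <- rep(c("+", "-"), c(length(cpgP), length(cpgM)))
    u <- runif(length(cpg_pos))
    st <- rep(NA_character_, length(cpg_pos))
    st[u < p_5mC_cpg] <- "5mC"
    st[u >= p_5mC_cpg & u < p_5mC_cpg + p_5hmC_cpg] <- "5hmC"

    non_pos <- c(nonP, nonM)
    non_str <- rep(c("+", "-"), c(length(nonP), length(nonM)))
    keep_non <- runif(length(non_pos)) < p_5hmC_noncpg

    pos <- c(cpg_pos[!is.na(st)], non_pos[keep_non])
    strd <- c(cpg_str[!is.na(st)], non_str[keep_non])
    state <- c(st[!is.na(st)], rep("5hmC", sum(keep_non)))
    if (!length(pos)) next
    out[[i]] <- GenomicRanges::GRanges(
      seqnames = names(seqs)[i],
      ranges = IRanges::IRanges(start = pos, width = 1L),
      strand = strd, state = state)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  gr <- if (length(out)) suppressWarnings(do.call(c, out))
        else GenomicRanges::GRanges(state = character(0))
  GenomeInfoDb::seqlevels(gr) <- names(seqs)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(seqs)
  new("ModificationMap", sites = gr[order(gr)])
}

# Per-contig, per-strand deamination probability vectors in plus-strand
# coordinates. stateP/stateM: 0 = not a cytosine on that strand, else row
# index into the model matrix. Contig-edge cytosines with no 5' neighbor
# use the row mean across contexts.
.strandProbs <- function(s, cls, mod_gr, contig, model) {
  L <- length(s)
  prob <- model@prob
  rowmean <- rowMeans(prob)

  stateP <- integer(L); stateM <- integer(L)
  isC <- s == "C"; isG <- s == "G"
  base_state <- switch(cls, "genomic" = 1L, "unmodified" = 1L,
                       "all-5mC" = 2L, "all-5hmC" = 3L)
  stateP[isC] <- base_state
  stateM[isG] <- base_state
  if (cls == "genomic" && length(mod_gr)) {
    sel <- as.character(GenomicRanges::seqnames(mod_gr)) == contig
    if (any(sel)) {
      g <- mod_gr[sel]
      st <- match(S4Vectors::mcols(g)$state, .MOD_STATES)
      pos <- GenomicRanges::start(g)
      plus <- as.character(GenomicRanges::strand(g)) == "+"
      stateP[pos[plus]] <- st[plus]
      stateM[pos[!plus]] <- st[!plus]
    }
  }

  ctxP <- c(NA_character_, s[-L])                  # 5' neighbor on plus
  ctxM <- c(.compChar(s[-1L]), NA_character_)      # 5' neighbor on minus

  lookup <- function(state, ctx) {
    p <- numeric(length(state))
    hot <- which(state > 0L)
    if (!length(hot)) return(p)
    ci <- match(ctx[hot], .CONTEXTS)
    p[hot] <- ifelse(is.na(ci), rowmean[state[hot]],
                     prob[cbind(state[hot], ci)])
    p
  }
  list(probP = lookup(stateP, ctxP), probM = lookup(stateM, ctxM),
       stateP = stateP, stateM = stateM)
}

#' Simulate deamination-converted sequencing reads
#'
#' Draws fixed-length single-end reads per strand with Poisson coverage
#' (the number of reads per contig and strand is Poisson with mean
#' `mean_depth * contig_length / read_len`, starts uniform), then applies
#' the deamination model once per molecule: each cytosine on the read's
#' strand is emitted as T with probability `p(state, 5' neighbor)` and as C
#' otherwise; all other bases are copied verbatim. Spike-in contigs take
#' their uniform state from their label; genomic contigs take per-site
#' states from `mods`. Quality strings are constant Phred 40.
#'
#' @param ref a [ReferenceSet-class].
#' @param mods a [ModificationMap-class] (ignored for spike-in contigs).
#' @param model a [DeaminationModel-class].
#' @param mean_depth mean per-strand coverage (>= 0).
#' @param read_len read length; must not exceed the shortest contig.
#' @param seed integer seed; FASTQ output is byte-identical given the seed.
#' @param error_rate optional uniform substitution rate applied after
#'   deamination (default 0, isolating the method's statistics).
#' @return A [ReadSet-class] whose truth sidecar records each read's
#'   origin (contig, 0-based start, strand).
#' @export
simulateReads <- function(ref, mods, model, mean_depth = 10, read_len = 100L,
                          seed = 1L, error_rate = 0) {
  read_len <- as.integer(read_len)
  if (read_len <= 0L) stop("read_len must be > 0")
  seqs <- refSequences(ref)
  if (read_len > min(Biostrings::width(seqs)))
    stop("read_len exceeds the shortest contig")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  set.seed(.deriveSeed(seed, 401L))
  if (mean_depth == 0) return(.emptyReadSet())

  mod_gr <- if (is(mods, "ModificationMap")) modSites(mods)
            else GenomicRanges::GRanges(state = character(0))
  cls <- contigClass(ref, names(seqs))

  seq_out <- list(); id_out <- list(); truth_out <- list()
  serial <- 0L
  for (i in seq_along(seqs)) {
    contig <- names(seqs)[i]
    sstr <- as.character(seqs[[i]])
    s <- .explode(sstr)
    L <- length(s)
    sp <- .strandProbs(s, cls[i], mod_gr, contig, model)
    rawref <- charToRaw(sstr)

    for (strand in c("+", "-")) {
      n <- rpois(1L, mean_depth * L / read_len)
      if (n == 0L) next
      starts0 <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
      posv <- as.vector(outer(seq_len(read_len), starts0, "+"))  # 1-based
      bytes <- rawref[posv]
      pr <- if (strand == "+") sp$probP[posv] else sp$probM[posv]
      hot <- which(pr > 0)
      if (length(hot)) {
        conv <- hot[runif(length(hot)) < pr[hot]]
        # plus-strand C reads as T; minus-strand deamination shows as A in
        # plus-space (the read itself is reverse-complemented below)
        bytes[conv] <- if (strand == "+") .RAW_T else .RAW_A
      }
      if (error_rate > 0) {
        err <- which(runif(length(bytes)) < error_rate)
        if (length(err)) {
          alt <- c(.RAW_A, .RAW_C, .RAW_G, .RAW_T)
          repl <- alt[sample.int(4L, length(err), replace = TRUE)]
          same <- repl == bytes[err]
          while (any(same)) {
            repl[same] <- alt[sample.int(4L, sum(same), replace = TRUE)]
            same <- repl == bytes[err]
          }
          bytes[err] <- repl
        }
      }
      reads <- .packStrings(bytes, read_len, n)
      if (strand == "-")
        reads <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads)))
      ids <- sprintf("r%08d:%s:%d:%s", serial + seq_len(n), contig,
                     starts0, strand)
      serial <- serial + n
      seq_out[[length(seq_out) + 1L]] <- reads
      id_out[[length(id_out) + 1L]] <- ids
      truth_out[[length(truth_out) + 1L]] <- data.frame(
        read_id = ids, contig = contig, start0 = starts0, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(seq_out)) return(.emptyReadSet())
  allseq <- unlist(seq_out, use.names = FALSE)
  ids <- unlist(id_out, use.names = FALSE)
  truth <- do.call(rbind, truth_out)
  new("ReadSet",
      sequences = Biostrings::DNAStringSet(setNames(allseq, ids)),
      qualities = Biostrings::BStringSet(rep(strrep("I", read_len),
                                             length(allseq))),
      truth = truth)
}

# Shared engine for colony and mixture simulations: full-length plus-strand
# molecules, one deamination pass per molecule, per-molecule state.
.deaminateMolecules <- function(substrate, states, model, contig) {
  sstr <- .asSeqString(substrate)
  s <- .explode(sstr)
  L <- length(s)
  if (L == 0L) stop("substrate must be non-empty")
  n <- length(states)
  cpos <- which(s == "C")
  ctx <- c(NA_character_, s[-L])[cpos]
  ci <- match(ctx, .CONTEXTS)
  rowmean <- rowMeans(model@prob)

  M <- matrix(rep(charToRaw(sstr), n), nrow = L, ncol = n)
  if (length(cpos)) {
    srow <- match(states, c("unmodified", "all-5mC", "all-5hmC"))
    p_by_state <- lapply(1:3, function(r)
      ifelse(is.na(ci), rowmean[r], model@prob[r, ][ci]))
    pvec <- unlist(p_by_state[srow], use.names = FALSE)  # colony-major
    lin <- rep(cpos, times = n) + (rep(seq_len(n), each = length(cpos)) - 1L) * L
    sel <- runif(length(lin)) < pvec
    M[lin[sel]] <- .RAW_T
  }
  reads <- .packStrings(as.vector(M), L, n)
  ids <- sprintf("mol%06d", seq_len(n))
  new("ReadSet",
      sequences = Biostrings::DNAStringSet(setNames(reads, ids)),
      qualities = Biostrings::BStringSet(rep(strrep("I", L), n)),
      truth = data.frame(read_id = ids, contig = contig, start0 = 0L,
                         strand = "+", state = states,
                         stringsAsFactors = FALSE))
}

#' Simulate colony sequencing of a uniformly modified substrate
#'
#' Each colony is one full-length single-stranded molecule deaminated
#' independently at every cytosine according to the model cell for the
#' substrate's uniform state.
#'
#' @param substrate DNA sequence (character or DNAString).
#' @param state "unmodified", "all-5mC" or "all-5hmC".
#' @param model a [DeaminationModel-class].
#' @param n_colonies number of colonies (>= 1).
#' @param seed integer seed.
#' @return A [ReadSet-class]; truth records the molecule state.
#' @export
simulateColonies <- function(substrate, state, model, n_colonies = 50L,
                             seed = 1L) {
  state <- match.arg(state, .SPIKE_CLASSES)
  n_colonies <- as.integer(n_colonies)
  if (n_colonies < 1L) stop("n_colonies must be >= 1")
  set.seed(.deriveSeed(seed, 503L))
  .deaminateMolecules(substrate, rep(state, n_colonies), model, "amplicon")
}

#' Simulate a C / 5hmC mixture read set
#'
#' Each molecule is all-5hmC with probability `frac_5hmC` and unmodified
#' otherwise, then deaminated. Mirrors the mixing experiment in which two
#' amplicons were combined at theoretical 5hmC fractions from 0 to 100%.
#'
#' @param frac_5hmC theoretical 5hmC molecule fraction in [0, 1].
#' @param n_molecules number of molecules (>= 1).
#' @param substrate DNA sequence shared by both species.
#' @param model a [DeaminationModel-class].
#' @param seed integer seed.
#' @return A [ReadSet-class]; truth records each molecule's state.
#' @export
simulateMixture <- function(frac_5hmC, n_molecules, substrate, model,
                            seed = 1L) {
  if (frac_5hmC < 0 || frac_5hmC > 1) stop("frac_5hmC must be in [0, 1]")
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  set.seed(.deriveSeed(seed, 607L))
  states <- ifelse(runif(n_molecules) < frac_5hmC, "all-5hmC", "unmodified")
  .deaminateMolecules(substrate, states, model, "amplicon")
}

#' Simulate steady-state deamination-rate data
#'
#' Generates the observed deaminated fraction at each substrate
#' concentration under the Michaelis-Menten rate law. The observable is
#' the product-ion fraction I_D/(I_U + I_D), which equals rate * [E] * t;
#' rate = k_cat [S] / (K_M + [S]). Gaussian noise (sd `noise_sd`) is added
#' to the fraction, then clamped to [0, 1].
#'
#' @param k_cat turnover number (min^-1).
#' @param K_M Michaelis constant (uM).
#' @param E enzyme concentration (uM).
#' @param t reaction time (min).
#' @param S_list substrate concentrations (uM), all > 0.
#' @param noise_sd Gaussian noise on the fraction (>= 0).
#' @param seed integer seed.
#' @param replicates independent measurements per concentration.
#' @return data.frame(S_uM, E_uM, t_min, frac_deaminated).
#' @export
simulateKinetics <- function(k_cat, K_M, E, t, S_list, noise_sd = 0,
                             seed = 1L, replicates = 1L) {
  if (k_cat <= 0 || K_M <= 0 || E <= 0 || t <= 0)
    stop("k_cat, K_M, E and t must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(S_list <= 0)) stop("all substrate concentrations must be > 0")
  set.seed(.deriveSeed(seed, 701L))
  S <- rep(as.numeric(S_list), each = as.integer(replicates))
  rate <- k_cat * S / (K_M + S)
  frac <- .clamp01(rate * E * t + rnorm(length(S), 0, noise_sd))
  data.frame(S_uM = S, E_uM = E, t_min = t, frac_deaminated = frac)
}

#' Generate the default synthetic 5hmC genome
#'
#' Convenience wrapper bundling the stated defaults: a CpG-depleted
#' chromosome (GC 0.42, CpG enrichment 0.25), the three-spike-in set, and
#' a modification map with 5hmC almost exclusively at CpG sites.
#'
#' @param seed integer seed.
#' @param genome_length chromosome length in bp.
#' @param p_5mC_cpg,p_5hmC_cpg,p_5hmC_noncpg passed to
#'   [plantModifications()].
#' @param spike_ins include the default spike-in contigs.
#' @return list(reference = ReferenceSet, modifications = ModificationMap).
#' @export
syntheticHmcGenome <- function(seed, genome_length = 1e6,
                               p_5mC_cpg = 0.70, p_5hmC_cpg = 0.05,
                               p_5hmC_noncpg = 1e-4, spike_ins = TRUE) {
  sp <- if (spike_ins) syntheticSpikeIns(seed) else NULL
  ref <- buildReference(seed, c(chr1 = as.integer(genome_length)),
                        gc_fraction = 0.42, cpg_enrichment = 0.25,
                        spike_ins = sp)
  mods <- plantModifications(ref, p_5mC_cpg, p_5hmC_cpg, p_5hmC_noncpg,
                             seed = seed)
  list(reference = ref, modifications = mods)
}
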