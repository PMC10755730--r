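# Internal helpers shared across modules. Hot paths work on raw byte
# vectors (one byte per base) rather than character matrices.

.RAW_A <- as.raw(0x41)
.RAW_C <- as.raw(0x43)
.RAW_G <- as.raw(0x47)
.RAW_T <- as.raw(0x54)

# Derive a 32-bit sub-seed so that independent stages of one run do not
# reuse the same RNG stream. Kept strictly below 2^31 - 1.
.deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 2147483629) * 48271 %% 2147483629 +
               salt) %% 2147483629L
}

.explode <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.compChar <- function(x) chartr("ACGTN", "TGCAN", x)

.clamp01 <- function(x) pmin(1, pmax(0, x))

# Coerce DNAString / DNAStringSet element / character to a single string.
.asSeqString <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single DNA sequence")
  x
}

# Pack a raw vector holding n concatenated fixed-width sequences into a
# character vector of n strings.
.packStrings <- function(bytes, width, n) {
  if (n == 0L) return(character(0))
  big <- rawToChar(bytes)
  substring(big, seq.int(1L, by = width, length.out = n),
            seq.int(width, by = width, length.out = n))
}

.emptyReadSet <- function(extra_truth = NULL) {
  truth <- data.frame(read_id = character(0), contig = character(0),
                      start0 = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(extra_truth)) truth <- cbind(truth, extra_truth)
  new("ReadSet",
      sequences = Biostrings::DNAStringSet(setNames(character(0), character(0))),
      qualities = Biostrings::BStringSet(character(0)),
      truth = truth)
}
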