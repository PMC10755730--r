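# Shared fixtures: all tiny inputs are built in code.

# deamination model with a single probability applied to every state cell
flatModel <- function(p) {
  deaminationModel("flat", prob = matrix(p, nrow = 3, ncol = 4,
                                         dimnames = list(c("C", "5mC", "5hmC"),
                                                         c("A", "C", "G", "T"))))
}

# model with distinct per-state probabilities, context-uniform
stateModel <- function(pC, p5mC, p5hmC) {
  deaminationModel("custom", prob = matrix(rep(c(pC, p5mC, p5hmC), 4),
                                           nrow = 3,
                                           dimnames = list(c("C", "5mC", "5hmC"),
                                                           c("A", "C", "G", "T"))))
}

# independent enumeration oracle for the upper-tail binomial p-value
enumPValue <- function(N_C, N_T, eps) {
  n <- N_C + N_T
  if (N_C == 0) return(1)
  sum(vapply(N_C:n, function(k) choose(n, k) * eps^k * (1 - eps)^(n - k),
             numeric(1)))
}

# hand-applied Benjamini-Hochberg step-up (independent of p.adjust)
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# small fully specified reference: one genomic contig
tinyRef <- function(seq, name = "chrT") referenceSet(setNames(seq, name))

countCpG <- function(ref) {
  sum(Biostrings::vcountPattern("CG", refSequences(ref)))
}
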