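test_that("buildReference is deterministic, validates names, and boosts CpG", {
  r1 <- buildReference(1L, c(chr1 = 10000))
  r2 <- buildReference(1L, c(chr1 = 10000))
  expect_identical(as.character(refSequences(r1)),
                   as.character(refSequences(r2)))
  r3 <- buildReference(2L, c(chr1 = 10000))
  expect_false(identical(as.character(refSequences(r1)),
                         as.character(refSequences(r3))))

  sp <- data.frame(name = c("lambda", "lambda"),
                   sequence = c("ACGT", "ACGT"),
                   class = c("unmodified", "unmodified"))
  expect_error(buildReference(1L, c(chr1 = 100), spike_ins = sp),
               "duplicate contig name")
  expect_error(buildReference(1L, c(chr1 = -5)), "lengths")
  expect_error(buildReference(1L, c(chr1 = 100), gc_fraction = 1.2),
               "gc_fraction")

  # CpG dinucleotide count strictly higher under enrichment, same seed
  plain <- buildReference(11L, c(chr1 = 50000), gc_fraction = 0.5,
                          cpg_enrichment = 1)
  rich <- buildReference(11L, c(chr1 = 50000), gc_fraction = 0.5,
                         cpg_enrichment = 4)
  expect_gt(countCpG(rich), countCpG(plain))
  # and depletion goes the other way
  poor <- buildReference(11L, c(chr1 = 50000), gc_fraction = 0.5,
                         cpg_enrichment = 0.25)
  expect_lt(countCpG(poor), countCpG(plain))
})

test_that("plantModifications respects probabilities and CpG structure", {
  ref <- buildReference(5L, c(chr1 = 20000), gc_fraction = 0.5)
  empty <- plantModifications(ref, 0, 0, 0, seed = 1)
  expect_equal(length(modSites(empty)), 0L)

  all5hmc <- plantModifications(ref, 0, 1, 0, seed = 1)
  gr <- modSites(all5hmc)
  expect_true(all(S4Vectors::mcols(gr)$state == "5hmC"))
  # every CpG cytosine on both strands is planted
  n_cpg_cyt <- 2L * countCpG(ref)
  expect_equal(length(gr), n_cpg_cyt)
  # each planted plus site is a C followed by G; minus site the paired G
  s <- strsplit(as.character(refSequences(ref)[["chr1"]]), "")[[1]]
  pos <- GenomicRanges::start(gr)
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  expect_true(all(s[pos[plus]] == "C" & s[pos[plus] + 1L] == "G"))
  expect_true(all(s[pos[!plus]] == "G" & s[pos[!plus] - 1L] == "C"))

  expect_error(plantModifications(ref, 1.5, 0, 0, seed = 1), "\\[0, 1\\]")
  expect_error(plantModifications(ref, 0.7, 0.5, 0, seed = 1), "<= 1")

  # binomial count check at p = 0.1 over ~10^4 CpG cytosines
  big <- buildReference(6L, c(chr1 = 120000), gc_fraction = 0.5)
  n <- 2L * countCpG(big)
  expect_gt(n, 10000)
  planted <- plantModifications(big, 0, 0.1, 0, seed = 2)
  k <- length(modSites(planted))
  expect_lt(abs(k - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
})

test_that("spike-in contigs are skipped by plantModifications", {
  ref <- buildReference(7L, c(chr1 = 2000), spike_ins = syntheticSpikeIns(7L))
  mods <- plantModifications(ref, 0, 1, 1, seed = 1)
  expect_true(all(as.character(GenomicRanges::seqnames(modSites(mods))) ==
                    "chr1"))
})

test_that("simulateReads honors depth, determinism and planted truth", {
  ref <- tinyRef(strrep("ACGTAC", 50))  # 300 bp
  mods <- modificationMap(data.frame(contig = character(0),
                                     pos0 = integer(0),
                                     strand = character(0),
                                     state = character(0)))
  m1 <- flatModel(1)

  expect_equal(length(simulateReads(ref, mods, m1, mean_depth = 0,
                                    read_len = 50, seed = 1)), 0L)
  expect_error(simulateReads(ref, mods, m1, read_len = 0, seed = 1), "> 0")
  expect_error(simulateReads(ref, mods, m1, read_len = 400, seed = 1),
               "shortest contig")

  a <- simulateReads(ref, mods, m1, mean_depth = 5, read_len = 50, seed = 9)
  b <- simulateReads(ref, mods, m1, mean_depth = 5, read_len = 50, seed = 9)
  expect_identical(as.character(readSequences(a)),
                   as.character(readSequences(b)))
  expect_true(all(Biostrings::width(readSequences(a)) == 50L))

  # all probabilities 1 and no 5hmC: no C at original-C read positions
  tr <- readTruth(a)
  s <- strsplit(as.character(refSequences(ref)[[1]]), "")[[1]]
  for (i in which(tr$strand == "+")) {
    rd <- strsplit(as.character(readSequences(a)[[i]]), "")[[1]]
    refwin <- s[tr$start0[i] + seq_len(50)]
    expect_true(all(rd[refwin == "C"] == "T"))
  }
  # minus-strand molecules: reference G positions read as A on the molecule
  for (i in which(tr$strand == "-")[1:5]) {
    rd <- strsplit(as.character(readSequences(a)[[i]]), "")[[1]]
    refwin <- s[tr$start0[i] + seq_len(50)]
    plus_space <- rev(chartr("ACGT", "TGCA", rd))
    expect_true(all(plus_space[refwin == "G"] == "A"))
  }

  # a planted 5hmC site with p(5hmC) = 0 shows C in every covering read
  m0 <- stateModel(1, 1, 0)
  cpos0 <- which(s == "C")[3] - 1L
  mods2 <- modificationMap(data.frame(contig = "chrT", pos0 = cpos0,
                                      strand = "+", state = "5hmC"), ref)
  rs <- simulateReads(ref, mods2, m0, mean_depth = 20, read_len = 50,
                      seed = 4)
  tr2 <- readTruth(rs)
  cover <- which(tr2$strand == "+" & tr2$start0 <= cpos0 &
                   tr2$start0 + 50L > cpos0)
  expect_gt(length(cover), 0)
  for (i in cover) {
    rd <- strsplit(as.character(readSequences(rs)[[i]]), "")[[1]]
    expect_identical(rd[cpos0 - tr2$start0[i] + 1L], "C")
  }
})

test_that("simulateColonies matches its molecule-level model", {
  sub <- paste(strsplit(as.character(
    refSequences(buildReference(3L, c(a = 367), gc_fraction = 0.5))[[1]]),
    "")[[1]], collapse = "")
  expect_error(simulateColonies("", "unmodified", flatModel(0), 5, 1),
               "non-empty")
  expect_error(simulateColonies(sub, "unmodified", flatModel(0), 0, 1),
               ">= 1")

  noop <- simulateColonies(sub, "all-5hmC", stateModel(1, 1, 0), 10, seed = 2)
  expect_true(all(as.character(readSequences(noop)) == sub))

  full <- simulateColonies(sub, "unmodified", flatModel(1), 10, seed = 2)
  expect_false(any(grepl("C", as.character(readSequences(full)))))

  # total T readouts across colonies ~ Binomial(n_obs, 0.0016)
  m <- deaminationModel("eA3A-v10")
  col <- simulateColonies(sub, "all-5hmC", m, 50, seed = 8)
  nC_sub <- sum(strsplit(sub, "")[[1]] == "C")
  expect_gte(nC_sub * 50, 4000)
  readsm <- do.call(rbind, strsplit(as.character(readSequences(col)), ""))
  cidx <- which(strsplit(sub, "")[[1]] == "C")
  nT <- sum(readsm[, cidx] == "T")
  n_obs <- 50 * nC_sub
  expect_gte(nT, qbinom(1e-6, n_obs, 0.0016))
  expect_lte(nT, qbinom(1 - 1e-6, n_obs, 0.0016))
})

test_that("simulateMixture reproduces the mixture expectation", {
  sub <- as.character(refSequences(
    buildReference(4L, c(a = 200), gc_fraction = 0.5))[[1]])
  m <- deaminationModel("eA3A-v10")
  expect_error(simulateMixture(1.5, 10, sub, m, 1), "\\[0, 1\\]")
  expect_error(simulateMixture(0.5, 0, sub, m, 1), ">= 1")

  frac_C <- function(rs) {
    f <- ampliconSiteFractions(rs, sub)
    sum(f$N_C) / sum(f$N_C + f$N_T)
  }
  lo <- simulateMixture(0, 2000, sub, m, seed = 3)
  expect_lt(abs(frac_C(lo) - 0.0008), 4 * sqrt(0.0008 * 0.9992 / 2000) + 1e-3)
  hi <- simulateMixture(1, 2000, sub, m, seed = 3)
  expect_lt(abs(frac_C(hi) - 0.9984), 4 * sqrt(0.9984 * 0.0016 / 2000) + 1e-3)

  half <- simulateMixture(0.5, 10000, sub, m, seed = 5)
  expected <- 0.5 * 0.9984 + 0.5 * 0.0008
  # molecule-state sampling dominates the SE at the pooled level
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac_C(half) - expected), 4 * se)
})

test_that("simulateKinetics follows the rate law and round-trips", {
  expect_error(simulateKinetics(2, 0.5, 0.04, 5, c(-1, 1)), "> 0")
  # half-saturation: rate = k_cat / 2
  pts <- simulateKinetics(2, 0.5, 0.1, 5, S_list = 0.5, noise_sd = 0)
  expect_equal(pts$frac_deaminated, (2 / 2) * 0.1 * 5, tolerance = 1e-12)
  # saturation limit approaches k_cat * E * t
  sat <- simulateKinetics(2, 0.5, 0.1, 5, S_list = 5e4, noise_sd = 0)
  expect_equal(sat$frac_deaminated, 2 * 0.1 * 5, tolerance = 1e-4)

  # noise-free generate-then-fit recovers parameters to machine precision
  pts <- simulateKinetics(2, 0.5, 0.04, 5, S_list = substrateSeries("C"),
                          noise_sd = 0)
  fit <- fitMichaelisMenten(pts)
  expect_equal(kcat(fit), 2, tolerance = 1e-9)
  expect_equal(Km(fit), 0.5, tolerance = 1e-9)
})

test_that("FASTQ output is byte-identical for a fixed seed", {
  g <- syntheticHmcGenome(21L, genome_length = 5000)
  m <- deaminationModel("eA3A-v10")
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeReadsFastq(simulateReads(g$reference, g$modifications, m,
                                mean_depth = 2, read_len = 80, seed = 13), f1)
  writeReadsFastq(simulateReads(g$reference, g$modifications, m,
                                mean_depth = 2, read_len = 80, seed = 13), f2)
  expect_identical(readLines(f1), readLines(f2))
  fq <- readLines(f1)
  expect_equal(length(fq) %% 4, 0)
  expect_true(all(nchar(fq[seq(2, length(fq), by = 4)]) == 80L))
  unlink(c(f1, f2))
})
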