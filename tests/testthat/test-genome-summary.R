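# build a small HmcCallSet directly from site positions and fractions
mkCalls <- function(pos0, fraction, contig = "c", strand = "+",
                    high_conf = TRUE) {
  n <- length(pos0)
  depth <- 10L
  fraction <- as.numeric(fraction)
  high_conf <- rep(as.logical(high_conf), length.out = n)
  calls <- data.frame(
    contig = rep(contig, length.out = n), pos0 = as.integer(pos0),
    strand = rep(strand, length.out = n),
    context5p = rep("A", n), context3p = rep("G", n),
    N_C = as.integer(round(fraction * depth)),
    N_T = as.integer(depth - round(fraction * depth)),
    fraction = fraction, p_value = ifelse(high_conf, 1e-6, 0.5),
    q_value = ifelse(high_conf, 1e-6, 0.5),
    high_confidence = rep(high_conf, length.out = n),
    stringsAsFactors = FALSE)
  new("HmcCallSet", calls = calls, epsilon = 0.001, minDepth = 5L,
      qCutoff = 0.01, method = "BH")
}

test_that("binSignal averages fractions within tiled bins", {
  calls <- mkCalls(c(100, 200), c(0.2, 0.4))
  b <- binSignal(calls, bin_width = 10000, seqlengths = c(c = 10000))
  expect_equal(nrow(b), 1L)
  expect_equal(b$mean_fraction, 0.3)
  expect_equal(b$n_sites, 2L)

  # no sites: every bin empty
  empty <- mkCalls(integer(0), numeric(0))
  b0 <- binSignal(empty, bin_width = 1000, seqlengths = c(c = 5000))
  expect_equal(nrow(b0), 5L)
  expect_true(all(b0$n_sites == 0))
  expect_true(all(is.na(b0$mean_fraction)))

  # translating all sites by one bin width shifts bins, identical means
  calls1 <- mkCalls(c(100, 250, 900), c(0.1, 0.5, 0.9))
  calls2 <- mkCalls(c(100, 250, 900) + 1000, c(0.1, 0.5, 0.9))
  b1 <- binSignal(calls1, bin_width = 1000, seqlengths = c(c = 4000))
  b2 <- binSignal(calls2, bin_width = 1000, seqlengths = c(c = 4000))
  expect_equal(b2$mean_fraction[-1], b1$mean_fraction[-nrow(b1)])

  # non-high-confidence sites are zeroed, not dropped
  mix <- mkCalls(c(10, 20), c(0.8, 0.6), high_conf = c(TRUE, FALSE))
  bm <- binSignal(mix, bin_width = 1000, seqlengths = c(c = 1000))
  expect_equal(bm$mean_fraction, 0.4)
  expect_equal(bm$n_sites, 2L)
  braw <- binSignal(mix, bin_width = 1000, high_conf_only = FALSE,
                    seqlengths = c(c = 1000))
  expect_equal(braw$mean_fraction, 0.7)
})

test_that("correlateBins matches bins and validates input", {
  calls <- mkCalls(seq(0, 9000, by = 1000), runif(10, 0.2, 0.8))
  a <- binSignal(calls, bin_width = 1000, seqlengths = c(c = 10000))
  expect_equal(correlateBins(a, a), 1)
  b <- a
  b$mean_fraction <- -a$mean_fraction + 1
  expect_equal(correlateBins(a, b), -1)
  # symmetry and positive-affine invariance
  b2 <- a
  b2$mean_fraction <- 2 * a$mean_fraction + 0.1
  expect_equal(correlateBins(a, b2), correlateBins(b2, a))
  expect_equal(correlateBins(a, b2), 1)

  flat <- a
  flat$mean_fraction <- 0.5
  expect_error(correlateBins(a, flat), "variance")
  expect_error(correlateBins(a[1:2, ], a[1:2, ]), "3 shared")
})

test_that("classifyContext reads context on the site strand", {
  ref <- tinyRef("TACGTCAGGCATC", name = "c")
  #               1234567890123  (1-based)
  # plus C at pos0 2 followed by G -> CpG
  expect_identical(classifyContext(ref, "c", 2, "+"), "CpG")
  # plus C at pos0 5: C A G -> CHG
  expect_identical(classifyContext(ref, "c", 5, "+"), "CHG")
  # plus C at pos0 9: C A T -> CHH
  expect_identical(classifyContext(ref, "c", 9, "+"), "CHH")
  # minus-strand site at the G of the same CG (pos0 3) -> CpG on minus
  expect_identical(classifyContext(ref, "c", 3, "-"), "CpG")
  # minus G at pos0 8: minus-strand 5'->3' reads C,C,T -> CHH? no: check
  # plus "GGC" at 1-based 8-10 -> minus strand G at pos0 8 has 3'
  # neighbors comp(s[8]) = C... minus read: C (site), then comp(s[8])="C",
  # comp(s[7])="T" -> CCT -> second base not G, third not G -> CHH
  expect_identical(classifyContext(ref, "c", 8, "-"), "CHH")
  # contig edge: plus C at the last base has no 3' neighbor -> NA
  expect_true(is.na(classifyContext(ref, "c", 12, "+")))
  expect_error(classifyContext(ref, "c", 0, "+"), "not a cytosine")
})

test_that("featureDistribution assigns by priority and sums to one", {
  calls <- mkCalls(c(10, 110, 210, 500), rep(1, 4))
  feats <- data.frame(contig = "c",
                      start = c(0, 100, 100),
                      end = c(50, 300, 250),
                      label = c("promoter", "intron", "exon"))
  p <- featureDistribution(calls, feats)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p["promoter"]), 0.25)
  # sites at 110 and 210 overlap both intron and exon; exon wins priority
  expect_equal(unname(p["exon"]), 0.5)
  expect_equal(unname(p["intergenic"]), 0.25)

  # boundary start position is inside (half-open)
  pb <- featureDistribution(mkCalls(100, 1), feats)
  expect_equal(unname(pb["exon"]), 1)

  # no features: everything intergenic
  p0 <- featureDistribution(calls, feats[0, ])
  expect_equal(unname(p0["intergenic"]), 1)

  expect_error(featureDistribution(calls,
                                   data.frame(contig = "c", start = 10,
                                              end = 10, label = "x")),
               "malformed")
})

test_that("tssMetaprofile orients offsets and finds planted enrichment", {
  # single TSS, single site at +10: exactly one non-empty bin
  calls <- mkCalls(1010, 0.8)
  tss <- data.frame(contig = "c", pos0 = 1000, strand = "+")
  prof <- tssMetaprofile(calls, tss, window = 500, bin = 100)
  expect_equal(sum(prof$n_sites), 1L)
  hit <- prof[prof$n_sites > 0, ]
  expect_equal(hit$offset_start, 0)
  expect_equal(hit$mean_fraction, 0.8)

  # minus-strand TSS: a site 10 bp to its left is downstream (+)
  tssm <- data.frame(contig = "c", pos0 = 1020, strand = "-")
  profm <- tssMetaprofile(calls, tssm, window = 500, bin = 100)
  hitm <- profm[profm$n_sites > 0, ]
  expect_equal(hitm$offset_start, 0)

  expect_error(tssMetaprofile(calls, tss[0, ], 500, 100), "non-empty")
  expect_error(tssMetaprofile(calls, tss, 500, 300), "multiple")

  # 5hmC planted only near the TSS: central bins exceed flanks
  set.seed(1)
  near <- sample(-400:400, 60)
  far <- sample(c(-(2000:1500), 1500:2000), 60)
  calls2 <- mkCalls(3000 + c(near, far),
                    c(rep(0.9, 60), rep(0.02, 60)))
  prof2 <- tssMetaprofile(calls2, data.frame(contig = "c", pos0 = 3000,
                                             strand = "+"),
                          window = 2000, bin = 500)
  central <- prof2$mean_fraction[prof2$offset_start %in% c(-500, 0)]
  flank <- prof2$mean_fraction[prof2$offset_start %in% c(-2000, 1500)]
  expect_true(all(central > flank))
})
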