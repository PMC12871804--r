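test_that("scan_pas finds all (including overlapping) motif occurrences", {
  expect_equal(nrow(scan_pas("CCCCCCCC")), 0L)
  expect_equal(nrow(scan_pas("")), 0L)

  hits <- scan_pas("AATAAATAAATAAA")
  expect_equal(hits$start, c(0L, 4L, 8L))
  expect_equal(hits$end - hits$start, rep(6L, 3L))

  # greedy non-overlapping mode: accept 0, skip 4 (overlaps), accept 8
  expect_equal(scan_pas("AATAAATAAATAAA", allow_overlap = FALSE)$start,
               c(0L, 8L))

  # lowercase (soft-masked) sequence matches; N never does
  expect_equal(scan_pas("aataaa")$start, 0L)
  expect_equal(nrow(scan_pas("AATAAN")), 0L)
  expect_error(scan_pas("AATXAA"), "offset 3")
})

test_that("scan_pas agrees with an independent matcher on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    s <- rand_seq(sample(50:400, 1L))
    expect_equal(scan_pas(s)$start, oracle_scan(s)$start)
  }
})

test_that("minus-strand scanning mirrors a reverse-complement plus scan", {
  set.seed(202)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in 1:50) {
    s <- rand_seq(300)
    plus_on_rc <- scan_pas(rc(s))$start
    # a minus-strand motif at plus-axis position p corresponds to a hit at
    # nchar(s) - p - 6 on the reverse complement
    minus_mirrored <- sort(nchar(s) - scan_pas(rc(s))$start - 6L)
    direct <- scan_pas(s, motifs = rc("AATAAA"))$start
    expect_equal(sort(direct), sort(nchar(s) - plus_on_rc - 6L))
    expect_equal(sort(direct), minus_mirrored)
  }
})

test_that("cluster_hits forms the transitive closure under >=1 nt overlap", {
  h <- scan_pas("AATAAATAAATAAA")
  cl <- cluster_hits(h)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_signals, 3L)
  expect_equal(cl$start, 0L)
  expect_equal(cl$end, 14L)

  h2 <- data.frame(start = c(0L, 100L), end = c(6L, 106L),
                   motif = "AATAAA")
  cl2 <- cluster_hits(h2)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$n_signals, c(1L, 1L))

  expect_equal(nrow(cluster_hits(scan_pas("CCCC"))), 0L)
})

test_that("clustering is idempotent and partitions the hits", {
  set.seed(303)
  for (i in 1:50) {
    s <- rand_seq(500, c("A", "A", "A", "T", "C", "G"))  # A-rich: many hits
    h <- scan_pas(s)
    cl <- cluster_hits(h)
    expect_equal(sum(cl$n_signals), nrow(h))
    if (nrow(h) > 0L) {
      member_starts <- sort(unname(unlist(lapply(cl$hits, `[[`, "start"))))
      expect_equal(member_starts, h$start)   # every hit in exactly one cluster
      expect_true(all(cl$start[-1L] >= cl$end[-nrow(cl)]))  # disjoint clusters
    }
  }
})

test_that("cleavage site sits offset nt past the 5'-most hexamer, strand-aware", {
  h <- data.frame(start = 100L, end = 106L, motif = "AATAAA")
  cl <- cluster_hits(h)
  expect_equal(predict_cleavage_site(cl[1, ], "+", 20L), 126L)
  expect_equal(predict_cleavage_site(cl[1, ], "-", 20L), 80L)

  # with overlapping signals the 5'-most (transcript orientation) wins
  h3 <- data.frame(start = c(100L, 104L, 108L), end = c(106L, 110L, 114L),
                   motif = "AATAAA")
  cl3 <- cluster_hits(h3)
  expect_equal(predict_cleavage_site(cl3[1, ], "+", 20L), 126L)
  expect_equal(predict_cleavage_site(cl3[1, ], "-", 20L), 88L)

  expect_error(predict_cleavage_site(list(n_signals = 0L), "+"), "at least one")
})

test_that("repeat overlap annotation picks the maximal-overlap element", {
  cl <- cluster_hits(data.frame(start = 150L, end = 170L, motif = "AATAAA"))
  reps <- data.frame(chrom = "c", start = 40L, end = 172L, strand = "+",
                     repeat_name = "FLAM-C", repeat_class = "SINE/Alu")
  out <- annotate_repeat_overlap(cl, reps)
  expect_equal(out$repeat_name, "FLAM-C")
  expect_equal(out$repeat_class, "SINE/Alu")

  far <- data.frame(chrom = "c", start = 1000L, end = 1100L, strand = "+",
                    repeat_name = "AluSx", repeat_class = "SINE/Alu")
  expect_true(is.na(annotate_repeat_overlap(cl, far)$repeat_name))

  # 10 nt overlap beats 3 nt overlap
  two <- data.frame(chrom = "c", start = c(167L, 140L), end = c(260L, 160L),
                    strand = "+", repeat_name = c("ov3", "ov10"),
                    repeat_class = "SINE/Alu")
  expect_equal(annotate_repeat_overlap(cl, two)$repeat_name, "ov10")
})

test_that("the walkthrough locus yields one triple-signal repeat-borne cluster", {
  loc <- taf8_like_locus(42)
  cl <- scan_locus_pas(loc$model$seq, repeats = loc$repeats)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_signals, 3L)
  expect_equal(cl$hits[[1]]$start, loc$truth$pas_starts)
  expect_equal(cl$cleavage_site, loc$truth$cleavage_site)
  expect_equal(cl$repeat_name, "FLAM-C")
})
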