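test_that("generators are pure functions of (seed, parameters)", {
  l1 <- gen_locus(9); l2 <- gen_locus(9)
  expect_identical(l1$model$seq, l2$model$seq)
  expect_identical(l1$truth, l2$truth)

  j1 <- gen_junction_counts(9, 0.4); j2 <- gen_junction_counts(9, 0.4)
  expect_identical(j1$up_counts, j2$up_counts)

  s1 <- gen_spectral_counts(9, c(b = 1, a = 2), c(b = 300, a = 200))
  s2 <- gen_spectral_counts(9, c(b = 1, a = 2), c(b = 300, a = 200))
  expect_identical(s1$counts, s2$counts)

  expect_false(identical(gen_locus(9)$model$seq, gen_locus(10)$model$seq))
})

test_that("planted PAS hexamers are the only canonical signals present", {
  for (n in c(0L, 1L, 3L)) {
    loc <- gen_locus(17, n_planted_pas = n)
    hits <- scan_pas(loc$model$seq)
    expect_equal(hits$start, loc$truth$pas_starts)
    expect_equal(nrow(hits), n)
  }
  # point mutations outside the planted hexamers never disturb the truth
  mut <- gen_locus(17, n_planted_pas = 3L, mutation_rate = 0.02)
  expect_equal(scan_pas(mut$model$seq)$start, mut$truth$pas_starts)
})

test_that("the planted element is annotated as the cluster's repeat", {
  loc <- gen_locus(23, n_planted_pas = 3L)
  cl <- scan_locus_pas(loc$model$seq, repeats = loc$repeats)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$repeat_name, "FLAM-C")
  expect_true(cl$start >= loc$truth$element[1] &&
              cl$end <= loc$truth$element[2])
})

test_that("junction simulation matches its mixture model", {
  j1 <- gen_junction_counts(3, psi = 1)
  expect_true(all(j1$down_counts == 0))

  j0 <- gen_junction_counts(3, psi = 0, depth = 1e5)
  p <- junction_percentages(c(j0$up_counts, j0$down_counts))$percent
  expect_lt(max(abs(p - 100 / 9)), 0.5)

  j5 <- gen_junction_counts(3, psi = 0.5, depth = 1e6)
  est <- estimate_short_fraction(j5$up_counts, j5$down_counts,
                                 n_boot = 50, seed = 3)
  expect_lt(abs(est$psi_hat - 0.5), 0.01)
})

test_that("a noiseless planted insertion is recovered branch-exactly", {
  fx <- primate_fixture()
  tr <- fx$tree
  target <- ape::getMRCA(tr, c("human", "macaque"))   # Catarrhini stem
  sim <- gen_tree_characters(5, tr, gain_rate = 0, loss_rate = 0,
                             insertion_branch = target)
  pres <- setNames(sim$characters$presence, sim$characters$tip)
  dol <- dollo_presence(tr, pres)
  expect_equal(unname(dol$gain_branch["child"]), target)
  expect_equal(dol$n_losses, 0L)
})

test_that("identifiable planted count events are reproduced by parsimony", {
  # exact event-branch recovery is only possible for identifiable
  # histories: no event on a root-adjacent branch (unpolarizable without
  # an outgroup) and no event nested within another event's clade (a
  # gain-then-reversal collapses to a cheaper explanation)
  fx <- primate_fixture()
  tr <- fx$tree
  root <- length(tr$tip.label) + 1L
  parent_of <- function(n) {
    p <- tr$edge[tr$edge[, 2] == n, 1]
    if (length(p)) p else NA_integer_
  }
  ancestors <- function(n) {
    out <- integer()
    while (!is.na(n <- parent_of(n))) out <- c(out, n)
    out
  }
  identifiable <- function(ev) {
    kids <- ev$child
    if (any(kids %in% tr$edge[tr$edge[, 1] == root, 2])) return(FALSE)
    if (anyDuplicated(vapply(kids, parent_of, integer(1)))) return(FALSE)
    anc <- lapply(kids, ancestors)
    for (i in seq_along(kids)) {
      others <- kids[-i]
      if (any(others %in% c(kids[i], anc[[i]]))) return(FALSE)
    }
    TRUE
  }
  found <- 0L; usable <- 0L
  for (s in 1:120) {
    sim <- gen_tree_characters(s, tr, gain_rate = 0.03, loss_rate = 0.015,
                               insertion_branch = root)
    ev_truth <- sim$truth$count_events
    n_events <- if (is.null(ev_truth)) 0L else nrow(ev_truth)
    if (n_events == 0L || n_events > 3L ||
        length(sim$truth$loss_branches) > 0L) next
    if (!identifiable(ev_truth)) next
    usable <- usable + 1L
    counts <- setNames(sim$characters$pas_count, sim$characters$tip)
    rec <- sankoff(tr, counts, linear_cost_matrix(0:6))
    ok <- nrow(rec$events) == n_events &&
      setequal(rec$events$child, ev_truth$child)
    found <- found + ok
  }
  expect_gte(usable, 20L)
  expect_gte(found / usable, 0.95)
})

test_that("spectral-count simulation respects abundance x length sampling", {
  sim <- gen_spectral_counts(13, c(bait = 1, A = 2), c(bait = 300, A = 300),
                             background_proteins = 0L, depth = 1e5,
                             n_runs = 2L)
  nsaf <- compute_nsaf(sim$counts, sim$lengths)
  st <- stoichiometry(nsaf, "bait")
  expect_equal(st$mean_ratio[st$protein == "A"], 2, tolerance = 0.05)
})

test_that("generated files are faithful on-disk dialects", {
  dir <- withr::local_tempdir()
  gen_junction_counts(4, 0.3, dir = dir)
  sj <- read_sj_table(file.path(dir, "sim.SJ.out.tab"))
  expect_equal(nrow(sj), 9L)
  expect_true(all(sj$unique_reads >= 0))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$psi, 0.3)

  gen_locus(4, dir = dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "locus.fa"))
  expect_equal(names(fa), "simchr")
  reps <- read_repeat_annotation(file.path(dir, "repeats.bed"))
  expect_equal(reps$repeat_name, "FLAM-C")
  expect_equal(reps$repeat_class, "SINE/Alu")
})

test_that("RepeatMasker .out tables parse with 1-based conversion", {
  f <- withr::local_tempfile()
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end (left)     repeat class/family",
    "",
    "  463 11.2  0.0  0.0  simchr  4241 4386 (5000) +  FLAM-C  SINE/Alu  1 137  (0) 1"),
    f)
  reps <- read_repeat_annotation(f)
  expect_equal(reps$start, 4240L)
  expect_equal(reps$end, 4386L)
  expect_equal(reps$repeat_name, "FLAM-C")
  expect_equal(reps$repeat_class, "SINE/Alu")
})
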