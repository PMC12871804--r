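test_that("NSAF normalises length-corrected counts to molar fractions", {
  one <- matrix(7L, 1, 1, dimnames = list("p1", "r1"))
  expect_equal(compute_nsaf(one, c(p1 = 350))[1, 1], 1)

  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("p1", "p2"), "r1"))
  n <- compute_nsaf(two, c(p1 = 100, p2 = 300))
  expect_equal(unname(n[, 1]), c(0.75, 0.25))
  expect_equal(compute_nsaf(two * 5L, c(p1 = 100, p2 = 300)), n)

  zero_run <- cbind(two, r2 = c(0L, 0L))
  expect_error(compute_nsaf(zero_run, c(p1 = 100, p2 = 300)), "r2")
  expect_error(compute_nsaf(two, c(p1 = 100, p2 = 0)), "positive length")
})

test_that("NSAF columns sum to one on simulated IP-MS data", {
  sim <- gen_spectral_counts(31, c(bait = 1, A = 1, B = 1),
                             c(bait = 310, A = 218, B = 1199))
  nsaf <- compute_nsaf(sim$counts, sim$lengths)
  expect_equal(unname(colSums(nsaf)), rep(1, ncol(nsaf)), tolerance = 1e-9)
})

test_that("identical groups produce zero fold change and no hits", {
  m <- matrix(2^c(10, 11, 12, 10, 11, 12,
                  10, 11, 12, 10, 11, 12), nrow = 3,
              dimnames = list(paste0("p", 1:3), paste0("r", 1:4)))
  res <- enrichment_test(m, bait_runs = c("r1", "r2"),
                         control_runs = c("r3", "r4"), seed = 1)
  expect_equal(res$log2fc, rep(0, 3))
  expect_false(any(res$significant))
})

test_that("t-test p-values match the closed-form Welch statistic", {
  set.seed(9)
  m <- matrix(2^rnorm(5 * 6, mean = 20), nrow = 5,
              dimnames = list(paste0("p", 1:5), paste0("r", 1:6)))
  res <- enrichment_test(m, bait_runs = paste0("r", 1:3),
                         control_runs = paste0("r", 4:6), seed = 1)
  # with no missing values, imputation and the seed are inert; the test
  # reduces to a Welch t-test on median-centred log2 intensities
  x <- log2(m)
  x <- sweep(x, 2, apply(x, 2, median), `-`)
  for (i in 1:5) {
    expect_equal(res$p[i], welch_p(x[i, 1:3], x[i, 4:6]), tolerance = 1e-6)
  }
})

test_that("spiked-in proteins dominate the ranking with no false flags", {
  # 8-fold spikes among 200 nulls at n = 3/group: with triplicates the
  # Welch t statistic is heavy-tailed (df ~ 2-4), so individual spike
  # p-values straddle the BH cutoff at FDR 0.01; the robust signatures are
  # the p-value ranking, the estimated fold change, and null control
  flag_sum <- 0L
  for (s in c(77L, 78L, 79L)) {
    set.seed(s)
    n_null <- 200L; n_spike <- 5L
    base <- rnorm(n_null + n_spike, mean = 20, sd = 1)
    make_run <- function(spiked) {
      shift <- c(rep(0, n_null), rep(if (spiked) 3 else 0, n_spike))
      2^(base + shift + rnorm(n_null + n_spike, sd = 0.3))
    }
    m <- cbind(b1 = make_run(TRUE), b2 = make_run(TRUE),
               b3 = make_run(TRUE), c1 = make_run(FALSE),
               c2 = make_run(FALSE), c3 = make_run(FALSE))
    rownames(m) <- c(paste0("null", seq_len(n_null)),
                     paste0("spike", seq_len(n_spike)))
    res <- enrichment_test(m, paste0("b", 1:3), paste0("c", 1:3), seed = s)
    spikes <- grepl("^spike", res$protein)
    expect_gte(sum(rank(res$p)[spikes] <= 8), 4L)
    expect_equal(res$log2fc[spikes], rep(3, 5), tolerance = 0.2)
    expect_lte(sum(res$significant[!spikes]), 1L)
    flag_sum <- flag_sum + sum(res$significant[spikes])
  }
  expect_gte(flag_sum, 1L)   # detection does fire across seeds
})

test_that("missing values are imputed from a down-shifted distribution", {
  set.seed(12)
  m <- matrix(2^rnorm(40 * 4, 20, 1), nrow = 40,
              dimnames = list(paste0("p", 1:40), paste0("r", 1:4)))
  m[1, 1:2] <- NA   # missing in the bait group only
  res <- enrichment_test(m, c("r1", "r2"), c("r3", "r4"), seed = 5)
  expect_equal(nrow(res), 40L)
  expect_lt(res$log2fc[res$protein == "p1"], 0)  # imputed low vs observed

  m_all_na <- m; m_all_na[2, ] <- NA
  expect_warning(res2 <- enrichment_test(m_all_na, c("r1", "r2"),
                                         c("r3", "r4"), seed = 5),
                 "missing in every run")
  expect_equal(nrow(res2), 39L)
})

test_that("stoichiometry is bait-normalised per run with SEM across runs", {
  nsaf <- rbind(bait = c(0.2, 0.1, 0.4),
                partner = c(0.1, 0.1, 0.6))
  colnames(nsaf) <- paste0("run", 1:3)
  st <- stoichiometry(nsaf, "bait")
  expect_equal(st$mean_ratio[st$protein == "bait"], 1)
  expect_equal(st$sem[st$protein == "bait"], 0)
  expect_equal(st$mean_ratio[st$protein == "partner"], 1)  # (0.5+1+1.5)/3
  expect_equal(st$sem[st$protein == "partner"], 0.5 / sqrt(3))

  nsaf0 <- nsaf; nsaf0["bait", 2] <- 0
  expect_warning(st0 <- stoichiometry(nsaf0, "bait"), "without bait")
  expect_equal(st0$n_runs[1], 2L)
})

test_that("known 2:1 stoichiometry is recovered from simulated counts", {
  # with triplicate runs, mean +/- 2*SEM is a Student-t interval with 2 df
  # (nominal coverage P(|t_2| < 2) = 0.816, not 95%); the estimator itself
  # is unbiased, so the mean over replicates converges on the truth
  reps <- vapply(1:25, function(r) {
    sim <- gen_spectral_counts(800L + r, c(bait = 1, A = 2, B = 1),
                               c(bait = 310, A = 250, B = 500),
                               depth = 20000L, n_runs = 3L)
    nsaf <- compute_nsaf(sim$counts, sim$lengths)
    st <- stoichiometry(nsaf, "bait")
    a <- st[st$protein == "A", ]
    c(hit = abs(a$mean_ratio - 2) <= 2 * a$sem, ratio = a$mean_ratio)
  }, c(hit = NA_real_, ratio = NA_real_))
  expect_gte(mean(reps["hit", ]), 0.6)
  expect_equal(mean(reps["ratio", ]), 2, tolerance = 0.03)
})
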