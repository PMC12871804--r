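test_that("parse_newick validates input and attaches node ages", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)

  tru <- parse_newick("((A:1,B:1):4,C:5);", ultrametric = TRUE)
  ages <- attr(tru, "node_ages")
  expect_equal(max(ages), 5)
  expect_equal(unname(ages[seq_len(3)]), c(0, 0, 0))

  expect_error(parse_newick("((A,A),B);"), "duplicate tip")
})

test_that("a constant character reconstructs with zero cost and no events", {
  tr <- parse_newick("((A,B),(C,D));")
  rec <- sankoff(tr, c(A = 1, B = 1, C = 1, D = 1), linear_cost_matrix(0:3))
  expect_equal(rec$total_cost, 0)
  expect_equal(nrow(rec$events), 0L)
  expect_true(all(vapply(rec$node_states, identical, logical(1), "1")))
})

test_that("a two-clade split costs one step, verified by enumeration", {
  tr <- parse_newick("((A,B),(C,D));")
  states <- c(A = 0, B = 0, C = 1, D = 1)
  cost <- linear_cost_matrix(0:1)
  rec <- sankoff(tr, states, cost)
  expect_equal(rec$total_cost, 1)
  expect_equal(rec$total_cost, brute_force_parsimony(tr, states, cost))
  # the change is on an internal branch, not a terminal one
  certain <- rec$events
  expect_true(all(is.na(certain$child_label)) || nrow(certain) == 0L)
})

test_that("sankoff matches exhaustive enumeration on random trees", {
  set.seed(404)
  for (i in 1:40) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n)
    k <- sample(2:4, 1L)
    st <- setNames(sample(0:(k - 1), n, replace = TRUE), tr$tip.label)
    st[sample(n, 1L)] <- NA                 # always exercise an NA tip
    cost <- if (runif(1) < 0.5) linear_cost_matrix(0:(k - 1)) else
      unit_cost_matrix(0:(k - 1))
    expect_equal(sankoff(tr, st, cost)$total_cost,
                 brute_force_parsimony(tr, st, cost))
  }
})

test_that("sankoff agrees with phangorn's implementation on the score", {
  skip_if_not_installed("phangorn")
  set.seed(505)
  for (i in 1:20) {
    tr <- ape::rtree(6)
    st <- setNames(sample(c("0", "1", "2"), 6, replace = TRUE),
                   tr$tip.label)
    cost <- linear_cost_matrix(0:2)
    pd <- phangorn::phyDat(as.matrix(st), type = "USER",
                           levels = c("0", "1", "2"))
    expect_equal(sankoff(tr, st, cost)$total_cost,
                 as.numeric(phangorn::sankoff(tr, pd, cost)))
  }
})

test_that("an NA tip never increases the total parsimony cost", {
  set.seed(606)
  for (i in 1:20) {
    tr <- ape::rtree(6)
    st <- setNames(sample(0:2, 6, replace = TRUE), tr$tip.label)
    cost <- linear_cost_matrix(0:2)
    full <- sankoff(tr, st, cost)$total_cost
    st_na <- st; st_na[sample(6, 1L)] <- NA
    expect_lte(sankoff(tr, st_na, cost)$total_cost, full)
  }
})

test_that("the primate PAS-count history is reconstructed branch-exactly", {
  fx <- primate_fixture()
  counts <- setNames(fx$chars$pas_count, fx$chars$tip)
  rec <- sankoff(fx$tree, counts, linear_cost_matrix(0:3))
  expect_equal(rec$total_cost, 4)
  expect_equal(nrow(rec$events), 3L)
  expect_equal(nrow(rec$possible_events), 0L)

  homo <- ape::getMRCA(fx$tree, c("human", "neanderthal"))
  gibbon <- ape::getMRCA(fx$tree, c("siamang", "hoolock"))
  colobinae <- ape::getMRCA(fx$tree, c("colobus", "langur"))
  ev <- rec$events
  expect_equal(ev$delta[ev$child == homo], 2)
  expect_equal(ev$delta[ev$child == gibbon], 1)
  expect_equal(ev$delta[ev$child == colobinae], -1)
})

test_that("Dollo places a unique gain above the MRCA and minimal losses", {
  fx <- primate_fixture()
  pres <- setNames(fx$chars$presence, fx$chars$tip)
  dol <- dollo_presence(fx$tree, pres)
  simiiformes <- ape::getMRCA(fx$tree, c("marmoset", "human", "macaque"))
  expect_equal(unname(dol$gain_branch["child"]), simiiformes)
  expect_equal(dol$n_losses, 1L)
  expect_equal(dol$loss_branches$child_label, "marmoset")

  # all tips present: gain on the root branch, no losses
  tr <- parse_newick("((A,B),C);")
  d_all <- dollo_presence(tr, c(A = "present", B = "present", C = "present"))
  expect_true(is.na(d_all$gain_branch["parent"]))
  expect_equal(d_all$n_losses, 0L)

  # single present tip: gain on that terminal branch
  d_one <- dollo_presence(tr, c(A = "present", B = "absent", C = "absent"))
  expect_equal(unname(d_one$gain_branch["child"]), 1L)
  expect_equal(d_one$n_losses, 0L)
})

test_that("Dollo is minimal among single-gain scenarios (enumeration)", {
  set.seed(707)
  # losses required when the single gain sits above `gain_node`: one per
  # maximal all-absent subtree below it
  losses_for_gain <- function(tree, gain_node, present_tips) {
    ntip <- length(tree$tip.label)
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    tips_under <- function(nd) {
      if (nd <= ntip) return(nd)
      unlist(lapply(kids[[as.character(nd)]], tips_under))
    }
    if (!all(present_tips %in% tips_under(gain_node))) return(Inf)
    n_loss <- function(nd) {
      under <- tips_under(nd)
      if (!any(under %in% present_tips)) return(1L)
      if (nd <= ntip) return(0L)
      sum(vapply(kids[[as.character(nd)]], n_loss, integer(1)))
    }
    n_loss(gain_node)
  }
  for (i in 1:12) {
    tr <- ape::rtree(6)
    present <- sort(sample(6, sample(2:5, 1)))
    pres <- setNames(ifelse(seq_len(6) %in% present, "present", "absent"),
                     tr$tip.label)
    dol <- dollo_presence(tr, pres)
    all_nodes <- seq_len(6 + tr$Nnode)
    costs <- vapply(all_nodes, losses_for_gain, numeric(1), tree = tr,
                    present_tips = present)
    expect_equal(dol$n_losses, min(costs))
    expect_equal(losses_for_gain(tr, dol$gain_node, present), min(costs))
  }
})

test_that("events are dated to the enclosing branch interval", {
  fx <- primate_fixture()
  counts <- setNames(fx$chars$pas_count, fx$chars$tip)
  rec <- sankoff(fx$tree, counts, linear_cost_matrix(0:3))
  ev <- rec$events[rec$events$delta == 2, ]
  d <- date_event(fx$tree, ev$parent, ev$child)
  expect_equal(d$age_min, 0.5)
  expect_equal(d$age_max, 6)

  dol <- dollo_presence(fx$tree,
                        setNames(fx$chars$presence, fx$chars$tip))
  di <- date_event(fx$tree, dol$gain_branch["parent"],
                   dol$gain_branch["child"])
  expect_equal(di$age_min, 43)
  expect_equal(di$age_max, 65)

  tr <- parse_newick("((A,B),C);")   # no branch lengths, no ages
  expect_warning(d0 <- date_event(tr, 4, 1), "no node ages")
  expect_true(is.na(d0$age_min))
})
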