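#' Parse a Newick species tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this
#' pipeline needs: unique tip labels, and (optionally) interpretation of
#' branch lengths as an ultrametric time scale, in which case node ages in
#' Mya are attached (tips of an ultrametric tree sit at age 0; tips ending
#' above the present, e.g. archaic hominins, keep their positive age).
#'
#' @param text Newick string (used if `file` is missing).
#' @param file Path to a Newick file.
#' @param ultrametric If `TRUE`, compute node ages from branch lengths.
#' @return An `ape::phylo` tree, with a numeric `node_ages` attribute
#'   (indexed tips first, then internal nodes) when `ultrametric = TRUE`.
#' @export
parse_newick <- function(text = NULL, file = NULL, ultrametric = FALSE) {
  tree <- if (!is.null(file)) ape::read.tree(file) else
    ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (ultrametric) {
    if (is.null(tree$edge.length)) {
      stop("ultrametric interpretation requires branch lengths")
    }
    depth <- ape::node.depth.edgelength(tree)
    attr(tree, "node_ages") <- max(depth) - depth
  }
  tree
}

node_children <- function(tree) {
  split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                levels = seq_len(ape::Nnode(tree) +
                                                 length(tree$tip.label))))
}

#' Sankoff parsimony ancestral reconstruction with per-branch events
#'
#' Minimal-cost ancestral state assignment for a single discrete character
#' under an arbitrary transition-cost matrix, by dynamic programming:
#' bottom-up conditional cost vectors, then a top-down pass computing for
#' every node the set of states attained in at least one globally optimal
#' assignment. Tips with `NA` state are unconstrained (zero cost in every
#' state) and never increase the total cost.
#'
#' Events are reported per branch. A branch carries a *certain* event when
#' the optimal state sets of its parent and child are disjoint (the state
#' must change in every optimal assignment); branches whose sets differ
#' but intersect are listed as *possible* events.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_states Named vector of states (names = tip labels); `NA`
#'   allowed. States must appear in the cost-matrix dimnames.
#' @param cost_matrix Square matrix with identical row/column state names;
#'   `cost_matrix[i, j]` is the cost of an i -> j change along a branch.
#'   See [linear_cost_matrix()] and [unit_cost_matrix()].
#' @return list of class `event_reconstruction`: `total_cost`,
#'   `node_states` (list of optimal state sets per node, ape node
#'   numbering), `events` and `possible_events` (data.frames with
#'   `parent`, `child`, `from`, `to`, `delta`).
#' @export
sankoff <- function(tree, tip_states, cost_matrix) {
  states <- rownames(cost_matrix)
  stopifnot(!is.null(states), identical(states, colnames(cost_matrix)))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seen <- tip_states[!is.na(tip_states)]
  if (!all(as.character(seen) %in% states)) {
    stop("tip state(s) outside the cost-matrix alphabet: ",
         paste(setdiff(as.character(seen), states), collapse = ", "))
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips)) {
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  }
  k <- length(states)
  INF <- .Machine$double.xmax / 4

  up <- matrix(0, nrow = nnode, ncol = k)       # cost of subtree given state
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (!is.na(s)) up[i, ] <- ifelse(states == as.character(s), 0, INF)
  }
  children <- node_children(tree)
  node_order <- unique(tree$edge[ape::postorder(tree), 1L])  # bottom-up
  for (nd in node_order) {
    for (ch in children[[as.character(nd)]]) {
      # min over child states of (transition cost + child's subtree cost)
      trans <- sweep(cost_matrix, 2L, up[ch, ], `+`)
      up[nd, ] <- up[nd, ] + apply(trans, 1L, min)
    }
  }
  root <- ntip + 1L
  total_cost <- min(up[root, ])

  # down[n, s]: min cost of the rest of the tree when node n has state s
  down <- matrix(0, nrow = nnode, ncol = k)
  # traverse branches parent-before-child (reverse postorder)
  pre <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    par <- pre[e, 1L]; ch <- pre[e, 2L]
    sibs <- setdiff(children[[as.character(par)]], ch)
    sib_cost <- rep(0, k)
    for (sb in sibs) {
      trans <- sweep(cost_matrix, 2L, up[sb, ], `+`)
      sib_cost <- sib_cost + apply(trans, 1L, min)
    }
    par_ctx <- down[par, ] + sib_cost           # cost above, per parent state
    trans <- sweep(cost_matrix, 1L, par_ctx, `+`)
    down[ch, ] <- apply(trans, 2L, min)
  }

  tot <- up + down
  node_states <- lapply(seq_len(nnode), function(n) {
    states[tot[n, ] <= min(tot[n, ]) + 1e-9]
  })

  numeric_states <- suppressWarnings(as.numeric(states))
  ev <- list(); pv <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    ps <- node_states[[par]]; cs <- node_states[[ch]]
    if (setequal(ps, cs)) next
    row <- data.frame(
      parent = par, child = ch,
      child_label = if (ch <= ntip) tree$tip.label[ch] else NA_character_,
      from = paste(ps, collapse = "|"), to = paste(cs, collapse = "|"),
      delta = if (length(ps) == 1L && length(cs) == 1L &&
                  !anyNA(numeric_states))
        numeric_states[match(cs, states)] - numeric_states[match(ps, states)]
      else NA_real_,
      stringsAsFactors = FALSE)
    if (length(intersect(ps, cs)) == 0L) ev[[length(ev) + 1L]] <- row
    else pv[[length(pv) + 1L]] <- row
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(parent = integer(), child = integer(),
               child_label = character(), from = character(),
               to = character(), delta = numeric())
  structure(list(total_cost = total_cost, node_states = node_states,
                 events = bind(ev), possible_events = bind(pv),
                 tree = tree),
            class = "event_reconstruction")
}

#' Linear transition-cost matrix over integer character states
#'
#' `cost(i -> j) = |i - j|`: each unit change (one hexamer gained or lost)
#' costs one step.
#' @param states Integer vector of allowed states, e.g. `0:3`.
#' @return Square numeric matrix with character dimnames.
#' @export
linear_cost_matrix <- function(states) {
  m <- abs(outer(states, states, `-`))
  dimnames(m) <- list(as.character(states), as.character(states))
  m
}

#' Unit transition-cost matrix (any change costs 1)
#' @inheritParams linear_cost_matrix
#' @return Square numeric matrix with character dimnames.
#' @export
unit_cost_matrix <- function(states) {
  m <- 1 - diag(length(states))
  dimnames(m) <- list(as.character(states), as.character(states))
  m
}

#' Dollo parsimony for a uniquely gained character
#'
#' Reconstructs the history of a character that can be gained only once
#' (e.g. a transposable-element insertion) but lost any number of times.
#' The single gain is placed on the branch above the most recent common
#' ancestor of all tips where the element is (or demonstrably was)
#' present; losses are placed on the minimal set of branches covering the
#' non-present descendants of that ancestor.
#'
#' Tip states: `"present"`, `"absent"`, or `"lost"`. `"lost"` marks tips
#' where independent evidence (e.g. a deletion whose breakpoints span the
#' element) shows the element was ancestrally present and secondarily
#' removed; such tips anchor the gain node like present tips but receive a
#' loss branch like absent ones.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_presence Named character/logical vector. Logical input is
#'   mapped to present/absent.
#' @return list of class `dollo_reconstruction`: `gain_node` (the node
#'   below the insertion branch), `gain_branch` (parent, child; parent
#'   `NA` when the gain sits on the root branch), `loss_branches`
#'   (data.frame parent/child/child_label), `n_losses`.
#' @export
dollo_presence <- function(tree, tip_presence) {
  if (is.logical(tip_presence)) {
    tip_presence <- ifelse(tip_presence, "present", "absent")
  }
  stopifnot(all(tip_presence %in% c("present", "absent", "lost")))
  missing_tips <- setdiff(tree$tip.label, names(tip_presence))
  if (length(missing_tips)) {
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  anchor <- tree$tip.label[tip_presence[tree$tip.label] %in%
                             c("present", "lost")]
  if (length(anchor) == 0L) stop("at least one present tip required")
  gain_node <- if (length(anchor) == 1L) match(anchor, tree$tip.label) else
    ape::getMRCA(tree, anchor)
  parent_of <- function(n) {
    p <- tree$edge[tree$edge[, 2L] == n, 1L]
    if (length(p)) p else NA_integer_
  }
  # minimal loss set: one loss at the stem of every maximal all-non-present
  # subtree under the gain node
  children <- node_children(tree)
  nonpresent_tip <- function(lbl) tip_presence[[lbl]] %in% c("absent", "lost")
  all_nonpresent <- function(n) {
    if (n <= ntip) return(nonpresent_tip(tree$tip.label[n]))
    all(vapply(children[[as.character(n)]], all_nonpresent, logical(1L)))
  }
  losses <- list()
  walk <- function(n) {
    if (n <= ntip) {
      if (nonpresent_tip(tree$tip.label[n])) {
        losses[[length(losses) + 1L]] <<- c(parent_of(n), n)
      }
      return(invisible())
    }
    for (ch in children[[as.character(n)]]) {
      if (all_nonpresent(ch)) {
        losses[[length(losses) + 1L]] <<- c(n, ch)
      } else {
        walk(ch)
      }
    }
  }
  if (gain_node > ntip) walk(gain_node)
  lb <- if (length(losses)) {
    m <- do.call(rbind, losses)
    data.frame(parent = m[, 1L], child = m[, 2L],
               child_label = ifelse(m[, 2L] <= ntip,
                                    tree$tip.label[m[, 2L]], NA_character_),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = integer(), child = integer(),
               child_label = character())
  }
  structure(list(gain_node = gain_node,
                 gain_branch = c(parent = parent_of(gain_node),
                                 child = gain_node),
                 loss_branches = lb, n_losses = nrow(lb), tree = tree),
            class = "dollo_reconstruction")
}

#' Date an event branch from node ages
#'
#' An event placed on a branch can be dated only to the interval between
#' the branch's endpoints: `[child age, parent age]` in Mya.
#'
#' @param tree `phylo` tree carrying a `node_ages` attribute (see
#'   [parse_newick()] with `ultrametric = TRUE`).
#' @param parent,child Node numbers of the branch endpoints; `parent = NA`
#'   (a root branch) yields an interval open at the old end.
#' @return list with `age_min`, `age_max` (Mya); both `NA` with a warning
#'   when the tree carries no ages.
#' @export
date_event <- function(tree, parent, child) {
  ages <- attr(tree, "node_ages")
  if (is.null(ages)) {
    warning("tree carries no node ages; event left undated")
    return(list(age_min = NA_real_, age_max = NA_real_))
  }
  list(age_min = ages[child],
       age_max = if (is.na(parent)) Inf else ages[parent])
}

#' @export
print.event_reconstruction <- function(x, ...) {
  cat("parsimony reconstruction: total cost", x$total_cost, "with",
      nrow(x$events), "certain and", nrow(x$possible_events),
      "possible event branches\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("Dollo reconstruction: single gain above node", x$gain_node,
      "with", x$n_losses, "loss branch(es)\n")
  if (x$n_losses) print(x$loss_branches)
  invisible(x)
}
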