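# Independent oracles and shared fixtures for the test suite.

# Motif scan oracle: Biostrings exact matching (independent of the
# package's windowed scan).
oracle_scan <- function(seq, motif = "AATAAA") {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(toupper(seq)))
  data.frame(start = BiocGenerics::start(m) - 1L,
             end = BiocGenerics::end(m),
             motif = rep(motif, length(m)),
             stringsAsFactors = FALSE)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Sankoff oracle: exhaustive enumeration over all ancestral assignments
# (free tips included for NA states). Returns the minimal total cost.
brute_force_parsimony <- function(tree, tip_states, cost_matrix) {
  states <- rownames(cost_matrix)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  fixed <- rep(NA_integer_, nnode)
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (!is.na(s)) fixed[i] <- match(as.character(s), states)
  }
  free <- which(is.na(fixed))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  A <- matrix(rep(fixed, each = nrow(grid)), nrow = nrow(grid))
  A[, free] <- grid
  total <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    total <- total + cost_matrix[cbind(A[, tree$edge[e, 1L]],
                                       A[, tree$edge[e, 2L]])]
  }
  min(total)
}

# the bundled primate tree and character matrix
primate_fixture <- function() {
  tree <- parse_newick(file = ipastrace_example("primate_tree.nwk"),
                       ultrametric = TRUE)
  chars <- read_character_matrix(
    ipastrace_example("pas_character_matrix.tsv"))
  list(tree = tree, chars = chars)
}

# canonical + short isoform models for the walkthrough locus
two_isoform_models <- function(loc) {
  ex <- loc$model$exons
  list(
    canonical = exon_chain("simchr", "+", ex$start, ex$end,
                           name = "canonical"),
    short = exon_chain("simchr", "+", ex$start[1:5],
                       c(ex$end[1:4], loc$truth$cleavage_site),
                       name = "short"))
}

# closed-form Welch t-test p-value for a single protein row
welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}
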