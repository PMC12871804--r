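#' Construct an exon chain
#'
#' The unit of long-read isoform comparison: an ordered set of exon blocks
#' on one chromosome and strand. Internal junctions (the introns between
#' consecutive blocks) are derived on construction and are the primary key
#' for collapse and classification.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon block boundaries, 0-based
#'   half-open, ascending, non-overlapping.
#' @param name Optional read/model name.
#' @return Object of class `exon_chain`.
#' @export
exon_chain <- function(chrom, strand, starts, ends, name = NA_character_) {
  stopifnot(length(starts) == length(ends), all(starts < ends),
            strand %in% c("+", "-"))
  if (length(starts) > 1L) {
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] < ends[-length(ends)])) {
      stop("exon blocks must be ascending and non-overlapping")
    }
  }
  n <- length(starts)
  junc <- if (n > 1L) cbind(ends[-n], starts[-1L]) else
    matrix(integer(), ncol = 2L)
  structure(list(chrom = chrom, strand = strand,
                 starts = as.integer(starts), ends = as.integer(ends),
                 junctions = junc, name = name),
            class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat("exon_chain", if (!is.na(x$name)) x$name else "", x$chrom, x$strand,
      length(x$starts), "exons,", nrow(x$junctions), "junctions\n")
  invisible(x)
}

chain_end3 <- function(chain) {
  if (chain$strand == "+") chain$ends[length(chain$ends)] else chain$starts[1L]
}

chain_end5 <- function(chain) {
  if (chain$strand == "+") chain$starts[1L] else chain$ends[length(chain$ends)]
}

junction_signature <- function(chain) {
  if (nrow(chain$junctions) == 0L) return("")
  paste(chain$junctions[, 1L], chain$junctions[, 2L],
        sep = "-", collapse = ";")
}

#' Collapse long-read exon chains into unique isoforms
#'
#' Reads are grouped by identical internal-junction chains; within a
#' junction group, terminal (5'/3') ends are merged when they differ by at
#' most `end_tolerance_nt`. Each group is represented by its longest-span
#' member and reported with its read support, ordered by decreasing
#' support.
#'
#' @param reads List of [exon_chain()] on a single locus and strand.
#' @param end_tolerance_nt Maximum terminal-end difference merged into one
#'   isoform, default 50.
#' @return data.frame with columns `representative` (list of exon_chain),
#'   `support`, `signature`.
#' @export
collapse_chains <- function(reads, end_tolerance_nt = 50L) {
  if (length(reads) == 0L) {
    return(data.frame(support = integer(), signature = character()))
  }
  sig <- vapply(reads, junction_signature, character(1L))
  groups <- split(seq_along(reads), sig)
  out <- list()
  for (g in groups) {
    # sub-cluster by terminal ends: single-linkage connected components
    # (two reads link when both termini agree within the tolerance)
    s5 <- vapply(reads[g], chain_end5, numeric(1L))
    e3 <- vapply(reads[g], chain_end3, numeric(1L))
    m <- length(g)
    link <- abs(outer(s5, s5, `-`)) <= end_tolerance_nt &
            abs(outer(e3, e3, `-`)) <= end_tolerance_nt
    sub <- integer(m)
    comp <- 0L
    for (i in seq_len(m)) {
      if (sub[i] > 0L) next
      comp <- comp + 1L
      queue <- i
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        if (sub[cur] > 0L) next
        sub[cur] <- comp
        queue <- c(queue, which(link[cur, ] & sub == 0L))
      }
    }
    for (s in unique(sub)) {
      members <- g[sub == s]
      span <- vapply(reads[members], function(r)
        r$ends[length(r$ends)] - r$starts[1L], numeric(1L))
      rep_chain <- reads[[members[which.max(span)]]]
      out[[length(out) + 1L]] <- list(representative = rep_chain,
                                      support = length(members),
                                      signature = junction_signature(rep_chain))
    }
  }
  res <- data.frame(
    support = vapply(out, `[[`, integer(1L), "support"),
    signature = vapply(out, `[[`, character(1L), "signature"),
    stringsAsFactors = FALSE)
  res$representative <- lapply(out, `[[`, "representative")
  res[order(-res$support), c("representative", "support", "signature")]
}

# offsets at which `sub` occurs as a contiguous subchain of `full`
subchain_offsets <- function(sub, full, tol) {
  k <- nrow(sub); n <- nrow(full)
  if (k == 0L) return(0:n)                      # mono-exon: any placement
  if (k > n) return(integer())
  Filter(function(o) {
    all(abs(full[o + seq_len(k), , drop = FALSE] - sub) <= tol)
  }, 0:(n - k))
}

#' Classify a long read against reference isoform models
#'
#' A read is assigned to the unique model whose internal junction chain it
#' reproduces exactly (within `junction_tolerance_nt` per coordinate) and
#' whose transcript termini it matches within `terminal_tolerance_nt`.
#' Reads whose junction chain is a proper subchain of one or more models
#' and whose ends stay within the corresponding model exons are truncation
#' artifacts and are labelled `"ambiguous"` - they are never counted as
#' evidence for a particular isoform, because a truncated isoform's only
#' distinguishing feature may be its terminus. Reads matching no model are
#' `"novel"`.
#'
#' @param read An [exon_chain()].
#' @param models Named list of [exon_chain()] reference models with
#'   pairwise distinct junction chains.
#' @param junction_tolerance_nt Per-coordinate junction slack; default 0
#'   (splice junctions are base-exact).
#' @param terminal_tolerance_nt Terminal-end slack, default 50.
#' @return A label: one of the model names, `"ambiguous"` or `"novel"`.
#' @export
classify_read <- function(read, models, junction_tolerance_nt = 0L,
                          terminal_tolerance_nt = 50L) {
  if (length(models) == 0L) stop("no isoform models supplied")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be named")
  }
  jt <- junction_tolerance_nt; tt <- terminal_tolerance_nt
  full_matches <- character()
  truncation_hit <- FALSE
  for (nm in names(models)) {
    m <- models[[nm]]
    if (m$chrom != read$chrom || m$strand != read$strand) next
    same_n <- nrow(read$junctions) == nrow(m$junctions)
    if (same_n &&
        (nrow(read$junctions) == 0L ||
         all(abs(read$junctions - m$junctions) <= jt)) &&
        abs(chain_end3(read) - chain_end3(m)) <= tt &&
        abs(chain_end5(read) - chain_end5(m)) <= tt) {
      full_matches <- c(full_matches, nm)
      next
    }
    # truncated-read compatibility: junctions a contiguous subchain and
    # both read ends contained in the flanking model exons
    for (o in subchain_offsets(read$junctions, m$junctions, jt)) {
      k <- nrow(read$junctions)
      first_ex <- o + 1L; last_ex <- o + k + 1L
      if (last_ex > length(m$starts)) next
      if (read$starts[1L] >= m$starts[first_ex] - tt &&
          read$ends[length(read$ends)] <= m$ends[last_ex] + tt) {
        truncation_hit <- TRUE
        break
      }
    }
  }
  if (length(full_matches) == 1L) return(full_matches)
  if (length(full_matches) > 1L) return("ambiguous")
  if (truncation_hit) return("ambiguous")
  "novel"
}

#' Classify a set of reads
#'
#' @param reads List of [exon_chain()].
#' @inheritParams classify_read
#' @return data.frame with `read`, `label`.
#' @export
classify_reads <- function(reads, models, junction_tolerance_nt = 0L,
                           terminal_tolerance_nt = 50L) {
  labels <- vapply(reads, classify_read, character(1L), models = models,
                   junction_tolerance_nt = junction_tolerance_nt,
                   terminal_tolerance_nt = terminal_tolerance_nt)
  nm <- vapply(reads, function(r)
    if (is.na(r$name)) "" else r$name, character(1L))
  data.frame(read = nm, label = labels, stringsAsFactors = FALSE)
}
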