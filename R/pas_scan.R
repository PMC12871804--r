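#' Scan a nucleotide sequence for polyadenylation-signal hexamers
#'
#' Finds every occurrence of the supplied PAS hexamer motifs in `seq`,
#' including mutually overlapping occurrences when `allow_overlap = TRUE`
#' (the default; overlapping signals are the biologically interesting case
#' for repeat-derived A-rich tracts, where AATAAA copies can share their
#' terminal adenosines).
#'
#' Coordinates are 0-based half-open on the supplied sequence. Soft-masked
#' (lowercase) sequence matches: PAS embedded in repeats are precisely the
#' signals of interest. `N` never matches any motif.
#'
#' @param seq Single nucleotide string over the alphabet `A,C,G,T,N`
#'   (case-insensitive).
#' @param motifs Character vector of 6-mer motifs. Default: canonical
#'   `AATAAA` only. Set `motifs = pas_variant_motifs()` to scan for the
#'   twelve common PAS variants as well.
#' @param allow_overlap If `FALSE`, a greedy left-to-right pass drops hits
#'   overlapping an already-accepted hit.
#' @return A data.frame with columns `start` (0-based), `end` (exclusive)
#'   and `motif`, sorted by `start`.
#' @export
#' @examples
#' scan_pas("AATAAATAAATAAA")   # three overlapping canonical signals
scan_pas <- function(seq, motifs = "AATAAA", allow_overlap = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, length(motifs) >= 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("invalid character '", substr(seq, bad, bad),
         "' at 0-based offset ", bad - 1L, call. = FALSE)
  }
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != 6L)) stop("all motifs must be 6-mers")
  n <- nchar(seq)
  hits <- list()
  for (m in motifs) {
    # fixed-width window scan; gregexpr() would skip overlapping matches
    if (n >= 6L) {
      starts <- 1:(n - 5L)
      win <- substring(seq, starts, starts + 5L)
      at <- starts[win == m]
      if (length(at)) {
        hits[[m]] <- data.frame(start = at - 1L, end = at + 5L,
                                motif = m, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(), motif = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  if (!allow_overlap && nrow(out) > 1L) {
    keep <- logical(nrow(out))
    last_end <- -1L
    for (i in seq_len(nrow(out))) {
      if (out$start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- out$end[i]
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' The twelve common polyadenylation-signal hexamer variants
#'
#' The canonical `AATAAA`, the major variant `ATTAAA`, and the ten minor
#' single-substitution variants recurrently observed at mammalian cleavage
#' sites.
#' @return Character vector of 12 hexamers.
#' @export
pas_variant_motifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Cluster overlapping PAS hits
#'
#' Groups hexamer hits by transitive closure under >= 1 nt overlap: two hits
#' sharing at least one base belong to the same cluster, and overlap chains
#' merge. Disjoint hits become singleton clusters.
#'
#' @param hits data.frame from [scan_pas()], sorted by `start`.
#' @return A data.frame with one row per cluster: `start`, `end` (span of
#'   the member hexamers), `n_signals`, and list-column `hits` holding the
#'   member rows. `cleavage_site`, `repeat_name` and `repeat_class` are
#'   initialised to `NA` and filled by [predict_cleavage_site()] /
#'   [annotate_repeat_overlap()].
#' @export
cluster_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_signals = integer(), cleavage_site = integer(),
                      repeat_name = character(), repeat_class = character()))
  }
  if (is.unsorted(hits$start)) stop("hits must be sorted by start")
  # a new cluster opens when a hit starts at/after the running max end
  run_end <- cummax(hits$end)
  new_cluster <- c(TRUE, hits$start[-1L] >= run_end[-nrow(hits)])
  id <- cumsum(new_cluster)
  cl <- do.call(rbind, lapply(split(hits, id), function(h) {
    data.frame(start = min(h$start), end = max(h$end),
               n_signals = nrow(h), cleavage_site = NA_integer_,
               repeat_name = NA_character_, repeat_class = NA_character_,
               stringsAsFactors = FALSE)
  }))
  cl$hits <- split(hits, id)
  rownames(cl) <- NULL
  cl
}

#' Predict the cleavage/polyadenylation site for a PAS cluster
#'
#' Applies a fixed-offset heuristic: cleavage occurs `offset_nt` downstream
#' (in transcript orientation) of the 3' end of the 5'-most hexamer in the
#' cluster. The 20 nt default reflects the canonical spacing between the
#' AATAAA signal and the cleavage site acted on by CPSF/CstF.
#'
#' @param cluster One row of the data.frame returned by [cluster_hits()]
#'   (or any object with `start`/`end` fields spanning the hexamers).
#' @param strand `"+"` or `"-"`: transcript orientation on the genome axis.
#' @param offset_nt Non-negative integer offset, default 20.
#' @return A single 0-based genomic position.
#' @export
predict_cleavage_site <- function(cluster, strand = "+", offset_nt = 20L) {
  stopifnot(offset_nt >= 0L, strand %in% c("+", "-"))
  if (is.null(cluster$n_signals) || length(cluster$n_signals) != 1L ||
      cluster$n_signals < 1L) {
    stop("cluster must contain at least one hit")
  }
  h <- cluster$hits[[1L]]
  if (strand == "+") {
    first <- h[which.min(h$start), ]
    first$end + offset_nt
  } else {
    # on the minus strand the 5'-most hexamer is the one with max end, and
    # its transcript-orientation 3' end is the genomic start
    first <- h[which.max(h$end), ]
    first$start - offset_nt
  }
}

#' Annotate PAS clusters with the overlapping repeat element
#'
#' Each cluster receives the name and class of the repeat annotation with
#' which it shares the largest overlap (ties broken by repeat coordinate);
#' clusters overlapping no repeat are left unannotated.
#'
#' @param clusters data.frame from [cluster_hits()].
#' @param repeats data.frame with columns `start`, `end`, `repeat_name`,
#'   `repeat_class` (0-based half-open, same coordinate system as the
#'   clusters). See [read_repeat_annotation()].
#' @return `clusters` with `repeat_name`/`repeat_class` filled in.
#' @export
annotate_repeat_overlap <- function(clusters, repeats) {
  if (nrow(clusters) == 0L || is.null(repeats) || nrow(repeats) == 0L) {
    return(clusters)
  }
  repeats <- repeats[order(repeats$start, repeats$end), , drop = FALSE]
  for (i in seq_len(nrow(clusters))) {
    ov <- pmin(clusters$end[i], repeats$end) -
          pmax(clusters$start[i], repeats$start)
    if (any(ov > 0L)) {
      j <- which.max(ov)  # first index wins ties after the coordinate sort
      clusters$repeat_name[i] <- repeats$repeat_name[j]
      clusters$repeat_class[i] <- repeats$repeat_class[j]
    }
  }
  clusters
}

#' Scan a locus end-to-end: hits, clusters, cleavage sites, repeat overlap
#'
#' Convenience wrapper chaining [scan_pas()], [cluster_hits()],
#' [predict_cleavage_site()] and [annotate_repeat_overlap()] on one
#' sequence.
#'
#' @inheritParams scan_pas
#' @inheritParams predict_cleavage_site
#' @param repeats Optional repeat annotation data.frame.
#' @return Annotated cluster data.frame with `cleavage_site` filled.
#' @export
scan_locus_pas <- function(seq, motifs = "AATAAA", strand = "+",
                           offset_nt = 20L, repeats = NULL) {
  cl <- cluster_hits(scan_pas(seq, motifs))
  for (i in seq_len(nrow(cl))) {
    cl$cleavage_site[i] <- predict_cleavage_site(cl[i, ], strand, offset_nt)
  }
  if (!is.null(repeats)) cl <- annotate_repeat_overlap(cl, repeats)
  cl
}
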