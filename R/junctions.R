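#' Read a STAR splice-junction table (`SJ.out.tab` dialect)
#'
#' Parses the 9-column tab-separated junction table written by the STAR
#' aligner. On disk intron coordinates are 1-based inclusive; they are
#' converted to the package-internal 0-based half-open convention on read.
#'
#' Columns: chrom, intron start, intron end, strand code (0 undefined,
#' 1 `+`, 2 `-`), intron motif code, annotation flag, uniquely mapping
#' read count, multi-mapping read count, maximum spliced overhang.
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `unique_reads`, `multi_reads`, `overhang`.
#' @export
read_sj_table <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      unique_reads = integer(), multi_reads = integer(),
                      overhang = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("line ", which(nf < 9L)[1L], ": expected 9 columns, found ",
         nf[which(nf < 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num)) {
    stop("line ", which(rowSums(is.na(num)) > 0)[1L],
         ": non-numeric field")
  }
  if (any(num[, 6] < 0 | num[, 7] < 0)) {
    stop("line ", which(num[, 6] < 0 | num[, 7] < 0)[1L],
         ": negative read count")
  }
  if (any(num[, 1] > num[, 2])) {
    stop("line ", which(num[, 1] > num[, 2])[1L],
         ": intron start exceeds end")
  }
  data.frame(chrom = m[, 1], start = as.integer(num[, 1]) - 1L,
             end = as.integer(num[, 2]),
             strand = c("." , "+", "-")[as.integer(num[, 3]) + 1L],
             unique_reads = as.integer(num[, 6]),
             multi_reads = as.integer(num[, 7]),
             overhang = as.integer(num[, 8]), stringsAsFactors = FALSE)
}

#' Junction usage profile as percentages of total junction-spanning reads
#'
#' @param counts Non-negative per-junction read counts, ordered along the
#'   gene in transcript orientation (J1..Jn).
#' @param labels Optional junction labels; default `J1..Jn`.
#' @return data.frame with `junction`, `count`, `percent` (summing to 100).
#' @export
junction_percentages <- function(counts, labels = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("undefined profile: all junction counts are zero")
  if (is.null(labels)) labels <- paste0("J", seq_along(counts))
  data.frame(junction = labels, count = counts,
             percent = 100 * counts / total, stringsAsFactors = FALSE)
}

#' Estimate the short-isoform fraction from junction counts
#'
#' Junctions shared by both isoforms (upstream of the intronic
#' polyadenylation site) see reads from every transcript; junctions
#' exclusive to the full-length isoform (downstream) see only the
#' non-truncated fraction. Writing psi for the fraction of transcripts
#' terminating at the iPAS, the estimator is
#' `psi_hat = 1 - mean(down) / mean(up)`, clipped to `[0, 1]`. Means
#' rather than sums are used so unequal numbers of upstream and downstream
#' junctions do not bias the estimate.
#'
#' Uncertainty is assessed by a seeded multinomial bootstrap over all
#' junctions (percentile interval), and departure from the no-truncation
#' model (equal expected coverage at every junction) by a chi-square
#' goodness-of-fit test; for small totals a Monte-Carlo multinomial
#' goodness-of-fit p-value is used instead.
#'
#' @param up_counts Counts of junctions shared by both isoforms.
#' @param down_counts Counts of junctions exclusive to the full-length
#'   isoform.
#' @param n_boot Bootstrap resamples, default 2000.
#' @param seed Integer seed for the bootstrap (required for
#'   reproducibility).
#' @param conf Confidence level, default 0.95.
#' @param exact_below Totals below this use the Monte-Carlo multinomial
#'   test rather than the chi-square approximation.
#' @return list of class `isoform_fraction` with `psi_hat`, `psi_raw`
#'   (unclipped), `ci_low`, `ci_high`, `n_up`, `n_down`, `p_uniform`.
#' @export
estimate_short_fraction <- function(up_counts, down_counts, n_boot = 2000L,
                                    seed = 1L, conf = 0.95,
                                    exact_below = 500L) {
  stopifnot(length(up_counts) >= 1L, length(down_counts) >= 1L,
            all(up_counts >= 0), all(down_counts >= 0))
  if (mean(up_counts) == 0) stop("undefined estimate: no upstream reads")
  psi_of <- function(up, down) {
    mu <- mean(up)
    if (mu == 0) return(NA_real_)
    1 - mean(down) / mu
  }
  psi_raw <- psi_of(up_counts, down_counts)
  psi_hat <- min(max(psi_raw, 0), 1)

  all_counts <- c(up_counts, down_counts)
  k_up <- length(up_counts)
  total <- sum(all_counts)
  probs <- all_counts / total
  set.seed(as.integer(seed))
  boot <- replicate(n_boot, {
    re <- as.vector(stats::rmultinom(1L, total, probs))
    psi_of(re[seq_len(k_up)], re[-seq_len(k_up)])
  })
  boot <- boot[!is.na(boot)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  ci <- pmin(pmax(ci, 0), 1)

  if (total < exact_below) {
    # Monte-Carlo multinomial goodness of fit against the uniform model
    sim <- stats::rmultinom(4999L, total, rep(1 / length(all_counts),
                                              length(all_counts)))
    ll <- function(x) stats::dmultinom(x, prob = rep(1 / length(x),
                                                     length(x)), log = TRUE)
    obs_ll <- ll(all_counts)
    p_uniform <- (sum(apply(sim, 2L, ll) <= obs_ll + 1e-12) + 1) / 5000
  } else {
    p_uniform <- suppressWarnings(stats::chisq.test(all_counts)$p.value)
  }
  structure(list(psi_hat = psi_hat, psi_raw = psi_raw,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_up = sum(up_counts), n_down = sum(down_counts),
                 p_uniform = p_uniform), class = "isoform_fraction")
}

#' @export
print.isoform_fraction <- function(x, ...) {
  cat(sprintf(
    "short-isoform fraction psi_hat = %.3f  [%.3f, %.3f]  p_uniform = %.3g\n",
    x$psi_hat, x$ci_low, x$ci_high, x$p_uniform))
  invisible(x)
}

#' Proportion of a gene's expression carried by transcripts containing an exon
#'
#' A pext-style inclusion score: for each tissue, the summed TPM of
#' transcripts containing the exon divided by the summed TPM of all the
#' gene's transcripts. Tissues with zero total expression are skipped with
#' a warning.
#'
#' @param tpm Numeric matrix, transcripts x tissues.
#' @param contains_exon Logical vector, one per transcript.
#' @return list with `per_tissue` (named numeric), `mean`, `sd`.
#' @export
pext_like <- function(tpm, contains_exon) {
  stopifnot(is.matrix(tpm), length(contains_exon) == nrow(tpm))
  tot <- colSums(tpm)
  zero <- tot == 0
  if (any(zero)) {
    warning("skipping ", sum(zero), " tissue(s) with zero total expression")
  }
  inc <- colSums(tpm[contains_exon, , drop = FALSE])
  val <- inc[!zero] / tot[!zero]
  list(per_tissue = val, mean = mean(val), sd = stats::sd(val))
}

#' Per-tissue short/canonical isoform expression ratio
#'
#' @param short_tpm,canonical_tpm Named numeric vectors (tissues).
#' @param range Ratios outside this interval are flagged; default
#'   `c(0.5, 2)`, the band within which the two isoforms are considered
#'   co-expressed at comparable levels.
#' @return data.frame with `tissue`, `ratio`, `in_range`.
#' @export
isoform_ratio <- function(short_tpm, canonical_tpm, range = c(0.5, 2)) {
  stopifnot(length(short_tpm) == length(canonical_tpm))
  ratio <- ifelse(canonical_tpm > 0, short_tpm / canonical_tpm, NA_real_)
  tissues <- names(short_tpm)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_along(short_tpm))
  data.frame(tissue = tissues, ratio = ratio,
             in_range = !is.na(ratio) & ratio >= range[1L] &
                        ratio <= range[2L],
             stringsAsFactors = FALSE)
}
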