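#' Normalized spectral abundance factors
#'
#' For each run, the spectral count of a protein is divided by its length
#' in amino acids (SAF), then each SAF is divided by the sum of SAF values
#' over all proteins detected in that run, so NSAF columns sum to one and
#' approximate molar fractions. Zero-count proteins get NSAF 0 and do not
#' enter the denominator.
#'
#' @param counts Integer matrix, proteins x runs, with rownames.
#' @param lengths Named numeric vector of protein lengths (amino acids);
#'   names must cover the rownames of `counts`.
#' @return Numeric matrix of NSAF values with the shape of `counts`.
#' @export
compute_nsaf <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("spectral counts must be non-negative")
  lens <- lengths[rownames(counts)]
  if (anyNA(lens) || any(lens <= 0)) {
    stop("every protein needs a positive length")
  }
  zero_runs <- colSums(counts) == 0
  if (any(zero_runs)) {
    stop("run(s) with no identified spectra: ",
         paste(colnames(counts)[zero_runs], collapse = ", "))
  }
  saf <- counts / lens
  sweep(saf, 2L, colSums(saf), `/`)
}

#' Perseus-style differential enrichment test for IP-MS intensities
#'
#' The label-free quantification workflow: log2 transform, per-run median
#' centering, imputation of missing values from a down-shifted Gaussian
#' (per run: mean - `shift` * sd of the observed values, width
#' `width` * sd), a per-protein two-sample t-test (Welch by default), and
#' Benjamini-Hochberg adjustment with significance called at the supplied
#' FDR.
#'
#' @param quant Numeric matrix, proteins x runs, of raw intensities with
#'   `NA` for missing values.
#' @param bait_runs,control_runs Column names or indices of the two
#'   groups (at least two runs each).
#' @param fdr Significance threshold on the adjusted p-value, default 0.01.
#' @param shift,width Imputation parameters in units of the per-run sd,
#'   defaults 1.8 and 0.3.
#' @param seed Integer seed for the imputation draw.
#' @param var_equal Use Student's (pooled-variance) t-test instead of
#'   Welch's.
#' @return data.frame per protein: `log2fc` (bait - control), `p`, `q`,
#'   `significant`.
#' @export
enrichment_test <- function(quant, bait_runs, control_runs, fdr = 0.01,
                            shift = 1.8, width = 0.3, seed = 1L,
                            var_equal = FALSE) {
  stopifnot(is.matrix(quant), length(bait_runs) >= 2L,
            length(control_runs) >= 2L)
  if (any(quant <= 0, na.rm = TRUE)) {
    stop("intensities must be positive where present")
  }
  x <- log2(quant)
  x <- sweep(x, 2L, apply(x, 2L, stats::median, na.rm = TRUE), `-`)

  all_missing <- rowSums(!is.na(x[, c(bait_runs, control_runs),
                                  drop = FALSE])) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " protein(s) missing in every run of both groups")
    x <- x[!all_missing, , drop = FALSE]
  }
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      m <- mean(x[, j], na.rm = TRUE)
      s <- stats::sd(x[, j], na.rm = TRUE)
      x[miss, j] <- stats::rnorm(sum(miss), m - shift * s, width * s)
    }
  }
  b <- x[, bait_runs, drop = FALSE]
  ctl <- x[, control_runs, drop = FALSE]
  log2fc <- rowMeans(b) - rowMeans(ctl)
  p <- vapply(seq_len(nrow(x)), function(i) {
    tryCatch(stats::t.test(b[i, ], ctl[i, ], var.equal = var_equal)$p.value,
             error = function(e) NA_real_)   # zero within-group variance
  }, numeric(1L))
  p[is.na(p) & abs(log2fc) < 1e-12] <- 1     # constant and identical groups
  q <- stats::p.adjust(p, method = "BH")
  data.frame(protein = rownames(x), log2fc = log2fc, p = p, q = q,
             significant = !is.na(q) & q < fdr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bait-relative stoichiometry from NSAF values
#'
#' Within each replicate run the NSAF of every protein is divided by the
#' bait's NSAF, then ratios are averaged across replicates; the bait is 1
#' by construction. Runs where the bait was not detected are excluded
#' with a warning.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param bait_protein Rowname of the bait.
#' @param replicate_runs Column names or indices of the replicate runs;
#'   default all columns.
#' @return data.frame per protein: `mean_ratio`, `sem` (sd / sqrt(n)),
#'   `n_runs`.
#' @export
stoichiometry <- function(nsaf, bait_protein,
                          replicate_runs = colnames(nsaf)) {
  stopifnot(bait_protein %in% rownames(nsaf))
  m <- nsaf[, replicate_runs, drop = FALSE]
  bait <- m[bait_protein, ]
  usable <- bait > 0
  if (!any(usable)) stop("bait not detected in any replicate run")
  if (!all(usable)) {
    warning("excluding run(s) without bait: ",
            paste(colnames(m)[!usable], collapse = ", "))
    m <- m[, usable, drop = FALSE]
    bait <- bait[usable]
  }
  ratios <- sweep(m, 2L, bait, `/`)
  n <- ncol(ratios)
  data.frame(protein = rownames(ratios),
             mean_ratio = rowMeans(ratios),
             sem = apply(ratios, 1L, stats::sd) / sqrt(n),
             n_runs = n, row.names = NULL, stringsAsFactors = FALSE)
}
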