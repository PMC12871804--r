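#' Build a gene model
#'
#' A lightweight container tying exon/CDS structure to a genomic sequence.
#' All intervals are 0-based half-open on the plus-strand genome axis of
#' `seq`; `exons` and `cds` are listed in transcript (5'->3') order, so for
#' a minus-strand gene genomic coordinates decrease along the list.
#'
#' @param gene_id Identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` columns.
#' @param cds data.frame with `start`, `end` columns; must lie within exons.
#' @param seq The genomic sequence (single string) the coordinates index.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds, seq) {
  stopifnot(strand %in% c("+", "-"), all(exons$start < exons$end),
            all(cds$start < cds$end))
  g5 <- if (strand == "+") exons$start else -exons$end
  if (is.unsorted(g5, strictly = TRUE)) {
    stop("exons must be ordered 5'->3' in transcript orientation")
  }
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, logical(1L))
  if (!all(in_exon)) stop("cds intervals must be contained in exons")
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 cds = cds, seq = toupper(seq)),
            class = "gene_model")
}

subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$strand, "):",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

# standard codon table via Biostrings; terminators return "*"
translate_nt <- function(nt) {
  if (nchar(nt) %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# average (not monoisotopic) residue masses, Da
.aa_avg_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Average molecular weight of a peptide
#'
#' Sum of standard average residue masses plus one water; N-terminal Met is
#' counted as written and no post-translational modifications are assumed.
#'
#' @param peptide Amino-acid string (one-letter codes, no stop symbol).
#' @return Mass in Daltons.
#' @export
peptide_mw <- function(peptide) {
  aa <- strsplit(peptide, "")[[1L]]
  unknown <- setdiff(aa, names(.aa_avg_mass))
  if (length(unknown)) stop("unknown residue(s): ",
                            paste(unknown, collapse = ","))
  sum(.aa_avg_mass[aa]) + 18.01528
}

#' Predict the truncated isoform produced by an intronic cleavage site
#'
#' Translates the CDS through exons `1..last_common_exon`, then continues
#' reading codons into the downstream intron (carrying any partial codon
#' across the exon/intron boundary) until the first in-frame stop codon.
#' The residues encoded by codons containing at least one intronic
#' nucleotide form the tail peptide unique to the truncated isoform; the
#' region between the stop codon and the cleavage site is its 3'UTR.
#'
#' @param model A [gene_model()].
#' @param last_common_exon 1-based index of the last exon shared with the
#'   canonical isoform.
#' @param cleavage_site 0-based genomic position of the predicted cleavage
#'   site (exclusive transcript end on the plus strand, inclusive start
#'   boundary on the minus strand), e.g. from [predict_cleavage_site()].
#' @return A list of class `truncated_isoform` with elements `tail_peptide`,
#'   `tail_length`, `protein`, `protein_length`, `protein_mw`, `stop_codon`
#'   (0-based half-open interval), `utr3` and `utr3_length`.
#' @export
extend_orf_into_intron <- function(model, last_common_exon, cleavage_site) {
  stopifnot(inherits(model, "gene_model"),
            last_common_exon >= 1L, last_common_exon <= nrow(model$exons))
  minus <- model$strand == "-"
  ex <- model$exons[seq_len(last_common_exon), , drop = FALSE]
  # CDS segments that fall within the retained exons, transcript order
  keep <- vapply(seq_len(nrow(model$cds)), function(i) {
    any(model$cds$start[i] >= ex$start & model$cds$end[i] <= ex$end)
  }, logical(1L))
  cds <- model$cds[keep, , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS within exons 1..", last_common_exon)
  seg <- vapply(seq_len(nrow(cds)), function(i) {
    s <- subseq0(model$seq, cds$start[i], cds$end[i])
    if (minus) revcomp(s) else s
  }, character(1L))
  common_nt <- paste(seg, collapse = "")
  boundary <- if (minus) ex$start[last_common_exon] else ex$end[last_common_exon]
  if (!minus && cleavage_site <= boundary)
    stop("cleavage site must lie downstream of the last common exon")
  if (minus && cleavage_site >= boundary)
    stop("cleavage site must lie downstream of the last common exon")

  intron_nt <- if (minus) revcomp(subseq0(model$seq, cleavage_site, boundary))
               else subseq0(model$seq, boundary, cleavage_site)

  carry <- nchar(common_nt) %% 3L                  # partial codon at boundary
  n_common_codons <- nchar(common_nt) %/% 3L
  common_pep <- translate_nt(substr(common_nt, 1L, 3L * n_common_codons))
  if (grepl("\\*", common_pep)) {
    stop("stop codon within the common CDS; check the gene model")
  }

  read <- paste0(substr(common_nt, 3L * n_common_codons + 1L,
                        nchar(common_nt)), intron_nt)
  n_cod <- nchar(read) %/% 3L
  tail_aa <- character()
  stop_idx <- NA_integer_
  for (i in seq_len(n_cod)) {
    aa <- translate_nt(substr(read, 3L * i - 2L, 3L * i))
    if (aa == "*") { stop_idx <- i; break }
    tail_aa <- c(tail_aa, aa)
  }
  if (is.na(stop_idx)) {
    stop("non-stop: no in-frame stop codon before the cleavage site")
  }
  tail_peptide <- paste(tail_aa, collapse = "")
  tail_length <- length(tail_aa)

  # genomic interval of the stop codon and the 3'UTR (stop -> cleavage site)
  stop_off <- 3L * stop_idx - carry - 3L   # intronic nt preceding the stop
  if (!minus) {
    stop_iv <- c(boundary + stop_off, boundary + stop_off + 3L)
    utr3 <- c(stop_iv[2L], cleavage_site)
    utr3_length <- cleavage_site - stop_iv[2L]
  } else {
    stop_iv <- c(boundary - stop_off - 3L, boundary - stop_off)
    utr3 <- c(cleavage_site, stop_iv[1L])
    utr3_length <- stop_iv[1L] - cleavage_site
  }
  protein <- paste0(common_pep, tail_peptide)
  structure(list(
    tail_peptide = tail_peptide, tail_length = tail_length,
    protein = protein, protein_length = nchar(protein),
    protein_mw = peptide_mw(protein),
    stop_codon = stop_iv, utr3 = utr3, utr3_length = utr3_length),
    class = "truncated_isoform")
}

#' @export
print.truncated_isoform <- function(x, ...) {
  cat("truncated isoform:", x$protein_length, "aa,",
      sprintf("%.1f kDa;", x$protein_mw / 1000),
      "tail", paste0('"', x$tail_peptide, '"'),
      sprintf("(%d aa); 3'UTR %d nt\n", x$tail_length, x$utr3_length))
  invisible(x)
}
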