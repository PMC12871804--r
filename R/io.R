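#' Read repeat annotations (BED6 or RepeatMasker .out)
#'
#' Both common dialects are accepted: 6-column BED (0-based half-open,
#' name column holds `repeat_name#repeat_class` or just the name), or the
#' RepeatMasker `.out` table (1-based inclusive, with its two header lines
#' and per-hit columns including repeat name and class/family).
#'
#' @param path File path.
#' @param format `"auto"` (default), `"bed"` or `"rmsk"`.
#' @return data.frame: `chrom`, `start` (0-based), `end`, `strand`,
#'   `repeat_name`, `repeat_class`.
#' @export
read_repeat_annotation <- function(path, format = c("auto", "bed", "rmsk")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*SW\\s+", lines[seq_len(min(3, length(lines)))])) ||
                  any(grepl("perc div", lines[seq_len(min(3, length(lines)))])))
      "rmsk" else "bed"
  }
  if (format == "rmsk") {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    f <- strsplit(trimws(body), "\\s+")
    df <- data.frame(
      chrom = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)) - 1L,
      end = as.integer(vapply(f, `[`, "", 7L)),
      strand = ifelse(vapply(f, `[`, "", 9L) == "C", "-", "+"),
      repeat_name = vapply(f, `[`, "", 10L),
      repeat_class = vapply(f, `[`, "", 11L),
      stringsAsFactors = FALSE)
    return(df)
  }
  f <- strsplit(lines[nzchar(lines)], "\t")
  name <- vapply(f, function(x) if (length(x) >= 4L) x[4L] else ".", "")
  parts <- strsplit(name, "#", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    strand = vapply(f, function(x) if (length(x) >= 6L) x[6L] else "+", ""),
    repeat_name = vapply(parts, `[`, "", 1L),
    repeat_class = vapply(parts, function(p)
      if (length(p) > 1L) p[2L] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Read a tip character matrix (presence + PAS count)
#'
#' Tab-separated with header `tip  presence  pas_count`; `presence` one of
#' present/absent/lost, `pas_count` an integer or `NA` (undefined when the
#' element is absent). Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return data.frame with `tip`, `presence`, `pas_count`.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("tip", "presence", "pas_count")
  if (!all(need %in% names(df))) {
    stop("character matrix needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$presence), c("present", "absent", "lost"))
  if (length(bad)) stop("unknown presence state(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' Read exon chains from a BED12 file
#'
#' Uses rtracklayer's BED parser (blocks become exon intervals) and
#' converts each record to an [exon_chain()].
#'
#' @param path File path.
#' @return Named list of `exon_chain` objects.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- vector("list", length(gr))
  blocks <- if (!is.null(gr$blocks)) gr$blocks else NULL
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomeInfoDb::seqnames(gr)[i])
    strand <- as.character(BiocGenerics::strand(gr)[i])
    if (strand == "*") strand <- "+"
    if (!is.null(blocks)) {
      b <- blocks[[i]]
      starts <- BiocGenerics::start(gr)[i] - 1L + BiocGenerics::start(b) - 1L
      ends <- starts + BiocGenerics::width(b)
    } else {
      starts <- BiocGenerics::start(gr)[i] - 1L
      ends <- BiocGenerics::end(gr)[i]
    }
    nm <- if (!is.null(gr$name)) gr$name[i] else paste0("record", i)
    out[[i]] <- exon_chain(chrom, strand, starts, ends, name = nm)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write exon chains as BED12
#'
#' @param chains List of [exon_chain()].
#' @param path Output path.
#' @export
write_bed12 <- function(chains, path) {
  lines <- vapply(chains, function(ch) {
    s0 <- ch$starts[1L]
    paste(ch$chrom, s0, ch$ends[length(ch$ends)],
          if (is.na(ch$name)) "." else ch$name, 0, ch$strand,
          s0, ch$ends[length(ch$ends)], "0,0,0", length(ch$starts),
          paste0(paste(ch$ends - ch$starts, collapse = ","), ","),
          paste0(paste(ch$starts - s0, collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Write a junction table in the STAR `SJ.out.tab` dialect
#'
#' @param junctions data.frame as returned by [read_sj_table()] (internal
#'   0-based half-open coordinates; converted back to the on-disk 1-based
#'   inclusive dialect).
#' @param path Output path.
#' @export
write_sj_table <- function(junctions, path) {
  strand_code <- match(junctions$strand, c(".", "+", "-")) - 1L
  lines <- paste(junctions$chrom, junctions$start + 1L, junctions$end,
                 strand_code, 1L, 1L, junctions$unique_reads,
                 junctions$multi_reads, junctions$overhang, sep = "\t")
  writeLines(lines, path)
}

#' Write a table as TSV with a commented header line
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Optional comment placed above the header (units,
#'   coordinate conventions).
#' @export
write_tsv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Path to a bundled example data file
#'
#' The package ships the primate species tree with node ages and the
#' orthologous-element character matrix (element presence and AATAAA
#' count per species) used in the documentation walkthrough.
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
ipastrace_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ipastrace")))
  }
  p <- system.file("extdata", file, package = "ipastrace")
  if (!nzchar(p)) stop("no bundled file called ", file)
  p
}
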