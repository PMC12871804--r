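#' Derive a stage-specific child seed from one global seed
#'
#' One global seed fans out deterministically to per-stage seeds so each
#' simulated dataset can be regenerated independently.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (one of the generator stages).
#' @return Integer seed below 2^31.
#' @export
child_seed <- function(seed, stage) {
  stages <- c(locus = 1L, junctions = 2L, tree = 3L, spectra = 4L,
              longreads = 5L, structure = 6L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + stages[[stage]] * 104729) %%
               2147483563)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate the centre of every AATAAA occurrence outside `protected`
# ([start, end) 0-based) so planted signals are the only ones present
sanitize_pas <- function(seq, protected = NULL, motif = "AATAAA") {
  repeat {
    hits <- scan_pas(seq, motif)
    if (!is.null(protected)) {
      hits <- hits[hits$start < protected[1L] | hits$start >= protected[2L], ,
                   drop = FALSE]
    }
    if (nrow(hits) == 0L) return(seq)
    for (s in hits$start) substr(seq, s + 4L, s + 4L) <- "C"
  }
}

# A-rich tail carrying exactly n overlapping AATAAA hexamers (stride 4)
planted_pas_tail <- function(n) {
  if (n == 0L) return("AAGAAAAGAAAAGAAAAGAAAAGC")
  paste0("AATAAA", strrep("TAAA", n - 1L), "AAC")
}

#' Simulate a gene locus with a planted repeat-borne PAS
#'
#' Generates a plus-strand gene model on a random background sequence and
#' inserts, into one intron, a FLAM-like element whose A-rich 3' tail
#' carries exactly `n_planted_pas` overlapping AATAAA hexamers. Point
#' mutations (outside the planted hexamers) can then be applied. Every
#' AATAAA occurrence outside the planted set is disrupted, so the planted
#' coordinates recorded in the truth sidecar are the complete ground
#' truth for a canonical-motif scan.
#'
#' @param seed Global seed ([child_seed()] stage `"locus"`).
#' @param n_exons Number of exons, default 10.
#' @param exon_length Exon length in nt (recycled), default 120.
#' @param intron_length Intron length in nt (recycled), default 800.
#' @param alu_intron Index of the intron receiving the element, default 5.
#' @param n_planted_pas Number of overlapping canonical hexamers, default 3.
#' @param mutation_rate Per-base substitution probability applied outside
#'   the planted hexamers, default 0.
#' @param element_offset Distance from the upstream exon end to the
#'   element start, default 120 nt.
#' @param dir Optional directory: writes `locus.fa`, `locus_exons.tsv`,
#'   `repeats.bed` and `truth.json`.
#' @return list: `model` ([gene_model()]), `repeats` (annotation
#'   data.frame), `truth` (planted PAS starts, element interval, seed).
#' @export
gen_locus <- function(seed, n_exons = 10L, exon_length = 120L,
                      intron_length = 800L, alu_intron = 5L,
                      n_planted_pas = 3L, mutation_rate = 0,
                      element_offset = 120L, dir = NULL) {
  stopifnot(n_planted_pas >= 0L, alu_intron < n_exons)
  set.seed(child_seed(seed, "locus"))
  ex_len <- rep_len(exon_length, n_exons)
  in_len <- rep_len(intron_length, n_exons - 1L)
  tail_seq <- planted_pas_tail(n_planted_pas)
  element_len <- 110L + nchar(tail_seq)
  if (in_len[alu_intron] < element_offset + element_len + 10L) {
    stop("intron ", alu_intron, " too short for the planted element")
  }

  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 50L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + ex_len[i]
    pos <- ends[i] + if (i < n_exons) in_len[i] else 50L
  }
  total_len <- pos
  seq <- rand_dna(total_len)

  elem_start <- ends[alu_intron] + element_offset
  body <- rand_dna(110L)
  element <- paste0(body, tail_seq)
  substr(seq, elem_start + 1L, elem_start + nchar(element)) <- element
  n_pas_nt <- if (n_planted_pas > 0L) 6L + 4L * (n_planted_pas - 1L) else 0L
  pas_span <- c(elem_start + 110L, elem_start + 110L + n_pas_nt)
  pas_starts <- if (n_planted_pas > 0L)
    pas_span[1L] + 4L * (seq_len(n_planted_pas) - 1L) else integer()

  if (mutation_rate > 0) {
    mut <- which(stats::runif(total_len) < mutation_rate) - 1L
    mut <- mut[mut < pas_span[1L] | mut >= pas_span[2L]]
    for (p in mut) {
      cur <- substr(seq, p + 1L, p + 1L)
      substr(seq, p + 1L, p + 1L) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    cur), 1L)
    }
  }
  seq <- sanitize_pas(seq, pas_span)

  # CDS: 30 nt 5'UTR in exon 1, coding to a length divisible by 3
  cds_start <- starts[1L] + 30L
  cds <- data.frame(start = c(cds_start, starts[-1L]),
                    end = ends)
  cds_len <- sum(cds$end - cds$start)
  trim <- cds_len %% 3L
  cds$end[n_exons] <- cds$end[n_exons] - trim - 60L  # leave a 3'UTR
  model <- gene_model("simgene", "+",
                      exons = data.frame(start = starts, end = ends),
                      cds = cds, seq = seq)
  repeats <- data.frame(chrom = "simchr", start = elem_start,
                        end = elem_start + nchar(element), strand = "+",
                        repeat_name = "FLAM-C", repeat_class = "SINE/Alu",
                        stringsAsFactors = FALSE)
  truth <- list(seed = seed, stage = "locus", pas_starts = pas_starts,
                element = c(elem_start, elem_start + nchar(element)),
                n_planted_pas = n_planted_pas)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seq, "simchr")),
      file.path(dir, "locus.fa"))
    write_tsv_commented(model$exons, file.path(dir, "locus_exons.tsv"),
                        "exon intervals, 0-based half-open")
    writeLines(paste("simchr", repeats$start, repeats$end,
                     paste0(repeats$repeat_name, "#", repeats$repeat_class),
                     0, "+", sep = "\t"),
               file.path(dir, "repeats.bed"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  list(model = model, repeats = repeats, truth = truth)
}

#' The TAF8-like walkthrough locus
#'
#' A deterministic ten-exon gene emulating the anatomy behind the
#' truncated-isoform prediction: the common CDS through exon 5 encodes
#' 163 residues and ends on a codon boundary; intron 5 opens with codons
#' for the 11-residue tail peptide `VSDEALGLRVV` followed by a stop, a
#' FLAM-like element sits 120 nt into the intron, and its A-rich tail
#' carries three overlapping AATAAA hexamers positioned so the 20-nt
#' cleavage offset yields a 240-nt 3'UTR and a 174-residue truncated
#' protein.
#'
#' @param seed Seed for the random (non-designed) portions, default 42.
#' @return Same shape as [gen_locus()], with `truth` extended by the
#'   designed tail peptide and expected isoform metrics.
#' @export
taf8_like_locus <- function(seed = 42L) {
  set.seed(child_seed(seed, "locus"))
  ex_len <- c(120L, 105L, 99L, 96L, 99L, 111L, 111L, 111L, 108L, 150L)
  in_len <- rep(600L, 9L)
  n_exons <- 10L
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 50L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + ex_len[i]
    pos <- ends[i] + if (i < n_exons) in_len[i] else 50L
  }
  seq <- rand_dna(pos)

  # stop-free random codons for the CDS so translation runs clean
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    names(Biostrings::GENETIC_CODE)[
                      Biostrings::GENETIC_CODE == "*"])
  cds_start <- starts[1L] + 30L
  cds <- data.frame(start = c(cds_start, starts[2:9]), end = ends[1:9])
  cds_nt <- sum(cds$end - cds$start)            # 930 nt -> 310 residues
  coding <- paste(c("ATG", sample(codons, cds_nt / 3L - 1L,
                                  replace = TRUE)), collapse = "")
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i]
    substr(seq, cds$start[i] + 1L, cds$end[i]) <-
      substr(coding, off + 1L, off + w)
    off <- off + w
  }
  substr(seq, starts[10L] + 1L, starts[10L] + 3L) <- "TAA"

  b <- ends[5L]
  tail_nt <- paste0("GTGTCCGACGAGGCCCTGGGCCTCCGCGTGGTC", "TGA")
  substr(seq, b + 1L, b + nchar(tail_nt)) <- tail_nt     # [b, b+36)
  elem_start <- b + 120L
  substr(seq, elem_start + 1L, elem_start + 110L) <- rand_dna(110L)
  pas_block <- "AATAAATAAATAAAAAC"
  substr(seq, b + 251L, b + 250L + nchar(pas_block)) <- pas_block
  pas_starts <- b + c(250L, 254L, 258L)
  cleavage_site <- b + 276L                     # end of 1st hexamer + 20
  seq <- sanitize_pas(seq, c(b + 250L, b + 264L))

  model <- gene_model("TAF8like", "+",
                      exons = data.frame(start = starts, end = ends),
                      cds = cds, seq = seq)
  repeats <- data.frame(chrom = "simchr", start = elem_start,
                        end = b + 267L, strand = "+",
                        repeat_name = "FLAM-C", repeat_class = "SINE/Alu",
                        stringsAsFactors = FALSE)
  truth <- list(seed = seed, stage = "locus", pas_starts = pas_starts,
                element = c(elem_start, b + 267L), n_planted_pas = 3L,
                cleavage_site = cleavage_site,
                tail_peptide = "VSDEALGLRVV", tail_length = 11L,
                protein_length = 174L, utr3_length = 240L,
                last_common_exon = 5L)
  list(model = model, repeats = repeats, truth = truth)
}

#' Simulate junction counts under a two-isoform mixture
#'
#' Upstream junctions (shared by both isoforms) have expected weight 1,
#' downstream junctions (full-length only) weight `1 - psi`; counts are a
#' single multinomial draw of size `depth`, optionally with
#' extra-multinomial noise (Dirichlet-perturbed weights with variance
#' controlled by `dispersion`).
#'
#' @param seed Global seed.
#' @param psi True short-isoform fraction in `[0, 1]`.
#' @param depth Total junction-spanning reads, > 0.
#' @param n_up,n_down Numbers of shared / full-length-only junctions,
#'   defaults 4 and 5 (a ten-exon gene truncated after exon 5).
#' @param dispersion Extra-multinomial noise; 0 (default) is pure
#'   multinomial.
#' @param dir Optional directory; writes `sim.SJ.out.tab` and
#'   `truth.json`.
#' @return list: `up_counts`, `down_counts`, `junctions` (SJ-style
#'   data.frame), `truth`.
#' @export
gen_junction_counts <- function(seed, psi, depth = 10000L, n_up = 4L,
                                n_down = 5L, dispersion = 0, dir = NULL) {
  stopifnot(psi >= 0, psi <= 1, depth > 0)
  set.seed(child_seed(seed, "junctions"))
  w <- c(rep(1, n_up), rep(1 - psi, n_down))
  if (dispersion > 0) {
    w <- w * stats::rgamma(length(w), shape = 1 / dispersion,
                           rate = 1 / dispersion)
  }
  counts <- if (sum(w) == 0) rep(0L, n_up + n_down) else
    as.vector(stats::rmultinom(1L, depth, w))
  k <- n_up + n_down
  junctions <- data.frame(
    chrom = "simchr",
    start = 1000L * seq_len(k), end = 1000L * seq_len(k) + 600L,
    strand = "+", unique_reads = counts, multi_reads = 0L,
    overhang = 30L, stringsAsFactors = FALSE)
  truth <- list(seed = seed, stage = "junctions", psi = psi,
                depth = depth, n_up = n_up, n_down = n_down)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sj_table(junctions, file.path(dir, "sim.SJ.out.tab"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  list(up_counts = counts[seq_len(n_up)], down_counts = counts[-seq_len(n_up)],
       junctions = junctions, truth = truth)
}

#' Simulate element presence and PAS-count evolution on a tree
#'
#' Plants a single element insertion (on a given or uniformly drawn
#' branch), then walks the tree: below the insertion, each branch loses
#' the element with probability `loss_rate`; while present, the PAS count
#' takes +1 / -1 steps with probabilities `gain_rate` / `loss_rate`
#' (floored at 0). Tips without the element get `pas_count = NA`.
#'
#' @param seed Global seed.
#' @param tree Rooted `phylo` tree.
#' @param gain_rate,loss_rate Per-branch event probabilities.
#' @param insertion_branch Child node of the insertion branch; `NULL`
#'   draws one uniformly.
#' @param dir Optional directory; writes `characters.tsv` + `truth.json`.
#' @return list: `characters` (data.frame tip/presence/pas_count),
#'   `truth` (insertion branch, loss branches, count-event branches).
#' @export
gen_tree_characters <- function(seed, tree, gain_rate = 0.05,
                                loss_rate = 0.05, insertion_branch = NULL,
                                dir = NULL) {
  set.seed(child_seed(seed, "tree"))
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  if (is.null(insertion_branch)) {
    insertion_branch <- edges[sample(nrow(edges), 1L), 2L]
  }
  children <- node_children(tree)
  presence <- rep(FALSE, ntip + tree$Nnode)
  count <- rep(NA_integer_, ntip + tree$Nnode)
  presence[insertion_branch] <- TRUE
  count[insertion_branch] <- 1L
  loss_branches <- integer(); count_events <- list()
  walk <- function(node) {
    for (ch in children[[as.character(node)]]) {
      if (presence[node]) {
        if (stats::runif(1L) < loss_rate) {
          presence[ch] <<- FALSE
          loss_branches <<- c(loss_branches, ch)
        } else {
          presence[ch] <<- TRUE
          delta <- 0L
          u <- stats::runif(1L)
          if (u < gain_rate) delta <- 1L
          else if (u < gain_rate + loss_rate && count[node] > 0L) delta <- -1L
          count[ch] <<- count[node] + delta
          if (delta != 0L) {
            count_events[[length(count_events) + 1L]] <<-
              c(child = ch, delta = delta)
          }
        }
      }
      if (ch > ntip) walk(ch)
    }
  }
  if (insertion_branch > ntip) walk(insertion_branch)
  tips <- seq_len(ntip)
  characters <- data.frame(
    tip = tree$tip.label,
    presence = ifelse(presence[tips], "present", "absent"),
    pas_count = ifelse(presence[tips], count[tips], NA_integer_),
    stringsAsFactors = FALSE)
  truth <- list(seed = seed, stage = "tree",
                insertion_branch = insertion_branch,
                loss_branches = loss_branches,
                count_events = if (length(count_events))
                  as.data.frame(do.call(rbind, count_events)) else NULL)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_commented(characters, file.path(dir, "characters.tsv"),
                        "tip character states: presence and AATAAA count")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(characters = characters, truth = truth)
}

#' Simulate IP-MS spectral counts from a known stoichiometry
#'
#' Per run, counts are a multinomial draw with probabilities proportional
#' to abundance x protein length over the complex members plus a set of
#' low-abundance background proteins.
#'
#' @param seed Global seed.
#' @param stoichiometry Named numeric vector of relative molar abundances
#'   of the complex members (first entry conventionally the bait).
#' @param lengths Named protein lengths (amino acids) for the members.
#' @param background_proteins Number of background proteins, default 50.
#' @param background_abundance Relative abundance of each background
#'   protein, default 0.02.
#' @param depth Spectra per run, default 20000.
#' @param n_runs Replicate runs, default 3.
#' @param dir Optional directory; writes `counts.tsv` + `truth.json`.
#' @return list: `counts` (matrix), `lengths` (full named vector),
#'   `truth`.
#' @export
gen_spectral_counts <- function(seed, stoichiometry, lengths,
                                background_proteins = 50L,
                                background_abundance = 0.02,
                                depth = 20000L, n_runs = 3L, dir = NULL) {
  stopifnot(all(stoichiometry > 0), depth > 0,
            identical(names(stoichiometry), names(lengths)))
  set.seed(child_seed(seed, "spectra"))
  bg_names <- sprintf("BG%03d", seq_len(background_proteins))
  bg_len <- sample(150:1500, background_proteins, replace = TRUE)
  all_len <- c(lengths, stats::setNames(bg_len, bg_names))
  abund <- c(stoichiometry,
             stats::setNames(rep(background_abundance, background_proteins),
                             bg_names))
  prob <- abund * all_len
  counts <- stats::rmultinom(n_runs, depth, prob)
  rownames(counts) <- names(all_len)
  colnames(counts) <- paste0("run", seq_len(n_runs))
  truth <- list(seed = seed, stage = "spectra",
                stoichiometry = as.list(stoichiometry))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- data.frame(protein = rownames(counts),
                      length = all_len[rownames(counts)], counts,
                      check.names = FALSE)
    write_tsv_commented(out, file.path(dir, "counts.tsv"),
                        "spectral counts per run; length in amino acids")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  list(counts = counts, lengths = all_len, truth = truth)
}

#' Simulate long reads from isoform models
#'
#' Samples reads from the supplied exon-chain models with Gaussian jitter
#' on the transcript termini (trimmed within the terminal exons) and
#' optional junction corruption: with probability `junction_noise_rate` a
#' read has one junction coordinate shifted by `noise_shift_nt`, breaking
#' any exact junction match.
#'
#' @param seed Global seed.
#' @param models Named list of [exon_chain()] models.
#' @param n_reads_per_model Reads per model, default 50.
#' @param end_jitter_sd SD (nt) of terminal jitter, default 10.
#' @param junction_noise_rate Probability of corrupting one junction,
#'   default 0.
#' @param noise_shift_nt Size of the corruption shift, default 25.
#' @param dir Optional directory; writes `reads.bed` + `truth.json`.
#' @return list: `reads` (list of exon_chain), `truth` (`source` label
#'   per read, corruption flags).
#' @export
gen_longreads <- function(seed, models, n_reads_per_model = 50L,
                          end_jitter_sd = 10, junction_noise_rate = 0,
                          noise_shift_nt = 25L, dir = NULL) {
  set.seed(child_seed(seed, "longreads"))
  reads <- list(); src <- character(); corrupted <- logical()
  for (nm in names(models)) {
    m <- models[[nm]]
    for (r in seq_len(n_reads_per_model)) {
      starts <- m$starts; ends <- m$ends
      n <- length(starts)
      j5 <- round(stats::rnorm(1L, 0, end_jitter_sd))
      j3 <- round(stats::rnorm(1L, 0, end_jitter_sd))
      if (m$strand == "+") {
        starts[1L] <- min(max(starts[1L] + j5, starts[1L] - 3L * end_jitter_sd),
                          ends[1L] - 1L)
        ends[n] <- max(ends[n] + j3, starts[n] + 1L)
      } else {
        ends[n] <- max(ends[n] + j5, starts[n] + 1L)
        starts[1L] <- min(starts[1L] + j3, ends[1L] - 1L)
      }
      corrupt <- stats::runif(1L) < junction_noise_rate && n > 1L
      if (corrupt) {
        k <- sample(n - 1L, 1L)                  # shift intron start k
        ends[k] <- ends[k] - noise_shift_nt
      }
      reads[[length(reads) + 1L]] <-
        exon_chain(m$chrom, m$strand, starts, ends,
                   name = sprintf("%s_read%03d", nm, r))
      src <- c(src, nm); corrupted <- c(corrupted, corrupt)
    }
  }
  truth <- list(seed = seed, stage = "longreads", source = src,
                corrupted = corrupted)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bed12(reads, file.path(dir, "reads.bed"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  list(reads = reads, truth = truth)
}

#' Generate a toy atomic structure with analytically known surface areas
#'
#' Three geometries: a single atom (isolated-sphere area), two identical
#' atoms at distance `d` (spherical-cap occlusion, closed form), and a
#' central atom enclosed by a shell of partner atoms (buried fraction
#' approaching 1).
#'
#' @param seed Global seed (used only for the shell's orientation).
#' @param geometry `"single"`, `"pair"` or `"shell"`.
#' @param r Atom van der Waals radius, default 1.7.
#' @param d Pair centre distance / shell radius, default 2.5.
#' @param n_shell Shell atoms, default 60.
#' @param probe_radius Probe used for the analytic truth, default 1.4.
#' @param file Optional path; writes a PDB file (chain A = target,
#'   chain B = partners).
#' @return list: `atoms` (data.frame usable by [shrake_rupley()]),
#'   `truth` (analytic per-atom area / buried fraction where closed-form).
#' @export
gen_toy_structure <- function(seed, geometry = c("single", "pair", "shell"),
                              r = 1.7, d = 2.5, n_shell = 60L,
                              probe_radius = 1.4, file = NULL) {
  geometry <- match.arg(geometry)
  set.seed(child_seed(seed, "structure"))
  R <- r + probe_radius
  if (geometry == "single") {
    atoms <- data.frame(x = 0, y = 0, z = 0, element = "C", radius = r,
                        chain = "A", resno = 1L, resid = "GLY")
    truth <- list(area = 4 * pi * R^2)
  } else if (geometry == "pair") {
    if (d <= 0) stop("overlapping identical centres")
    atoms <- data.frame(x = c(0, d), y = 0, z = 0, element = "C",
                        radius = r, chain = c("A", "B"), resno = 1L,
                        resid = "GLY")
    cap <- if (d < 2 * R) 2 * pi * R * (R - d / 2) else 0
    truth <- list(area_per_atom = 4 * pi * R^2 - cap, cap_area = cap)
  } else {
    pts <- golden_spiral_points(n_shell) * d
    atoms <- rbind(
      data.frame(x = 0, y = 0, z = 0, element = "C", radius = r,
                 chain = "A", resno = 1L, resid = "GLY"),
      data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                 element = "C", radius = r, chain = "B",
                 resno = seq_len(n_shell), resid = "GLY"))
    truth <- list(buried_fraction_lower_bound = 0.95)
  }
  truth$seed <- seed; truth$stage <- "structure"; truth$geometry <- geometry
  if (!is.null(file)) {
    n <- nrow(atoms)
    bio3d::write.pdb(file = file,
                     xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resno, chain = atoms$chain,
                     resid = atoms$resid, elety = rep("CA", n),
                     elesy = atoms$element)
  }
  list(atoms = atoms, truth = truth)
}
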