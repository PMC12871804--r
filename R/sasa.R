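#' Bundled van der Waals radii (Angstrom)
#'
#' Standard element radii (Bondi-type compilation) used when a structure
#' file carries no radii. Unknown elements default to 1.70 A (carbon).
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
           ZN = 1.39, MG = 1.73, FE = 1.80, CA = 2.31, NA. = 2.27,
           K = 2.75, MN = 1.80, CU = 1.40)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read an atomic structure into an atom table
#'
#' Reads a PDB or mmCIF file (via bio3d), keeps heavy atoms by default
#' (cryo-EM models typically lack hydrogens), resolves alternate locations
#' to the highest-occupancy conformer, and attaches van der Waals radii.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param heavy_only Drop hydrogens; default `TRUE`.
#' @return data.frame: `x`, `y`, `z`, `element`, `radius`, `chain`,
#'   `resno`, `resid`.
#' @export
read_structure <- function(path, heavy_only = TRUE) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(a$elety), 1L, 1L)
  }
  elem <- trimws(elem)
  keep <- rep(TRUE, nrow(a))
  if (heavy_only) keep <- keep & toupper(elem) != "H"
  # alternate locations: keep the highest-occupancy conformer per atom
  if (!is.null(a$alt) && any(!is.na(a$alt) & nzchar(trimws(a$alt)))) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- if (!is.null(a$o)) a$o else rep(1, nrow(a))
    best <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    keep <- keep & seq_len(nrow(a)) %in% best
  }
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  data.frame(x = a$x, y = a$y, z = a$z, element = elem,
             radius = vdw_radius(elem), chain = a$chain, resno = a$resno,
             resid = a$resid, stringsAsFactors = FALSE)
}

# deterministic golden-spiral quadrature on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic golden-spiral quadrature of `n_points` points on
#' each atom's solvent-expanded sphere (radius + probe) and counts points
#' not occluded by any neighbouring atom's expanded sphere; the per-atom
#' area is the unoccluded fraction of `4 * pi * (r + probe)^2`. Neighbour
#' search uses a uniform spatial grid, so identical inputs give
#' bit-identical areas.
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `radius` (and
#'   optionally `chain`, `resno` for the aggregates), e.g. from
#'   [read_structure()].
#' @param probe_radius Solvent probe radius in Angstrom, default 1.4
#'   (water).
#' @param n_points Quadrature points per atom, default 960.
#' @return list of class `sasa_result`: `atom_area` (numeric vector, A^2),
#'   `total`, and when chain/resno columns are present, `by_chain` and
#'   `by_residue` data.frames.
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  stopifnot(nrow(atoms) >= 1L, all(atoms$radius > 0), probe_radius >= 0,
            all(is.finite(c(atoms$x, atoms$y, atoms$z))))
  n <- nrow(atoms)
  pts <- golden_spiral_points(n_points)
  R <- atoms$radius + probe_radius
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  cell <- 2 * max(R)
  key <- function(m) paste(floor(m[, 1L] / cell), floor(m[, 2L] / cell),
                           floor(m[, 3L] / cell))
  cells <- key(xyz)
  lookup <- split(seq_len(n), cells)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  area <- numeric(n)
  for (i in seq_len(n)) {
    ci <- c(floor(xyz[i, 1L] / cell), floor(xyz[i, 2L] / cell),
            floor(xyz[i, 3L] / cell))
    nb_keys <- paste(ci[1L] + offs[, 1L], ci[2L] + offs[, 2L],
                     ci[3L] + offs[, 3L])
    cand <- unlist(lookup[nb_keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (xyz[cand, 1L] - xyz[i, 1L])^2 +
            (xyz[cand, 2L] - xyz[i, 2L])^2 +
            (xyz[cand, 3L] - xyz[i, 3L])^2
      cand <- cand[d2 < (R[i] + R[cand])^2 & d2 > 0]
    }
    if (length(cand) == 0L) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- sweep(pts * R[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(free)) break
      dx <- sp[free, 1L] - xyz[j, 1L]
      dy <- sp[free, 2L] - xyz[j, 2L]
      dz <- sp[free, 3L] - xyz[j, 3L]
      free[free] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  out <- list(atom_area = area, total = sum(area))
  if (!is.null(atoms$chain)) {
    out$by_chain <- stats::aggregate(area,
                                     list(chain = atoms$chain), sum)
    names(out$by_chain)[2L] <- "area"
    if (!is.null(atoms$resno)) {
      out$by_residue <- stats::aggregate(
        area, list(chain = atoms$chain, resno = atoms$resno), sum)
      names(out$by_residue)[3L] <- "area"
    }
  }
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms\n", x$total,
              length(x$atom_area)))
  invisible(x)
}

#' Buried-surface fraction of a chain within a complex
#'
#' The fraction of a chain's isolated solvent-accessible surface that is
#' lost upon complex formation:
#' `(SASA(chain alone) - SASA(chain in complex)) / SASA(chain alone)`.
#'
#' @param atoms Atom table of the full complex (see [read_structure()]).
#' @param target_chain Chain identifier.
#' @inheritParams shrake_rupley
#' @return A fraction in `[0, 1]`.
#' @export
buried_fraction <- function(atoms, target_chain, probe_radius = 1.4,
                            n_points = 960L) {
  tgt <- atoms$chain == target_chain
  if (!any(tgt)) stop("chain ", target_chain, " not present")
  alone <- shrake_rupley(atoms[tgt, , drop = FALSE], probe_radius, n_points)
  if (alone$total <= 0) stop("degenerate input: chain has zero SASA")
  complexed <- shrake_rupley(atoms, probe_radius, n_points)
  in_complex <- sum(complexed$atom_area[tgt])
  max(0, (alone$total - in_complex) / alone$total)
}

#' Per-residue interface map of a target chain
#'
#' For every residue of the target chain, the surface area buried against
#' each partner chain is computed pairwise (SASA of the target alone minus
#' SASA of the target in the presence of that single partner). The main
#' interacting subunit of a residue is the partner burying the largest
#' area (ties resolved by the order of `partner_chains`); residues burying
#' nothing against any partner are unassigned, and residue numbers missing
#' from the model between the chain's first and last resolved residue are
#' reported in the unresolved mask.
#'
#' @param atoms Atom table of the full complex.
#' @param target_chain Target chain id.
#' @param partner_chains Character vector of partner chain ids, in
#'   priority order for tie-breaking.
#' @inheritParams shrake_rupley
#' @return list of class `interface_map`: `map` (data.frame `resno`,
#'   one `buried_<chain>` column per partner, `main_partner`),
#'   `unresolved` (integer vector of missing residue numbers).
#' @export
residue_interface_map <- function(atoms, target_chain, partner_chains,
                                  probe_radius = 1.4, n_points = 960L) {
  if (target_chain %in% partner_chains) {
    stop("target and partner chains must be disjoint")
  }
  known <- unique(atoms$chain)
  bad <- setdiff(c(target_chain, partner_chains), known)
  if (length(bad)) stop("unknown chain id(s): ", paste(bad, collapse = ", "))
  tgt <- atoms[atoms$chain == target_chain, , drop = FALSE]
  res <- sort(unique(tgt$resno))
  res_area <- function(sasa, sub_atoms) {
    v <- tapply(sasa$atom_area[sub_atoms$chain == target_chain],
                sub_atoms$resno[sub_atoms$chain == target_chain], sum)
    out <- stats::setNames(numeric(length(res)), res)
    out[names(v)] <- v
    out
  }
  alone <- shrake_rupley(tgt, probe_radius, n_points)
  alone_res <- res_area(alone, tgt)
  buried <- sapply(partner_chains, function(p) {
    pair <- atoms[atoms$chain %in% c(target_chain, p), , drop = FALSE]
    with_p <- shrake_rupley(pair, probe_radius, n_points)
    pmax(0, alone_res - res_area(with_p, pair))
  })
  buried <- matrix(buried, nrow = length(res),
                   dimnames = list(res, partner_chains))
  main <- apply(buried, 1L, function(b) {
    if (max(b) <= 0) NA_character_ else partner_chains[which.max(b)]
  })
  map <- data.frame(resno = res, buried, main_partner = main,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(map) <- c("resno", paste0("buried_", partner_chains), "main_partner")
  unresolved <- setdiff(seq(min(res), max(res)), res)
  structure(list(map = map, unresolved = unresolved),
            class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  assigned <- sum(!is.na(x$map$main_partner))
  cat("interface map:", nrow(x$map), "residues,", assigned,
      "at an interface,", length(x$unresolved), "unresolved\n")
  invisible(x)
}
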