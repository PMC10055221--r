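#' van der Waals radius table
#'
#' Heavy-atom element radii (Angstrom) used by the Shrake-Rupley
#' calculation. Shipped as an editable TSV (`inst/extdata/vdw_radii.tsv`);
#' this accessor reads the installed copy.
#'
#' @return named numeric vector, element symbol -> radius.
#' @export
vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.tsv", package = "resstack")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}

#' Maximum accessible surface area per residue type
#'
#' Theoretical maximum ASA values (Angstrom^2) for the 20 canonical residues
#' (Tien et al. 2013 convention), used to normalize residue SASA to relative
#' solvent accessibility. Shipped as an editable TSV
#' (`inst/extdata/max_asa.tsv`).
#'
#' @return named numeric vector, 3-letter residue code -> max ASA.
#' @export
max_asa_table <- function() {
  path <- system.file("extdata", "max_asa.tsv", package = "resstack")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$max_asa, tab$residue)
}

#' Parse ATOM records from a PDB file
#'
#' Minimal fixed-column PDB reader for the SASA stage: keeps heavy-atom ATOM
#' records (hydrogens dropped), resolves alternate locations by highest
#' occupancy (first wins on ties), and skips HETATM records unless their
#' residue name appears in `hetatm_aliases` (e.g. `c(MSE = "MET")`), in which
#' case the record is kept under the aliased residue name.
#'
#' @param path PDB file path.
#' @param hetatm_aliases named character vector mapping HETATM residue names
#'   to standard residue names.
#' @return data.frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb_atoms <- function(path, hetatm_aliases = c(MSE = "MET")) {
  if (!file.exists(path))
    stop_resstack("resstack_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) == "ATOM"
  is_het <- trimws(rec) == "HETATM"
  keep_het <- is_het & trimws(substr(lines, 18, 20)) %in% names(hetatm_aliases)
  lines <- lines[is_atom | keep_het]
  if (length(lines) == 0)
    stop_resstack("resstack_format_error", "no ATOM records in %s", path)
  fld <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    chain = fld(22, 22), resnum = as.integer(fld(23, 26)),
    icode = fld(27, 27), resname = fld(18, 20), atom = fld(13, 16),
    altloc = fld(17, 17),
    element = toupper(fld(77, 78)),
    x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    occupancy = suppressWarnings(as.numeric(fld(55, 60))),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # element fallback from the atom-name column for files without col 77-78
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[^A-Za-z]", "", atoms$atom[blank]), 1, 1)
  alias <- atoms$resname %in% names(hetatm_aliases)
  atoms$resname[alias] <- unname(hetatm_aliases[atoms$resname[alias]])
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", ]
  # alternate locations: keep the highest-occupancy conformer per atom
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom)
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$chain, atoms$resnum, atoms$icode), ]
  rownames(atoms) <- NULL
  atoms[, setdiff(names(atoms), "altloc")]
}

# deterministic golden-spiral unit sphere points (n x 3)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point SASA: each atom's van der Waals sphere is inflated by
#' the probe radius and covered with a deterministic golden-spiral point set;
#' a test point is exposed iff it lies outside every other atom's inflated
#' sphere, and the atom's SASA is the exposed fraction times the inflated
#' sphere's area. No randomness, so results are bit-stable.
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `element` (see
#'   [read_pdb_atoms()]).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_sphere_points test points per atom (default 960; doubling
#'   changes single-atom SASA by < 0.2%).
#' @param radii named vdW radius table (default [vdw_radii()]).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_sphere_points = 960L,
                          radii = vdw_radii()) {
  n <- nrow(atoms)
  if (is.null(n) || n < 1)
    stop_resstack("resstack_input_error", "need at least one atom")
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown) > 0)
    stop_resstack("resstack_radius_error",
                  "no van der Waals radius for element(s): %s",
                  paste(unknown, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop_resstack("resstack_value_error", "non-finite atom coordinates")
  r <- unname(radii[atoms$element]) + probe_radius
  pts <- golden_spiral_points(n_sphere_points)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      idx <- which(exposed)
      dj2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      exposed[idx[dj2 < r[j]^2]] <- FALSE
    }
    sasa[i] <- sum(exposed) / n_sphere_points * 4 * pi * r[i]^2
  }
  sasa
}

#' Aggregate atom SASA to residues
#'
#' Sums member-atom SASA per residue; total area is conserved.
#'
#' @param per_atom_sasa numeric vector from [shrake_rupley()].
#' @param atoms the matching atom table.
#' @return data.frame: `chain`, `resnum`, `icode`, `resname`, `sasa`.
#' @export
residue_sasa <- function(per_atom_sasa, atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "\r")
  agg <- rowsum(per_atom_sasa, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(chain = atoms$chain[first], resnum = atoms$resnum[first],
             icode = atoms$icode[first], resname = atoms$resname[first],
             sasa = agg[match(key[first], rownames(agg)), 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize residue SASA to relative solvent accessibility
#'
#' RSA = SASA / max ASA of the residue type. Values are not clipped: RSA
#' slightly above 1 can occur (e.g. chain termini) and is preserved.
#'
#' @param sasa numeric residue SASA values.
#' @param resname matching 3-letter residue codes.
#' @param table max-ASA lookup (default [max_asa_table()]).
#' @return numeric RSA vector.
#' @export
normalize_rsa <- function(sasa, resname, table = max_asa_table()) {
  unknown <- setdiff(unique(resname), names(table))
  if (length(unknown) > 0)
    stop_resstack("resstack_normalization_error",
                  "no max-ASA entry for residue(s): %s",
                  paste(unknown, collapse = ", "))
  sasa / unname(table[resname])
}

#' Per-residue RSA from a PDB file
#'
#' Convenience wrapper: [read_pdb_atoms()] then [shrake_rupley()],
#' [residue_sasa()] and [normalize_rsa()].
#'
#' @inheritParams read_pdb_atoms
#' @inheritParams shrake_rupley
#' @return data.frame: `chain`, `resnum`, `icode`, `resname`, `sasa`, `rsa`.
#' @export
pdb_rsa <- function(path, probe_radius = 1.4, n_sphere_points = 960L,
                    hetatm_aliases = c(MSE = "MET")) {
  atoms <- read_pdb_atoms(path, hetatm_aliases = hetatm_aliases)
  res <- residue_sasa(shrake_rupley(atoms, probe_radius, n_sphere_points),
                      atoms)
  res$rsa <- normalize_rsa(res$sasa, res$resname)
  res
}
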