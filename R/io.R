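METADATA_COLS <- c("atom_serial", "molecule_id", "molecule_class",
                   "residue_id", "residue_name", "region", "atom_class",
                   "face_label", "radius", "mass", "element")

#' Write a structure as PDB plus metadata sidecar
#'
#' Coordinates go to a standard PDB file (Angstrom, CRYST1 record when a box
#' is present); the per-atom annotations that PDB cannot carry go to a
#' sidecar CSV keyed by atom serial.
#'
#' @param structure A `biomass_structure`.
#' @param pdb_path Output PDB path.
#' @param metadata_path Output CSV path; default replaces the extension.
#' @return Invisibly, the two paths.
#' @export
write_structure <- function(structure, pdb_path,
                            metadata_path = sub("\\.pdb$", ".csv", pdb_path)) {
  stopifnot(is_biomass_structure(structure))
  if (nrow(structure) > 99999) {
    abort("PDB serials support at most 99999 atoms; write subsets")
  }
  box <- structure_box(structure)
  lines <- character(0)
  if (!is.null(box)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90)
  }
  chain <- LETTERS[(structure$molecule_id - 1) %% 26 + 1]
  atom_lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    structure$serial,
    substr(paste0(structure$element, seq_len(nrow(structure)) %% 10), 1, 4),
    substr(structure$residue_name, 1, 3), chain,
    structure$residue_id %% 10000,
    structure$x, structure$y, structure$z, 1, 0, structure$element)
  writeLines(c(lines, atom_lines, "END"), pdb_path)

  meta <- tibble(atom_serial = structure$serial,
                 molecule_id = structure$molecule_id,
                 molecule_class = structure$molecule_class,
                 residue_id = structure$residue_id,
                 residue_name = structure$residue_name,
                 region = structure$region,
                 atom_class = structure$atom_class,
                 face_label = structure$face_label,
                 radius = structure$radius,
                 mass = structure$mass,
                 element = structure$element)
  readr::write_csv(meta, metadata_path)
  invisible(c(pdb = pdb_path, metadata = metadata_path))
}

read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  box_nm <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]][1:3])
  tibble(serial = as.integer(substr(at, 16, 20)),
         residue_id = as.integer(substr(at, 1, 5)),
         residue_name = trimws(substr(at, 6, 10)),
         name = trimws(substr(at, 11, 15)),
         x = as.numeric(substr(at, 21, 28)) * 10,
         y = as.numeric(substr(at, 29, 36)) * 10,
         z = as.numeric(substr(at, 37, 44)) * 10,
         box = list(box_nm * 10))
}

#' Read a structure from PDB or GRO plus metadata
#'
#' Reads coordinates from a PDB (Angstrom, via bio3d) or GRO (nm, converted
#' to Angstrom) file, joins the per-atom annotation sidecar by atom serial,
#' and drops hydrogens. Serial mismatches between the two files are
#' rejected, naming the first offending serial.
#'
#' @param path PDB or GRO file.
#' @param metadata_path Sidecar CSV as written by [write_structure()].
#' @return A `biomass_structure`.
#' @export
read_structure <- function(path, metadata_path) {
  is_gro <- grepl("\\.gro$", path, ignore.case = TRUE)
  if (is_gro) {
    g <- read_gro(path)
    coords <- tibble(serial = g$serial, x = g$x, y = g$y, z = g$z,
                     element = substr(g$name, 1, 1))
    box <- g$box[[1]]
  } else {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    coords <- tibble(serial = as.integer(a$eleno),
                     x = a$x, y = a$y, z = a$z,
                     element = ifelse(is.na(a$elesy) | a$elesy == "",
                                      substr(trimws(a$elety), 1, 1),
                                      trimws(a$elesy)))
    cl <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
    box <- if (length(cl) > 0) {
      abc <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
      if (all(is.finite(abc)) && all(abc > 0)) abc else NULL
    } else NULL
  }
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  missing_serials <- setdiff(coords$serial, meta$atom_serial)
  extra_serials <- setdiff(meta$atom_serial, coords$serial)
  if (length(missing_serials) > 0 || length(extra_serials) > 0) {
    off <- c(missing_serials, extra_serials)[1]
    abort(sprintf("coordinate/metadata serial mismatch (first offending serial: %d)",
                  off))
  }
  if (anyNA(meta$molecule_class)) abort("metadata is missing molecule classes")
  if ("element" %in% names(meta)) coords$element <- NULL
  tab <- left_join(coords, meta, by = c(serial = "atom_serial"))
  tab <- tab[tab$element != "H", ]
  as_biomass_structure(tab, box = box)
}

#' Write a trajectory as DCD
#'
#' Minimal CHARMM-flavoured binary DCD (Fortran unformatted records,
#' native endianness) holding the coordinate frames in Angstrom.
#'
#' @param trajectory A `biomass_trajectory` (or list of n x 3 matrices).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dcd <- function(trajectory, path) {
  coords <- if (inherits(trajectory, "biomass_trajectory"))
    trajectory$coords else trajectory
  n_atoms <- nrow(coords[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(raw_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    raw_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- length(coords)   # NSET
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- length(coords)
  icntrl[20] <- 24L             # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "lignocontact trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(n_atoms), con, size = 4), 4)
  for (fr in coords) {
    for (k in 1:3) {
      rec(function() writeBin(as.numeric(fr[, k]), con, size = 4),
          4 * n_atoms)
    }
  }
  invisible(path)
}

#' Read a trajectory from DCD
#'
#' Reads the frames back (via bio3d) over an existing annotated structure.
#'
#' @param path DCD file.
#' @param structure The `biomass_structure` the frames belong to; atom
#'   counts must match.
#' @param dt Frame spacing in ns.
#' @return A `biomass_trajectory`.
#' @export
read_trajectory <- function(path, structure, dt = 1) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n <- ncol(xyz) / 3
  if (n != nrow(structure)) {
    abort(sprintf("trajectory has %d atoms but structure has %d",
                  n, nrow(structure)))
  }
  coords <- lapply(seq_len(nrow(xyz)), function(f) {
    matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  })
  biomass_trajectory(structure, coords, box = structure_box(structure),
                     dt = dt)
}

#' Export per-residue values in the PDB B-factor column
#'
#' Visualization export: writes the structure with a per-residue scalar
#' (e.g. mean contact number) in the beta column, the standard trick for
#' colouring a molecular view by a residue property.
#'
#' @param structure A `biomass_structure`.
#' @param values Tibble with `residue_id` and a value column (second
#'   column used).
#' @param path Output PDB path.
#' @export
write_pdb_beta <- function(structure, values, path) {
  stopifnot(is_biomass_structure(structure))
  v <- setNames(values[[2]], values$residue_id)
  beta <- unname(v[as.character(structure$residue_id)])
  beta[is.na(beta)] <- 0
  chain <- LETTERS[(structure$molecule_id - 1) %% 26 + 1]
  atom_lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    structure$serial,
    substr(paste0(structure$element, seq_len(nrow(structure)) %% 10), 1, 4),
    substr(structure$residue_name, 1, 3), chain,
    structure$residue_id %% 10000,
    structure$x, structure$y, structure$z, 1, pmin(beta, 999.99),
    structure$element)
  writeLines(c(atom_lines, "END"), path)
  invisible(path)
}
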