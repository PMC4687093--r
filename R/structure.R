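# van der Waals radii (Angstrom) and atomic masses for the heavy elements
# that occur in the coarse biomass models.
ELEMENT_RADII <- c(C = 1.70, O = 1.52, N = 1.55, S = 1.80, P = 1.80)
ELEMENT_MASSES <- c(C = 12.011, O = 15.999, N = 14.007, S = 32.06, P = 30.974)

STRUCTURE_COLS <- c("serial", "x", "y", "z", "element", "radius", "mass",
                    "molecule_id", "molecule_class", "residue_id",
                    "residue_name", "region", "atom_class", "face_label")

#' Build an annotated heavy-atom structure
#'
#' The central container of the package: one row per heavy atom, with
#' coordinates in Angstrom and per-atom annotations (molecule id and class,
#' residue, region, atom class, face label, radius, mass). Implemented as a
#' tibble subclass so the usual dplyr verbs apply; an orthorhombic box
#' (lengths in Angstrom) travels along as an attribute.
#'
#' @param atoms Data frame with at least `x`, `y`, `z`, `molecule_id` and
#'   `molecule_class`. Missing `element` defaults to carbon; `radius` and
#'   `mass` are filled from the element when absent.
#' @param box Optional orthorhombic box lengths, numeric of length 3 (Angstrom).
#' @param provenance Optional named list recorded on the object (e.g. seed).
#' @return A `biomass_structure` tibble.
#' @export
as_biomass_structure <- function(atoms, box = NULL, provenance = list()) {
  atoms <- as_tibble(atoms)
  for (col in c("x", "y", "z", "molecule_id", "molecule_class")) {
    if (!col %in% names(atoms)) abort(paste0("missing column `", col, "`"))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("coordinates must be finite")
  }
  if (anyNA(atoms$molecule_id) || anyNA(atoms$molecule_class)) {
    abort("every atom needs a molecule id and class")
  }
  if (!"element" %in% names(atoms)) atoms$element <- "C"
  if (!"radius" %in% names(atoms)) {
    atoms$radius <- unname(ELEMENT_RADII[atoms$element])
  }
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- unname(ELEMENT_MASSES[atoms$element])
  }
  if (anyNA(atoms$radius) || any(atoms$radius <= 0)) {
    abort("all atoms must have a positive radius (unknown element?)")
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"residue_id" %in% names(atoms)) atoms$residue_id <- 1L
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "UNK"
  if (!"region" %in% names(atoms)) atoms$region <- NA_character_
  if (!"atom_class" %in% names(atoms)) atoms$atom_class <- NA_character_
  if (!"face_label" %in% names(atoms)) atoms$face_label <- NA_character_
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms <- atoms[, union(STRUCTURE_COLS, names(atoms))]
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    box <- as.numeric(box)
  }
  structure(atoms,
            class = c("biomass_structure", class(tibble())),
            box = box, provenance = provenance)
}

#' @export
print.biomass_structure <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("<biomass_structure> %d heavy atoms, %d molecules%s\n",
              nrow(x), length(unique(x$molecule_id)),
              if (is.null(box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A", box[1], box[2], box[3])))
  cls <- table(x$molecule_class[!duplicated(x$molecule_id)])
  cat("  molecules:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  NextMethod()
}

#' @rdname as_biomass_structure
#' @param x Object to test.
#' @export
is_biomass_structure <- function(x) inherits(x, "biomass_structure")

structure_box <- function(structure) attr(structure, "box")

# keep class/attributes through a row subset
structure_subset <- function(structure, rows) {
  out <- as_tibble(structure)[rows, , drop = FALSE]
  as_biomass_structure(out, box = attr(structure, "box"),
                       provenance = attr(structure, "provenance"))
}

coords_matrix <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

# Resolve an atom selection to integer row indices. Accepts molecule class
# names ("cellulose"), integer row indices, or a logical mask.
resolve_atoms <- function(structure, sel) {
  if (is.character(sel)) {
    which(structure$molecule_class %in% sel)
  } else if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(structure))
    which(sel)
  } else {
    sel <- as.integer(sel)
    stopifnot(all(sel >= 1), all(sel <= nrow(structure)))
    sel
  }
}

box_or_zero <- function(structure) {
  box <- attr(structure, "box")
  if (is.null(box)) c(0, 0, 0) else box
}

#' Merge several structures into one scene
#'
#' Concatenates atom tables, renumbering serials and (optionally) molecule
#' ids so they stay unique.
#'
#' @param structures List of `biomass_structure` objects.
#' @param box Box for the combined scene.
#' @param renumber_molecules Reassign molecule ids sequentially
#'   (per input molecule) when `TRUE`.
#' @return A `biomass_structure`.
#' @export
bind_structures <- function(structures, box = NULL, renumber_molecules = TRUE) {
  stopifnot(length(structures) >= 1)
  tabs <- lapply(structures, as_tibble)
  if (renumber_molecules) {
    offset <- 0L
    for (i in seq_along(tabs)) {
      ids <- tabs[[i]]$molecule_id
      tabs[[i]]$molecule_id <- as.integer(factor(ids, levels = unique(ids))) + offset
      offset <- offset + length(unique(ids))
    }
  }
  out <- bind_rows(tabs)
  out$serial <- seq_len(nrow(out))
  as_biomass_structure(out, box = box)
}
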