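#' Normal of a (near-)planar ring
#'
#' Unit normal of the best-fit plane through the ring atoms, from the cross
#' product of the two leading principal directions of the centred
#' coordinates: exact for planar rings, robust to slight pucker.
#'
#' @param ring_xyz Numeric matrix (>= 3 rows) of ring atom coordinates.
#' @return Unit numeric vector of length 3.
#' @export
ring_normal <- function(ring_xyz) {
  ring_xyz <- as.matrix(ring_xyz)
  if (nrow(ring_xyz) < 3) abort("a ring needs at least 3 atoms")
  centred <- sweep(ring_xyz, 2, colMeans(ring_xyz))
  sv <- svd(centred)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    abort("ring atoms are collinear: no plane defined")
  }
  normalize(pracma_cross(sv$v[, 1], sv$v[, 2]))
}

#' Crossing angle between two ring planes
#'
#' Angle between the ring normals folded to `[0, 90]` degrees (a ring plane
#' has no preferred normal sign): 0 for coplanar stacking, 90 for a
#' T-shaped arrangement.
#'
#' @param ring_a,ring_b Coordinate matrices of the two rings.
#' @return Angle in degrees.
#' @examples
#' flat <- cbind(c(0, 1, 0), c(0, 0, 1), 0)
#' crossing_angle(flat, flat)  # 0
#' @export
crossing_angle <- function(ring_a, ring_b) {
  na <- ring_normal(ring_a)
  nb <- ring_normal(ring_b)
  acos(min(1, abs(sum(na * nb)))) * 180 / pi
}

# centroids + normals of all rings of given molecule classes, one row per
# (molecule, residue) with atom_class == "ring"
ring_table <- function(structure, classes) {
  rows <- which(structure$molecule_class %in% classes &
                  structure$atom_class == "ring")
  if (length(rows) == 0) return(NULL)
  tab <- as_tibble(structure)[rows, ]
  tab |>
    group_by(.data$molecule_id, .data$molecule_class, .data$residue_id) |>
    summarise(cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              xyz = list(cbind(.data$x, .data$y, .data$z)), .groups = "drop")
}

#' Stacking angles of the CBM tyrosines against biomass rings
#'
#' For every tagged CBM tyrosine ring of every enzyme, finds the closest
#' biomass ring (glucose ring of cellulose or phenolic ring of lignin) by
#' centroid distance within `partner_cutoff`, and reports the crossing
#' angle between the ring normals. Ties are broken deterministically toward
#' the smaller molecule id, then residue id.
#'
#' @param structure A `biomass_structure`.
#' @param partner_cutoff Maximum centroid distance for a pairing (Angstrom).
#' @return Tibble: `enzyme`, `residue_id` (466/492/493), `partner_class`,
#'   `partner_molecule`, `partner_residue`, `distance`, `angle`. Tyrosines
#'   without a partner in range are omitted.
#' @export
stacking_angles <- function(structure, partner_cutoff = 5) {
  tyr_rows <- which(structure$molecule_class == "enzyme" &
                      structure$region == "CBM" &
                      structure$atom_class == "ring")
  if (length(tyr_rows) == 0) abort("no tagged CBM tyrosine rings in scene")
  tyr <- as_tibble(structure)[tyr_rows, ] |>
    group_by(.data$molecule_id, .data$residue_id) |>
    summarise(cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              xyz = list(cbind(.data$x, .data$y, .data$z)), .groups = "drop")
  partners <- ring_table(structure, c("cellulose", "lignin"))
  if (is.null(partners)) {
    return(tibble(enzyme = integer(), residue_id = integer(),
                  partner_class = character(), partner_molecule = integer(),
                  partner_residue = integer(), distance = numeric(),
                  angle = numeric()))
  }
  purrr::pmap_dfr(tyr, function(molecule_id, residue_id, cx, cy, cz, xyz) {
    d <- sqrt((partners$cx - cx)^2 + (partners$cy - cy)^2 +
                (partners$cz - cz)^2)
    in_range <- which(d <= partner_cutoff)
    if (length(in_range) == 0) return(tibble())
    ord <- in_range[order(d[in_range], partners$molecule_id[in_range],
                          partners$residue_id[in_range])]
    best <- ord[1]
    tibble(enzyme = molecule_id, residue_id = residue_id,
           partner_class = partners$molecule_class[best],
           partner_molecule = partners$molecule_id[best],
           partner_residue = partners$residue_id[best],
           distance = d[best],
           angle = crossing_angle(xyz, partners$xyz[[best]]))
  })
}

#' Random-stacking reference distribution
#'
#' Folded angles between pairs of independent, uniformly random unit
#' vectors: the null distribution of crossing angles in the absence of any
#' angular preference, with analytic density sin(gamma) on `[0, 90]`
#' degrees and mean 1 radian (57.30 degrees).
#'
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return Tibble: `angle` (degrees). The analytic density is available as
#'   [stacking_reference_density()].
#' @export
random_reference_distribution <- function(n, seed = NULL) {
  stopifnot(n > 0)
  with_seed(seed, {
    u <- random_unit_vector(n)
    v <- random_unit_vector(n)
    tibble(angle = acos(pmin(1, abs(rowSums(u * v)))) * 180 / pi)
  })
}

#' @rdname random_reference_distribution
#' @param angle_deg Angles in degrees.
#' @return `stacking_reference_density`: density values (per degree)
#'   integrating to 1 over `[0, 90]`.
#' @export
stacking_reference_density <- function(angle_deg) {
  ifelse(angle_deg < 0 | angle_deg > 90, 0,
         sin(angle_deg * pi / 180) * pi / 180)
}

# principal axis (unit) of a fibril's atoms
fibril_axis <- function(structure, fibril) {
  rows <- which(structure$molecule_id == fibril)
  if (length(rows) == 0) abort("no such fibril molecule")
  xyz <- coords_matrix(structure)[rows, , drop = FALSE]
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))
  v <- normalize(sv$v[, 1])
  # SVD leaves the sign free; fix it so the axis is deterministic
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Procession lengths along a fibril face
#'
#' Projects the lignin atoms in hard contact with the chosen face onto the
#' fibril axis, merges the projected points into occupied intervals
#' (1-D single linkage with `gap_tolerance`), and reports the gaps between
#' consecutive intervals: the distances an enzyme could process along the
#' fibril before a lignin cluster blocks its path. Gaps to the fibril ends
#' are excluded from the statistics.
#'
#' @param structure A `biomass_structure`.
#' @param fibril Molecule id of the fibril.
#' @param face Face label (`"hydrophobic"` or `"hydrophilic"`).
#' @param gap_tolerance Merge distance for projected points (Angstrom).
#' @param params A [contact_params()] (hard cutoff).
#' @return A `procession_report`: list with `intervals` (tibble `start`,
#'   `end`, in Angstrom along the axis), `gaps`, `mean_gap`, `span`,
#'   `face_empty` (no lignin contact; the single span-long gap is then
#'   flagged, not averaged).
#' @export
procession_lengths <- function(structure, fibril, face, gap_tolerance = 5,
                               params = contact_params()) {
  stopifnot(is_biomass_structure(structure))
  axis <- fibril_axis(structure, fibril)
  rows_face <- which(structure$molecule_id == fibril &
                       structure$face_label == face)
  if (length(rows_face) == 0) abort("fibril has no atoms with that face label")
  xyz <- coords_matrix(structure)
  proj_face <- xyz[rows_face, , drop = FALSE] %*% axis
  span <- range(proj_face)
  rows_l <- which(structure$molecule_class == "lignin")
  touching <- integer(0)
  if (length(rows_l) > 0) {
    d <- cpp_min_dist_to_set(xyz, rows_l, rows_face, params$hard_cutoff,
                             box_or_zero(structure))
    touching <- rows_l[is.finite(d)]
  }
  if (length(touching) == 0) {
    return(structure(list(intervals = tibble(start = numeric(),
                                             end = numeric()),
                          gaps = diff(span), mean_gap = NA_real_,
                          span = diff(span), face_empty = TRUE),
                     class = "procession_report"))
  }
  p <- sort(xyz[touching, , drop = FALSE] %*% axis)
  breaks <- which(diff(p) > gap_tolerance)
  starts <- p[c(1, breaks + 1)]
  ends <- p[c(breaks, length(p))]
  gaps <- if (length(starts) > 1) starts[-1] - ends[-length(ends)] else numeric()
  structure(list(intervals = tibble(start = starts, end = ends),
                 gaps = gaps,
                 mean_gap = if (length(gaps) > 0) mean(gaps) else NA_real_,
                 span = diff(span), face_empty = FALSE),
            class = "procession_report")
}

#' @export
print.procession_report <- function(x, ...) {
  if (x$face_empty) {
    cat(sprintf("<procession_report> face free of lignin: single %.1f A gap (full span)\n",
                x$span))
  } else {
    cat(sprintf("<procession_report> %d lignin intervals, %d gaps, mean gap %.1f A over %.1f A span\n",
                nrow(x$intervals), length(x$gaps),
                if (length(x$gaps)) mean(x$gaps) else NA, x$span))
  }
  invisible(x)
}

#' Orientation of a bound enzyme relative to a fibril
#'
#' Angle between the enzyme's substrate-tunnel axis and the fibril axis:
#' parallel below 60 degrees, antiparallel above 120, perpendicular
#' between. Processive hydrolysis favours the parallel arrangement.
#'
#' @param structure A `biomass_structure`.
#' @param enzyme Enzyme molecule id (must carry tunnel tags).
#' @param fibril Fibril molecule id.
#' @param params A [contact_params()] (hard cutoff for the bound check).
#' @return Tibble: `enzyme`, `fibril`, `angle` (degrees), `orientation`;
#'   `orientation` is `NA` with zero rows kept when the enzyme is not bound
#'   to the fibril.
#' @export
enzyme_orientation <- function(structure, enzyme, fibril,
                               params = contact_params()) {
  rows_e <- which(structure$molecule_id == enzyme)
  rows_f <- which(structure$molecule_id == fibril)
  stopifnot(length(rows_e) > 0, length(rows_f) > 0)
  d <- cpp_min_dist_to_set(coords_matrix(structure), rows_e, rows_f,
                           params$hard_cutoff, box_or_zero(structure))
  if (!any(is.finite(d))) {
    return(tibble(enzyme = integer(), fibril = integer(), angle = numeric(),
                  orientation = character()))
  }
  ax_t <- tunnel_axis(structure, enzyme)
  ax_f <- fibril_axis(structure, fibril)
  ang <- acos(max(-1, min(1, sum(ax_t * ax_f)))) * 180 / pi
  orientation <- if (ang < 60) "parallel" else if (ang > 120) "antiparallel"
  else "perpendicular"
  tibble(enzyme = enzyme, fibril = fibril, angle = ang,
         orientation = orientation)
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration of one molecule's heavy atoms.
#'
#' @param structure A `biomass_structure` (or any atom table with a `mass`
#'   column; unit masses are assumed when absent).
#' @param molecule Molecule id; `NULL` uses all atoms.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, molecule = NULL) {
  tab <- as_tibble(structure)
  if (!is.null(molecule)) tab <- tab[tab$molecule_id == molecule, ]
  if (nrow(tab) == 0) abort("no atoms selected")
  m <- if ("mass" %in% names(tab)) tab$mass else rep(1, nrow(tab))
  xyz <- cbind(tab$x, tab$y, tab$z)
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' Radius of gyration over a trajectory
#'
#' @param trajectory A `biomass_trajectory`.
#' @param molecule Molecule id.
#' @return Tibble: `frame`, `rg`.
#' @export
rg_series <- function(trajectory, molecule) {
  st <- trajectory$structure
  rows <- which(st$molecule_id == molecule)
  if (length(rows) == 0) abort("no such molecule")
  m <- st$mass[rows]
  purrr::map_dfr(seq_along(trajectory$coords), function(f) {
    xyz <- trajectory$coords[[f]][rows, , drop = FALSE]
    com <- colSums(xyz * m) / sum(m)
    tibble(frame = f, rg = sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m)))
  })
}
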