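#' Gaussian density grid of an atom selection
#'
#' Sums one truncated Gaussian kernel per heavy atom,
#' \eqn{\rho(x) = \sum_i \exp(-|x - c_i|^2 / (2 r_i'^2))} with
#' \eqn{r_i' = s (r_i + a)}: the offset `a` (3 Angstrom) absorbs the
#' implicit hydrogens, the scale `s` (0.47) converts the hard-sphere radius
#' to a Gaussian width. The grid covers the selection plus the kernel
#' truncation margin and its origin is snapped to a global lattice, so
#' grids of different selections of the same scene align exactly.
#'
#' @param atoms A `biomass_structure` (or tibble with `x`, `y`, `z`,
#'   `radius`).
#' @param params A [surface_params()].
#' @param bbox Optional 2x3 matrix (min row, max row) forcing grid extent,
#'   e.g. the union box shared by interface operands.
#' @return A `density_grid`: list with `values` (3D array), `origin`,
#'   `spacing`, `params`.
#' @export
gaussian_density_grid <- function(atoms, params = surface_params(),
                                  bbox = NULL) {
  stopifnot(inherits(params, "surface_params"))
  if (nrow(atoms) == 0) abort("empty atom set")
  if (!"radius" %in% names(atoms)) abort("atoms need a `radius` column")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  h <- params$grid_spacing
  margin <- params$kernel_truncation + h
  if (is.null(bbox)) {
    bbox <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  }
  origin <- floor((bbox[1, ] - margin) / h) * h
  top <- bbox[2, ] + margin
  dims <- as.integer(ceiling((top - origin) / h)) + 1L
  values <- cpp_gaussian_grid(xyz, atoms$radius, origin, dims, h,
                              params$radius_offset, params$radius_scale,
                              params$kernel_truncation)
  structure(list(values = array(values, dim = dims), origin = origin,
                 spacing = h, params = params),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d voxels at %.2f A (max %.3f)\n",
              d[1], d[2], d[3], x$spacing, max(x$values)))
  invisible(x)
}

#' Extract the isosurface of a density grid
#'
#' Triangulates the `iso` level set of the grid by tetrahedral decomposition
#' of every grid cell (six tetrahedra per cell sharing the main diagonal)
#' with linear interpolation along crossed edges. The decomposition is the
#' same in every cell, so the mesh is watertight for any blob fully inside
#' the grid, and extraction is deterministic.
#'
#' @param grid A [gaussian_density_grid()] result.
#' @param iso Density threshold; defaults to the grid's `iso_threshold`.
#' @return A `surface_mesh`: list with `vertices` (n x 3, Angstrom) and
#'   `triangles` (m x 3, 1-based vertex indices). Empty (with a warning)
#'   when `iso` lies outside the grid value range.
#' @export
extract_isosurface <- function(grid, iso = grid$params$iso_threshold) {
  stopifnot(inherits(grid, "density_grid"))
  rng <- range(grid$values)
  if (iso <= rng[1] || iso >= rng[2]) {
    warn(sprintf("iso level %.3g outside grid range [%.3g, %.3g]: empty mesh",
                 iso, rng[1], rng[2]))
    return(structure(list(vertices = matrix(numeric(), 0, 3),
                          triangles = matrix(integer(), 0, 3)),
                     class = "surface_mesh"))
  }
  res <- cpp_isosurface(as.numeric(grid$values), dim(grid$values),
                        grid$origin, grid$spacing, iso)
  structure(list(vertices = res$vertices, triangles = res$triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.1f A^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total area of a triangle mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Sum of triangle areas in square Angstrom.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$triangles) == 0) return(0)
  V <- mesh$vertices; Tm <- mesh$triangles
  a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Gaussian-isosurface area of an atom selection
#'
#' Convenience wrapper: density grid, isosurface, area.
#'
#' @inheritParams gaussian_density_grid
#' @return Area in square Angstrom.
#' @export
gaussian_surface_area <- function(atoms, params = surface_params(),
                                  bbox = NULL) {
  mesh_area(extract_isosurface(gaussian_density_grid(atoms, params, bbox)))
}

#' Interfacial area between two atom groups
#'
#' Buried-surface identity on a common grid:
#' \eqn{I = (S_A + S_B - S_{A \cup B}) / 2}, which counts the buried area
#' once per partner. Symmetric in A and B, zero (to mesh tolerance) for
#' well-separated groups.
#'
#' @param atoms_a,atoms_b Disjoint atom tables (no shared serials).
#' @param params A [surface_params()].
#' @return Interface area in square Angstrom (can be slightly negative at
#'   mesh tolerance for separated groups).
#' @export
interface_area <- function(atoms_a, atoms_b, params = surface_params()) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) abort("empty atom group")
  if ("serial" %in% names(atoms_a) && "serial" %in% names(atoms_b) &&
      length(intersect(atoms_a$serial, atoms_b$serial)) > 0) {
    abort("atom groups overlap")
  }
  all_xyz <- rbind(cbind(atoms_a$x, atoms_a$y, atoms_a$z),
                   cbind(atoms_b$x, atoms_b$y, atoms_b$z))
  bbox <- rbind(apply(all_xyz, 2, min), apply(all_xyz, 2, max))
  s_a <- gaussian_surface_area(atoms_a, params, bbox)
  s_b <- gaussian_surface_area(atoms_b, params, bbox)
  ab <- bind_rows(as_tibble(atoms_a)[, c("x", "y", "z", "radius")],
                  as_tibble(atoms_b)[, c("x", "y", "z", "radius")])
  s_ab <- gaussian_surface_area(ab, params, bbox)
  (s_a + s_b - s_ab) / 2
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Conventional sphere-point SASA over heavy atoms: `n_points` points on a
#' deterministic golden-spiral sphere of radius `radius + probe_radius`
#' around each atom; points inside any neighbour's expanded sphere are
#' buried. This is the reference method the Gaussian-isosurface areas are
#' benchmarked against.
#'
#' @param atoms Atom table with `x`, `y`, `z`, `radius`.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere points per atom (default 500).
#' @return Total area in square Angstrom, with per-atom areas in attribute
#'   `per_atom`.
#' @export
shrake_rupley_sasa <- function(atoms, probe_radius = 1.4, n_points = 500) {
  if (nrow(atoms) == 0) abort("empty atom set")
  per <- cpp_sasa(cbind(atoms$x, atoms$y, atoms$z), atoms$radius,
                  probe_radius, as.integer(n_points))
  structure(sum(per), per_atom = per)
}

#' Face-resolved interface coverage of cellulose fibrils
#'
#' For every fibril and face class: the total Gaussian surface area of the
#' face's atoms (A_T), the interfacial area with the enzymes (A_E) and with
#' the lignins (A_L), and the coverage ratios A_E/A_T and A_L/A_T.
#'
#' @param scene A `biomass_structure` with face labels on its cellulose.
#' @param params A [surface_params()].
#' @return Tibble of class `interface_areas`: `fibril`, `face`, `a_t`,
#'   `a_e`, `a_l`, `ratio_e`, `ratio_l`.
#' @export
coverage_report <- function(scene, params = surface_params()) {
  stopifnot(is_biomass_structure(scene))
  cel <- scene[scene$molecule_class == "cellulose", ]
  if (nrow(cel) == 0) abort("scene contains no cellulose")
  if (anyNA(cel$face_label)) abort("cellulose atoms lack face labels")
  enz <- scene[scene$molecule_class == "enzyme", ]
  lig <- scene[scene$molecule_class == "lignin", ]
  combos <- distinct(as_tibble(cel)[, c("molecule_id", "face_label")])
  out <- purrr::pmap_dfr(combos, function(molecule_id, face_label) {
    face_atoms <- cel[cel$molecule_id == molecule_id &
                        cel$face_label == face_label, ]
    a_t <- gaussian_surface_area(face_atoms, params)
    a_e <- if (nrow(enz) > 0) {
      max(0, interface_area(face_atoms, enz, params))
    } else 0
    a_l <- if (nrow(lig) > 0) {
      max(0, interface_area(face_atoms, lig, params))
    } else 0
    tibble(fibril = molecule_id, face = face_label,
           a_t = a_t, a_e = a_e, a_l = a_l,
           ratio_e = a_e / a_t, ratio_l = a_l / a_t)
  })
  class(out) <- c("interface_areas", class(out))
  out
}

#' Spatially compact random atom selections
#'
#' Draws selections for surface benchmarking: each selection is the `size`
#' nearest atoms to a randomly chosen seed atom, i.e. a compact connected
#' blob of the scene.
#'
#' @param structure A `biomass_structure`.
#' @param sizes Integer vector of selection sizes.
#' @param seed RNG seed.
#' @return List of integer atom-row vectors.
#' @export
sample_atom_selections <- function(structure, sizes, seed = NULL) {
  stopifnot(all(sizes >= 1), all(sizes <= nrow(structure)))
  xyz <- coords_matrix(structure)
  with_seed(seed, {
    lapply(sizes, function(k) {
      ctr <- xyz[sample.int(nrow(xyz), 1), ]
      d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
        (xyz[, 3] - ctr[3])^2
      order(d2)[seq_len(k)]
    })
  })
}

#' Benchmark Gaussian-isosurface areas against Shrake-Rupley SASA
#'
#' Computes both areas for each selection, fits ordinary least squares
#' (Gaussian ~ SASA) and reports the correlation together with the mean
#' percentage by which the smoother Gaussian surfaces fall below SASA
#' (they smooth over the crevices between atoms).
#'
#' @param structure A `biomass_structure`.
#' @param selections List (length >= 2) of atom-row vectors, e.g. from
#'   [sample_atom_selections()].
#' @param params A [surface_params()].
#' @param probe_radius,n_points Shrake-Rupley settings.
#' @return A `surface_benchmark`: list with `pairs` (tibble: `n_atoms`,
#'   `sasa`, `gaussian`), `r`, `slope`, `intercept`,
#'   `mean_percent_deficit`.
#' @export
benchmark_vs_sasa <- function(structure, selections,
                              params = surface_params(),
                              probe_radius = 1.4, n_points = 500) {
  if (length(selections) < 2) abort("need at least two selections")
  pairs <- purrr::map_dfr(selections, function(rows) {
    atoms <- structure[rows, ]
    tibble(n_atoms = length(rows),
           sasa = as.numeric(shrake_rupley_sasa(atoms, probe_radius, n_points)),
           gaussian = gaussian_surface_area(atoms, params))
  })
  fit <- lm(gaussian ~ sasa, data = pairs)
  structure(list(pairs = pairs,
                 r = stats::cor(pairs$sasa, pairs$gaussian),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 mean_percent_deficit =
                   mean((pairs$sasa - pairs$gaussian) / pairs$sasa) * 100),
            class = "surface_benchmark")
}

#' @export
print.surface_benchmark <- function(x, ...) {
  cat(sprintf("<surface_benchmark> %d selections: r = %.5f, slope = %.4f, mean deficit = %.1f%%\n",
              nrow(x$pairs), x$r, x$slope, x$mean_percent_deficit))
  invisible(x)
}

#' @export
tidy.surface_benchmark <- function(x, ...) x$pairs

#' @export
glance.surface_benchmark <- function(x, ...) {
  tibble(r = x$r, slope = x$slope, intercept = x$intercept,
         mean_percent_deficit = x$mean_percent_deficit,
         n_selections = nrow(x$pairs))
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.4f %.4f %.4f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}
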