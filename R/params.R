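#' Soft-contact parameters
#'
#' Parameters of the sigmoid-weighted contact number
#' \deqn{C_i = \sum_{j \in B} \frac{1}{1 + \exp[k (d_{ij} - d_0)]}}
#' with steepness \eqn{k} (default 5 per Angstrom) and midpoint \eqn{d_0}
#' (default 4 Angstrom), which interpolates between hydrogen-bond-range and
#' hydrophobic-range interactions. The sum is truncated at
#' `truncation_distance`, where the weight has decayed to about 2e-9 of its
#' midpoint value. `hard_cutoff` (default 3.2 Angstrom) is the binary
#' any-heavy-atom criterion used for binding states, aggregate clustering and
#' contact lifetimes.
#'
#' @param steepness Sigmoid steepness in 1/Angstrom; must be positive.
#' @param midpoint Sigmoid midpoint in Angstrom.
#' @param truncation_distance Distance beyond which the weight is taken as
#'   zero, in Angstrom; must exceed `midpoint`.
#' @param hard_cutoff Binary contact cutoff in Angstrom.
#' @return An object of class `contact_params`.
#' @examples
#' p <- contact_params()
#' soft_contact_weight(4, p)  # 0.5 at the midpoint
#' @export
contact_params <- function(steepness = 5, midpoint = 4,
                           truncation_distance = 8, hard_cutoff = 3.2) {
  stopifnot(steepness > 0, midpoint > 0, hard_cutoff > 0)
  if (truncation_distance <= midpoint) {
    abort("`truncation_distance` must lie beyond `midpoint`")
  }
  structure(list(steepness = steepness, midpoint = midpoint,
                 truncation_distance = truncation_distance,
                 hard_cutoff = hard_cutoff),
            class = "contact_params")
}

#' Gaussian-isosurface parameters
#'
#' Controls the density-grid surface: each heavy atom contributes a Gaussian
#' kernel of width `radius_scale * (radius + radius_offset)`; the surface is
#' the `iso_threshold` level set extracted from the summed density on a grid
#' of `grid_spacing`. Defaults follow the QuickSurf-style parameterisation
#' (offset 3 Angstrom for the implicit hydrogens, scale 0.47, iso level 0.4,
#' 1.5 Angstrom production grid); the kernel is truncated at
#' `kernel_truncation`, within the 5-7 Angstrom range where it is negligible.
#'
#' @param grid_spacing Grid spacing in Angstrom.
#' @param radius_offset Added to every heavy-atom radius (Angstrom).
#' @param radius_scale Dimensionless scaling of the offset radius.
#' @param iso_threshold Density level of the extracted surface, in (0, 1).
#' @param kernel_truncation Kernel truncation distance in Angstrom (>= 5).
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(grid_spacing = 1.5, radius_offset = 3,
                           radius_scale = 0.47, iso_threshold = 0.4,
                           kernel_truncation = 6) {
  stopifnot(grid_spacing > 0, radius_offset >= 0, radius_scale > 0)
  if (iso_threshold <= 0 || iso_threshold >= 1) {
    abort("`iso_threshold` must lie in (0, 1)")
  }
  if (kernel_truncation < 5) abort("`kernel_truncation` must be >= 5 Angstrom")
  structure(list(grid_spacing = grid_spacing, radius_offset = radius_offset,
                 radius_scale = radius_scale, iso_threshold = iso_threshold,
                 kernel_truncation = kernel_truncation),
            class = "surface_params")
}

#' Lignin aggregate morphology parameters
#'
#' Operational thresholds for labelling lignin aggregates as sheets, piles or
#' linkages. An aggregate contacting two or more fibrils is a linkage; else,
#' if at least `layer_fraction_min` of its heavy atoms lie within
#' `monolayer_distance` of the contacted fibril it is a sheet (a monolayer
#' hugging the surface), otherwise a pile. `edge_threshold` is the minimum
#' soft-contact total for an edge of the molecule contact network.
#'
#' @param monolayer_distance Monolayer thickness threshold (Angstrom).
#' @param layer_fraction_min Minimum in-layer atom fraction for a sheet.
#' @param edge_threshold Minimum contact number for a network edge.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(monolayer_distance = 7, layer_fraction_min = 0.8,
                              edge_threshold = 0.5) {
  stopifnot(monolayer_distance > 0,
            layer_fraction_min > 0, layer_fraction_min <= 1,
            edge_threshold >= 0)
  structure(list(monolayer_distance = monolayer_distance,
                 layer_fraction_min = layer_fraction_min,
                 edge_threshold = edge_threshold),
            class = "morphology_params")
}

#' Brownian dynamics parameters
#'
#' Rigid-body Brownian parameters for the synthetic trajectory generator.
#' Translational steps are drawn per axis from Normal(0, 2 D_trans dt);
#' rotation steps compose small rotations about the three laboratory axes,
#' each with angle variance 2 D_rot dt, so the mean squared angular
#' displacement of a body-fixed axis grows as 4 D_rot t.
#'
#' @param d_trans Named numeric: translational diffusion constant per
#'   molecule id (cm^2/s), or a single value recycled to all molecules.
#' @param d_rot Rotational diffusion constants (rad^2/s), same conventions.
#' @param dt Frame spacing in ns.
#' @param n_frames Number of frames to generate (>= 1).
#' @param frozen_molecules Integer molecule ids held immobile.
#' @return An object of class `brownian_params`.
#' @export
brownian_params <- function(d_trans, d_rot = 0, dt = 1, n_frames = 100,
                            frozen_molecules = integer()) {
  stopifnot(all(d_trans >= 0), all(d_rot >= 0), dt > 0, n_frames >= 1)
  structure(list(d_trans = d_trans, d_rot = d_rot, dt = dt,
                 n_frames = as.integer(n_frames),
                 frozen_molecules = as.integer(frozen_molecules)),
            class = "brownian_params")
}
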