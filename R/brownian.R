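#' Trajectory container
#'
#' A sequence of coordinate frames over a fixed annotated structure.
#'
#' @param structure A `biomass_structure` (topology and annotations).
#' @param coords List of numeric n_atoms x 3 matrices, one per frame
#'   (Angstrom, wrapped into the box when one is present).
#' @param box Orthorhombic box lengths (Angstrom) or `NULL`.
#' @param dt Frame spacing in ns.
#' @param provenance Named list recorded on the object.
#' @return A `biomass_trajectory`.
#' @export
biomass_trajectory <- function(structure, coords, box = structure_box(structure),
                               dt = 1, provenance = list()) {
  stopifnot(is_biomass_structure(structure), is.list(coords),
            length(coords) >= 1)
  n <- nrow(structure)
  for (fr in coords) stopifnot(is.matrix(fr), nrow(fr) == n, ncol(fr) == 3)
  structure(list(structure = structure, coords = coords, box = box, dt = dt,
                 provenance = provenance),
            class = "biomass_trajectory")
}

#' @export
print.biomass_trajectory <- function(x, ...) {
  cat(sprintf("<biomass_trajectory> %d frames x %d atoms, dt = %g ns\n",
              length(x$coords), nrow(x$structure), x$dt))
  invisible(x)
}

#' Number of frames
#' @param trajectory A `biomass_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$coords)

#' Extract one frame as a structure
#' @param trajectory A `biomass_trajectory`.
#' @param frame Frame index (1-based).
#' @return A `biomass_structure` with that frame's coordinates.
#' @export
trajectory_frame <- function(trajectory, frame) {
  stopifnot(frame >= 1, frame <= n_frames(trajectory))
  st <- trajectory$structure
  xyz <- trajectory$coords[[frame]]
  st$x <- xyz[, 1]; st$y <- xyz[, 2]; st$z <- xyz[, 3]
  attr(st, "box") <- trajectory$box
  st
}

# Unit conversions: D in cm^2/s <-> step variance in A^2 over dt ns.
# 1 cm^2/s = 1e16 A^2 / 1e9 ns = 1e7 A^2/ns.
CM2S_TO_A2NS <- 1e7

#' Generate a rigid-body Brownian trajectory
#'
#' Evolves every molecule of `structure` as a rigid body: per frame, a
#' translation with per-axis displacement ~ Normal(0, sqrt(2 D_trans dt))
#' and a rotation about the molecule centroid composed of small rotations
#' about the three laboratory axes, each with angle ~
#' Normal(0, sqrt(2 D_rot dt)), which together realise isotropic rotational
#' diffusion with mean squared axis displacement 4 D_rot t. Molecules listed
#' in `frozen_molecules` stay immobile. Coordinates are wrapped into the box
#' by molecule centroid, so trajectories are unwrappable by minimum-image
#' accumulation.
#'
#' @param structure A `biomass_structure` with a box.
#' @param params A [brownian_params()]; `d_trans` in cm^2/s, `d_rot` in
#'   rad^2/s, `dt` in ns.
#' @param seed Seed; identical seeds give bit-identical trajectories.
#' @return A `biomass_trajectory` of `params$n_frames` frames (frame 1 is
#'   the input configuration).
#' @export
generate_brownian_trajectory <- function(structure, params, seed = NULL) {
  stopifnot(is_biomass_structure(structure), inherits(params, "brownian_params"))
  box <- structure_box(structure)
  if (is.null(box)) abort("structure needs an orthorhombic box")
  mols <- unique(structure$molecule_id)
  d_trans <- rep(params$d_trans, length.out = length(mols))
  d_rot <- rep(params$d_rot, length.out = length(mols))
  if (!is.null(names(params$d_trans))) {
    d_trans <- unname(params$d_trans[as.character(mols)])
  }
  if (!is.null(names(params$d_rot))) {
    d_rot <- unname(params$d_rot[as.character(mols)])
  }
  dt_ns <- params$dt
  sig_t <- sqrt(2 * d_trans * CM2S_TO_A2NS * dt_ns)     # A per axis per step
  sig_r <- sqrt(2 * d_rot * dt_ns * 1e-9)               # rad per axis per step
  if (any(5 * sig_t > min(box) / 4)) {
    abort("unphysical step: 5 sigma of the translational step exceeds box/4; reduce D_trans * dt")
  }
  frozen <- mols %in% params$frozen_molecules
  sig_t[frozen] <- 0; sig_r[frozen] <- 0

  rows_by_mol <- split(seq_len(nrow(structure)), structure$molecule_id)[as.character(mols)]
  xyz0 <- coords_matrix(structure)

  with_seed(seed, {
    frames <- vector("list", params$n_frames)
    # per-molecule state: centroid (unwrapped) + orientation
    cents <- lapply(rows_by_mol, function(r) colMeans(xyz0[r, , drop = FALSE]))
    locals <- lapply(seq_along(mols), function(i) {
      sweep(xyz0[rows_by_mol[[i]], , drop = FALSE], 2, cents[[i]])
    })
    rots <- lapply(mols, function(m) diag(3))
    wrap_frame <- function() {
      out <- matrix(NA_real_, nrow(structure), 3)
      for (i in seq_along(mols)) {
        cen <- cents[[i]]
        cen_w <- cen - box * floor(cen / box)
        out[rows_by_mol[[i]], ] <- sweep(locals[[i]] %*% t(rots[[i]]), 2,
                                         cen_w, `+`)
      }
      out
    }
    frames[[1]] <- wrap_frame()
    if (params$n_frames > 1) {
      for (f in 2:params$n_frames) {
        for (i in seq_along(mols)) {
          if (frozen[i]) next
          cents[[i]] <- cents[[i]] + rnorm(3, 0, sig_t[i])
          if (sig_r[i] > 0) {
            ang <- rnorm(3, 0, sig_r[i])
            step <- rotation_matrix(c(1, 0, 0), ang[1]) %*%
              rotation_matrix(c(0, 1, 0), ang[2]) %*%
              rotation_matrix(c(0, 0, 1), ang[3])
            rots[[i]] <- step %*% rots[[i]]
          }
        }
        frames[[f]] <- wrap_frame()
      }
    }
    biomass_trajectory(structure, frames, box = box, dt = dt_ns,
                       provenance = list(generator = "generate_brownian_trajectory",
                                         seed = seed,
                                         d_trans = d_trans, d_rot = d_rot,
                                         molecules = mols))
  })
}
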