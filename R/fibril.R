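#' Specify a cellulose fibril
#'
#' A coarse multi-chain cellulose fibril: `n_chains` parallel glucose-bead
#' chains of degree of polymerization `dp` on a hexagonal cross-section. Each
#' glucose monomer carries a three-atom ring-plane proxy plus one
#' hydroxyl-class oxygen, which is all the downstream geometry (ring
#' stacking, face assignment, contacts) needs. The two extreme chain rows of
#' the cross-section expose ring planes and are labelled hydrophobic; the
#' remaining chains are hydrophilic.
#'
#' @param n_chains Number of glucose chains (default 36).
#' @param dp Degree of polymerization, monomers per chain (default 160).
#' @param crystalline Logical; `FALSE` adds Gaussian positional disorder.
#' @param disorder_amplitude Per-axis standard deviation (Angstrom) of the
#'   rigid per-monomer displacement applied when not crystalline.
#' @param axis Fibril axis direction (need not be unit length).
#' @param chain_spacing Distance between neighbouring chain centres (Angstrom).
#' @param monomer_spacing Rise per glucose monomer along the axis (Angstrom),
#'   default 5.2 so a dp 160 chain spans about 832 Angstrom.
#' @return An object of class `fibril_spec`.
#' @export
fibril_spec <- function(n_chains = 36, dp = 160, crystalline = TRUE,
                        disorder_amplitude = 1.0, axis = c(0, 0, 1),
                        chain_spacing = 6.0, monomer_spacing = 5.2) {
  stopifnot(n_chains >= 1, dp >= 1, chain_spacing > 0, monomer_spacing > 0,
            disorder_amplitude >= 0)
  structure(list(n_chains = as.integer(n_chains), dp = as.integer(dp),
                 crystalline = isTRUE(crystalline),
                 disorder_amplitude = disorder_amplitude,
                 axis = normalize(axis), chain_spacing = chain_spacing,
                 monomer_spacing = monomer_spacing),
            class = "fibril_spec")
}

# hexagonal-lattice chain centres: lattice points nearest the origin
hex_chain_centers <- function(n_chains, spacing) {
  r <- ceiling(sqrt(n_chains))
  pts <- expand.grid(i = -r:r, j = -r:r)
  x <- spacing * (pts$i + 0.5 * (pts$j %% 2))
  y <- spacing * sqrt(3) / 2 * pts$j
  d <- x^2 + y^2
  keep <- order(d, y, x)[seq_len(n_chains)]
  cbind(x = x[keep] - mean(x[keep]), y = y[keep] - mean(y[keep]))
}

#' Generate a cellulose fibril structure
#'
#' Realises a [fibril_spec()] as an annotated heavy-atom structure. The ring
#' proxy of every glucose is a flat three-carbon triangle whose normal points
#' along the cross-section y axis, so the hydrophobic faces (extreme y chain
#' rows) expose ring planes, as on the real crystalline fibril surface.
#'
#' @param spec A `fibril_spec`.
#' @param seed Seed for the disorder displacements (non-crystalline only).
#' @param center Fibril centroid position, length-3 (Angstrom).
#' @param molecule_id Molecule id of the fibril.
#' @return A `biomass_structure` with `molecule_class = "cellulose"`.
#' @examples
#' fib <- generate_fibril(fibril_spec(n_chains = 7, dp = 10))
#' range(fib$z)  # ~ (10 - 1) * 5.2 Angstrom span
#' @export
generate_fibril <- function(spec, seed = NULL, center = c(0, 0, 0),
                            molecule_id = 1L) {
  stopifnot(inherits(spec, "fibril_spec"))
  with_seed(seed, {
    centers <- hex_chain_centers(spec$n_chains, spec$chain_spacing)
    ytop <- max(centers[, "y"]); ybot <- min(centers[, "y"])
    row_tol <- spec$chain_spacing * 0.4
    face <- ifelse(centers[, "y"] > ytop - row_tol |
                     centers[, "y"] < ybot + row_tol,
                   "hydrophobic", "hydrophilic")

    # per-monomer glucose template in the local frame (z = axis): a pyranose
    # ring proxy (six carbons, ring plane xz so the normal faces the
    # hydrophobic surface), the glycosidic bridge oxygen toward the next
    # monomer, and two exocyclic hydroxyl oxygens. Bonded heavy-atom
    # spacings are ~1.4-2.6 A, as in real carbohydrate heavy-atom packing.
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(1.43 * cos(th), 0, 1.43 * sin(th))
    bridge <- c(0, 0, 2.6)
    hydroxyls <- rbind(c(0, 1.4, 0), c(1.2, -1.1, 0.8))
    template <- rbind(ring, bridge, hydroxyls)
    atom_class <- c(rep("ring", 6), "glycosidic", "hydroxyl", "hydroxyl")
    element <- c(rep("C", 6), "O", "O", "O")

    n_mono <- spec$n_chains * spec$dp
    z0 <- -(spec$dp - 1) * spec$monomer_spacing / 2
    chain <- rep(seq_len(spec$n_chains), each = spec$dp)
    mono <- rep(seq_len(spec$dp), times = spec$n_chains)
    base <- cbind(centers[chain, "x"], centers[chain, "y"],
                  z0 + (mono - 1) * spec$monomer_spacing)
    if (!spec$crystalline && spec$disorder_amplitude > 0) {
      base <- base + matrix(rnorm(3 * n_mono, 0, spec$disorder_amplitude),
                            ncol = 3)
    }
    k <- nrow(template)
    xyz <- base[rep(seq_len(n_mono), each = k), ] +
      template[rep(seq_len(k), times = n_mono), ]

    # orient local z onto the requested axis
    axis <- spec$axis
    if (abs(sum(axis * c(0, 0, 1))) < 1 - 1e-12) {
      rot_axis <- normalize(pracma_cross(c(0, 0, 1), axis))
      ang <- acos(max(-1, min(1, sum(axis * c(0, 0, 1)))))
      xyz <- xyz %*% t(rotation_matrix(rot_axis, ang))
    } else if (sum(axis * c(0, 0, 1)) < 0) {
      xyz <- xyz %*% diag(c(1, -1, -1))
    }
    xyz <- sweep(xyz, 2, center, `+`)

    as_biomass_structure(
      tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = rep(element, n_mono),
             molecule_id = molecule_id, molecule_class = "cellulose",
             residue_id = rep(seq_len(n_mono), each = k),
             residue_name = "GLC",
             region = sprintf("chain_%02d", rep(chain, each = k)),
             atom_class = rep(atom_class, n_mono),
             face_label = rep(face[chain], each = k)),
      provenance = list(generator = "generate_fibril", seed = seed,
                        axis = axis, crystalline = spec$crystalline))
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a coarse multi-domain pseudo-cellulase
#'
#' Bead model of a processive cellobiohydrolase with the canonical domain
#' organisation: a globular catalytic domain (CD) carrying two tagged beads
#' that define the substrate-tunnel axis, an O-glycosylated linker, and a
#' small carbohydrate-binding module (CBM) presenting three flat tyrosine
#' rings tagged with the residue numbers 466, 492 and 493 that anchor the
#' enzyme to cellulose. Glycan beads are sugar residues of their own so that
#' residue-level contact profiles mix amino acids and sugars, as real
#' glycosylated cellulases do.
#'
#' @param seed Seed for the CD bead placement jitter.
#' @param molecule_id Molecule id.
#' @param center Enzyme centroid (Angstrom).
#' @param cd_radius Catalytic-domain radius (Angstrom).
#' @param bead_spacing Target bead spacing (Angstrom); the default 2.3
#'   approximates heavy-atom packing, which the surface computations are
#'   sensitive to.
#' @return A `biomass_structure` with `molecule_class = "enzyme"` and
#'   regions CD, linker, CBM and glycan.
#' @export
generate_pseudo_enzyme <- function(seed = NULL, molecule_id = 1L,
                                   center = c(0, 0, 0), cd_radius = 14,
                                   bead_spacing = 2.3) {
  with_seed(seed, {
    # CD: concentric Fibonacci shells at heavy-atom-like packing density
    shells <- list(matrix(c(0, 0, 0), 1, 3))
    radii <- seq(bead_spacing, cd_radius, by = bead_spacing)
    for (r in radii) {
      m <- max(6, round(4 * pi * r^2 / bead_spacing^2))
      i <- seq_len(m)
      ga <- pi * (3 - sqrt(5))
      zc <- 1 - 2 * (i - 0.5) / m
      rc <- sqrt(pmax(0, 1 - zc^2))
      shells[[length(shells) + 1]] <- cbind(r * rc * cos(ga * i),
                                            r * rc * sin(ga * i), r * zc)
    }
    cd <- do.call(rbind, shells)
    cd <- cd + matrix(rnorm(length(cd), 0, 0.25), ncol = 3)
    # tunnel axis: two tagged beads on opposite poles along x
    tunnel <- rbind(c(-(cd_radius + 1), 0, 0), c(cd_radius + 1, 0, 0))

    # linker leaves the CD along +x beyond the tunnel exit
    x0 <- cd_radius + 2
    n_link <- 12
    link <- cbind(x0 + 1.9 * seq_len(n_link), 0, 0)
    # O-glycan trisaccharide stubs on alternate linker beads
    gly_idx <- seq(1, n_link, by = 2)
    n_gly <- length(gly_idx)
    gly <- do.call(rbind, lapply(gly_idx, function(g) {
      cbind(x0 + 1.9 * g, c(1.6, 3.1, 4.6), c(0, 0.7, 0))
    }))

    # CBM: flat dense wedge beyond the linker, three tyrosine rings on its
    # flat face
    cbm_base <- c(x0 + 1.9 * (n_link + 1), 0, 0)
    gx <- as.matrix(expand.grid(x = seq(0, 7.2, by = 1.8),
                                y = c(0, 1.8),
                                z = seq(-2.7, 2.7, by = 1.8)))
    cbm <- sweep(gx, 2, c(cbm_base[1], 0, 0), `+`)
    hexagon <- function(cen, r = 1.4) {
      th <- seq(0, 2 * pi, length.out = 7)[-7]
      cbind(cen[1] + r * cos(th), cen[2] - 1.8, cen[3] + r * sin(th))
    }
    tyr_centers <- rbind(cbm_base + c(1.5, 0, -2.7), cbm_base + c(3.9, 0, 0),
                         cbm_base + c(6.3, 0, 2.7))
    tyr <- do.call(rbind, lapply(seq_len(3), function(i) hexagon(tyr_centers[i, ])))

    xyz <- rbind(cd, tunnel, link, gly, cbm, tyr)
    n_cd <- nrow(cd); n_cbm <- nrow(cbm)
    region <- c(rep("CD", n_cd + 2), rep("linker", n_link),
                rep("glycan", 3 * n_gly), rep("CBM", n_cbm + 18))
    atom_class <- c(rep("backbone", n_cd), "tunnel_entry", "tunnel_exit",
                    rep("backbone", n_link), rep("glycan", 3 * n_gly),
                    rep("backbone", n_cbm), rep("ring", 18))
    element <- ifelse(atom_class == "glycan", "O", "C")
    # residues: CD+tunnel beads 1..; linker continues; each glycan stub is a
    # sugar residue of its own; CBM beads; tyrosines keep their canonical
    # numbers 466/492/493
    residue_id <- c(seq_len(n_cd + 2), n_cd + 2 + seq_len(n_link),
                    n_cd + 2 + n_link + rep(seq_len(n_gly), each = 3),
                    n_cd + 2 + n_link + n_gly + seq_len(n_cbm),
                    rep(c(466L, 492L, 493L), each = 6))
    residue_name <- c(rep("ALA", n_cd + 2), rep("GLY", n_link),
                      rep("MAN", 3 * n_gly), rep("SER", n_cbm),
                      rep("TYR", 18))
    xyz <- sweep(xyz, 2, colMeans(xyz))
    xyz <- sweep(xyz, 2, center, `+`)
    as_biomass_structure(
      tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = element,
             molecule_id = molecule_id, molecule_class = "enzyme",
             residue_id = as.integer(residue_id), residue_name = residue_name,
             region = region, atom_class = atom_class),
      provenance = list(generator = "generate_pseudo_enzyme", seed = seed))
  })
}

#' Tunnel axis of a pseudo-enzyme
#'
#' Unit vector from the tagged tunnel-entry bead to the tunnel-exit bead.
#'
#' @param structure A `biomass_structure`.
#' @param molecule_id Enzyme molecule id.
#' @return Unit numeric vector of length 3.
#' @export
tunnel_axis <- function(structure, molecule_id) {
  rows <- structure$molecule_id == molecule_id
  a <- structure[rows & structure$atom_class == "tunnel_entry", ]
  b <- structure[rows & structure$atom_class == "tunnel_exit", ]
  if (nrow(a) != 1 || nrow(b) != 1) {
    abort("enzyme must carry exactly one tunnel_entry and one tunnel_exit bead")
  }
  normalize(c(b$x - a$x, b$y - a$y, b$z - a$z))
}
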