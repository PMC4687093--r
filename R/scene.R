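# Per-monomer guaiacyl (G-unit) template in the local frame: the aromatic
# ring C1-C6 plus O3, O4 and the methoxy carbon C10 (atom class "ring",
# all in the xz plane, normal +y) and the propanoid tail C7-C9 with O7-O9
# (atom class "chain"). Bonded spacings ~1.4 A; the small y extent
# (<= 0.8 A) lets flat-placed aggregates hug a surface without clashing.
LIGNIN_TEMPLATE <- local({
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring6 <- cbind(1.40 * cos(th), 0, 1.40 * sin(th))          # C1..C6
  o4 <- c(2.65 * cos(th[4]), 0, 2.65 * sin(th[4]))
  o3 <- c(2.65 * cos(th[3]), 0, 2.65 * sin(th[3]))
  c10 <- c(4.0 * cos(th[3]), 0.4, 4.0 * sin(th[3]))
  c7 <- c(2.65 * cos(th[1]), 0.3, 2.65 * sin(th[1]))
  c8 <- c(3.9 * cos(th[1]), -0.4, 3.9 * sin(th[1]) + 0.6)
  c9 <- c(5.0 * cos(th[1]), 0.4, 5.0 * sin(th[1]) + 1.2)
  o7 <- c7 + c(0.3, 0.8, 1.2)
  o8 <- c8 + c(0.4, 0.8, -1.1)
  o9 <- c9 + c(1.2, -0.4, 0.6)
  list(xyz = rbind(ring6, o4, o3, c10, c7, c8, c9, o7, o8, o9),
       element = c(rep("C", 6), "O", "O", "C", "C", "C", "C", "O", "O", "O"),
       atom_class = c(rep("ring", 9), rep("chain", 6)))
})

#' Embed a lignin topology in 3D
#'
#' Realises a [generate_lignin_topology()] bonding graph as a coarse bead
#' structure: monomers are placed by a self-avoiding walk over the tree, each
#' monomer carrying a flat aromatic-ring proxy (atom class `ring`) and a
#' propanoid tail (atom class `chain`). Three embedding modes shape the
#' aggregate morphologies: `blob` (3D compact, random ring orientations),
#' `flat` (walk confined to the xz plane, rings parallel to it) and
#' `extended` (flat walk biased along +x).
#'
#' @param topology A `lignin_topology`.
#' @param mode One of `"blob"`, `"flat"`, `"extended"`.
#' @param bond_length Distance between bonded monomer centres (Angstrom).
#' @param seed Seed for the walk.
#' @param molecule_id Molecule id for the resulting structure.
#' @param origin Position of the first monomer.
#' @param xlim,zlim Optional in-plane bounds (relative to `origin`) for the
#'   flat and extended walks, used to confine a sheet to a fibril face.
#' @return A `biomass_structure` with `molecule_class = "lignin"`.
#' @export
generate_lignin_structure <- function(topology,
                                      mode = c("blob", "flat", "extended"),
                                      bond_length = 4.8, seed = NULL,
                                      molecule_id = 1L, origin = c(0, 0, 0),
                                      xlim = c(-Inf, Inf),
                                      zlim = c(-Inf, Inf)) {
  mode <- match.arg(mode)
  n <- topology$monomer_count
  adj <- vector("list", n)
  for (k in seq_len(nrow(topology$linkages))) {
    i <- topology$linkages$monomer_i[k]
    j <- topology$linkages$monomer_j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # root the walk at an endpoint of the tree diameter so extended embeddings
  # reach their full contour length
  bfs_far <- function(start) {
    dist <- rep(-1L, n)
    dist[start] <- 0L
    q <- start
    while (length(q) > 0) {
      cur <- q[1]; q <- q[-1]
      for (nb in adj[[cur]]) if (dist[nb] < 0) {
        dist[nb] <- dist[cur] + 1L
        q <- c(q, nb)
      }
    }
    which.max(dist)
  }
  root <- bfs_far(bfs_far(1L))

  with_seed(seed, {
    pos <- matrix(NA_real_, n, 3)
    pos[root, ] <- origin
    queue <- root
    placed_idx <- root
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (child in adj[[cur]]) {
        if (!is.na(pos[child, 1])) next
        best <- NULL; best_min <- -Inf
        for (try in seq_len(40)) {
          dir <- switch(mode,
            blob = {
              # bias toward the centroid: a hydrophobically collapsed,
              # compact globule rather than an open coil
              r <- as.numeric(random_unit_vector())
              ctr <- colMeans(pos[placed_idx, , drop = FALSE]) - pos[cur, ]
              nc <- sqrt(sum(ctr^2))
              if (nc > 1e-9) normalize(r + 1.0 * ctr / nc) else r
            },
            flat = {
              th <- runif(1, 0, 2 * pi)
              c(cos(th), 0, sin(th))
            },
            extended = {
              th <- rnorm(1, 0, 0.45)
              c(cos(th), 0, sin(th))
            })
          cand <- pos[cur, ] + bond_length * dir
          dmin <- min(sqrt(rowSums(sweep(pos[placed_idx, , drop = FALSE],
                                         2, cand)^2)))
          if (mode != "blob" &&
              (cand[1] - origin[1] < xlim[1] || cand[1] - origin[1] > xlim[2] ||
                 cand[3] - origin[3] < zlim[1] || cand[3] - origin[3] > zlim[2])) {
            dmin <- dmin - 1e3  # out of bounds: only as a last resort
          }
          if (dmin > best_min) { best <- cand; best_min <- dmin }
          if (dmin >= 4.0) break
        }
        pos[child, ] <- best
        placed_idx <- c(placed_idx, child)
        queue <- c(queue, child)
      }
    }

    tmpl <- LIGNIN_TEMPLATE
    k <- nrow(tmpl$xyz)
    xyz <- matrix(NA_real_, n * k, 3)
    for (m in seq_len(n)) {
      local <- tmpl$xyz
      if (mode == "blob") {
        local <- local %*% t(rotation_matrix(as.numeric(random_unit_vector()),
                                             runif(1, 0, 2 * pi)))
      }
      xyz[(m - 1) * k + seq_len(k), ] <- sweep(local, 2, pos[m, ], `+`)
    }
    as_biomass_structure(
      tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = rep(tmpl$element, n),
             molecule_id = molecule_id, molecule_class = "lignin",
             residue_id = rep(seq_len(n), each = k),
             residue_name = "GUA",
             atom_class = rep(tmpl$atom_class, n)),
      provenance = list(generator = "generate_lignin_structure", mode = mode,
                        seed = seed))
  })
}

#' Specify a synthetic biomass scene
#'
#' @param fibrils List of [fibril_spec()] objects (laid out parallel along z,
#'   spaced along x).
#' @param lignin Tibble/data frame with one row per lignin aggregate:
#'   columns `morphology` (`"sheet"`, `"pile"` or `"linkage"`), `fibril`
#'   (index of the target fibril; for linkages the aggregate bridges
#'   `fibril` and `fibril + 1`), and optionally `n_molecules` and
#'   `monomer_count` (defaults 1 and 61). `NULL` for no lignin.
#' @param n_enzymes Number of pseudo-enzymes placed at random without steric
#'   clash.
#' @param box Orthorhombic box lengths (Angstrom); `NULL` sizes the box to
#'   the content plus a margin.
#' @param fibril_gap Surface-to-surface spacing between neighbouring fibrils
#'   (Angstrom).
#' @param clash_distance Minimum allowed inter-molecular heavy-atom distance.
#' @param seed Scene seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fibrils = list(fibril_spec()), lignin = NULL,
                       n_enzymes = 0, box = NULL, fibril_gap = 45,
                       clash_distance = 2.0, seed = 1L) {
  stopifnot(length(fibrils) >= 1)
  for (f in fibrils) stopifnot(inherits(f, "fibril_spec"))
  if (!is.null(lignin)) {
    lignin <- as_tibble(lignin)
    stopifnot(all(c("morphology", "fibril") %in% names(lignin)))
    if (!all(lignin$morphology %in% c("sheet", "pile", "linkage"))) {
      abort("aggregate morphology must be sheet, pile or linkage")
    }
    if (!"n_molecules" %in% names(lignin)) lignin$n_molecules <- 1L
    if (!"monomer_count" %in% names(lignin)) lignin$monomer_count <- 61L
    bad <- lignin$morphology == "linkage" & lignin$fibril >= length(fibrils)
    if (any(lignin$fibril > length(fibrils)) || any(bad)) {
      abort("aggregate targets a fibril index that does not exist")
    }
  }
  structure(list(fibrils = fibrils, lignin = lignin,
                 n_enzymes = as.integer(n_enzymes), box = box,
                 fibril_gap = fibril_gap, clash_distance = clash_distance,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Translate `mobile` along -e_y until its minimum distance to `target_xyz`
# equals `gap` (binary search on a continuous, decreasing profile).
slide_to_gap <- function(mobile_xyz, target_xyz, gap = 2.6) {
  # restrict the target to the lateral footprint of the mobile group
  keep <- target_xyz[, 1] > min(mobile_xyz[, 1]) - 12 &
    target_xyz[, 1] < max(mobile_xyz[, 1]) + 12 &
    target_xyz[, 3] > min(mobile_xyz[, 3]) - 12 &
    target_xyz[, 3] < max(mobile_xyz[, 3]) + 12
  if (any(keep)) target_xyz <- target_xyz[keep, , drop = FALSE]
  min_dist <- function(dy) {
    shifted <- mobile_xyz
    shifted[, 2] <- shifted[, 2] + dy
    min(cpp_min_dist_to_set(rbind(shifted, target_xyz),
                            seq_len(nrow(shifted)),
                            nrow(shifted) + seq_len(nrow(target_xyz)),
                            50, c(0, 0, 0)))
  }
  lo <- -(max(mobile_xyz[, 2]) - min(target_xyz[, 2])) - 1
  hi <- 0
  for (it in seq_len(45)) {
    mid <- (lo + hi) / 2
    if (min_dist(mid) > gap) hi <- mid else lo <- mid
  }
  mobile_xyz[, 2] <- mobile_xyz[, 2] + hi
  mobile_xyz
}

#' Assemble a synthetic biomass scene
#'
#' Builds the full annotated structure a trajectory analysis consumes:
#' fibrils laid out in parallel, lignin aggregates constructed so that each
#' satisfies the operational criteria of its requested morphology (sheets
#' hug a single hydrophobic face as a monolayer, piles sit on one fibril as
#' 3D blobs, linkages bridge two neighbouring fibrils), and enzymes dropped
#' at random positions and orientations, re-drawn until free of steric
#' clashes. Placement fails with an error naming the offending molecule
#' after `max_attempts` draws.
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Placement attempts per molecule before giving up.
#' @return A `biomass_structure` of the whole scene (box attached).
#' @export
assemble_scene <- function(spec, max_attempts = 200) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    parts <- list()
    mol_id <- 0L

    # --- fibrils side by side along x ---
    fib_structs <- list()
    x_cursor <- 0
    for (i in seq_along(spec$fibrils)) {
      f <- generate_fibril(spec$fibrils[[i]], seed = NULL,
                           molecule_id = mol_id + 1L)
      mol_id <- mol_id + 1L
      w <- max(f$x) - min(f$x)
      shift <- x_cursor - min(f$x)
      f$x <- f$x + shift
      x_cursor <- x_cursor + w + spec$fibril_gap
      fib_structs[[i]] <- f
    }
    fib_ids <- vapply(fib_structs, function(s) s$molecule_id[1], integer(1))
    parts <- fib_structs
    scene_xyz <- do.call(rbind, lapply(parts, coords_matrix))

    # --- lignin aggregates ---
    if (!is.null(spec$lignin)) {
      n_agg <- nrow(spec$lignin)
      lignin_prev <- NULL  # atoms of earlier aggregates: keep aggregates apart
      for (a in seq_len(n_agg)) {
        row <- spec$lignin[a, ]
        target <- fib_structs[[row$fibril]]
        # each aggregate gets its own stretch of the fibril so separately
        # requested aggregates stay distinct clusters
        z_lo <- stats::quantile(target$z, (a - 1 + 0.15) / n_agg)
        z_hi <- stats::quantile(target$z, (a - 0.15) / n_agg)
        face_rows <- which(target$face_label == "hydrophobic" &
                             target$y > mean(target$y))
        face_xyz <- coords_matrix(target)[face_rows, , drop = FALSE]
        prev_tail <- NULL
        agg_xyz <- NULL
        for (m in seq_len(row$n_molecules)) {
          top <- generate_lignin_topology(row$monomer_count, seed = NULL,
                                          molecule_id = mol_id + 1L)
          mode <- switch(row$morphology, sheet = "flat", pile = "blob",
                         linkage = "extended")
          placed <- NULL
          face_w <- diff(range(target$x[face_rows]))
          for (att in seq_len(max_attempts)) {
            lig <- if (row$morphology == "sheet") {
              generate_lignin_structure(top, mode = "flat",
                                        molecule_id = mol_id + 1L,
                                        xlim = c(-1, 1) * (face_w / 2 + 1),
                                        zlim = c(-1, 1) * ((z_hi - z_lo) / 2 + 2))
            } else {
              generate_lignin_structure(top, mode = mode,
                                        molecule_id = mol_id + 1L)
            }
            lxyz <- coords_matrix(lig)
            if (row$morphology == "linkage") {
              nxt <- fib_structs[[row$fibril + 1L]]
              # span the two fibril tops with a slanted extended chain
              t1 <- c(mean(range(target$x)), max(target$y))
              t2 <- c(mean(range(nxt$x)), max(nxt$y))
              span_z <- runif(1, z_lo, z_hi)
              lxyz <- sweep(lxyz, 2, colMeans(lxyz))
              lxyz[, 1] <- lxyz[, 1] - min(lxyz[, 1])
              slope <- (t2[2] - t1[2]) / (t2[1] - t1[1])
              lxyz[, 2] <- lxyz[, 2] + slope * lxyz[, 1]
              lxyz <- sweep(lxyz, 2, c(t1[1] - 10, t1[2] + 3.2, span_z), `+`)
            } else {
              span_z <- runif(1, z_lo, z_hi)
              cx <- mean(range(target$x)) + if (row$morphology == "pile")
                runif(1, -5, 5) else 0
              lxyz <- sweep(lxyz, 2, colMeans(lxyz))
              lxyz <- sweep(lxyz, 2, c(cx, max(target$y) + 30, span_z), `+`)
              lxyz <- slide_to_gap(lxyz, face_xyz, gap = 2.6)
            }
            # steric check against everything placed so far, contact checks
            dmin_scene <- min(cpp_min_dist_to_set(
              rbind(lxyz, scene_xyz), seq_len(nrow(lxyz)),
              nrow(lxyz) + seq_len(nrow(scene_xyz)), 5, c(0, 0, 0)))
            ok <- dmin_scene >= spec$clash_distance
            if (ok) {
              d_t <- min(cpp_min_dist_to_set(
                rbind(lxyz, coords_matrix(target)), seq_len(nrow(lxyz)),
                nrow(lxyz) + seq_len(nrow(target)), 5, c(0, 0, 0)))
              ok <- d_t <= 3.2
            }
            if (ok && row$morphology == "linkage") {
              nxt <- fib_structs[[row$fibril + 1L]]
              d_n <- min(cpp_min_dist_to_set(
                rbind(lxyz, coords_matrix(nxt)), seq_len(nrow(lxyz)),
                nrow(lxyz) + seq_len(nrow(nxt)), 5, c(0, 0, 0)))
              ok <- d_n <= 3.2
            }
            if (ok && !is.null(lignin_prev)) {
              d_sep <- min(cpp_min_dist_to_set(
                rbind(lxyz, lignin_prev), seq_len(nrow(lxyz)),
                nrow(lxyz) + seq_len(nrow(lignin_prev)), 5, c(0, 0, 0)))
              ok <- d_sep > 3.4
            }
            if (ok && !is.null(prev_tail)) {
              d_p <- min(cpp_min_dist_to_set(
                rbind(lxyz, prev_tail), seq_len(nrow(lxyz)),
                nrow(lxyz) + seq_len(nrow(prev_tail)), 5, c(0, 0, 0)))
              ok <- d_p <= 3.2
            }
            if (ok) { placed <- lig; placed$x <- lxyz[, 1]
                      placed$y <- lxyz[, 2]; placed$z <- lxyz[, 3]; break }
          }
          if (is.null(placed)) {
            abort(sprintf("could not place lignin molecule %d of aggregate %d without clashes",
                          m, a))
          }
          mol_id <- mol_id + 1L
          parts[[length(parts) + 1]] <- placed
          prev_tail <- coords_matrix(placed)
          agg_xyz <- rbind(agg_xyz, prev_tail)
          scene_xyz <- rbind(scene_xyz, prev_tail)
        }
        lignin_prev <- rbind(lignin_prev, agg_xyz)
      }
    }

    # --- enzymes: random position + orientation, clash rejection ---
    lo <- apply(scene_xyz, 2, min) - 35
    hi <- apply(scene_xyz, 2, max) + 35
    if (spec$n_enzymes > 0) {
      for (e in seq_len(spec$n_enzymes)) {
        enz0 <- generate_pseudo_enzyme(seed = NULL,
                                       molecule_id = mol_id + 1L)
        exyz0 <- sweep(coords_matrix(enz0), 2, colMeans(coords_matrix(enz0)))
        placed <- NULL
        for (att in seq_len(max_attempts)) {
          R <- rotation_matrix(as.numeric(random_unit_vector()),
                               runif(1, 0, 2 * pi))
          cen <- runif(3, lo + 20, hi - 20)
          exyz <- sweep(exyz0 %*% t(R), 2, cen, `+`)
          dmin <- min(cpp_min_dist_to_set(
            rbind(exyz, scene_xyz), seq_len(nrow(exyz)),
            nrow(exyz) + seq_len(nrow(scene_xyz)), 5, c(0, 0, 0)))
          if (dmin >= spec$clash_distance) {
            placed <- enz0
            placed$x <- exyz[, 1]; placed$y <- exyz[, 2]; placed$z <- exyz[, 3]
            break
          }
        }
        if (is.null(placed)) {
          abort(sprintf("could not place enzyme %d without steric clashes", e))
        }
        mol_id <- mol_id + 1L
        parts[[length(parts) + 1]] <- placed
        scene_xyz <- rbind(scene_xyz, coords_matrix(placed))
      }
    }

    # --- shift into the box ---
    all_tab <- bind_rows(lapply(parts, as_tibble))
    margin <- 15
    mins <- c(min(all_tab$x), min(all_tab$y), min(all_tab$z))
    all_tab$x <- all_tab$x - mins[1] + margin
    all_tab$y <- all_tab$y - mins[2] + margin
    all_tab$z <- all_tab$z - mins[3] + margin
    extent <- c(max(all_tab$x), max(all_tab$y), max(all_tab$z)) + margin
    box <- spec$box %||% extent
    if (any(extent > box + 1e-9)) {
      abort("scene content does not fit in the requested box")
    }
    all_tab$serial <- seq_len(nrow(all_tab))
    as_biomass_structure(all_tab, box = box,
                         provenance = list(generator = "assemble_scene",
                                           seed = spec$seed,
                                           fibril_ids = fib_ids))
  })
}
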