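# Independent oracles used across the suite. These deliberately avoid the
# package's compiled kernels: plain-R double loops / matrix algebra.

# O(N^2) soft-contact total (Eq.-style sigmoid weights, inter-molecular
# pairs only, optional minimum-image box, optional truncation)
brute_soft_total <- function(structure, params = contact_params(),
                             truncate = TRUE) {
  xyz <- cbind(structure$x, structure$y, structure$z)
  box <- attr(structure, "box")
  n <- nrow(xyz)
  dmat <- matrix(0, n, n)
  for (k in 1:3) {
    d <- outer(xyz[, k], xyz[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    dmat <- dmat + d^2
  }
  dmat <- sqrt(dmat)
  w <- 1 / (1 + exp(params$steepness * (dmat - params$midpoint)))
  if (truncate) w[dmat > params$truncation_distance] <- 0
  same <- outer(structure$molecule_id, structure$molecule_id, "==")
  w[same] <- 0
  sum(w) / 2
}

# brute-force inter-molecular pair distances (any-atom minimum)
brute_min_dists <- function(structure) {
  xyz <- cbind(structure$x, structure$y, structure$z)
  box <- attr(structure, "box")
  n <- nrow(xyz)
  dmat <- matrix(0, n, n)
  for (k in 1:3) {
    d <- outer(xyz[, k], xyz[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    dmat <- dmat + d^2
  }
  dmat <- sqrt(dmat)
  ids <- sort(unique(structure$molecule_id))
  out <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    ra <- structure$molecule_id == ids[a]
    rb <- structure$molecule_id == ids[b]
    out[[length(out) + 1]] <- data.frame(
      mol_i = ids[a], mol_j = ids[b],
      min_dist = min(dmat[ra, rb, drop = FALSE]))
  }
  do.call(rbind, out)
}

# connected components by hand-rolled BFS over an edge list
brute_components <- function(nodes, edge_i, edge_j) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(edge_i)) {
    a <- as.character(edge_i[k]); b <- as.character(edge_j[k])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (v in as.character(nodes)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) if (is.na(comp[nb])) {
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# tree check (connected + acyclic) by traversal, independent of igraph
is_tree <- function(n, edge_i, edge_j) {
  if (length(edge_i) != n - 1) return(FALSE)
  adj <- vector("list", n)
  for (k in seq_along(edge_i)) {
    adj[[edge_i[k]]] <- c(adj[[edge_i[k]]], edge_j[k])
    adj[[edge_j[k]]] <- c(adj[[edge_j[k]]], edge_i[k])
  }
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  all(seen)  # connected with n-1 edges => acyclic tree
}

# Exact oracle for atoms placed on a common axis: the iso-level set of the
# summed Gaussian density is a surface of revolution, so its area is the 1-D
# integral 2 pi s(x) sqrt(1 + s'(x)^2) dx with s(x) solved from the
# closed-form density (no grids, no meshes).
axisym_gaussian_area <- function(centers_x, radius, params, dx = 5e-4) {
  rp <- params$radius_scale * (radius + params$radius_offset)
  iso <- params$iso_threshold
  rho <- function(x, s) {
    out <- 0
    for (cx in centers_x) out <- out + exp(-((x - cx)^2 + s^2) / (2 * rp^2))
    out
  }
  xs <- seq(min(centers_x) - 4, max(centers_x) + 4, by = dx)
  sx <- vapply(xs, function(x) {
    f <- function(s) rho(x, s) - iso
    if (f(0) <= 0) return(NA_real_)
    stats::uniroot(f, c(0, 10), tol = 1e-12)$root
  }, numeric(1))
  ok <- !is.na(sx)
  x <- xs[ok]; s <- sx[ok]
  dsdx <- diff(s) / diff(x)
  smid <- (s[-1] + s[-length(s)]) / 2
  sum(2 * pi * smid * sqrt(1 + dsdx^2) * diff(x))
}

# small random multi-molecule scene
random_scene <- function(n_atoms, n_mols, box = NULL, span = 30,
                         classes = "lignin") {
  mol <- sample.int(n_mols, n_atoms, replace = TRUE)
  mol_class <- sample(classes, n_mols, replace = TRUE)
  as_biomass_structure(tibble::tibble(
    x = runif(n_atoms, 0, span), y = runif(n_atoms, 0, span),
    z = runif(n_atoms, 0, span),
    molecule_id = mol, molecule_class = mol_class[mol]), box = box)
}

# minimal fixture scene used by several files
demo_scene <- function(seed = 42, monomers = 25) {
  # the linkage chain must span the inter-fibril gap regardless of `monomers`
  assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 12, dp = 24),
                   fibril_spec(n_chains = 12, dp = 24)),
    lignin = tibble::tibble(morphology = c("sheet", "pile", "linkage"),
                            fibril = 1,
                            monomer_count = c(monomers, monomers,
                                              max(monomers, 35))),
    n_enzymes = 2, seed = seed))
}
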