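# Softwood linkage chemistry: average composition and which linkage types
# occur in left/right-handed forms (the 5-5' biphenyl bond is achiral).
SOFTWOOD_LINKAGE_FRACTIONS <- c("beta-O-4" = 0.5, "5-5" = 0.3,
                                "alpha-O-4" = 0.1, "beta-5" = 0.1)
CHIRAL_LINKAGE_TYPES <- c("beta-O-4", "alpha-O-4", "beta-5")

# Largest-remainder apportionment of `total` items to `fractions`.
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a constrained-random lignin topology
#'
#' Builds the bonding topology of one branched softwood-like lignin molecule:
#' a connected acyclic graph (tree) over `monomer_count` guaiacyl monomers,
#' with inter-monomer linkage types drawn to an exact per-molecule composition
#' (largest-remainder rounding of `linkage_fractions` times the number of
#' linkages) and equal numbers of left- and right-handed forms for each chiral
#' linkage type, so the molecule is optically inactive. The number of branch
#' points (monomers of degree >= 3) is drawn per molecule from
#' Binomial(`monomer_count`, `crosslink_density`), capped at feasibility, so
#' the ensemble mean equals `crosslink_density * monomer_count` (3.17 branch
#' points per 61 monomers at the softwood density 0.052).
#'
#' @param monomer_count Number of monolignol monomers (default 61).
#' @param linkage_fractions Named fractions over linkage types
#'   `beta-O-4`, `5-5`, `alpha-O-4`, `beta-5`; must sum to 1.
#' @param crosslink_density Expected fraction of monomers that are branch
#'   points (default 0.052, spruce-like).
#' @param seed Integer seed; the topology is reproducible given the seed.
#' @param molecule_id Identifier stored on the topology.
#' @return A `lignin_topology`: list with `monomer_count`, `linkages`
#'   (tibble: `monomer_i`, `monomer_j`, `linkage_type`, `chirality`),
#'   `branch_points`, `molecule_id`.
#' @examples
#' top <- generate_lignin_topology(seed = 1)
#' table(top$linkages$linkage_type)   # exactly 30/18/6/6 of the four types
#' top$branch_points
#' @export
generate_lignin_topology <- function(monomer_count = 61,
                                     linkage_fractions = SOFTWOOD_LINKAGE_FRACTIONS,
                                     crosslink_density = 0.052,
                                     seed = NULL,
                                     molecule_id = 1L) {
  n <- as.integer(monomer_count)
  if (n < 2) abort("`monomer_count` must be at least 2")
  if (abs(sum(linkage_fractions) - 1) > 1e-8) {
    abort("`linkage_fractions` must sum to 1")
  }
  if (any(linkage_fractions < 0)) abort("linkage fractions must be non-negative")
  if (is.null(names(linkage_fractions)) || any(!nzchar(names(linkage_fractions)))) {
    abort("`linkage_fractions` must be named by linkage type")
  }
  if (crosslink_density < 0 || crosslink_density * n > n - 2) {
    abort("infeasible crosslink density: density * monomers must be <= monomers - 2")
  }

  with_seed(seed, {
    b_max <- (n - 2L) %/% 2L
    b <- min(stats::rbinom(1, n, crosslink_density), b_max)

    # Tree with exactly b degree>=3 monomers: a backbone path plus b linear
    # branches attached at b distinct interior backbone positions. The
    # n - 2b - 2 monomers beyond the minimal construction are spread
    # uniformly over backbone and branches.
    extra <- n - 2L * b - 2L
    bins <- if (b > 0) {
      as.integer(stats::rmultinom(1, extra, rep(1, b + 1L)))
    } else c(extra)
    backbone_len <- b + 2L + bins[1]
    branch_len <- if (b > 0) 1L + bins[-1] else integer()

    edges_i <- integer(0); edges_j <- integer(0)
    # backbone path over nodes 1..backbone_len
    if (backbone_len > 1) {
      edges_i <- c(edges_i, seq_len(backbone_len - 1L))
      edges_j <- c(edges_j, seq_len(backbone_len - 1L) + 1L)
    }
    nxt <- backbone_len + 1L
    if (b > 0) {
      interior <- seq(2L, backbone_len - 1L)
      attach_at <- sample(interior, b)
      for (k in seq_len(b)) {
        chain <- seq.int(nxt, nxt + branch_len[k] - 1L)
        edges_i <- c(edges_i, attach_at[k], chain[-length(chain)])
        edges_j <- c(edges_j, chain)
        nxt <- nxt + branch_len[k]
      }
    }
    # randomize monomer labels so branch positions vary along the chain
    perm <- sample.int(n)
    edges_i <- perm[edges_i]
    edges_j <- perm[edges_j]

    m <- n - 1L
    counts <- largest_remainder(linkage_fractions, m)
    types <- sample(rep(names(linkage_fractions), counts))
    chirality <- rep("none", m)
    for (ty in intersect(CHIRAL_LINKAGE_TYPES, names(linkage_fractions))) {
      rows <- which(types == ty)
      k <- length(rows)
      if (k == 0) next
      hands <- c(rep("L", k %/% 2), rep("R", k %/% 2))
      if (k %% 2 == 1) hands <- c(hands, sample(c("L", "R"), 1))
      chirality[rows] <- sample(hands)
    }

    deg <- tabulate(c(edges_i, edges_j), nbins = n)
    structure(list(
      monomer_count = n,
      linkages = tibble(monomer_i = edges_i, monomer_j = edges_j,
                        linkage_type = types, chirality = chirality),
      branch_points = sum(deg >= 3L),
      molecule_id = molecule_id,
      seed = seed
    ), class = "lignin_topology")
  })
}

#' @export
print.lignin_topology <- function(x, ...) {
  cat(sprintf("<lignin_topology> %d monomers, %d linkages, %d branch points\n",
              x$monomer_count, nrow(x$linkages), x$branch_points))
  print(table(x$linkages$linkage_type))
  invisible(x)
}

#' @export
tidy.lignin_topology <- function(x, ...) x$linkages

#' @export
glance.lignin_topology <- function(x, ...) {
  tab <- table(factor(x$linkages$linkage_type,
                      levels = unique(x$linkages$linkage_type)))
  tibble(monomer_count = x$monomer_count,
         n_linkages = nrow(x$linkages),
         branch_points = x$branch_points,
         beta_o4_fraction = mean(x$linkages$linkage_type == "beta-O-4"))
}

#' Check the structural invariants of a lignin topology
#'
#' Verifies that the linkage graph is a tree (connected, acyclic, n - 1
#' edges), that the stored branch-point count matches the degree sequence,
#' and that left/right-handed counts balance (within 1 for odd totals) for
#' every chiral linkage type.
#'
#' @param topology A `lignin_topology`.
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
validate_lignin_topology <- function(topology) {
  n <- topology$monomer_count
  lk <- topology$linkages
  if (nrow(lk) != n - 1) abort("linkage count must equal monomer_count - 1")
  g <- igraph::graph_from_edgelist(cbind(lk$monomer_i, lk$monomer_j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1) abort("topology is not connected")
  if (igraph::girth(g)$girth != Inf) abort("topology contains a cycle")
  deg <- igraph::degree(g)
  if (sum(deg >= 3) != topology$branch_points) {
    abort("stored branch_points disagrees with the degree sequence")
  }
  for (ty in intersect(CHIRAL_LINKAGE_TYPES, unique(lk$linkage_type))) {
    h <- lk$chirality[lk$linkage_type == ty]
    if (any(!h %in% c("L", "R"))) abort("chiral linkage without handedness")
    if (abs(sum(h == "L") - sum(h == "R")) > 1) {
      abort(paste0("unbalanced chirality for ", ty))
    }
  }
  if (any(lk$chirality[lk$linkage_type == "5-5"] != "none")) {
    abort("5-5 linkages are achiral")
  }
  invisible(TRUE)
}

#' Generate an ensemble of lignin topologies
#'
#' @inheritParams generate_lignin_topology
#' @param n_molecules Number of distinct molecules to generate.
#' @return List of `lignin_topology` objects (class `lignin_ensemble`).
#' @export
generate_lignin_ensemble <- function(n_molecules,
                                     monomer_count = 61,
                                     linkage_fractions = SOFTWOOD_LINKAGE_FRACTIONS,
                                     crosslink_density = 0.052,
                                     seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(n_molecules), function(i) {
      generate_lignin_topology(monomer_count, linkage_fractions,
                               crosslink_density, seed = NULL,
                               molecule_id = i)
    })
    structure(out, class = "lignin_ensemble")
  })
}

#' Per-molecule summary of a lignin ensemble
#'
#' @param ensemble A list of `lignin_topology` objects.
#' @return Tibble with one row per molecule: branch points and per-type
#'   linkage counts.
#' @export
lignin_ensemble_stats <- function(ensemble) {
  purrr::map_dfr(ensemble, function(top) {
    lk <- top$linkages
    tibble(molecule_id = top$molecule_id,
           monomer_count = top$monomer_count,
           n_linkages = nrow(lk),
           branch_points = top$branch_points,
           n_beta_o4 = sum(lk$linkage_type == "beta-O-4"),
           n_55 = sum(lk$linkage_type == "5-5"),
           n_alpha_o4 = sum(lk$linkage_type == "alpha-O-4"),
           n_beta_5 = sum(lk$linkage_type == "beta-5"))
  })
}

#' Write a lignin topology to JSON
#'
#' @param topology A `lignin_topology`.
#' @param path Output file.
#' @export
write_lignin_topology <- function(topology, path) {
  jsonlite::write_json(
    list(monomer_count = topology$monomer_count,
         molecule_id = topology$molecule_id,
         branch_points = topology$branch_points,
         linkages = topology$linkages),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
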