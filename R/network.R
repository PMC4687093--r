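#' Build the molecule-level contact network
#'
#' Nodes are molecules (cellulose fibrils, lignins, enzymes); an undirected
#' edge joins two molecules whose total soft-contact number exceeds
#' `edge_threshold`, weighted by that number. In crowded biomass scenes this
#' graph becomes fully interconnected, with the fibrils acting as hubs and
#' lignin/enzyme molecules as the glue between them.
#'
#' @param contacts A [contact_number()] result (or its `pair_totals`
#'   tibble).
#' @param structure The `biomass_structure` the contacts came from (for
#'   node classes).
#' @param edge_threshold Minimum contact number for an edge.
#' @return A `contact_network`: igraph graph with vertex attributes `name`
#'   (molecule id) and `class`, and edge attribute `weight`.
#' @export
build_network <- function(contacts, structure, edge_threshold = 0.5) {
  pt <- if (inherits(contacts, "contact_result")) contacts$pair_totals else
    as_tibble(contacts)
  stopifnot(all(c("mol_i", "mol_j", "total") %in% names(pt)))
  cls <- molecule_classes(structure)
  keep <- pt[pt$total > edge_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(keep$mol_i),
               to = as.character(keep$mol_j),
               weight = keep$total),
    directed = FALSE,
    vertices = data.frame(name = names(cls), class = unname(cls)))
  class(g) <- c("contact_network", class(g))
  g
}

#' Connectivity summary of a contact network
#'
#' @param network A [build_network()] result.
#' @return List: `n_components`, `largest_fraction` (fraction of molecules
#'   in the largest component), `degree_by_class` (tibble: `class`,
#'   `mean_degree`, `max_degree`, `n`).
#' @export
connectivity_summary <- function(network) {
  comp <- igraph::components(network)
  deg <- igraph::degree(network)
  by_cls <- tibble(class = igraph::V(network)$class, degree = deg) |>
    group_by(.data$class) |>
    summarise(mean_degree = mean(.data$degree),
              max_degree = max(.data$degree), n = dplyr::n(),
              .groups = "drop")
  list(n_components = comp$no,
       largest_fraction = max(comp$csize) / igraph::vcount(network),
       degree_by_class = by_cls)
}

#' Cluster lignin molecules into aggregates
#'
#' Single-linkage clustering at the hard contact cutoff: two lignin
#' molecules belong to the same aggregate when any heavy-atom pair between
#' them is within `hard_cutoff`; aggregates are the connected components of
#' that relation.
#'
#' @param structure A `biomass_structure`.
#' @param params A [contact_params()].
#' @return Tibble: `molecule_id`, `aggregate_id`.
#' @export
cluster_lignin_aggregates <- function(structure, params = contact_params()) {
  stopifnot(is_biomass_structure(structure))
  lig_ids <- unique(structure$molecule_id[structure$molecule_class == "lignin"])
  if (length(lig_ids) == 0) {
    return(tibble(molecule_id = integer(), aggregate_id = integer()))
  }
  rows_l <- which(structure$molecule_class == "lignin")
  pairs <- cpp_hard_contact_pairs(coords_matrix(structure),
                                  structure$molecule_id,
                                  rows_l, rows_l,
                                  params$hard_cutoff, box_or_zero(structure))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$mol_i),
               to = as.character(pairs$mol_j)),
    directed = FALSE, vertices = data.frame(name = as.character(lig_ids)))
  comp <- igraph::components(g)
  tibble(molecule_id = as.integer(igraph::V(g)$name),
         aggregate_id = as.integer(comp$membership)) |>
    arrange(.data$molecule_id)
}

#' Classify the morphology of one lignin aggregate
#'
#' Decision rules over the aggregate's relation to the cellulose fibrils:
#' contact (hard cutoff) with two or more fibrils makes a linkage; contact
#' with exactly one makes a sheet when at least `layer_fraction_min` of the
#' aggregate's heavy atoms lie within `monolayer_distance` of that fibril
#' (a monolayer hugging the surface) and a pile otherwise; an aggregate
#' touching no fibril is labelled free.
#'
#' @param structure A `biomass_structure`.
#' @param members Lignin molecule ids forming the aggregate.
#' @param params A [morphology_params()].
#' @param contact A [contact_params()] for the hard cutoff.
#' @return List: `morphology` (`"sheet"`, `"pile"`, `"linkage"` or
#'   `"free"`), `fibrils_contacted`, `layer_fraction`.
#' @export
classify_morphology <- function(structure, members,
                                params = morphology_params(),
                                contact = contact_params()) {
  rows_a <- which(structure$molecule_id %in% members)
  stopifnot(length(rows_a) > 0)
  rows_c <- which(structure$molecule_class == "cellulose")
  box <- box_or_zero(structure)
  xyz <- coords_matrix(structure)
  if (length(rows_c) == 0) {
    return(list(morphology = "free", fibrils_contacted = integer(),
                layer_fraction = NA_real_))
  }
  pairs <- cpp_hard_contact_pairs(xyz, structure$molecule_id,
                                  rows_a, rows_c, contact$hard_cutoff, box)
  cel_ids <- unique(structure$molecule_id[rows_c])
  touched <- intersect(unique(c(pairs$mol_i, pairs$mol_j)), cel_ids)
  if (length(touched) == 0) {
    return(list(morphology = "free", fibrils_contacted = integer(),
                layer_fraction = NA_real_))
  }
  if (length(touched) >= 2) {
    return(list(morphology = "linkage", fibrils_contacted = touched,
                layer_fraction = NA_real_))
  }
  rows_f <- which(structure$molecule_id == touched)
  d <- cpp_min_dist_to_set(xyz, rows_a, rows_f,
                           params$monolayer_distance, box)
  layer_fraction <- mean(is.finite(d))
  morph <- if (layer_fraction >= params$layer_fraction_min) "sheet" else "pile"
  list(morphology = morph, fibrils_contacted = touched,
       layer_fraction = layer_fraction)
}

#' Morphology table of all lignin aggregates
#'
#' Clusters the lignins and classifies every aggregate.
#'
#' @param structure A `biomass_structure`.
#' @param params A [morphology_params()].
#' @param contact A [contact_params()].
#' @return Tibble: `aggregate_id`, `members` (list column of molecule ids),
#'   `n_molecules`, `n_fibrils_contacted`, `layer_fraction`, `morphology`.
#' @export
lignin_morphologies <- function(structure, params = morphology_params(),
                                contact = contact_params()) {
  agg <- cluster_lignin_aggregates(structure, contact)
  if (nrow(agg) == 0) {
    return(tibble(aggregate_id = integer(), members = list(),
                  n_molecules = integer(), n_fibrils_contacted = integer(),
                  layer_fraction = numeric(), morphology = character()))
  }
  agg |>
    group_by(.data$aggregate_id) |>
    summarise(members = list(.data$molecule_id), .groups = "drop") |>
    mutate(cls = purrr::map(.data$members, function(m) {
      classify_morphology(structure, m, params, contact)
    }),
    n_molecules = lengths(.data$members),
    n_fibrils_contacted = purrr::map_int(.data$cls, function(x)
      length(x$fibrils_contacted)),
    layer_fraction = purrr::map_dbl(.data$cls, "layer_fraction"),
    morphology = purrr::map_chr(.data$cls, "morphology")) |>
    select(-"cls")
}

#' Exposed lignin surface per morphology
#'
#' Mean exposed (not cellulose-buried) Gaussian surface area of lignin
#' aggregates, grouped by morphology: the aggregate's total Gaussian area
#' minus its interfacial area with the contacted cellulose. Extended
#' morphologies (sheets, linkages) expose more surface per unit lignin than
#' compact piles, which is what makes them better enzyme traps.
#'
#' @param structure A `biomass_structure`.
#' @param morphologies A [lignin_morphologies()] table.
#' @param params A [surface_params()].
#' @return Tibble: `morphology`, `n_aggregates`, `mean_exposed_area`,
#'   `mean_total_area`.
#' @export
exposure_per_morphology <- function(structure, morphologies,
                                    params = surface_params()) {
  if (nrow(morphologies) == 0) {
    return(tibble(morphology = character(), n_aggregates = integer(),
                  mean_exposed_area = numeric(), mean_total_area = numeric()))
  }
  cel <- structure[structure$molecule_class == "cellulose", ]
  per <- purrr::pmap_dfr(
    morphologies[, c("aggregate_id", "members", "morphology")],
    function(aggregate_id, members, morphology) {
      atoms <- structure[structure$molecule_id %in% members, ]
      total <- gaussian_surface_area(atoms, params)
      buried <- if (nrow(cel) > 0 && morphology != "free") {
        max(0, interface_area(atoms, cel, params))
      } else 0
      tibble(aggregate_id = aggregate_id, morphology = morphology,
             total_area = total, exposed_area = total - buried)
    })
  per |>
    group_by(.data$morphology) |>
    summarise(n_aggregates = dplyr::n(),
              mean_exposed_area = mean(.data$exposed_area),
              mean_total_area = mean(.data$total_area), .groups = "drop")
}

#' Export a contact network
#'
#' @param network A `contact_network`.
#' @param path Output path; format from extension (`.graphml` or `.csv`
#'   edge list).
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    readr::write_csv(el, path)
  }
  invisible(path)
}
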