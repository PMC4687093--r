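#' Sigmoid contact weight
#'
#' The soft contact weight \eqn{w(d) = 1 / (1 + e^{k(d - d_0)})}: 0.5 at the
#' midpoint, close to 1 inside hydrogen-bond range, decaying smoothly through
#' hydrophobic-interaction range, and truncated to exactly zero beyond
#' `truncation_distance` (where it has decayed to ~2e-9 at the defaults).
#'
#' @param distance Non-negative distance(s) in Angstrom.
#' @param params A [contact_params()].
#' @return Weights in `[0, 1)`, vectorised over `distance`.
#' @examples
#' soft_contact_weight(c(3, 4, 5), contact_params())
#' @export
soft_contact_weight <- function(distance, params = contact_params()) {
  stopifnot(inherits(params, "contact_params"))
  if (any(distance < 0)) abort("distances must be non-negative")
  w <- 1 / (1 + exp(params$steepness * (distance - params$midpoint)))
  w[distance > params$truncation_distance] <- 0
  w
}

#' Weighted inter-molecular contact numbers
#'
#' Computes, for every heavy atom of group A, the sigmoid-weighted number of
#' contacts to group B, counting only pairs in different molecules (internal
#' molecular contacts are neglected, also when A and B are the same group).
#' Distances use the minimum-image convention when the structure carries an
#' orthorhombic box. The neighbour search is a cell list at the truncation
#' distance, so totals agree with the full double sum to the truncation
#' error (~1e-9 relative at defaults).
#'
#' @param structure A `biomass_structure`.
#' @param group_a,group_b Atom selections: molecule class name(s), integer
#'   row indices, or a logical mask. Defaults to all atoms for both.
#' @param params A [contact_params()].
#' @return A `contact_result`: list with `per_atom` (tibble: atom row,
#'   serial, molecule_id, `contacts`), `pair_totals` (tibble: `mol_i`,
#'   `mol_j`, `total`; each unordered molecule pair once) and `total`.
#' @export
contact_number <- function(structure, group_a = NULL, group_b = NULL,
                           params = contact_params()) {
  stopifnot(is_biomass_structure(structure), inherits(params, "contact_params"))
  idx_a <- if (is.null(group_a)) seq_len(nrow(structure)) else
    resolve_atoms(structure, group_a)
  idx_b <- if (is.null(group_b)) seq_len(nrow(structure)) else
    resolve_atoms(structure, group_b)
  if (length(idx_a) == 0 || length(idx_b) == 0) {
    warn("empty atom group: contact result is zero")
    return(structure(list(per_atom = tibble(atom = integer(), serial = integer(),
                                            molecule_id = integer(),
                                            contacts = numeric()),
                          pair_totals = tibble(mol_i = integer(),
                                               mol_j = integer(),
                                               total = numeric()),
                          total = 0, params = params),
                     class = "contact_result"))
  }
  identical_ab <- length(idx_a) == length(idx_b) && all(idx_a == idx_b)
  res <- cpp_soft_contacts(coords_matrix(structure), structure$molecule_id,
                           idx_a, idx_b,
                           params$steepness, params$midpoint,
                           params$truncation_distance,
                           box_or_zero(structure), identical_ab)
  pair_totals <- tibble(mol_i = res$pair_mol_i, mol_j = res$pair_mol_j,
                        total = res$pair_total)
  structure(list(
    per_atom = tibble(atom = idx_a, serial = structure$serial[idx_a],
                      molecule_id = structure$molecule_id[idx_a],
                      contacts = res$per_atom),
    pair_totals = pair_totals,
    total = sum(pair_totals$total),
    params = params), class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> total %.4f over %d molecule pairs (%d atoms in A)\n",
              x$total, nrow(x$pair_totals), nrow(x$per_atom)))
  invisible(x)
}

#' @export
tidy.contact_result <- function(x, ...) x$pair_totals

# molecule id -> class lookup
molecule_classes <- function(structure) {
  i <- !duplicated(structure$molecule_id)
  setNames(structure$molecule_class[i], structure$molecule_id[i])
}

#' Contact time series between molecule classes
#'
#' Per-frame total soft-contact numbers for every unordered pair of molecule
#' classes present (enzyme-enzyme, enzyme-lignin, enzyme-cellulose,
#' lignin-lignin, lignin-cellulose, cellulose-cellulose), obtained by
#' summing inter-molecular pair totals over each class pair.
#'
#' @param trajectory A `biomass_trajectory`.
#' @param class_pairs Optional two-column matrix/data frame of class pairs to
#'   keep; default all pairs over the classes present. Pairs naming a class
#'   absent from the scene yield an empty (all-`NA`) series with a warning.
#' @param params A [contact_params()].
#' @return A tibble of class `contact_series`: `frame`, `class_a`,
#'   `class_b`, `total` (class pair sorted alphabetically).
#' @export
contact_time_series <- function(trajectory, class_pairs = NULL,
                                params = contact_params()) {
  stopifnot(inherits(trajectory, "biomass_trajectory"))
  st <- trajectory$structure
  cls <- molecule_classes(st)
  present <- sort(unique(unname(cls)))
  if (is.null(class_pairs)) {
    grid <- expand.grid(a = present, b = present, stringsAsFactors = FALSE)
    grid <- grid[grid$a <= grid$b, ]
  } else {
    grid <- as.data.frame(class_pairs, stringsAsFactors = FALSE)
    names(grid) <- c("a", "b")
    swap <- grid$a > grid$b
    tmp <- grid$a[swap]; grid$a[swap] <- grid$b[swap]; grid$b[swap] <- tmp
    missing_cls <- setdiff(unique(c(grid$a, grid$b)), present)
    if (length(missing_cls) > 0) {
      warn(paste0("class(es) absent from the scene: ",
                  paste(missing_cls, collapse = ", "),
                  "; their series are NA"))
    }
  }
  box <- if (is.null(trajectory$box)) c(0, 0, 0) else trajectory$box
  n_atoms <- nrow(st)
  out <- purrr::map_dfr(seq_along(trajectory$coords), function(f) {
    res <- cpp_soft_contacts(trajectory$coords[[f]], st$molecule_id,
                             seq_len(n_atoms), seq_len(n_atoms),
                             params$steepness, params$midpoint,
                             params$truncation_distance, box, TRUE)
    pt <- tibble(a = unname(cls[as.character(res$pair_mol_i)]),
                 b = unname(cls[as.character(res$pair_mol_j)]),
                 total = res$pair_total)
    swap <- pt$a > pt$b
    tmp <- pt$a[swap]; pt$a[swap] <- pt$b[swap]; pt$b[swap] <- tmp
    agg <- pt |> group_by(.data$a, .data$b) |>
      summarise(total = sum(.data$total), .groups = "drop")
    full <- left_join(as_tibble(grid), agg, by = c("a", "b"))
    full$total[is.na(full$total) &
                 full$a %in% present & full$b %in% present] <- 0
    full$frame <- f
    full
  })
  out <- out |> rename(class_a = "a", class_b = "b") |>
    select("frame", "class_a", "class_b", "total")
  class(out) <- c("contact_series", class(out))
  out
}
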