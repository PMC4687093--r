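BINDING_STATES <- c("U", "C", "L", "E", "E+C", "E+L", "L+C", "E+C+L")

state_from_flags <- function(e, c, l) {
  if (!e && !c && !l) return("U")
  if (e && c && l) return("E+C+L")
  if (e && c) return("E+C")
  if (e && l) return("E+L")
  if (l && c) return("L+C")
  if (e) return("E")
  if (c) return("C")
  "L"
}

#' Classify the binding state of one enzyme
#'
#' An enzyme is bound to a molecule class when any of its heavy atoms lies
#' within `hard_cutoff` (default 3.2 Angstrom) of a heavy atom of another
#' molecule of that class. The three independent flags (bound to other
#' enzymes E, cellulose C, lignin L) combine into one of the eight mutually
#' exclusive states U, C, L, E, E+C, E+L, L+C, E+C+L.
#'
#' @param structure A `biomass_structure`.
#' @param enzyme_id Molecule id of the enzyme.
#' @param params A [contact_params()] (only `hard_cutoff` is used).
#' @return A length-1 factor with the eight state levels.
#' @export
classify_binding_state <- function(structure, enzyme_id,
                                   params = contact_params()) {
  stopifnot(is_biomass_structure(structure))
  rows_e <- which(structure$molecule_id == enzyme_id)
  if (length(rows_e) == 0) abort("no such enzyme molecule")
  if (structure$molecule_class[rows_e[1]] != "enzyme") {
    abort("`enzyme_id` is not an enzyme molecule")
  }
  pairs <- cpp_hard_contact_pairs(coords_matrix(structure),
                                  structure$molecule_id,
                                  rows_e, seq_len(nrow(structure)),
                                  params$hard_cutoff, box_or_zero(structure))
  partners <- setdiff(unique(c(pairs$mol_i, pairs$mol_j)), enzyme_id)
  cls <- molecule_classes(structure)[as.character(partners)]
  factor(state_from_flags("enzyme" %in% cls, "cellulose" %in% cls,
                          "lignin" %in% cls),
         levels = BINDING_STATES)
}

#' Binding states of all enzymes over a trajectory
#'
#' @param trajectory A `biomass_trajectory` (or a single `biomass_structure`,
#'   treated as one frame).
#' @param params A [contact_params()].
#' @return Tibble of class `binding_state_series`: `frame`, `molecule_id`,
#'   `state` (factor over the eight states).
#' @export
binding_states <- function(trajectory, params = contact_params()) {
  if (is_biomass_structure(trajectory)) {
    trajectory <- biomass_trajectory(trajectory,
                                     list(coords_matrix(trajectory)),
                                     box = structure_box(trajectory))
  }
  st <- trajectory$structure
  cls <- molecule_classes(st)
  enz <- as.integer(names(cls)[cls == "enzyme"])
  if (length(enz) == 0) abort("scene contains no enzymes")
  rows_enz <- which(st$molecule_class == "enzyme")
  box <- if (is.null(trajectory$box)) c(0, 0, 0) else trajectory$box
  out <- purrr::map_dfr(seq_along(trajectory$coords), function(f) {
    pairs <- cpp_hard_contact_pairs(trajectory$coords[[f]], st$molecule_id,
                                    rows_enz, seq_len(nrow(st)),
                                    params$hard_cutoff, box)
    states <- vapply(enz, function(eid) {
      partners <- c(pairs$mol_j[pairs$mol_i == eid],
                    pairs$mol_i[pairs$mol_j == eid])
      pc <- cls[as.character(partners)]
      state_from_flags("enzyme" %in% pc, "cellulose" %in% pc, "lignin" %in% pc)
    }, character(1))
    tibble(frame = f, molecule_id = enz,
           state = factor(states, levels = BINDING_STATES))
  })
  class(out) <- c("binding_state_series", class(out))
  out
}

#' Per-frame fractions of the eight binding states
#'
#' @inheritParams binding_states
#' @return Tibble: `frame`, `state`, `fraction`; the eight fractions sum to
#'   1 in every frame.
#' @export
binding_state_fractions <- function(trajectory, params = contact_params()) {
  states <- binding_states(trajectory, params)
  states |>
    group_by(.data$frame) |>
    dplyr::reframe(fraction = as.numeric(table(.data$state)) / dplyr::n(),
                   state = BINDING_STATES) |>
    select("frame", "state", "fraction") |>
    mutate(state = factor(.data$state, levels = BINDING_STATES))
}

#' Bound-protein capacity
#'
#' Converts a bound-enzyme fraction and an enzyme loading into the mass of
#' protein bound per gram of biomass solids (cellulose plus lignin). With
#' the full loading of 230 mg protein per g solids, a bound fraction of
#' 0.696 corresponds to 160 mg/g.
#'
#' @param bound_fraction Fraction of enzymes counted as bound, in `[0, 1]`.
#' @param total_enzyme_mass Total enzyme mass (same unit as `solids_mass`).
#' @param solids_mass Mass of biomass solids (> 0).
#' @return Bound protein in mg per g of solids.
#' @examples
#' bound_protein_capacity(1.0, 230, 1000)   # 230 mg/g loading, all bound
#' @export
bound_protein_capacity <- function(bound_fraction, total_enzyme_mass,
                                   solids_mass) {
  stopifnot(bound_fraction >= 0, bound_fraction <= 1, total_enzyme_mass > 0)
  if (solids_mass <= 0) abort("`solids_mass` must be positive")
  bound_fraction * total_enzyme_mass / solids_mass * 1000
}
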