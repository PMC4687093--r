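#' Per-residue contact profile of the enzymes
#'
#' Mean soft-contact number each enzyme residue (amino acid bead or glycan
#' sugar) makes with each partner class, averaged over the enzymes and over
#' a frame window. Residues are aligned across enzyme copies by their
#' within-molecule residue id, so the profile is the per-residue propensity
#' map that can be projected onto the enzyme structure.
#'
#' @param trajectory A `biomass_trajectory`.
#' @param window Integer frame indices to average over (e.g. the last third
#'   of the trajectory); must be non-empty and within bounds.
#' @param partner_classes Character vector of partner classes.
#' @param params A [contact_params()].
#' @return Tibble of class `residue_contact_profile`: `residue_id`,
#'   `residue_name`, `region`, `partner_class`, `mean_contacts`.
#' @export
residue_contact_profile <- function(trajectory,
                                    window = seq_len(n_frames(trajectory)),
                                    partner_classes = c("cellulose", "lignin",
                                                        "enzyme"),
                                    params = contact_params()) {
  stopifnot(inherits(trajectory, "biomass_trajectory"))
  window <- as.integer(window)
  if (length(window) == 0) abort("`window` must contain at least one frame")
  if (any(window < 1 | window > n_frames(trajectory))) {
    abort("`window` lies outside the trajectory")
  }
  st <- trajectory$structure
  rows_enz <- which(st$molecule_class == "enzyme")
  if (length(rows_enz) == 0) abort("scene contains no enzymes")
  n_enzymes <- length(unique(st$molecule_id[rows_enz]))
  box <- if (is.null(trajectory$box)) c(0, 0, 0) else trajectory$box

  per <- purrr::map_dfr(partner_classes, function(pc) {
    rows_b <- which(st$molecule_class == pc)
    if (length(rows_b) == 0) {
      return(tibble(residue_id = integer(), residue_name = character(),
                    region = character(), partner_class = character(),
                    mean_contacts = numeric()))
    }
    frame_sums <- purrr::map_dfr(window, function(f) {
      res <- cpp_soft_contacts(trajectory$coords[[f]], st$molecule_id,
                               rows_enz, rows_b,
                               params$steepness, params$midpoint,
                               params$truncation_distance, box,
                               identical(rows_enz, rows_b))
      tibble(residue_id = st$residue_id[rows_enz],
             residue_name = st$residue_name[rows_enz],
             region = st$region[rows_enz],
             contacts = res$per_atom)
    })
    frame_sums |>
      group_by(.data$residue_id, .data$residue_name, .data$region) |>
      summarise(mean_contacts = sum(.data$contacts) /
                  (length(window) * n_enzymes),
                .groups = "drop") |>
      mutate(partner_class = pc)
  })
  out <- per |> select("residue_id", "residue_name", "region",
                       "partner_class", "mean_contacts") |>
    arrange(.data$partner_class, .data$residue_id)
  class(out) <- c("residue_contact_profile", class(out))
  out
}

#' Rank residues by contact propensity
#'
#' Top-k residues per partner class with cumulative contact sums, mirroring
#' how the most contact-prone residues (CBM tyrosines, linker glycans) are
#' tabulated.
#'
#' @param profile A [residue_contact_profile()] result.
#' @param n Number of top residues per partner class.
#' @return Tibble with `rank` and `cumulative_contacts` added.
#' @export
rank_residue_contacts <- function(profile, n = 10) {
  profile |>
    group_by(.data$partner_class) |>
    arrange(desc(.data$mean_contacts), .by_group = TRUE) |>
    mutate(rank = dplyr::row_number(),
           cumulative_contacts = cumsum(.data$mean_contacts)) |>
    filter(.data$rank <= n) |>
    ungroup()
}

#' Ring/chain partition of lignin contacts
#'
#' Splits the soft contacts each lignin monomer makes with a partner class
#' between its aromatic-ring atoms (ring carbons plus the ring oxygens) and
#' its propanoid-tail atoms, averaged over frames. The two parts sum
#' exactly to the unpartitioned lignin contact total.
#'
#' @param trajectory A `biomass_trajectory` (or single structure).
#' @param partner_class Partner molecule class (`"enzyme"`, `"lignin"` or
#'   `"cellulose"`).
#' @param params A [contact_params()].
#' @return Tibble: `molecule_id`, `residue_id`, `atom_class` (ring/chain),
#'   `contacts` (mean per frame).
#' @export
atom_class_contacts <- function(trajectory, partner_class,
                                params = contact_params()) {
  if (is_biomass_structure(trajectory)) {
    trajectory <- biomass_trajectory(trajectory,
                                     list(coords_matrix(trajectory)),
                                     box = structure_box(trajectory))
  }
  st <- trajectory$structure
  rows_l <- which(st$molecule_class == "lignin")
  if (length(rows_l) == 0) abort("scene contains no lignin")
  if (any(!st$atom_class[rows_l] %in% c("ring", "chain"))) {
    abort("every lignin atom must be tagged as ring or chain")
  }
  rows_b <- which(st$molecule_class == partner_class)
  box <- if (is.null(trajectory$box)) c(0, 0, 0) else trajectory$box
  sums <- purrr::map_dfr(seq_along(trajectory$coords), function(f) {
    res <- cpp_soft_contacts(trajectory$coords[[f]], st$molecule_id,
                             rows_l, rows_b,
                             params$steepness, params$midpoint,
                             params$truncation_distance, box,
                             identical(rows_l, rows_b))
    tibble(molecule_id = st$molecule_id[rows_l],
           residue_id = st$residue_id[rows_l],
           atom_class = st$atom_class[rows_l],
           contacts = res$per_atom)
  })
  sums |>
    group_by(.data$molecule_id, .data$residue_id, .data$atom_class) |>
    summarise(contacts = sum(.data$contacts) / length(trajectory$coords),
              .groups = "drop") |>
    tidyr::complete(tidyr::nesting(molecule_id, residue_id),
                    atom_class = c("ring", "chain"),
                    fill = list(contacts = 0))
}

#' Contact lifetimes and survival
#'
#' A pair (of molecules, or of inter-molecular residues) is in contact in a
#' frame when any inter-atomic distance is within the hard cutoff. Events
#' are maximal runs of consecutive in-contact frames, at frame resolution
#' with no smoothing. Events touching either trajectory end are censored
#' (their true duration is unknown).
#'
#' @param trajectory A `biomass_trajectory` with at least 2 frames.
#' @param pair_level `"molecule"` or `"residue"`.
#' @param params A [contact_params()].
#' @return A `contact_lifetimes` object: list with `events` (tibble:
#'   pair ids, `start`, `length` in frames, `censored`), `survival`
#'   (tibble: `lag`, `surv` = fraction of uncensored events with length >
#'   lag) and `n_frames`.
#' @export
contact_lifetimes <- function(trajectory, pair_level = c("molecule", "residue"),
                              params = contact_params()) {
  stopifnot(inherits(trajectory, "biomass_trajectory"))
  pair_level <- match.arg(pair_level)
  nf <- n_frames(trajectory)
  if (nf < 2) abort("need at least two frames")
  st <- trajectory$structure
  key <- if (pair_level == "molecule") st$molecule_id else {
    as.integer(factor(paste(st$molecule_id, st$residue_id)))
  }
  box <- if (is.null(trajectory$box)) c(0, 0, 0) else trajectory$box
  n_atoms <- nrow(st)
  frame_pairs <- lapply(seq_len(nf), function(f) {
    p <- cpp_hard_contact_pairs_keyed(trajectory$coords[[f]],
                                      st$molecule_id, key,
                                      seq_len(n_atoms), seq_len(n_atoms),
                                      params$hard_cutoff, box)
    paste(p$key_i, p$key_j)
  })
  all_pairs <- unique(unlist(frame_pairs))
  events <- purrr::map_dfr(all_pairs, function(pp) {
    present <- vapply(frame_pairs, function(fp) pp %in% fp, logical(1))
    r <- rle(present)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    ids <- strsplit(pp, " ")[[1]]
    tibble(key_i = as.integer(ids[1]), key_j = as.integer(ids[2]),
           start = starts[keep], length = r$lengths[keep],
           censored = starts[keep] == 1 | ends[keep] == nf)
  })
  lags <- seq_len(nf)
  complete <- events$length[!events$censored]
  surv <- vapply(lags, function(L) {
    if (length(complete) == 0) NA_real_ else mean(complete > L)
  }, numeric(1))
  structure(list(events = events,
                 survival = tibble(lag = lags, surv = surv),
                 n_frames = nf, pair_level = pair_level),
            class = "contact_lifetimes")
}

#' @export
print.contact_lifetimes <- function(x, ...) {
  cat(sprintf("<contact_lifetimes> %d events over %d %s pairs (%d censored)\n",
              nrow(x$events), length(unique(paste(x$events$key_i, x$events$key_j))),
              x$pair_level, sum(x$events$censored)))
  invisible(x)
}

#' Fraction of contact events broken within a lag
#'
#' @param lifetimes A [contact_lifetimes()] result.
#' @param lag Lag in frames.
#' @param include_censored Count censored events in the denominator.
#' @return Fraction of events with length <= `lag`.
#' @export
fraction_broken_within <- function(lifetimes, lag, include_censored = FALSE) {
  ev <- lifetimes$events
  if (!include_censored) ev <- ev[!ev$censored, ]
  if (nrow(ev) == 0) return(NA_real_)
  mean(ev$length <= lag)
}
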