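mk_atom <- function(id, cls, x, y = 0, z = 0) {
  tibble::tibble(x = x, y = y, z = z, molecule_id = id, molecule_class = cls)
}

test_that("the eight-state classifier follows the 3.2 A any-atom rule", {
  st <- as_biomass_structure(dplyr::bind_rows(
    tibble::tibble(x = c(0, 10), y = 0, z = 0, molecule_id = 1,
                   molecule_class = "enzyme"),
    mk_atom(2, "lignin", -3.0),          # 3.0 A from enzyme atom 1
    mk_atom(3, "cellulose", 13.1),       # 3.1 A from enzyme atom 2
    mk_atom(4, "enzyme", 0, 50)))
  expect_identical(as.character(classify_binding_state(st, 1)), "L+C")
  expect_identical(as.character(classify_binding_state(st, 4)), "U")
  # nearest foreign atom beyond the cutoff -> unbound
  st_u <- as_biomass_structure(dplyr::bind_rows(
    mk_atom(1, "enzyme", 0), mk_atom(2, "lignin", 5)))
  expect_identical(as.character(classify_binding_state(st_u, 1)), "U")
  # all three classes within reach -> E+C+L
  st_all <- as_biomass_structure(dplyr::bind_rows(
    mk_atom(1, "enzyme", 0), mk_atom(2, "lignin", 3.0),
    mk_atom(3, "cellulose", -3.0), mk_atom(4, "enzyme", 0, 3.1)))
  expect_identical(as.character(classify_binding_state(st_all, 1)), "E+C+L")
})

test_that("state is invariant to atom ordering", {
  st <- as_biomass_structure(dplyr::bind_rows(
    tibble::tibble(x = c(0, 10), y = 0, z = 0, molecule_id = 1,
                   molecule_class = "enzyme"),
    mk_atom(2, "lignin", -3.0), mk_atom(3, "cellulose", 13.1)))
  set.seed(3)
  shuffled <- structure_subset(st, sample(nrow(st)))
  expect_identical(classify_binding_state(st, 1),
                   classify_binding_state(shuffled, 1))
})

test_that("state fractions sum to one per frame and match per-enzyme classification", {
  set.seed(8)
  st <- random_scene(240, 12, box = c(25, 25, 25),
                     classes = c("enzyme", "lignin", "cellulose"))
  # make sure at least one enzyme exists
  st$molecule_class[st$molecule_id == st$molecule_id[1]] <- "enzyme"
  xyz <- cbind(st$x, st$y, st$z)
  tr <- biomass_trajectory(st, list(xyz, xyz + 0.5))
  fr <- binding_state_fractions(tr)
  sums <- fr |> dplyr::group_by(frame) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 2), tolerance = 1e-12)
  # oracle: per-enzyme brute-force distances per class
  states <- binding_states(tr)
  md <- brute_min_dists(trajectory_frame(tr, 1))
  cls <- setNames(st$molecule_class[!duplicated(st$molecule_id)],
                  st$molecule_id[!duplicated(st$molecule_id)])
  for (eid in unique(states$molecule_id)) {
    rows <- md[(md$mol_i == eid | md$mol_j == eid) & md$min_dist <= 3.2, ]
    partners <- setdiff(c(rows$mol_i, rows$mol_j), eid)
    pc <- cls[as.character(partners)]
    flags <- c(E = "enzyme" %in% pc, C = "cellulose" %in% pc,
               L = "lignin" %in% pc)
    want <- if (!any(flags)) "U" else if (all(flags)) "E+C+L"
      else if (flags["E"] && flags["C"]) "E+C"
      else if (flags["E"] && flags["L"]) "E+L"
      else if (flags["L"] && flags["C"]) "L+C"
      else names(flags)[flags]
    got <- as.character(states$state[states$frame == 1 &
                                       states$molecule_id == eid])
    expect_identical(got, unname(want))
  }
})

test_that("bound-protein capacity arithmetic matches the loading bookkeeping", {
  expect_equal(bound_protein_capacity(1.0, 0.230, 1), 230)
  expect_identical(bound_protein_capacity(0, 1, 1), 0)
  expect_equal(bound_protein_capacity(0.696, 0.230, 1), 160.08)
  expect_error(bound_protein_capacity(0.5, 1, 0), "solids")
})
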