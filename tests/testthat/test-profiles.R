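test_that("a single-contact fixture lights up exactly one residue", {
  enz <- tibble::tibble(
    x = c(0, 10, 20), y = 0, z = 0, molecule_id = 1,
    molecule_class = "enzyme", residue_id = 1:3, residue_name = "ALA",
    region = "CD")
  lig <- tibble::tibble(x = 10, y = 3.5, z = 0, molecule_id = 2,
                        molecule_class = "lignin", residue_id = 1,
                        residue_name = "GUA")
  st <- as_biomass_structure(dplyr::bind_rows(enz, lig))
  tr <- biomass_trajectory(st, list(cbind(st$x, st$y, st$z)))
  prof <- residue_contact_profile(tr, window = 1,
                                  partner_classes = "lignin")
  nz <- prof[prof$mean_contacts > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_identical(nz$residue_id, 2L)
  expect_equal(nz$mean_contacts, soft_contact_weight(3.5), tolerance = 1e-9)
  expect_error(residue_contact_profile(tr, window = integer()), "window")
  expect_error(residue_contact_profile(tr, window = 5), "outside")
})

test_that("profile means equal the brute per-frame average over a window", {
  sc <- demo_scene(seed = 13, monomers = 15)
  xyz1 <- cbind(sc$x, sc$y, sc$z)
  xyz2 <- xyz1 + 0.8
  tr <- biomass_trajectory(sc, list(xyz1, xyz2))
  prof <- residue_contact_profile(tr, window = 1:2,
                                  partner_classes = "cellulose")
  n_enz <- length(unique(sc$molecule_id[sc$molecule_class == "enzyme"]))
  # oracle: explicit per-frame per-atom sums from the weight function
  total_expected <- 0
  for (f in 1:2) {
    fr <- trajectory_frame(tr, f)
    rows_e <- which(fr$molecule_class == "enzyme")
    rows_c <- which(fr$molecule_class == "cellulose")
    d2 <- outer(fr$x[rows_e], fr$x[rows_c], "-")^2 +
      outer(fr$y[rows_e], fr$y[rows_c], "-")^2 +
      outer(fr$z[rows_e], fr$z[rows_c], "-")^2
    w <- soft_contact_weight(sqrt(d2))
    total_expected <- total_expected + sum(w)
  }
  # sum over residues of the mean = grand total / (n_frames x n_enzymes)
  expect_equal(sum(prof$mean_contacts), total_expected / (2 * n_enz),
               tolerance = 1e-6)
  # ranking is stable under residue relabeling (permutation of ids)
  ranked <- rank_residue_contacts(prof, n = 5)
  expect_true(all(diff(ranked$mean_contacts) <= 1e-12))
  expect_equal(ranked$cumulative_contacts,
               cumsum(ranked$mean_contacts), tolerance = 1e-12)
})

test_that("ring/chain partition conserves lignin contact totals", {
  sc <- demo_scene(seed = 21, monomers = 12)
  acc <- atom_class_contacts(sc, "cellulose")
  expect_setequal(unique(acc$atom_class), c("ring", "chain"))
  total <- contact_number(sc, "lignin", "cellulose")$total
  expect_equal(sum(acc$contacts), total, tolerance = 1e-9)
  # untagged lignin atoms are rejected
  bad <- sc
  bad$atom_class[which(bad$molecule_class == "lignin")[1]] <- NA
  expect_error(atom_class_contacts(bad, "cellulose"), "ring or chain")
})

test_that("an all-ring contact fixture has zero chain contacts", {
  lig <- tibble::tibble(
    x = c(0, 2), y = 0, z = 0, molecule_id = 1, molecule_class = "lignin",
    residue_id = 1, residue_name = "GUA", atom_class = c("ring", "chain"))
  cel <- tibble::tibble(x = -3.5, y = 0, z = 0, molecule_id = 2,
                        molecule_class = "cellulose", residue_id = 1,
                        residue_name = "GLC")
  st <- as_biomass_structure(dplyr::bind_rows(lig, cel))
  acc <- atom_class_contacts(st, "cellulose",
                             params = contact_params(truncation_distance = 5))
  expect_gt(acc$contacts[acc$atom_class == "ring"], 0)
  expect_identical(acc$contacts[acc$atom_class == "chain"], 0)
})

test_that("contact lifetimes are maximal runs at frame resolution", {
  st <- as_biomass_structure(tibble::tibble(
    x = c(0, 3), y = 0, z = 0, molecule_id = 1:2,
    molecule_class = "lignin"))
  near <- cbind(c(0, 3), c(0, 0), c(0, 0))
  far <- cbind(c(0, 30), c(0, 0), c(0, 0))
  # always bound: one censored event spanning everything
  tr_all <- biomass_trajectory(st, rep(list(near), 5))
  lt_all <- contact_lifetimes(tr_all)
  expect_identical(nrow(lt_all$events), 1L)
  expect_identical(lt_all$events$length, 5L)
  expect_true(lt_all$events$censored)
  # alternating frames: all interior events have length one
  tr_alt <- biomass_trajectory(st, list(far, near, far, near, far))
  lt_alt <- contact_lifetimes(tr_alt)
  expect_true(all(lt_alt$events$length == 1))
  expect_true(all(!lt_alt$events$censored))
  expect_identical(fraction_broken_within(lt_alt, 1), 1)
})

test_that("telegraph-process lifetimes match the geometric closed form", {
  set.seed(31)
  p_off <- 0.25                      # per-frame break probability
  n <- 4000
  state <- logical(n)
  state[1] <- TRUE
  for (f in 2:n) {
    state[f] <- if (state[f - 1]) runif(1) > p_off else runif(1) < 0.3
  }
  st <- as_biomass_structure(tibble::tibble(
    x = c(0, 3), y = 0, z = 0, molecule_id = 1:2,
    molecule_class = "lignin"))
  near <- cbind(c(0, 3), c(0, 0), c(0, 0))
  far <- cbind(c(0, 30), c(0, 0), c(0, 0))
  tr <- biomass_trajectory(st, lapply(state, function(s) if (s) near else far))
  lt <- contact_lifetimes(tr)
  complete <- lt$events$length[!lt$events$censored]
  expect_lt(abs(mean(complete) - 1 / p_off) / (1 / p_off), 0.15)
  # survival curve agrees with the geometric law at lag 3
  expect_lt(abs(lt$survival$surv[3] - (1 - p_off)^3), 0.08)
})
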