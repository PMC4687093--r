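test_that("sigmoid weight matches its closed form and stated properties", {
  p <- contact_params()
  expect_identical(soft_contact_weight(4, p), 0.5)
  expect_equal(soft_contact_weight(3, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(soft_contact_weight(5, p), 1 / (1 + exp(5)), tolerance = 1e-12)
  d <- seq(0, 7.9, by = 0.05)
  w <- soft_contact_weight(d, p)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w < 1))
  expect_identical(soft_contact_weight(8.01, p), 0)
  expect_error(soft_contact_weight(-0.1, p), "non-negative")
})

test_that("cell-list totals equal the O(N^2) brute force on random scenes", {
  set.seed(101)
  for (rep in 1:20) {
    boxed <- rep %% 2 == 0
    st <- random_scene(sample(50:500, 1), sample(2:8, 1),
                       box = if (boxed) c(30, 30, 30) else NULL)
    res <- contact_number(st)
    oracle <- brute_soft_total(st)
    expect_lt(abs(res$total - oracle) / max(oracle, 1e-12), 1e-9)
  }
})

test_that("truncating the sigmoid sum changes totals by less than 1e-3", {
  set.seed(5)
  for (rep in 1:5) {
    st <- random_scene(200, 4, box = c(25, 25, 25))
    full <- brute_soft_total(st, truncate = FALSE)
    trunc <- contact_number(st)$total
    expect_lt(abs(full - trunc) / full, 1e-3)
  }
})

test_that("intra-molecular pairs are neglected, also when A equals B", {
  two <- as_biomass_structure(tibble::tibble(
    x = c(0, 4), y = 0, z = 0, molecule_id = 1:2, molecule_class = "lignin"))
  expect_equal(contact_number(two)$total, 0.5, tolerance = 1e-12)
  one <- as_biomass_structure(tibble::tibble(
    x = c(0, 4), y = 0, z = 0, molecule_id = 1, molecule_class = "lignin"))
  expect_identical(contact_number(one)$total, 0)
})

test_that("empty atom groups warn and return a zero result", {
  st <- random_scene(20, 2)
  expect_warning(res <- contact_number(st, "enzyme", "lignin"), "empty")
  expect_identical(res$total, 0)
})

test_that("contact series are constant for static scenes and symmetric in class order", {
  st <- demo_scene(seed = 7, monomers = 15)
  xyz <- cbind(st$x, st$y, st$z)
  tr <- biomass_trajectory(st, list(xyz, xyz, xyz))
  cs <- contact_time_series(tr)
  spread <- cs |> dplyr::group_by(class_a, class_b) |>
    dplyr::summarise(rng = diff(range(total)), .groups = "drop")
  expect_true(all(spread$rng == 0))
  cs2 <- contact_time_series(tr, class_pairs = cbind("lignin", "cellulose"))
  cs1 <- contact_time_series(tr, class_pairs = cbind("cellulose", "lignin"))
  expect_equal(cs1$total, cs2$total)
})

test_that("an enzyme approaching lignin gives a non-decreasing E-L series", {
  top <- generate_lignin_topology(15, seed = 2)
  lig <- generate_lignin_structure(top, "blob", seed = 3, molecule_id = 1)
  enz <- generate_pseudo_enzyme(seed = 1, molecule_id = 2)
  lig$x <- lig$x + 150; lig$y <- lig$y + 100; lig$z <- lig$z + 100
  scn <- bind_structures(list(lig, enz), box = c(400, 300, 300),
                         renumber_molecules = FALSE)
  rows <- scn$molecule_class == "enzyme"
  base <- cbind(scn$x, scn$y, scn$z)
  base[rows, 2] <- base[rows, 2] + 100
  base[rows, 3] <- base[rows, 3] + 100
  d0 <- min(sqrt(outer(base[rows, 1], base[!rows, 1], "-")^2 +
                   outer(base[rows, 2], base[!rows, 2], "-")^2 +
                   outer(base[rows, 3], base[!rows, 3], "-")^2))
  # straight-line approach that ends just short of van der Waals contact
  frames <- lapply(seq(0, d0 - 4, length.out = 9), function(s) {
    xyz <- base
    xyz[rows, 1] <- xyz[rows, 1] + s
    xyz
  })
  tr <- biomass_trajectory(scn, frames)
  el <- contact_time_series(tr) |>
    dplyr::filter(class_a == "enzyme", class_b == "lignin")
  expect_true(all(diff(el$total) >= 0))
  expect_gt(dplyr::last(el$total), 0)
  # per-frame values match the single-frame engine
  direct <- contact_number(trajectory_frame(tr, length(frames)),
                           "enzyme", "lignin")$total
  expect_equal(dplyr::last(el$total), direct, tolerance = 1e-9)
})
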