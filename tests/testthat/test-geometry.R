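hexring <- function() {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(cos(th), 0, sin(th))
}

test_that("crossing angles reproduce constructed rotations and fold to [0, 90]", {
  r1 <- hexring()
  expect_equal(crossing_angle(r1, r1), 0, tolerance = 1e-9)
  ortho <- cbind(r1[, 2], r1[, 1], r1[, 3])
  expect_equal(crossing_angle(r1, ortho), 90, tolerance = 1e-9)
  for (th in c(10, 30, 75)) {
    a <- th * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    expect_equal(crossing_angle(r1, r1 %*% t(Rx)), th, tolerance = 1e-6)
    # symmetry and folding
    expect_equal(crossing_angle(r1 %*% t(Rx), r1), th, tolerance = 1e-6)
    a2 <- (180 - th) * pi / 180
    Rx2 <- matrix(c(1, 0, 0, 0, cos(a2), sin(a2), 0, -sin(a2), cos(a2)), 3, 3)
    expect_equal(crossing_angle(r1, r1 %*% t(Rx2)), th, tolerance = 1e-6)
  }
  expect_error(ring_normal(cbind(0:2, 0, 0)), "collinear")
})

test_that("crossing angles are invariant under rigid transforms of the pair", {
  set.seed(4)
  r1 <- hexring()
  a <- 0.6
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  r2 <- r1 %*% t(Rx) + 3
  base <- crossing_angle(r1, r2)
  M <- rotation_matrix(c(1, 2, 0.5), 1.1)
  shift <- c(5, -2, 7)
  expect_equal(crossing_angle(sweep(r1 %*% t(M), 2, shift, `+`),
                              sweep(r2 %*% t(M), 2, shift, `+`)),
               base, tolerance = 1e-6)
})

test_that("stacking pairs pick the nearest biomass ring within 5 A", {
  enz <- generate_pseudo_enzyme(seed = 1, molecule_id = 1)
  tyr <- tibble::as_tibble(enz) |>
    dplyr::filter(region == "CBM", atom_class == "ring", residue_id == 492)
  cen <- c(mean(tyr$x), mean(tyr$y), mean(tyr$z))
  top <- generate_lignin_topology(4, seed = 2)
  lig <- generate_lignin_structure(top, "flat", seed = 3, molecule_id = 2)
  ring1 <- tibble::as_tibble(lig) |>
    dplyr::filter(residue_id == 1, atom_class == "ring")
  shift <- cen + c(0, -3.5, 0) - c(mean(ring1$x), mean(ring1$y), mean(ring1$z))
  lig$x <- lig$x + shift[1]; lig$y <- lig$y + shift[2]; lig$z <- lig$z + shift[3]
  st <- bind_structures(list(enz, lig), renumber_molecules = FALSE)
  sa <- stacking_angles(st)
  expect_true(492 %in% sa$residue_id)
  row <- sa[sa$residue_id == 492, ]
  expect_identical(row$partner_class, "lignin")
  expect_lte(row$distance, 5)
  expect_gte(row$angle, 0); expect_lte(row$angle, 90)
})

test_that("the random stacking reference follows sin(gamma)", {
  rr <- random_reference_distribution(1e4, seed = 12)
  expect_lt(abs(mean(rr$angle) - 180 / pi), 0.5)
  ks <- suppressWarnings(stats::ks.test(rr$angle * pi / 180,
                                        function(q) 1 - cos(q)))
  expect_gt(ks$p.value, 0.01)
  # analytic density integrates to one over [0, 90] degrees
  expect_equal(stats::integrate(stacking_reference_density, 0, 90)$value, 1,
               tolerance = 1e-6)
})

test_that("procession gaps follow the stated interval construction", {
  fib <- generate_fibril(fibril_spec(n_chains = 12, dp = 40), molecule_id = 1)
  hyd <- tibble::as_tibble(fib) |>
    dplyr::filter(face_label == "hydrophobic", atom_class == "hydroxyl",
                  y > mean(fib$y))
  xc <- hyd$x[which.min(abs(hyd$x - mean(range(fib$x))))]
  top_y <- max(hyd$y)
  clust <- function(id, zs) tibble::tibble(
    x = xc, y = top_y + 1.5, z = zs + min(fib$z), molecule_id = id,
    molecule_class = "lignin", atom_class = "ring")
  lig <- dplyr::bind_rows(clust(2, seq(10, 20, 2)), clust(3, seq(50, 60, 2)),
                          clust(4, seq(100, 150, 2)))
  sc <- bind_structures(list(fib, as_biomass_structure(lig)),
                        renumber_molecules = FALSE)
  pr <- procession_lengths(sc, 1, "hydrophobic")
  expect_equal(sort(pr$gaps), c(30, 40), tolerance = 0.2)
  expect_false(pr$face_empty)
  # conservation: occupied + gaps + end margins = span
  occupied <- sum(pr$intervals$end - pr$intervals$start)
  margins <- (min(pr$intervals$start) - (-pr$span / 2)) +
    (pr$span / 2 - max(pr$intervals$end))
  expect_equal(occupied + sum(pr$gaps) + margins, pr$span, tolerance = 1e-6)
  # two clusters -> one gap of 30
  sc2 <- bind_structures(list(fib, as_biomass_structure(
    dplyr::bind_rows(clust(2, seq(10, 20, 2)), clust(3, seq(50, 60, 2))))),
    renumber_molecules = FALSE)
  expect_equal(procession_lengths(sc2, 1, "hydrophobic")$gaps, 30,
               tolerance = 0.2)
})

test_that("a lignin-free face reports the full span as a flagged gap", {
  fib <- generate_fibril(fibril_spec(n_chains = 12, dp = 20), molecule_id = 1)
  pr <- procession_lengths(fib, 1, "hydrophobic")
  expect_true(pr$face_empty)
  expect_equal(pr$gaps, pr$span)
  expect_identical(nrow(pr$intervals), 0L)
})

test_that("enzyme orientation classes follow the tunnel-fibril angle", {
  fib <- generate_fibril(fibril_spec(n_chains = 7, dp = 10), molecule_id = 1)
  enz0 <- generate_pseudo_enzyme(seed = 2, molecule_id = 9)
  place <- function(rot) {
    xyz <- cbind(enz0$x, enz0$y, enz0$z) %*% t(rot)
    e <- enz0
    e$x <- xyz[, 1]; e$y <- xyz[, 2]; e$z <- xyz[, 3]
    # drop one atom right next to the fibril surface so the enzyme is bound
    probe <- e[1, ]
    probe$x <- max(fib$x) + 2.5; probe$y <- 0; probe$z <- 0
    bind_structures(list(fib, dplyr::bind_rows(tibble::as_tibble(e),
                                               tibble::as_tibble(probe)) |>
                           as_biomass_structure()),
                    renumber_molecules = FALSE)
  }
  align <- rotation_matrix(c(0, 1, 0), -pi / 2)  # tunnel x -> z
  expect_identical(enzyme_orientation(place(align), 9, 1)$orientation,
                   "parallel")
  anti <- rotation_matrix(c(0, 1, 0), pi / 2)
  expect_identical(enzyme_orientation(place(anti), 9, 1)$orientation,
                   "antiparallel")
  expect_identical(enzyme_orientation(place(diag(3)), 9, 1)$orientation,
                   "perpendicular")
  # unbound enzyme: no class
  far <- enz0
  far$x <- far$x + 500
  st <- bind_structures(list(fib, far), renumber_molecules = FALSE)
  expect_identical(nrow(enzyme_orientation(st, 9, 1)), 0L)
})

test_that("radius of gyration matches closed forms", {
  two <- as_biomass_structure(tibble::tibble(
    x = c(-1, 1), y = 0, z = 0, molecule_id = 1, molecule_class = "enzyme",
    mass = 1))
  expect_equal(radius_of_gyration(two), 1, tolerance = 1e-12)
  square <- as_biomass_structure(tibble::tibble(
    x = c(1, 1, -1, -1), y = c(1, -1, 1, -1), z = 0, molecule_id = 1,
    molecule_class = "enzyme", mass = 1))
  expect_equal(radius_of_gyration(square), sqrt(2), tolerance = 1e-12)
  one <- as_biomass_structure(tibble::tibble(
    x = 3, y = 4, z = 5, molecule_id = 1, molecule_class = "enzyme"))
  expect_equal(radius_of_gyration(one), 0, tolerance = 1e-12)
})
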