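fine <- surface_params(grid_spacing = 0.5)

test_that("single-atom isosurface matches the closed-form sphere", {
  carbon <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
  R <- 0.47 * (1.7 + 3) * sqrt(2 * log(1 / 0.4))
  area <- gaussian_surface_area(carbon, fine)
  expect_lt(abs(area - 4 * pi * R^2) / (4 * pi * R^2), 0.05)
  # error shrinks as the grid refines
  err_coarse <- abs(gaussian_surface_area(carbon, surface_params(grid_spacing = 1.0)) -
                      4 * pi * R^2)
  expect_lt(abs(area - 4 * pi * R^2), err_coarse + 1e-9)
})

test_that("the density grid evaluates the stated kernel sum", {
  p <- surface_params(grid_spacing = 0.5)
  atoms <- tibble::tibble(x = c(0, 3), y = 0, z = 0, radius = 1.7)
  g <- gaussian_density_grid(atoms, p)
  # value at a known lattice point from the closed form
  rp <- 0.47 * (1.7 + 3)
  probe_ix <- round((1.5 - g$origin[1]) / g$spacing) + 1
  iy <- round((0 - g$origin[2]) / g$spacing) + 1
  iz <- round((0 - g$origin[3]) / g$spacing) + 1
  px <- g$origin[1] + (probe_ix - 1) * g$spacing
  expected <- exp(-(px - 0)^2 / (2 * rp^2)) + exp(-(px - 3)^2 / (2 * rp^2))
  expect_equal(g$values[probe_ix, iy, iz], expected, tolerance = 1e-10)
  # maximum sits at an atom and exceeds 1 for overlapping kernels
  expect_gte(max(g$values), 1)
  expect_error(gaussian_density_grid(tibble::tibble(x = numeric(),
                                                    y = numeric(),
                                                    z = numeric(),
                                                    radius = numeric()), p),
               "empty")
})

test_that("an isolated-blob mesh is closed and iso out of range warns", {
  g <- gaussian_density_grid(tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7),
                             fine)
  mesh <- extract_isosurface(g)
  edges <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
                 mesh$triangles[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  expect_warning(empty <- extract_isosurface(g, iso = max(g$values) + 1),
                 "outside")
  expect_identical(nrow(empty$triangles), 0L)
  expect_identical(mesh_area(empty), 0)
})

test_that("areas are additive for far atoms and rigid-motion invariant", {
  one <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
  two_far <- tibble::tibble(x = c(0, 40), y = 0, z = 0, radius = 1.7)
  a1 <- gaussian_surface_area(one, fine)
  a2 <- gaussian_surface_area(two_far, fine)
  expect_lt(abs(a2 - 2 * a1) / (2 * a1), 0.01)
  set.seed(2)
  blob <- tibble::tibble(x = rnorm(8, 0, 2), y = rnorm(8, 0, 2),
                         z = rnorm(8, 0, 2), radius = 1.7)
  base <- gaussian_surface_area(blob, fine)
  rotz <- function(th) matrix(c(cos(th), sin(th), 0,
                                -sin(th), cos(th), 0,
                                0, 0, 1), 3, 3)
  xyz <- as.matrix(blob[, 1:3]) %*% rotz(0.83)
  rot <- tibble::tibble(x = xyz[, 1] + 5, y = xyz[, 2] - 3, z = xyz[, 3],
                        radius = 1.7)
  expect_lt(abs(gaussian_surface_area(rot, fine) - base) / base, 0.01)
})

test_that("Shrake-Rupley matches closed forms for spheres and caps", {
  carbon <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
  expect_lt(abs(as.numeric(shrake_rupley_sasa(carbon)) - 4 * pi * 3.1^2) /
              (4 * pi * 3.1^2), 0.02)
  # two equal spheres at distance d: exposed area from the spherical caps
  d <- 3; R <- 1.7 + 1.4
  h <- R - d / 2
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  two <- tibble::tibble(x = c(0, d), y = 0, z = 0, radius = 1.7)
  expect_lt(abs(as.numeric(shrake_rupley_sasa(two)) - analytic) / analytic,
            0.02)
  # fully buried atom contributes nothing
  buried <- tibble::tibble(x = c(0, 0.3), y = 0, z = 0, radius = c(1.0, 6.0))
  per <- attr(shrake_rupley_sasa(buried), "per_atom")
  expect_identical(per[1], 0)
})

test_that("interface area is symmetric, zero for far groups, and matches the co-area oracle", {
  a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7, serial = 1)
  b <- tibble::tibble(x = 3.5, y = 0, z = 0, radius = 1.7, serial = 2)
  iab <- interface_area(a, b, fine)
  iba <- interface_area(b, a, fine)
  expect_equal(iab, iba, tolerance = 1e-9)
  expect_gt(iab, 0)
  far <- tibble::tibble(x = 40, y = 0, z = 0, radius = 1.7, serial = 2)
  expect_lt(abs(interface_area(a, far, fine)), 1e-6)
  expect_error(interface_area(a, a, fine), "overlap")
  # oracle: interface = (A(A) + A(B) - A(AB)) / 2 with each area from the
  # exact axisymmetric surface-of-revolution integral of the closed-form
  # density (the atoms lie on one axis)
  o_a <- axisym_gaussian_area(0, 1.7, fine)
  o_b <- axisym_gaussian_area(3.5, 1.7, fine)
  o_ab <- axisym_gaussian_area(c(0, 3.5), 1.7, fine)
  oracle <- (o_a + o_b - o_ab) / 2
  expect_lt(abs(iab - oracle) / oracle, 0.05)
})

test_that("Gaussian areas trail SASA at molecular scale", {
  # smooth Gaussian surfaces bridge the inter-chain grooves of a fibril
  fib <- generate_fibril(fibril_spec(n_chains = 36, dp = 12))
  atoms <- tibble::as_tibble(fib)
  g <- gaussian_surface_area(atoms, surface_params())
  s <- as.numeric(shrake_rupley_sasa(atoms))
  expect_lt(g, s)
})

test_that("coverage reports face-resolved ratios with the expected ordering", {
  sc <- assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 12, dp = 16)),
    lignin = tibble::tibble(morphology = "sheet", fibril = 1,
                            monomer_count = 16),
    n_enzymes = 0, seed = 3))
  cov <- coverage_report(sc)
  expect_true(all(cov$a_t > 0))
  expect_true(all(cov$ratio_e == 0))
  expect_true(all(cov$ratio_l >= 0 & cov$ratio_l <= 1))
  hyd <- cov$ratio_l[cov$face == "hydrophobic"]
  phil <- cov$ratio_l[cov$face == "hydrophilic"]
  expect_gt(hyd, phil)  # the sheet sits on the hydrophobic face
  no_lig <- structure_subset(sc, which(sc$molecule_class != "lignin"))
  cov0 <- coverage_report(no_lig)
  expect_true(all(cov0$a_l == 0))
})

test_that("the SASA benchmark reports correlation, fit and deficit", {
  sc <- assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 12, dp = 20)), n_enzymes = 1,
    seed = 5))
  sel <- sample_atom_selections(sc, c(600, 1200, 2000, 3000, nrow(sc)),
                                seed = 6)
  bm <- benchmark_vs_sasa(sc, sel)
  expect_gt(bm$r, 0.99)
  expect_gt(bm$mean_percent_deficit, 0)
  expect_identical(nrow(bm$pairs), 5L)
  expect_error(benchmark_vs_sasa(sc, sel[1]), "two selections")
  # self-comparison degenerate case: identical values on both axes
  same <- bm$pairs$sasa
  expect_equal(stats::cor(same, same), 1)
})
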