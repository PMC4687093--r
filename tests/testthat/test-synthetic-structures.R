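test_that("fibril geometry follows the spec: span, counts, faces", {
  fib <- generate_fibril(fibril_spec(n_chains = 36, dp = 20))
  expect_identical(length(unique(fib$residue_id)), 36L * 20L)
  span <- diff(range(fib$z))
  expect_lt(abs(span - 20 * 5.2), 6)  # dp x monomer spacing, within a monomer
  # face labels cover all chains and the two hydrophobic rows oppose
  expect_false(anyNA(fib$face_label))
  chains <- tibble::as_tibble(fib) |>
    dplyr::distinct(region, face_label,
                    ymean = round(ave(y, region, FUN = mean), 3))
  hydro <- chains[chains$face_label == "hydrophobic", ]
  expect_gt(nrow(hydro), 0)
  expect_gt(max(hydro$ymean), mean(chains$ymean))
  expect_lt(min(hydro$ymean), mean(chains$ymean))
  # every monomer carries a planar ring proxy and a hydroxyl
  per_res <- tibble::as_tibble(fib) |>
    dplyr::count(residue_id, atom_class) |>
    tidyr::pivot_wider(names_from = atom_class, values_from = n)
  expect_true(all(per_res$ring == 6))
  expect_true(all(per_res$hydroxyl == 2))
})

test_that("crystalline fibrils are noise-free; zero disorder equals crystalline", {
  a <- generate_fibril(fibril_spec(n_chains = 7, dp = 6), seed = 1)
  b <- generate_fibril(fibril_spec(n_chains = 7, dp = 6), seed = 99)
  expect_identical(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z))
  c <- generate_fibril(fibril_spec(n_chains = 7, dp = 6, crystalline = FALSE,
                                   disorder_amplitude = 0), seed = 1)
  expect_equal(cbind(c$x, c$y, c$z), cbind(a$x, a$y, a$z), tolerance = 1e-12)
  d <- generate_fibril(fibril_spec(n_chains = 7, dp = 6, crystalline = FALSE,
                                   disorder_amplitude = 1.5), seed = 1)
  expect_false(isTRUE(all.equal(d$x, a$x)))
})

test_that("a non-default fibril axis reorients the whole fibril", {
  fib <- generate_fibril(fibril_spec(n_chains = 7, dp = 12,
                                     axis = c(1, 0, 0)))
  expect_gt(diff(range(fib$x)), diff(range(fib$z)))
})

test_that("the pseudo-enzyme carries its tagged anatomy", {
  enz <- generate_pseudo_enzyme(seed = 4)
  expect_setequal(unique(enz$region), c("CD", "linker", "CBM", "glycan"))
  expect_false(anyNA(enz$region))  # regions partition all beads
  tyr <- tibble::as_tibble(enz) |>
    dplyr::filter(region == "CBM", atom_class == "ring")
  expect_setequal(unique(tyr$residue_id), c(466L, 492L, 493L))
  expect_identical(nrow(tyr), 18L)  # three six-atom rings
  expect_equal(sum(tunnel_axis(enz, 1L)^2), 1, tolerance = 1e-12)
  expect_true(all(enz$residue_name[enz$region == "glycan"] == "MAN"))
})

test_that("lignin embeddings respect the topology and atom classes", {
  top <- generate_lignin_topology(20, seed = 5)
  lig <- generate_lignin_structure(top, "blob", seed = 6)
  expect_identical(nrow(lig), 20L * 15L)
  expect_setequal(unique(lig$atom_class), c("ring", "chain"))
  per_res <- tibble::as_tibble(lig) |> dplyr::count(residue_id, atom_class)
  expect_true(all(per_res$n[per_res$atom_class == "ring"] == 9))
  expect_true(all(per_res$n[per_res$atom_class == "chain"] == 6))
  # bonded monomers sit ~bond_length apart
  # the aromatic hexagon (first six atoms of each monomer) is centred on
  # the walk position, so its centroid recovers the monomer placement
  cents <- tibble::as_tibble(lig) |>
    dplyr::group_by(residue_id) |>
    dplyr::slice_head(n = 6) |>
    dplyr::summarise(x = mean(x), y = mean(y), z = mean(z))
  d <- sqrt((cents$x[top$linkages$monomer_i] - cents$x[top$linkages$monomer_j])^2 +
              (cents$y[top$linkages$monomer_i] - cents$y[top$linkages$monomer_j])^2 +
              (cents$z[top$linkages$monomer_i] - cents$z[top$linkages$monomer_j])^2)
  expect_true(all(abs(d - 4.8) < 1e-6))
  # flat mode stays in its plane
  flat <- generate_lignin_structure(top, "flat", seed = 7)
  expect_lt(diff(range(flat$y)), 4)
})

test_that("scene assembly honours boxes, clash distances and determinism", {
  sc <- demo_scene(seed = 11, monomers = 20)
  box <- attr(sc, "box")
  expect_true(all(sc$x >= 0 & sc$x <= box[1]))
  expect_true(all(sc$y >= 0 & sc$y <= box[2]))
  expect_true(all(sc$z >= 0 & sc$z <= box[3]))
  # brute-force clash scan on a subsample of molecule pairs
  md <- brute_min_dists(structure_subset(
    sc, which(sc$molecule_id %in% unique(sc$molecule_id)[1:5])))
  expect_true(all(md$min_dist >= 2.0))
  sc2 <- demo_scene(seed = 11, monomers = 20)
  expect_identical(tibble::as_tibble(sc), tibble::as_tibble(sc2))
  # no enzymes requested -> only cellulose and lignin present
  sc0 <- assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 7, dp = 10)),
    lignin = tibble::tibble(morphology = "pile", fibril = 1,
                            monomer_count = 10),
    n_enzymes = 0, seed = 2))
  expect_setequal(unique(sc0$molecule_class), c("cellulose", "lignin"))
})

test_that("impossible placements fail with an error naming the molecule", {
  spec <- scene_spec(
    fibrils = list(fibril_spec(n_chains = 7, dp = 6)),
    lignin = tibble::tibble(morphology = "sheet", fibril = 1,
                            monomer_count = 10, n_molecules = 40),
    n_enzymes = 0, seed = 1)
  expect_error(assemble_scene(spec, max_attempts = 3), "lignin molecule")
})

test_that("a linkage aggregate touches both bridged fibrils", {
  sc <- assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 10, dp = 20),
                   fibril_spec(n_chains = 10, dp = 20)),
    lignin = tibble::tibble(morphology = "linkage", fibril = 1,
                            monomer_count = 40),
    n_enzymes = 0, seed = 6))
  lig_id <- unique(sc$molecule_id[sc$molecule_class == "lignin"])
  md <- brute_min_dists(sc)
  touch <- md[(md$mol_i == lig_id | md$mol_j == lig_id) & md$min_dist <= 3.2, ]
  fibs <- setdiff(unique(c(touch$mol_i, touch$mol_j)), lig_id)
  expect_identical(length(fibs), 2L)
})
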