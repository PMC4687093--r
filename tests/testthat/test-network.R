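test_that("network edges pass contact totals through above the threshold", {
  st <- as_biomass_structure(tibble::tibble(
    x = c(0, 4, 8), y = 0, z = 0, molecule_id = 1:3,
    molecule_class = c("cellulose", "lignin", "enzyme")))
  contacts <- contact_number(st)
  net <- build_network(contacts, st, edge_threshold = 0.1)
  expect_equal(igraph::ecount(net), 2)  # 1-2 and 2-3; 1-3 is 8 A apart
  expect_equal(igraph::components(net)$no, 1)
  w <- igraph::E(net)$weight
  expect_equal(sort(w),
               sort(contacts$pair_totals$total[contacts$pair_totals$total > 0.1]),
               tolerance = 1e-12)
  # empty contacts -> edgeless graph over all molecules
  empty <- build_network(tibble::tibble(mol_i = integer(), mol_j = integer(),
                                        total = numeric()), st)
  expect_equal(igraph::ecount(empty), 0)
  expect_equal(igraph::vcount(empty), 3)
})

test_that("connectivity summary counts components and class degrees", {
  # star: one fibril hub touching three lignins that touch nothing else
  st <- as_biomass_structure(tibble::tibble(
    x = c(0, 3, -3, 0, 0), y = c(0, 0, 0, 3, 50), z = 0,
    molecule_id = 1:5,
    molecule_class = c("cellulose", "lignin", "lignin", "lignin", "lignin")))
  net <- build_network(contact_number(st), st, edge_threshold = 0.1)
  cs <- connectivity_summary(net)
  expect_equal(cs$n_components, 2)
  expect_equal(cs$largest_fraction, 4 / 5)
  deg <- cs$degree_by_class
  expect_gt(deg$mean_degree[deg$class == "cellulose"],
            deg$mean_degree[deg$class == "lignin"])
})

test_that("aggregate clustering equals brute-force connected components", {
  set.seed(21)
  for (rep in 1:5) {
    st <- random_scene(150, 10, span = 25,
                       classes = c("lignin", "lignin", "cellulose"))
    agg <- cluster_lignin_aggregates(st)
    lig_ids <- sort(unique(st$molecule_id[st$molecule_class == "lignin"]))
    if (length(lig_ids) == 0) next
    md <- brute_min_dists(structure_subset(
      st, which(st$molecule_class == "lignin")))
    touching <- md[md$min_dist <= 3.2, ]
    comp <- brute_components(lig_ids, touching$mol_i, touching$mol_j)
    # same partition: equal co-membership for every molecule pair
    got <- setNames(agg$aggregate_id, agg$molecule_id)
    for (a in seq_along(lig_ids)) for (b in seq_len(a - 1)) {
      ia <- as.character(lig_ids[a]); ib <- as.character(lig_ids[b])
      expect_identical(got[ia] == got[ib], comp[ia] == comp[ib])
    }
  }
})

test_that("distant lignins are singleton aggregates and touching ones merge", {
  top <- generate_lignin_topology(10, seed = 1)
  l1 <- generate_lignin_structure(top, "blob", seed = 1, molecule_id = 1)
  l2 <- generate_lignin_structure(top, "blob", seed = 2, molecule_id = 2)
  l2$x <- l2$x + 100
  st <- bind_structures(list(l1, l2), renumber_molecules = FALSE)
  expect_identical(dplyr::n_distinct(cluster_lignin_aggregates(st)$aggregate_id), 2L)
  l2b <- generate_lignin_structure(top, "blob", seed = 2, molecule_id = 2)
  # translate so one specific atom pair sits exactly 3.0 A apart
  shift <- c(l1$x[1] + 3.0 - l2b$x[1], l1$y[1] - l2b$y[1], l1$z[1] - l2b$z[1])
  l2b$x <- l2b$x + shift[1]; l2b$y <- l2b$y + shift[2]; l2b$z <- l2b$z + shift[3]
  st2 <- bind_structures(list(l1, l2b), renumber_molecules = FALSE)
  expect_identical(dplyr::n_distinct(cluster_lignin_aggregates(st2)$aggregate_id), 1L)
})

test_that("constructed sheet, pile and linkage scenes are labelled correctly", {
  sc <- demo_scene(seed = 42, monomers = 25)
  m <- lignin_morphologies(sc)
  expect_setequal(m$morphology, c("sheet", "pile", "linkage"))
  expect_gte(m$layer_fraction[m$morphology == "sheet"], 0.8)
  expect_lt(m$layer_fraction[m$morphology == "pile"], 0.8)
  expect_gte(m$n_fibrils_contacted[m$morphology == "linkage"], 2)
  # free label for an aggregate touching nothing
  top <- generate_lignin_topology(10, seed = 3)
  free <- generate_lignin_structure(top, "blob", seed = 4, molecule_id = 99)
  free$x <- free$x + 500
  st <- bind_structures(list(sc, free), renumber_molecules = FALSE)
  res <- classify_morphology(st, 99)
  expect_identical(res$morphology, "free")
})

test_that("morphology labels survive molecule reordering and rigid transforms", {
  sc <- demo_scene(seed = 7, monomers = 20)
  m0 <- lignin_morphologies(sc)
  set.seed(1)
  shuffled <- structure_subset(sc, sample(nrow(sc)))
  m1 <- lignin_morphologies(shuffled)
  expect_identical(dplyr::arrange(m0[, c("morphology", "n_molecules")], morphology),
                   dplyr::arrange(m1[, c("morphology", "n_molecules")], morphology))
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- cbind(sc$x, sc$y, sc$z) %*% R
  moved <- sc
  moved$x <- xyz[, 1] + 10; moved$y <- xyz[, 2]; moved$z <- xyz[, 3] - 5
  m2 <- lignin_morphologies(moved)
  expect_identical(sort(m0$morphology), sort(m2$morphology))
})

test_that("extended morphologies expose more lignin surface than piles", {
  sc <- assemble_scene(scene_spec(
    fibrils = list(fibril_spec(n_chains = 24, dp = 30)),
    lignin = tibble::tibble(morphology = c("sheet", "pile"), fibril = 1,
                            monomer_count = 16),
    n_enzymes = 0, seed = 5))
  m <- lignin_morphologies(sc)
  ex <- exposure_per_morphology(sc, m)
  expect_gt(ex$mean_exposed_area[ex$morphology == "sheet"],
            ex$mean_exposed_area[ex$morphology == "pile"])
  expect_true(all(ex$mean_exposed_area <= ex$mean_total_area + 1e-9))
  none <- exposure_per_morphology(sc, m[0, ])
  expect_identical(nrow(none), 0L)
})
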