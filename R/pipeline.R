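RUN_CONFIG_KEYS <- c("seed", "output_dir", "scene", "trajectory", "contacts",
                     "surface", "morphology", "stages", "window")
SCENE_KEYS <- c("n_fibrils", "n_chains", "dp", "crystalline", "fibril_gap",
                "lignin", "n_enzymes", "box")
TRAJ_KEYS <- c("n_frames", "dt", "d_trans", "d_rot", "frozen_cellulose")

#' Build and validate a pipeline configuration
#'
#' Strict configuration for [run_pipeline()]: unknown keys are rejected and
#' every scientific threshold must be explicit or comes from the documented
#' parameter constructors (no silent overrides).
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return A validated `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "lignocontact-out"
  config$stages <- config$stages %||%
    c("scene", "trajectory", "contacts", "states", "network", "morphology")
  bad_stage <- setdiff(config$stages,
                       c("scene", "trajectory", "contacts", "states",
                         "profile", "lifetimes", "surface", "network",
                         "morphology", "diffusion"))
  if (length(bad_stage) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  sc <- config$scene %||% list()
  unknown <- setdiff(names(sc), SCENE_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown scene key(s): ", paste(unknown, collapse = ", ")))
  }
  sc$n_fibrils <- sc$n_fibrils %||% 2L
  sc$n_chains <- sc$n_chains %||% 12L
  sc$dp <- sc$dp %||% 20L
  sc$crystalline <- sc$crystalline %||% TRUE
  sc$fibril_gap <- sc$fibril_gap %||% 45
  sc$n_enzymes <- sc$n_enzymes %||% 2L
  config$scene <- sc
  tr <- config$trajectory %||% list()
  unknown <- setdiff(names(tr), TRAJ_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown trajectory key(s): ", paste(unknown, collapse = ", ")))
  }
  tr$n_frames <- tr$n_frames %||% 50L
  tr$dt <- tr$dt %||% 1
  tr$d_trans <- tr$d_trans %||% 1e-7
  tr$d_rot <- tr$d_rot %||% 1e6
  tr$frozen_cellulose <- tr$frozen_cellulose %||% TRUE
  config$trajectory <- tr
  config$contacts <- do.call(contact_params, config$contacts %||% list())
  config$surface <- do.call(surface_params, config$surface %||% list())
  config$morphology <- do.call(morphology_params, config$morphology %||% list())
  structure(config, class = "run_config")
}

provenance_header <- function(config) {
  # hash the scientific configuration only, not where it is written
  sci <- unclass(config)
  sci$output_dir <- NULL
  hash <- rlang::hash(sci)
  c(sprintf("# lignocontact %s",
            as.character(utils::packageVersion("lignocontact"))),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %d", config$seed))
}

write_csv_prov <- function(tab, path, header) {
  writeLines(header, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic scene:
#' scene generation, Brownian trajectory, class contact series, binding
#' states, per-residue profile, contact lifetimes, face coverage, contact
#' network, aggregate morphology, diffusion. Every output file carries a
#' provenance header (package version, config hash, seed); identical
#' configs give identical outputs.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @return Invisibly, a named list of the objects computed, with the output
#'   paths in `$files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(name) file.path(config$output_dir, name)
  header <- provenance_header(config)
  stages <- config$stages
  results <- list(files = character())
  note <- function(p) results$files <<- c(results$files, p)

  sc <- config$scene
  lignin_req <- if (!is.null(sc$lignin)) {
    as_tibble(as.data.frame(do.call(rbind, lapply(sc$lignin, as.data.frame))))
  } else if (sc$n_fibrils >= 2) {
    tibble(morphology = c("sheet", "pile", "linkage"), fibril = 1L)
  } else {
    tibble(morphology = c("sheet", "pile"), fibril = 1L)
  }
  spec <- scene_spec(
    fibrils = replicate(sc$n_fibrils,
                        fibril_spec(n_chains = sc$n_chains, dp = sc$dp,
                                    crystalline = sc$crystalline),
                        simplify = FALSE),
    lignin = lignin_req, n_enzymes = sc$n_enzymes, box = sc$box,
    fibril_gap = sc$fibril_gap, seed = config$seed)
  scene <- assemble_scene(spec)
  results$scene <- scene
  if ("scene" %in% stages) {
    paths <- write_structure(scene, out_path("scene.pdb"),
                             out_path("scene_metadata.csv"))
    note(paths)
  }

  needs_traj <- any(c("trajectory", "contacts", "states", "profile",
                      "lifetimes", "diffusion") %in% stages)
  if (needs_traj) {
    tr <- config$trajectory
    frozen <- if (isTRUE(tr$frozen_cellulose)) {
      unique(scene$molecule_id[scene$molecule_class == "cellulose"])
    } else integer()
    bp <- brownian_params(d_trans = tr$d_trans, d_rot = tr$d_rot,
                          dt = tr$dt, n_frames = tr$n_frames,
                          frozen_molecules = frozen)
    traj <- generate_brownian_trajectory(scene, bp, seed = config$seed + 1L)
    results$trajectory <- traj
    if ("trajectory" %in% stages) {
      note(write_dcd(traj, out_path("trajectory.dcd")))
    }
    if ("contacts" %in% stages) {
      series <- contact_time_series(traj, params = config$contacts)
      results$contact_series <- series
      note(write_csv_prov(series, out_path("contact_series.csv"), header))
    }
    if ("states" %in% stages) {
      fr <- binding_state_fractions(traj, config$contacts)
      results$state_fractions <- fr
      jsonlite::write_json(list(provenance = list(seed = config$seed),
                                fractions = fr),
                           out_path("binding_states.json"), auto_unbox = TRUE,
                           digits = NA)
      note(out_path("binding_states.json"))
    }
    if ("profile" %in% stages) {
      nf <- n_frames(traj)
      win <- config$window %||% seq.int(max(1, nf - ceiling(nf / 3) + 1), nf)
      prof <- residue_contact_profile(traj, window = win,
                                      params = config$contacts)
      results$profile <- prof
      note(write_csv_prov(prof, out_path("residue_profile.csv"), header))
    }
    if ("lifetimes" %in% stages) {
      lt <- contact_lifetimes(traj, params = config$contacts)
      results$lifetimes <- lt
      note(write_csv_prov(lt$events, out_path("contact_events.csv"), header))
    }
    if ("diffusion" %in% stages) {
      enz <- unique(scene$molecule_id[scene$molecule_class == "enzyme"])
      if (length(enz) > 0) {
        dtr <- translational_diffusion(traj, enz)
        drt <- rotational_diffusion(traj, enz)
        results$diffusion <- list(translational = dtr, rotational = drt)
        note(write_csv_prov(bind_rows(glance(dtr), glance(drt)),
                            out_path("diffusion.csv"), header))
      }
    }
  }
  if ("surface" %in% stages) {
    cov <- coverage_report(scene, config$surface)
    results$coverage <- cov
    note(write_csv_prov(cov, out_path("coverage.csv"), header))
  }
  if ("network" %in% stages) {
    contacts <- contact_number(scene, params = config$contacts)
    net <- build_network(contacts, scene,
                         edge_threshold = config$morphology$edge_threshold)
    results$network <- net
    note(write_network(net, out_path("network.graphml")))
    note(write_csv_prov(contacts$pair_totals, out_path("network_edges.csv"),
                        header))
  }
  if ("morphology" %in% stages) {
    morph <- lignin_morphologies(scene, config$morphology, config$contacts)
    results$morphologies <- morph
    flat <- morph |>
      mutate(members = purrr::map_chr(.data$members, paste, collapse = ";"))
    note(write_csv_prov(flat, out_path("morphologies.csv"), header))
  }
  invisible(results)
}
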