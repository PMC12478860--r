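default_run_config <- function() {
  list(
    system = list(n_protein = 5000, dna_length = 250,
                  dna_bead_budget = 5000, box_edge = 2000,
                  placement_radius = NULL, seed = 1),
    forcefield = list(),   # overrides of ff_params() defaults
    dynamics = list(temperature = 300, dt = 10, t_damp = 1000,
                    n_steps = 1000, sample_every = 100, seed = 1,
                    record_velocities = FALSE,
                    quench_steps = 0, quench_t_damp = 0.1),
    analysis = list(cluster_cutoff = NULL,       # 1.5 * sigma_PD
                    cluster_per_pair = FALSE,    # 1.5 * sigma_ij variant
                    bound_cutoff = NULL,         # sigma_P + sigma_D
                    bin_width = 10,
                    n_blocks = 5, n_discard = 1,
                    lags = NULL,                 # ns; default from span
                    n_bins = 300, n_max_modes = 6,
                    improvement_threshold = 0.2, p_min = 0.01))
}

merge_section <- function(defaults, given, section) {
  bad <- setdiff(names(given), names(defaults))
  if (length(bad))
    stop(sprintf("unknown key(s) in config section '%s': %s", section,
                 paste(bad, collapse = ", ")))
  utils::modifyList(defaults, given)
}

#' Read a run configuration
#'
#' Parses a YAML run configuration with sections `system`, `forcefield`,
#' `dynamics` and `analysis`.  Every omitted key takes the published default
#' (5000 proteins, 5000 DNA beads in 250-bp chains, 2000 A box, 300 K,
#' 10 fs step, 1000 ps damping, cluster cutoff `1.5 sigma_PD`, binding
#' cutoff `sigma_P + sigma_D`, five blocks with the first discarded).
#' Unknown keys are rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    given <- yaml::read_yaml(path)
    bad <- setdiff(names(given), names(cfg))
    if (length(bad))
      stop("unknown config section(s): ", paste(bad, collapse = ", "))
    ff_known <- names(formals(ff_params))
    ff_bad <- setdiff(names(given$forcefield), ff_known)
    if (length(ff_bad))
      stop("unknown forcefield key(s): ", paste(ff_bad, collapse = ", "))
    for (s in names(given)) {
      if (s == "forcefield") cfg$forcefield <-
          utils::modifyList(cfg$forcefield, given$forcefield)
      else cfg[[s]] <- merge_section(cfg[[s]], given[[s]], s)
    }
  }
  structure(cfg, class = "run_config")
}

#' Interaction-regime labels
#'
#' Classifies a parameter point by the interaction bands used to discuss
#' condensate composition: heterotypic coupling is weak below
#' `lambda_PD = 0.5`, moderate to 1.0, strong above; homotypic coupling is
#' weak below `lambda_PP = 3` and strong from 3 up.
#'
#' @param lambda_PP,lambda_PD Hydropathy values.
#' @return `list(homotypic =, heterotypic =)` character labels.
#' @export
interaction_regime <- function(lambda_PP, lambda_PD) {
  list(homotypic = if (lambda_PP >= 3) "strong" else "weak",
       heterotypic = if (lambda_PD < 0.5) "weak"
                     else if (lambda_PD <= 1.0) "moderate" else "strong")
}

#' Run the build-simulate-analyze pipeline
#'
#' Builds the mixture, runs Langevin dynamics, and analyses the trajectory:
#' per-frame largest-cluster composition and DNA-bound fraction, mean DNA
#' R_g, coexistence concentrations, the radial protein profile with its
#' tanh fit on the final frame, and (optionally) displacement-distribution
#' diffusion modes.  All outputs are written under `out_dir` as plain-text
#' files plus a JSON manifest carrying the configuration, seeds and package
#' version; re-running the analysis stage on the stored trajectory is
#' bit-for-bit reproducible.
#'
#' @param config A `run_config` (see [read_run_config]).
#' @param out_dir Output directory (created if missing).
#' @param stages Character subset of `c("build", "simulate", "analyze")`;
#'   later stages reuse stored artifacts, so the analysis stage can be
#'   re-run alone on an existing trajectory.
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with the trajectory and analysis results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("build", "simulate", "analyze"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ff <- do.call(ff_params, config$forcefield)
  say <- function(...) if (verbose) message(sprintf(...))
  sysf <- file.path(out_dir, "system.xyz")
  trajf <- file.path(out_dir, "trajectory.xyz")

  topo <- NULL; sys <- NULL; traj <- NULL
  sc <- config$system
  n_chains <- chain_count(sc$dna_bead_budget, sc$dna_length)
  if ("build" %in% stages) {
    say("build: %d proteins + %d chains x %d beads in a %g A box",
        sc$n_protein, n_chains, sc$dna_length, sc$box_edge)
    built <- build_mixture(sc$n_protein, sc$dna_length, sc$dna_bead_budget,
                           sc$box_edge,
                           placement_radius =
                             if (is.null(sc$placement_radius))
                               sc$box_edge / 4 else sc$placement_radius,
                           seed = sc$seed, ff = ff)
    sys <- built$system; topo <- built$topology
    write_xyz(sys, sysf)
  } else {
    x <- read_xyz(sysf, ff)
    sys <- x$system
    topo <- make_topology(sum(sys$species == "protein"), n_chains,
                          sc$dna_length)
  }

  dyn <- config$dynamics
  if ("simulate" %in% stages) {
    if (dyn$quench_steps > 0) {
      # strong-friction quench to drain the energy of the packed start,
      # then fresh Maxwell-Boltzmann velocities for production
      say("simulate: quench %d steps at t_damp %g ps", dyn$quench_steps,
          dyn$quench_t_damp)
      lq <- langevin_params(temperature = dyn$temperature,
                            t_damp = dyn$quench_t_damp, dt = dyn$dt,
                            n_steps = dyn$quench_steps, seed = dyn$seed,
                            sample_every = dyn$quench_steps)
      tq <- run_langevin(sys, topo, ff, lq)
      sys$positions <- tq$positions[[n_frames(tq)]]
      sys$images <- tq$images[[n_frames(tq)]]
      sys <- maxwell_velocities(sys, dyn$temperature, seed = dyn$seed + 1)
    }
    lp <- langevin_params(temperature = dyn$temperature, t_damp = dyn$t_damp,
                          dt = dyn$dt, n_steps = dyn$n_steps,
                          seed = dyn$seed, sample_every = dyn$sample_every,
                          record_velocities = isTRUE(dyn$record_velocities))
    say("simulate: %d steps of %g fs at %g K (t_damp %g ps)",
        lp$n_steps, lp$dt, lp$temperature, lp$t_damp)
    traj <- run_langevin(sys, topo, ff, lp)
    write_traj_xyz(traj, trajf)
    say("simulate: final T_kin n/a, potential energy %.6g kcal/mol",
        traj$energies[n_frames(traj)])
  } else {
    traj <- read_traj_xyz(trajf, ff)
    traj$meta$topology <- topo
  }

  results <- list()
  if ("analyze" %in% stages) {
    an <- config$analysis
    ccut <- if (is.null(an$cluster_cutoff))
      1.5 * pair_sigma("protein", "dna", ff) else an$cluster_cutoff
    bcut <- if (is.null(an$bound_cutoff)) ff$sigma_P + ff$sigma_D
            else an$bound_cutoff
    blocks <- block_scheme(an$n_blocks, an$n_discard)
    say("analyze: clustering at %.4g A, binding at %.4g A", ccut, bcut)
    comp <- condensate_composition(traj, topo, cutoff = ccut,
                                   bound_cutoff = bcut, blocks = blocks,
                                   per_pair = isTRUE(an$cluster_per_pair))
    utils::write.table(comp$per_frame,
                       file.path(out_dir, "composition.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    rg <- if (n_chains > 0) mean_chain_rg(traj, topo, blocks) else NULL
    if (!is.null(rg))
      write_chain_observable(rg, file.path(out_dir, "chain_rg.tsv"))
    coex <- coexistence_concentrations(traj, topo, blocks,
                                       bin_width = an$bin_width,
                                       cutoff = ccut,
                                       per_pair = isTRUE(an$cluster_per_pair))
    # final-frame profile + fit
    p <- traj$positions[[n_frames(traj)]]
    cl <- cluster_beads(p, traj$box_edge, ccut, species = traj$species,
                        per_pair = isTRUE(an$cluster_per_pair))
    fr <- largest_cluster_fractions(cl, topo)
    members <- which(cl$labels == fr$largest_id & traj$species == "protein")
    prof_fit <- NULL
    if (length(members) >= 2) {
      ref <- periodic_com(p[members, , drop = FALSE], traj$box_edge)
      prof <- radial_density_profile(p, which(traj$species == "protein"),
                                     ref, traj$box_edge, an$bin_width)
      prof_fit <- tryCatch(fit_double_tanh(prof, r_max = traj$box_edge / 2),
                           error = function(e) NULL)
      write_profile(prof, file.path(out_dir, "protein_profile.tsv"),
                    prof_fit)
    }
    modes <- NULL
    if (!is.null(an$lags) && length(an$lags)) {
      dists <- lapply(an$lags, function(l)
        displacement_distribution(traj, l, an$n_bins))
      nsel <- select_mode_count(dists, an$n_max_modes,
                                an$improvement_threshold, an$p_min)
      modes <- fit_diffusion_modes(dists, nsel)
      for (i in seq_along(dists))
        write_displacement(dists[[i]],
                           file.path(out_dir, sprintf("displacement_lag%g.tsv",
                                                      an$lags[i])),
                           modes)
    }
    results <- list(composition = comp, chain_rg = rg, coexistence = coex,
                    profile_fit = prof_fit, modes = modes,
                    regime = interaction_regime(ff$lambda_PP, ff$lambda_PD))
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "cgdroplet",
    version = as.character(utils::packageVersion("cgdroplet")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seeds = list(system = config$system$seed,
                 dynamics = config$dynamics$seed),
    regime = interaction_regime(ff$lambda_PP, ff$lambda_PD),
    stages = stages,
    n_beads = length(sys$species),
    n_frames = if (!is.null(traj)) n_frames(traj) else 0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(system = sys, topology = topo, trajectory = traj,
                 results = results, manifest = manifest))
}
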