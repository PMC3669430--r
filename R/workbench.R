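# Configuration, orchestration and the build/run/analyze commands backing
# the command-line interface (inst/cli/mmcg).

#' Default run configuration
#'
#' All defaults equal the production protocol's values: 16 A nonbonded
#' cutoff, 6 A interface cutoff, 15 A droplet radius, 31 A membrane
#' thickness, 2 A lateral wall offset, 300 K, 0.4 ps friction relaxation
#' time, 1 A cluster cutoff, two replicas.
#'
#' @return nested configuration list (schema version 1)
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    structure = list(
      path = NULL,          # PDB path; NULL -> generate the toy fixture
      fixture = list(n_helices = 4L, residues_per_helix = 10L,
                     cavity_radius = 5.0, n_waters = 60L, seed = 1L),
      water_resnames = c("HOH", "SOL", "WAT"),
      ligand_resnames = c("LIG", "UNL", "UNK")
    ),
    regions = list(
      mm_residues = NULL,   # range string, e.g. "14-23, 70-101"; NULL -> fixture cavity
      interface_cutoff = 6.0
    ),
    forcefield = list(
      parameters = NULL,    # parameter YAML path; NULL -> toy_parameters()
      r_cut = 16.0
    ),
    go = list(eps_go = 16.0, k_chain = 1000, s_min = 3L, c_map = 4.5,
              sigma_rep = 4.0),
    walls = list(slab_thickness = 31.0, lateral_offset = 2.0,
                 droplet_radius = 15.0, droplet_mode = "ligand_centroid",
                 k_wall = 250, k_drop = 250),
    integrator = list(timestep = 0.002, temperature = 300,
                      tau_friction = 0.4, seed = 1L, n_steps = 2000L,
                      output_stride = 100L, com_removal = TRUE,
                      minimize_steps = 500L),
    replicas = list(n_replicas = 2L),
    analysis = list(cluster_cutoff = 1.0, exclude_residues = NULL,
                    hbond_max_distance = 3.5, hbond_min_angle = 130,
                    start_time = 0)
  )
}

#' Validate a configuration against the schema
#'
#' Unknown keys are errors, not warnings: silent typos in simulation
#' configurations are dangerous.
#'
#' @param config nested configuration list
#' @return the validated config (with defaults filled in)
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  merged <- merge_config(defaults, config, path = "")
  stopifnot(merged$forcefield$r_cut > 0,
            merged$regions$interface_cutoff > 0,
            merged$walls$droplet_radius > 0,
            merged$walls$slab_thickness > 0,
            merged$integrator$timestep > 0,
            merged$replicas$n_replicas >= 1)
  merged
}

merge_config <- function(defaults, config, path) {
  if (is.null(config)) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  out <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(defaults[[nm]], config[[nm]],
                                paste0(path, ".", nm))
    } else {
      out[[nm]] <- config[[nm]]
    }
  }
  out
}

#' @rdname validate_config
#' @param path YAML config file
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Effective configuration as flat key-value text
#' @param config validated config list
#' @export
format_config <- function(config) {
  flatten <- function(x, prefix = "") {
    out <- character(0)
    for (nm in names(x)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      v <- x[[nm]]
      if (is.list(v)) {
        out <- c(out, flatten(v, key))
      } else {
        out <- c(out, paste0(key, " = ",
                             if (is.null(v)) "NULL" else paste(v, collapse = ",")))
      }
    }
    out
  }
  flatten(config)
}

#' Build a simulation bundle from a configuration
#'
#' Reads or generates the structure, assigns regions, builds the Go model,
#' walls and constraints, prints the region census and serializes the
#' system to a versioned bundle directory.
#'
#' @param config configuration list (validated with [validate_config()])
#' @param out_dir bundle output directory
#' @param quiet suppress the census printout
#' @return the `mmcg_system`, invisibly; on disk: `system.rds`,
#'   `census.tsv`, `manifest.json`
#' @export
cmd_build <- function(config, out_dir, quiet = FALSE) {
  config <- validate_config(config)
  wall_hints <- list()
  if (!is.null(config$structure$path)) {
    st <- read_pdb(config$structure$path,
                   water_resnames = config$structure$water_resnames,
                   ligand_resnames = config$structure$ligand_resnames)
    topo <- st$topology; coords <- st$coordinates
    mm <- config$regions$mm_residues
    if (is.null(mm)) stop("regions.mm_residues is required for an external structure")
  } else {
    fx <- config$structure$fixture
    ts <- make_toy_system(n_helices = fx$n_helices,
                          residues_per_helix = fx$residues_per_helix,
                          cavity_radius = fx$cavity_radius,
                          n_waters = fx$n_waters,
                          droplet_radius = config$walls$droplet_radius,
                          seed = fx$seed)
    topo <- ts$topology; coords <- ts$coordinates
    mm <- config$regions$mm_residues
    if (is.null(mm)) mm <- ts$mm_residues
    wall_hints <- ts$wall_hints
  }
  if (is.character(mm)) mm <- parse_residue_ranges(mm)

  params <- if (is.null(config$forcefield$parameters)) {
    toy_parameters()
  } else {
    read_parameters(config$forcefield$parameters)
  }
  params$options$r_cut <- config$forcefield$r_cut

  regions <- assign_regions(topo, coords, mm,
                            interface_cutoff = config$regions$interface_cutoff)
  go <- build_go_model(topo, coords, regions,
                       eps_go = config$go$eps_go, k_chain = config$go$k_chain,
                       s_min = config$go$s_min, c_map = config$go$c_map,
                       sigma_rep = config$go$sigma_rep,
                       r_cut = config$forcefield$r_cut)
  system <- build_system(topo, coords, regions, params, go_model = go,
                         walls = c(list(
                           slab_thickness = config$walls$slab_thickness,
                           lateral_offset = config$walls$lateral_offset,
                           droplet_radius = config$walls$droplet_radius,
                           droplet_mode = config$walls$droplet_mode,
                           k_wall = config$walls$k_wall,
                           k_drop = config$walls$k_drop), wall_hints))
  if (config$integrator$minimize_steps > 0) {
    system <- prepare_system(system,
                             max_steps = config$integrator$minimize_steps)
  }
  census <- region_census(regions)
  if (!quiet) {
    message("region census: ",
            paste(census$region, census$n_residues, sep = "=", collapse = " "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(system, file.path(out_dir, "system.rds"), compress = FALSE)
    write.table(census, file.path(out_dir, "census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- list(
      bundle_version = 1L,
      package_version = as.character(utils::packageVersion("mmcg")),
      created_from = if (is.null(config$structure$path)) "fixture"
      else config$structure$path,
      n_particles = n_atoms(system$topology),
      config = config
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    writeLines(format_config(config), file.path(out_dir, "effective_config.txt"))
  }
  invisible(system)
}

#' Run replica simulations from a bundle
#'
#' Replica `k` runs with seed `seed + k - 1`; each replica's trajectory is
#' written as multi-model PDB plus an energy log.
#'
#' @param bundle an `mmcg_system` or a bundle directory from [cmd_build()]
#' @param config configuration list (integrator/replica blocks are used)
#' @param out_dir output directory (`NULL` to skip writing)
#' @return list of `mmcg_trajectory`, invisibly
#' @export
cmd_run <- function(bundle, config, out_dir = NULL) {
  config <- validate_config(config)
  system <- if (inherits(bundle, "mmcg_system")) bundle
  else readRDS(file.path(bundle, "system.rds"))
  ip <- config$integrator
  params <- make_integrator_params(
    timestep = ip$timestep, temperature = ip$temperature,
    tau_friction = ip$tau_friction, seed = ip$seed, n_steps = ip$n_steps,
    output_stride = ip$output_stride, com_removal = ip$com_removal
  )
  trajs <- run_replicas(system, params, n_replicas = config$replicas$n_replicas)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(trajs)) {
      write_trajectory_pdb(trajs[[k]],
                           file.path(out_dir, sprintf("replica_%d.pdb", k)))
      write_energy_log(trajs[[k]],
                       file.path(out_dir, sprintf("replica_%d_energy.tsv", k)))
    }
  }
  invisible(trajs)
}

#' Analyze joined replica trajectories
#'
#' Joins the replicas, computes the C-alpha RMSD series (with optional
#' residue exclusion), clusters the ligand poses, extracts central
#' structures, and computes H-bond distance series for every ligand N-H
#' donor against protein/water acceptors named in the config.
#'
#' @param trajectories list of `mmcg_trajectory` (or a single one)
#' @param config configuration list (analysis block)
#' @param out_dir report directory (`NULL` to skip writing)
#' @param distance_spec optional [distance_table()] spec evaluated on the
#'   top cluster's central structure
#' @param hbond_triples optional data frame for [hbond_series()]
#' @return list with `rmsd`, `clusters`, `central`, `hbonds`, `distances`
#' @export
cmd_analyze <- function(trajectories, config, out_dir = NULL,
                        distance_spec = NULL, hbond_triples = NULL) {
  config <- validate_config(config)
  if (inherits(trajectories, "mmcg_trajectory")) {
    trajectories <- list(trajectories)
  }
  joined <- join_replicas(trajectories)
  an <- config$analysis
  if (an$start_time > 0) {
    keep <- joined$times >= an$start_time
    joined$frames <- joined$frames[, , keep, drop = FALSE]
    joined$steps <- joined$steps[keep]
    joined$times <- joined$times[keep]
    joined$replica <- joined$replica[keep]
  }

  rmsd <- rmsd_timeseries(joined, exclude_residues = an$exclude_residues)
  clusters <- daura_cluster(joined, cutoff = an$cluster_cutoff)
  n_top <- min(2L, nrow(clusters$clusters))
  central <- lapply(seq_len(n_top), function(k) {
    central_structure(clusters, joined, k)
  })

  hb <- NULL
  if (is.null(hbond_triples)) hbond_triples <- default_hbond_triples(joined$topology)
  if (!is.null(hbond_triples) && nrow(hbond_triples) > 0) {
    hb <- hbond_series(joined, hbond_triples,
                       max_distance = an$hbond_max_distance,
                       min_angle = an$hbond_min_angle)
  }
  dist_tab <- NULL
  if (!is.null(distance_spec)) {
    dist_tab <- distance_table(central[[1]], joined$topology, distance_spec)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(rmsd, file.path(out_dir, "rmsd.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(clusters$clusters, file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in seq_along(central)) {
      write_pdb(joined$topology, central[[k]],
                file.path(out_dir, sprintf("central_cluster_%d.pdb", k)))
    }
    if (!is.null(hb)) {
      write.table(hb, file.path(out_dir, "hbonds.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(hbond_histogram(hb), file.path(out_dir, "hbond_histogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(dist_tab)) {
      write.table(dist_tab, file.path(out_dir, "distances.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  list(rmsd = rmsd, clusters = clusters, central = central, hbonds = hb,
       distances = dist_tab)
}

# ligand N-H donors paired with the nearest water oxygens is the natural
# default for the toy chemistry; returns NULL when no donor exists
default_hbond_triples <- function(topology) {
  a <- topology$atoms
  lig <- topology$ligand
  if (length(lig) == 0) return(NULL)
  donors <- lig[a$element[lig] %in% c("N", "O")]
  triples <- list()
  for (d in donors) {
    hs <- intersect(neighbors_of(topology, d), which(a$is_hydrogen))
    acceptors <- c(topology$water[a$element[topology$water] == "O"],
                   lig[a$element[lig] == "S"])
    acceptors <- setdiff(acceptors, d)
    for (h in hs) {
      for (acc in utils::head(acceptors, 3)) {
        triples[[length(triples) + 1]] <-
          data.frame(donor = d, hydrogen = h, acceptor = acc)
      }
    }
  }
  if (length(triples) == 0) return(NULL)
  do.call(rbind, triples)
}

neighbors_of <- function(topology, i) {
  b <- topology$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Run the full pipeline: build, run replicas, join, analyze
#'
#' @param config configuration list
#' @param out_dir run directory; subdirectories `bundle/`, `trajectories/`,
#'   `reports/` are created
#' @return the [cmd_analyze()] result, invisibly
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  bdir <- if (is.null(out_dir)) NULL else file.path(out_dir, "bundle")
  tdir <- if (is.null(out_dir)) NULL else file.path(out_dir, "trajectories")
  rdir <- if (is.null(out_dir)) NULL else file.path(out_dir, "reports")
  system <- cmd_build(config, bdir, quiet = TRUE)
  trajs <- cmd_run(system, config, tdir)
  invisible(cmd_analyze(trajs, config, rdir))
}
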