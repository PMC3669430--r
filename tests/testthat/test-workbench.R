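# Configuration, orchestration and the parameter-file interface.

test_that("config defaults carry the production protocol values", {
  cfg <- default_config()
  expect_equal(cfg$forcefield$r_cut, 16.0)
  expect_equal(cfg$regions$interface_cutoff, 6.0)
  expect_equal(cfg$walls$droplet_radius, 15.0)
  expect_equal(cfg$walls$slab_thickness, 31.0)
  expect_equal(cfg$walls$lateral_offset, 2.0)
  expect_equal(cfg$integrator$temperature, 300)
  expect_equal(cfg$integrator$tau_friction, 0.4)
  expect_equal(cfg$analysis$cluster_cutoff, 1.0)
  expect_equal(cfg$replicas$n_replicas, 2L)
  # the flattened effective config prints them all
  txt <- format_config(validate_config(cfg))
  for (needle in c("forcefield.r_cut = 16", "regions.interface_cutoff = 6",
                   "walls.droplet_radius = 15", "walls.slab_thickness = 31",
                   "walls.lateral_offset = 2", "integrator.temperature = 300",
                   "integrator.tau_friction = 0.4",
                   "analysis.cluster_cutoff = 1")) {
    expect_true(any(startsWith(txt, needle)), info = needle)
  }
})

test_that("unknown configuration keys are rejected, not warned about", {
  expect_error(validate_config(list(integrator = list(timestpe = 0.002))),
               "integrator.timestpe")
  expect_error(validate_config(list(walz = list())), "walz")
})

test_that("configs round-trip through YAML", {
  cfg <- default_config()
  cfg$integrator$n_steps <- 123L
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  back <- read_config(f)
  expect_equal(back$integrator$n_steps, 123L)
  expect_equal(back$walls$slab_thickness, 31)
})

test_that("parameter sets round-trip through their YAML schema", {
  params <- toy_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(params, f)
  back <- read_parameters(f)
  expect_equal(back$atom_types$OW$sigma, params$atom_types$OW$sigma)
  expect_equal(back$water$q_o, -0.82)
  # schema stamps are enforced
  bad <- unclass(params)
  bad$schema_version <- 99L
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f2)
  expect_error(read_parameters(f2), "schema")
})

test_that("the region census partitions the protein on a built bundle", {
  cfg <- default_config()
  cfg$structure$fixture$n_waters <- 10L
  cfg$integrator$minimize_steps <- 50L
  sys <- cmd_build(cfg, out_dir = NULL, quiet = TRUE)
  cen <- region_census(sys$regions)
  expect_equal(sum(cen$n_residues), 40)
})

test_that("the production MM residue list gives an MM census of 94 on a 320-residue chain", {
  n <- 320L
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resid = seq_len(n), resname = "ALA", chain = "A")
  topo <- make_topology(atoms)
  coords <- cbind(seq(0, by = 3.8, length.out = n), 0, 0)
  spec <- "14-23, 70-101, 103-104, 151-164, 187, 189, 193-204, 258-268, 277-287"
  reg <- assign_regions(topo, coords, spec)
  cen <- region_census(reg)
  expect_equal(cen$n_residues[cen$region == "MM"], 94L)
  # independent range-sum oracle
  lens <- c(23 - 14, 101 - 70, 104 - 103, 164 - 151, 0, 0, 204 - 193,
            268 - 258, 287 - 277) + 1
  expect_equal(sum(lens), 94)
})

test_that("rebuilding a bundle from the same inputs is byte-identical", {
  cfg <- default_config()
  cfg$structure$fixture$n_waters <- 8L
  cfg$integrator$minimize_steps <- 30L
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cmd_build(cfg, d1, quiet = TRUE)
  cmd_build(cfg, d2, quiet = TRUE)
  for (f in c("system.rds", "census.tsv", "effective_config.txt")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("replica runs use consecutive seeds and write logs and trajectories", {
  cfg <- default_config()
  cfg$structure$fixture$n_waters <- 8L
  cfg$integrator$minimize_steps <- 30L
  cfg$integrator$n_steps <- 300L
  cfg$integrator$output_stride <- 100L
  sys <- cmd_build(cfg, NULL, quiet = TRUE)
  d <- withr::local_tempdir()
  trajs <- cmd_run(sys, cfg, d)
  expect_length(trajs, 2)
  expect_false(identical(trajs[[1]]$frames, trajs[[2]]$frames))
  expect_true(file.exists(file.path(d, "replica_1.pdb")))
  expect_true(file.exists(file.path(d, "replica_2_energy.tsv")))
  lg <- read.table(file.path(d, "replica_1_energy.tsv"), header = TRUE)
  expect_equal(nrow(lg), 4) # n_steps / log_stride + 1
})

test_that("analysis of ground-truth fixtures recovers the known answers", {
  ts <- toy_system_small()
  cfg <- default_config()
  # static trajectory: zero RMSD, one cluster
  st <- make_reference_trajectory(ts$topology, ts$coordinates, "static",
                                  n_frames = 10)
  res <- cmd_analyze(list(st), cfg)
  expect_true(all(res$rmsd$rmsd < 1e-12))
  expect_equal(nrow(res$clusters$clusters), 1)
  # two-pose trajectory: populations 0.7 / 0.3
  tp <- make_reference_trajectory(ts$topology, ts$coordinates,
                                  "two_pose_switch", n_frames = 60,
                                  split = 0.7)
  res2 <- cmd_analyze(list(tp), cfg)
  expect_equal(res2$clusters$clusters$population, c(0.7, 0.3))
  # distance table on a constructed frame matches hand-computed values
  lig <- ts$topology$ligand
  a <- ts$topology$atoms
  spec <- list(list(label = "LigRing - LigS",
                    a = lig[a$name[lig] %in% paste0("C", 1:6)],
                    b = lig[a$name[lig] == "S1"]))
  res3 <- cmd_analyze(list(st), cfg, distance_spec = spec)
  ring <- colMeans(ts$coordinates[lig[a$name[lig] %in% paste0("C", 1:6)], ])
  sulfur <- ts$coordinates[lig[a$name[lig] == "S1"], ]
  expect_equal(res3$distances$distance, sqrt(sum((ring - sulfur)^2)))
})

test_that("the full pipeline is deterministic and reproduces every report byte for byte", {
  cfg <- default_config()
  cfg$structure$fixture$n_waters <- 8L
  cfg$integrator$minimize_steps <- 30L
  cfg$integrator$n_steps <- 200L
  cfg$integrator$output_stride <- 50L
  cfg$replicas$n_replicas <- 2L
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  reports <- list.files(file.path(d1, "reports"), recursive = TRUE)
  expect_gt(length(reports), 2)
  for (f in reports) {
    expect_identical(readBin(file.path(d1, "reports", f), "raw", 1e7),
                     readBin(file.path(d2, "reports", f), "raw", 1e7),
                     label = f)
  }
})

test_that("trajectory files round-trip through multi-model PDB and XYZ", {
  tr <- short_toy_trajectory()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, f)
  back <- read_trajectory_pdb(f)
  expect_equal(n_frames(back), n_frames(tr))
  expect_equal(back$frames, tr$frames, tolerance = 1e-3)

  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, f2)
  back2 <- read_trajectory_xyz(f2, tr$topology)
  expect_equal(back2$frames, tr$frames, tolerance = 1e-6)
  expect_equal(back2$steps, tr$steps)
})
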