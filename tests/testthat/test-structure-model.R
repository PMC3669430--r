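# PDB I/O, residue-range parsing and MM/I/CG region assignment.

test_that("a hand-written 3-atom PDB parses to the expected topology", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  st <- read_pdb(f)
  expect_equal(nrow(st$topology$atoms), 3)
  expect_equal(nrow(st$topology$residues), 1)
  expect_equal(st$topology$atoms$name, c("N", "CA", "C"))
  expect_equal(st$coordinates[2, 1], 1.458)
})

test_that("PDB write/read round-trips the toy bundle", {
  ts <- toy_system_small()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts$topology, ts$coordinates, f)
  st <- read_pdb(f)
  expect_equal(nrow(st$topology$atoms), n_atoms(ts$topology))
  expect_equal(st$topology$atoms$name, ts$topology$atoms$name)
  expect_equal(st$topology$atoms$resid, ts$topology$atoms$resid)
  expect_equal(st$coordinates, ts$coordinates, tolerance = 1e-3)
  # waters and ligand identified by residue name
  expect_equal(st$topology$water, ts$topology$water)
  expect_equal(st$topology$ligand, ts$topology$ligand)
})

test_that("ligand CONECT records round-trip and match a direct text scan", {
  ts <- toy_system_small()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts$topology, ts$coordinates, f)
  st <- read_pdb(f)
  # independent scan of CONECT lines
  lines <- readLines(f)
  con <- lines[startsWith(lines, "CONECT")]
  pairs <- do.call(rbind, lapply(con, function(l) {
    v <- as.integer(strsplit(trimws(substring(l, 7)), "\\s+")[[1]])
    cbind(v[1], v[-1])
  }))
  serial_to_idx <- setNames(seq_len(nrow(st$topology$atoms)),
                            st$topology$atoms$serial)
  scanned <- unique(t(apply(cbind(serial_to_idx[as.character(pairs[, 1])],
                                  serial_to_idx[as.character(pairs[, 2])]),
                            1, sort)))
  lig <- st$topology$ligand
  got <- st$topology$bonds
  got <- got[got[, 1] %in% lig & got[, 2] %in% lig, , drop = FALSE]
  expect_equal(got[order(got[, 1], got[, 2]), ],
               scanned[order(scanned[, 1], scanned[, 2]), ],
               ignore_attr = TRUE)
  # the toy ligand has 9 bonds: 6 ring + C-N + N-S + N-H
  expect_equal(nrow(got), 9)
})

test_that("PDB parsing rejects malformed records and duplicate serials", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       bad_coords_here", "END"), f)
  expect_error(read_pdb(f), "line 1")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      1  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), f2)
  expect_error(read_pdb(f2), "duplicate")
})

test_that("write_pdb uses fixed columns and enforces the column width", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C", resid = 1L,
                      resname = "ALA", chain = "A")
  topo <- make_topology(atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(topo, matrix(c(1, 2, 3), 1, 3), f)
  line <- readLines(f)[1]
  expect_equal(substr(line, 31, 54), "   1.000   2.000   3.000")
  expect_error(write_pdb(topo, matrix(c(12345, 0, 0), 1, 3), f),
               "column width")
})

test_that("atom count is conserved when writing large systems", {
  n <- 10000L
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resid = seq_len(n), resname = "ALA", chain = "A")
  topo <- make_topology(atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(topo, matrix(runif(3 * n, -99, 99), n, 3), f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "ATOM") | startsWith(lines, "HETATM")), n)
})

test_that("residue-range strings parse inclusively with hyphen or en-dash", {
  expect_equal(parse_residue_ranges("5"), 5L)
  expect_equal(parse_residue_ranges("1-3,3-5"), 1:5)
  expect_equal(parse_residue_ranges("1–3, 7"), c(1:3, 7L))
  expect_error(parse_residue_ranges("9-3"), "start exceeds end")
  expect_error(parse_residue_ranges("2, x"), "invalid token")
})

test_that("the production receptor MM residue string yields 94 residues", {
  spec <- "14–23, 70–101, 103–104, 151–164, 187, 189, 193–204, 258–268, 277–287"
  got <- parse_residue_ranges(spec)
  # independent brute-force enumeration over the printed ranges
  ranges <- list(c(14, 23), c(70, 101), c(103, 104), c(151, 164), c(187, 187),
                 c(189, 189), c(193, 204), c(258, 268), c(277, 287))
  oracle <- integer(0)
  for (r in ranges) for (k in r[1]:r[2]) oracle <- c(oracle, k)
  oracle <- sort(unique(oracle))
  expect_equal(got, oracle)
  expect_length(got, 94)
})

test_that("the 6 A interface rule is sharp at the cutoff", {
  # one MM residue at the origin; X's nearest atom at 6.0, Y's at 6.1
  atoms <- data.frame(
    serial = 1:3, name = "CA", element = "C",
    resid = 1:3, resname = "ALA", chain = "A"
  )
  topo <- make_topology(atoms)
  coords <- rbind(c(0, 0, 0), c(6.0, 0, 0), c(0, 6.1, 0))
  reg <- assign_regions(topo, coords, mm_residues = 1L)
  expect_equal(unname(unclass(reg)[c("2", "3")]), c("I", "CG"))
})

test_that("assigning every residue to MM leaves no I and no CG", {
  ts <- toy_system_small()
  reg <- assign_regions(ts$topology, ts$coordinates,
                        protein_residues(ts$topology))
  cen <- region_census(reg)
  expect_equal(cen$n_residues[cen$region == "I"], 0L)
  expect_equal(cen$n_residues[cen$region == "CG"], 0L)
})

test_that("region assignment matches the exhaustive all-pairs oracle", {
  set.seed(101)
  for (rep in 1:5) {
    nres <- 12L
    atoms <- data.frame(
      serial = seq_len(2 * nres),
      name = rep(c("CA", "CB"), nres),
      element = "C",
      resid = rep(seq_len(nres), each = 2),
      resname = "ALA", chain = "A"
    )
    topo <- make_topology(atoms)
    coords <- matrix(runif(6 * nres, 0, 25), ncol = 3)
    mm <- sort(sample(nres, 3))
    reg <- assign_regions(topo, coords, mm)
    oracle <- oracle_assign_regions(topo, coords, mm, 6.0)
    expect_equal(unclass(reg)[names(oracle)], oracle)
  }
})

test_that("region assignment partitions protein residues and is rigid-motion invariant", {
  ts <- toy_system_small()
  reg <- toy_regions_small()
  prot <- protein_residues(ts$topology)
  expect_setequal(as.integer(names(reg)), prot)
  expect_true(all(unclass(reg) %in% c("MM", "I", "CG")))

  # arbitrary rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ts$coordinates %*% R + matrix(c(5, -3, 11), n_atoms(ts$topology), 3,
                                         byrow = TRUE)
  reg2 <- assign_regions(ts$topology, moved, ts$mm_residues)
  expect_equal(unclass(reg2), unclass(reg))
})

test_that("mm_residues referencing an absent residue is an error", {
  ts <- toy_system_small()
  expect_error(assign_regions(ts$topology, ts$coordinates, c(1L, 999L)),
               "absent")
})
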