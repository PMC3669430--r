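#' Read a PDB file into a topology and coordinates
#'
#' ATOM/HETATM records are parsed with bio3d; CONECT records (used for ligand
#' bonds) are scanned directly since bio3d drops them. Waters and the ligand
#' are identified by configurable residue-name whitelists.
#'
#' @param path path to a PDB file
#' @inheritParams make_topology
#' @return list with elements `topology` (an [make_topology()] object) and
#'   `coordinates` (`n x 3` matrix, Angstrom)
#' @export
read_pdb <- function(path, water_resnames = c("HOH", "SOL", "WAT"),
                     ligand_resnames = c("LIG", "UNL", "UNK")) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # validate records up front so malformed lines fail with their line number
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54) {
      stop("malformed ATOM/HETATM record at line ", ln, ": too short")
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)
    )))
    if (anyNA(xyz)) {
      stop("malformed ATOM/HETATM record at line ", ln,
           ": unparseable coordinates")
    }
    serial <- suppressWarnings(as.integer(substr(l, 7, 11)))
    if (is.na(serial)) {
      stop("malformed ATOM/HETATM record at line ", ln, ": bad serial")
    }
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  if (anyDuplicated(a$eleno)) {
    stop("duplicate atom serial number(s) in ", path, ": ",
         paste(unique(a$eleno[duplicated(a$eleno)]), collapse = ", "))
  }
  element <- a$elesy
  bad <- is.na(element) | trimws(element) == ""
  element[bad] <- guess_element(trimws(a$elety[bad]))
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = trimws(element),
    resid = a$resno,
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    stringsAsFactors = FALSE
  )
  coords <- cbind(a$x, a$y, a$z)

  # CONECT records: pairs of serials -> atom indices
  conect <- lines[rec == "CONECT"]
  bonds <- NULL
  if (length(conect) > 0) {
    serial_to_index <- setNames(seq_len(nrow(atoms)), atoms$serial)
    pairs <- list()
    for (l in conect) {
      flds <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))),
                                                   "\\s+")[[1]]))
      flds <- flds[!is.na(flds)]
      if (length(flds) >= 2) {
        for (to in flds[-1]) pairs[[length(pairs) + 1]] <- c(flds[1], to)
      }
    }
    if (length(pairs) > 0) {
      pm <- do.call(rbind, pairs)
      known <- pm[, 1] %in% atoms$serial & pm[, 2] %in% atoms$serial
      pm <- pm[known, , drop = FALSE]
      bonds <- cbind(serial_to_index[as.character(pm[, 1])],
                     serial_to_index[as.character(pm[, 2])])
    }
  }

  topology <- make_topology(atoms, bonds = bonds,
                            water_resnames = water_resnames,
                            ligand_resnames = ligand_resnames)
  list(topology = topology, coordinates = check_coords(topology, coords))
}

#' Write a topology and coordinates as a fixed-column PDB file
#'
#' Protein atoms are written as ATOM records, ligand and water atoms as
#' HETATM; ligand bonds are emitted as CONECT records so they round-trip
#' through [read_pdb()].
#'
#' @param topology an `mmcg_topology`
#' @param coordinates `n x 3` matrix, Angstrom
#' @param path output file
#' @param model optional model number; when given, records are wrapped in
#'   MODEL/ENDMDL (used for multi-model trajectories)
#' @param append append to an existing file instead of overwriting
#' @export
write_pdb <- function(topology, coordinates, path, model = NULL, append = FALSE) {
  coordinates <- check_coords(topology, coordinates)
  if (any(abs(coordinates) >= 10000)) {
    stop("coordinate exceeds PDB fixed-column width (|x| >= 10000 A)")
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(format_pdb_records(topology, coordinates, model = model), con)
}

format_pdb_records <- function(topology, coordinates, model = NULL) {
  a <- topology$atoms
  n <- nrow(a)
  het <- seq_len(n) %in% c(topology$ligand, topology$water)
  rec <- ifelse(het, "HETATM", "ATOM  ")
  # atom names of <4 characters start in column 14 by PDB convention
  name <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, name, a$resname, a$chain, a$resid,
                   coordinates[, 1], coordinates[, 2], coordinates[, 3],
                   1.0, 0.0, a$element)
  if (length(topology$ligand) > 0 && nrow(topology$bonds) > 0) {
    lig_bonds <- topology$bonds[topology$bonds[, 1] %in% topology$ligand &
                                  topology$bonds[, 2] %in% topology$ligand, ,
                                drop = FALSE]
    if (nrow(lig_bonds) > 0) {
      conect <- sprintf("CONECT%5d%5d",
                        a$serial[lig_bonds[, 1]], a$serial[lig_bonds[, 2]])
      lines <- c(lines, conect)
    }
  }
  if (!is.null(model)) {
    lines <- c(sprintf("MODEL     %4d", model), lines, "ENDMDL")
  } else {
    lines <- c(lines, "END")
  }
  lines
}
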