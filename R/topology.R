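#' Build a molecular topology
#'
#' A topology records the atoms of the simulated complex (protein, ligand,
#' water), the residue table, the bond list and which atoms belong to the
#' ligand and to water. Coordinates are kept separately as an `n x 3` matrix
#' in Angstrom.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`, `resid`,
#'   `resname`, `chain`; optional `mass` (amu) and `charge` (e). Missing
#'   masses are filled from the element, missing charges are 0.
#' @param bonds integer matrix with two columns of atom indices (1-based,
#'   row order of `atoms`), or `NULL` for no bonds.
#' @param water_resnames,ligand_resnames residue-name whitelists used to
#'   classify atoms; PDB dialects vary, so these are configurable.
#' @return an object of class `mmcg_topology`.
#' @export
make_topology <- function(atoms, bonds = NULL,
                          water_resnames = c("HOH", "SOL", "WAT"),
                          ligand_resnames = c("LIG", "UNL", "UNK")) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "resid", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(atoms)
  if (n == 0) stop("topology must contain at least one atom")
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serial number(s): ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  }
  if (any(atoms$serial <= 0)) stop("atom serials must be positive")
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms$element[is.na(atoms$element) | atoms$element == ""] <-
    guess_element(atoms$name[is.na(atoms$element) | atoms$element == ""])
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  atoms$mass[is.na(atoms$mass)] <- element_mass(atoms$element[is.na(atoms$mass)])
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$charge[is.na(atoms$charge)] <- 0
  atoms$is_hydrogen <- toupper(atoms$element) == "H"

  # residues must occupy contiguous atom spans; each atom belongs to one
  key <- paste(atoms$chain, atoms$resid, sep = "|")
  rle_key <- rle(key)
  if (anyDuplicated(rle_key$values)) {
    stop("residue atom records are not contiguous for: ",
         paste(unique(rle_key$values[duplicated(rle_key$values)]), collapse = ", "))
  }
  last <- cumsum(rle_key$lengths)
  first <- last - rle_key$lengths + 1L
  residues <- data.frame(
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    chain = atoms$chain[first],
    first = first,
    last = last,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(residues$resid)) {
    stop("residue indices must be unique across chains")
  }

  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2) stop("bonds must have two columns")
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond atom index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    # canonical order, drop duplicates
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }

  water <- which(atoms$resname %in% water_resnames)
  ligand <- which(atoms$resname %in% ligand_resnames)
  if (length(intersect(water, ligand)) > 0) {
    stop("water and ligand residue-name whitelists overlap")
  }

  structure(
    list(atoms = atoms, residues = residues, bonds = bonds,
         ligand = ligand, water = water),
    class = "mmcg_topology"
  )
}

#' @export
print.mmcg_topology <- function(x, ...) {
  cat("mmcg topology:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues,",
      nrow(x$bonds), "bonds\n")
  cat("  ligand atoms:", length(x$ligand), " water atoms:", length(x$water), "\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Protein residue indices (everything that is neither ligand nor water)
#' @param topology an `mmcg_topology`
#' @return integer vector of residue indices
#' @export
protein_residues <- function(topology) {
  special <- unique(topology$atoms$resid[c(topology$ligand, topology$water)])
  setdiff(topology$residues$resid, special)
}

#' Select atom indices by residue, name, residue name, element or chain
#'
#' All given filters are combined with AND; `NULL` filters are ignored.
#'
#' @param topology an `mmcg_topology`
#' @param resid,name,resname,element,chain filter values (vectors allowed)
#' @return integer vector of atom indices (row order of the atom table)
#' @export
select_atoms <- function(topology, resid = NULL, name = NULL, resname = NULL,
                         element = NULL, chain = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

#' Indices of the C-alpha atoms, ordered by the residue table
#' @param topology an `mmcg_topology`
#' @param residues optional residue indices to restrict to
#' @export
calpha_indices <- function(topology, residues = NULL) {
  idx <- select_atoms(topology, name = "CA")
  if (!is.null(residues)) idx <- idx[topology$atoms$resid[idx] %in% residues]
  idx[order(topology$atoms$resid[idx])]
}

heavy_atoms <- function(topology) which(!topology$atoms$is_hydrogen)

atoms_of_residue <- function(topology, resid) {
  r <- topology$residues[topology$residues$resid == resid, ]
  if (nrow(r) == 0) stop("residue ", resid, " not present in topology")
  seq.int(r$first, r$last)
}

check_coords <- function(topology, coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) != n_atoms(topology)) {
    stop("coordinates must be a numeric matrix with one row per atom and 3 columns")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  unname(coords)
}
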