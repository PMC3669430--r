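#' Parse a residue-range specification string
#'
#' Accepts comma-separated single indices and inclusive ranges written with
#' either a hyphen or an en-dash (the form residue lists are printed in),
#' e.g. `"14-23, 70-101, 187"`.
#'
#' @param spec character scalar
#' @return sorted integer vector, the union of all listed indices
#' @export
parse_residue_ranges <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  spec <- gsub("–|—", "-", spec) # en/em-dash -> hyphen
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0) stop("empty residue range specification")
  out <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      if (ab[1] > ab[2]) {
        stop("invalid range '", tok, "': start exceeds end")
      }
      out <- c(out, seq.int(ab[1], ab[2]))
    } else {
      stop("invalid token in residue specification: '", tok, "'")
    }
  }
  sort(unique(out))
}

#' Partition protein residues into MM, I and CG regions
#'
#' MM residues are given explicitly (the binding-cavity residues); the
#' interface (I) region consists of every remaining protein residue whose
#' minimum heavy-atom distance to the MM boundary (the MM protein residues
#' and the ligand) is within `interface_cutoff`; everything else is CG.
#' Ligand and water belong to the MM region unconditionally and are not
#' assigned here; the mobile solvent does not define the boundary.
#'
#' @param topology an `mmcg_topology`
#' @param coordinates `n x 3` matrix, Angstrom
#' @param mm_residues integer vector of MM residue indices, or a range string
#'   for [parse_residue_ranges()]
#' @param interface_cutoff Angstrom; default 6
#' @return an `mmcg_regions` object: a named character vector
#'   (`MM`/`I`/`CG`) over protein residue indices, with the cutoff as an
#'   attribute
#' @export
assign_regions <- function(topology, coordinates, mm_residues,
                           interface_cutoff = 6.0) {
  coordinates <- check_coords(topology, coordinates)
  if (is.character(mm_residues)) mm_residues <- parse_residue_ranges(mm_residues)
  mm_residues <- as.integer(mm_residues)
  if (length(mm_residues) == 0) stop("mm_residues must be nonempty")
  if (!is.numeric(interface_cutoff) || interface_cutoff <= 0) {
    stop("interface_cutoff must be positive")
  }
  prot <- protein_residues(topology)
  absent <- setdiff(mm_residues, prot)
  if (length(absent) > 0) {
    stop("mm_residues reference absent protein residue(s): ",
         paste(absent, collapse = ", "))
  }

  region <- setNames(rep("CG", length(prot)), prot)
  region[as.character(mm_residues)] <- "MM"

  # the MM boundary: heavy atoms of the MM protein residues and the ligand
  # (water is MM but mobile solvent, so it does not define the boundary)
  heavy <- !topology$atoms$is_hydrogen
  mm_atoms <- c(
    which(topology$atoms$resid %in% mm_residues & heavy &
            !(seq_len(n_atoms(topology)) %in% c(topology$ligand, topology$water))),
    topology$ligand[heavy[topology$ligand]]
  )
  mm_xyz <- coordinates[mm_atoms, , drop = FALSE]

  for (r in setdiff(prot, mm_residues)) {
    idx <- atoms_of_residue(topology, r)
    idx <- idx[heavy[idx]]
    if (length(idx) == 0) next
    dmin <- min_cross_distance(coordinates[idx, , drop = FALSE], mm_xyz)
    if (dmin <= interface_cutoff) region[as.character(r)] <- "I"
  }

  structure(region, interface_cutoff = interface_cutoff, class = "mmcg_regions")
}

# minimum distance between two point sets (vectorised over the larger set)
min_cross_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2min <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    d2min <- min(d2min, min(d2))
  }
  sqrt(d2min)
}

#' @export
print.mmcg_regions <- function(x, ...) {
  census <- table(factor(unclass(x), levels = c("MM", "I", "CG")))
  cat("mmcg region assignment (interface cutoff ",
      attr(x, "interface_cutoff"), " A):\n", sep = "")
  cat(sprintf("  MM %d | I %d | CG %d residues\n",
              census["MM"], census["I"], census["CG"]))
  invisible(x)
}

#' Region census as a tibble
#' @param regions an `mmcg_regions` object
#' @export
region_census <- function(regions) {
  tab <- table(factor(unclass(regions), levels = c("MM", "I", "CG")))
  tibble::tibble(region = names(tab), n_residues = as.integer(tab))
}

residues_in_region <- function(regions, which_region) {
  as.integer(names(regions)[unclass(regions) %in% which_region])
}
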