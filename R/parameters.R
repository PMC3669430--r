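#' MM parameter sets
#'
#' A parameter set defines the atomistic force field: per-type Lennard-Jones
#' parameters, per-atom type assignments and partial charges, harmonic bond
#' and angle terms, periodic dihedral terms, the SPC water model and the
#' nonbonded options (16 A energy-shifted cutoff, 1-4 scaling). The
#' functional forms are fixed (harmonic bonds `E = k/2 (r-r0)^2`, harmonic
#' angles, periodic dihedrals `E = k (1 + cos(n phi - delta))`, 12-6 LJ,
#' Coulomb); parameters are data. Lorentz-Berthelot combination rules are
#' used for LJ cross terms.
#'
#' `toy_parameters()` returns the small parameter set used by the synthetic
#' fixture systems; [read_parameters()] / [write_parameters()] exchange a
#' parameter set with a version-stamped YAML file.
#'
#' @return an object of class `mmcg_parameters`
#' @export
toy_parameters <- function() {
  params <- list(
    schema_version = 1L,
    atom_types = list(
      CA = list(sigma = 3.4, epsilon = 0.30),
      CB = list(sigma = 3.4, epsilon = 0.40),
      CR = list(sigma = 3.4, epsilon = 0.35),
      NL = list(sigma = 3.2, epsilon = 0.50),
      SL = list(sigma = 3.6, epsilon = 0.60),
      HL = list(sigma = 1.2, epsilon = 0.10),
      OW = list(sigma = 3.166, epsilon = 0.650),
      HW = list(sigma = 1.2, epsilon = 0.10)
    ),
    type_map = list(
      ALA = list(CA = list(type = "CA", charge = 0.0),
                 CB = list(type = "CB", charge = 0.0)),
      LIG = list(C1 = list(type = "CR", charge = 0.40),
                 C2 = list(type = "CR", charge = 0.0),
                 C3 = list(type = "CR", charge = 0.0),
                 C4 = list(type = "CR", charge = 0.0),
                 C5 = list(type = "CR", charge = 0.0),
                 C6 = list(type = "CR", charge = 0.0),
                 N1 = list(type = "NL", charge = -0.40),
                 S1 = list(type = "SL", charge = -0.30),
                 HN1 = list(type = "HL", charge = 0.30))
    ),
    bond_types = list(
      `CA:CA` = list(k = 1000, r0 = 3.83),
      `CA:CB` = list(k = 1000, r0 = 1.90),
      `CR:CR` = list(k = 2000, r0 = 1.39),
      `CR:NL` = list(k = 2000, r0 = 1.35),
      `NL:SL` = list(k = 2000, r0 = 1.65),
      `HL:NL` = list(k = 400, r0 = 1.01),
      `*` = list(k = 1000, r0 = 1.50)
    ),
    angle_types = list(
      `CA:CA:CA` = list(k = 100, theta0 = 90.4),
      `CA:CA:CB` = list(k = 0, theta0 = 109.47),
      `CR:CR:CR` = list(k = 300, theta0 = 120),
      `CR:CR:NL` = list(k = 300, theta0 = 120),
      `CR:NL:SL` = list(k = 300, theta0 = 120),
      `CR:NL:HL` = list(k = 150, theta0 = 118),
      `HL:NL:SL` = list(k = 150, theta0 = 120),
      `*` = list(k = 100, theta0 = 109.47)
    ),
    dihedral_types = list(
      `CA:CA:CA:CA` = list(k = 20, n = 1, delta = -130),
      `CR:CR:CR:CR` = list(k = 15, n = 2, delta = 180),
      `*` = list(k = 0, n = 1, delta = 0)
    ),
    water = list(
      resnames = c("SOL", "HOH", "WAT"),
      d_oh = 1.0, angle = 109.47,
      q_o = -0.82, q_h = 0.41,
      type_o = "OW", type_h = "HW",
      k_bond = 400, k_angle = 100
    ),
    options = list(
      r_cut = 16.0, shift = TRUE,
      scale14_lj = 1.0, scale14_coul = 1.0,
      sigma_rep = 4.0, eps_rep = 1.0
    )
  )
  validate_parameters(params)
}

validate_parameters <- function(params) {
  stopifnot(is.list(params))
  for (nm in c("schema_version", "atom_types", "type_map", "bond_types",
               "angle_types", "dihedral_types", "water", "options")) {
    if (is.null(params[[nm]])) stop("parameter set is missing '", nm, "'")
  }
  for (tn in names(params$atom_types)) {
    at <- params$atom_types[[tn]]
    if (!is.numeric(at$sigma) || at$sigma <= 0) {
      stop("atom type ", tn, ": sigma must be > 0")
    }
    if (!is.numeric(at$epsilon) || at$epsilon < 0) {
      stop("atom type ", tn, ": epsilon must be >= 0")
    }
  }
  for (bn in names(params$bond_types)) {
    if (params$bond_types[[bn]]$k < 0) stop("bond type ", bn, ": k must be >= 0")
  }
  for (an in names(params$angle_types)) {
    if (params$angle_types[[an]]$k < 0) stop("angle type ", an, ": k must be >= 0")
  }
  w <- params$water
  if (abs(w$q_o + 2 * w$q_h) > 1e-9) stop("water charges must sum to zero")
  if (params$options$r_cut <= 0) stop("nonbonded cutoff must be positive")
  structure(params, class = "mmcg_parameters")
}

#' @rdname toy_parameters
#' @param path YAML file
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file does not exist: ", path)
  params <- yaml::read_yaml(path)
  if (is.null(params$schema_version)) {
    stop("parameter file has no schema_version stamp")
  }
  if (params$schema_version != 1) {
    stop("unsupported parameter schema version: ", params$schema_version)
  }
  params$water$resnames <- as.character(params$water$resnames)
  validate_parameters(params)
}

#' @rdname toy_parameters
#' @param params an `mmcg_parameters` object
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# --- lookups ---------------------------------------------------------------

atom_params <- function(topology, params) {
  a <- topology$atoms
  n <- nrow(a)
  type <- character(n)
  charge <- numeric(n)
  water_mask <- seq_len(n) %in% topology$water
  w <- params$water
  for (i in seq_len(n)) {
    if (water_mask[i]) {
      if (toupper(a$element[i]) == "O") {
        type[i] <- w$type_o; charge[i] <- w$q_o
      } else {
        type[i] <- w$type_h; charge[i] <- w$q_h
      }
      next
    }
    tm <- params$type_map[[a$resname[i]]]
    if (is.null(tm)) {
      stop("no type map for residue name '", a$resname[i], "'")
    }
    ent <- tm[[a$name[i]]]
    if (is.null(ent)) ent <- tm[["*"]]
    if (is.null(ent)) {
      stop("no type-map entry for atom '", a$name[i], "' in residue '",
           a$resname[i], "'")
    }
    type[i] <- ent$type
    charge[i] <- ent$charge
  }
  unknown <- setdiff(unique(type), names(params$atom_types))
  if (length(unknown) > 0) {
    stop("atom type(s) without LJ parameters: ", paste(unknown, collapse = ", "))
  }
  sigma <- vapply(type, function(t) params$atom_types[[t]]$sigma, numeric(1))
  eps <- vapply(type, function(t) params$atom_types[[t]]$epsilon, numeric(1))
  data.frame(type = type, sigma = unname(sigma), eps = unname(eps),
             charge = charge, stringsAsFactors = FALSE)
}

lookup_bond <- function(params, t1, t2) {
  key <- paste(sort(c(t1, t2)), collapse = ":")
  ent <- params$bond_types[[key]]
  if (is.null(ent)) ent <- params$bond_types[["*"]]
  if (is.null(ent)) stop("no bond parameters for type pair ", key)
  ent
}

lookup_angle <- function(params, t1, t2, t3) {
  keys <- c(paste(c(t1, t2, t3), collapse = ":"),
            paste(c(t3, t2, t1), collapse = ":"))
  for (k in keys) {
    ent <- params$angle_types[[k]]
    if (!is.null(ent)) return(ent)
  }
  ent <- params$angle_types[["*"]]
  if (is.null(ent)) stop("no angle parameters for type triple ", keys[1])
  ent
}

lookup_dihedral <- function(params, t1, t2, t3, t4) {
  keys <- c(paste(c(t1, t2, t3, t4), collapse = ":"),
            paste(c(t4, t3, t2, t1), collapse = ":"))
  for (k in keys) {
    ent <- params$dihedral_types[[k]]
    if (!is.null(ent)) return(ent)
  }
  ent <- params$dihedral_types[["*"]]
  if (is.null(ent)) stop("no dihedral parameters for type quadruple ", keys[1])
  ent
}

# --- bonded-term and exclusion construction --------------------------------

# Adjacency list of the bond graph (constraint bonds included: exclusions
# and angle/dihedral enumeration see the full connectivity).
bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

# Bonded terms + exclusions for the atomistic part of a topology.
# `constrained` is a 2-column matrix of atom pairs handled by SHAKE; those
# bonds carry no harmonic term, and angles whose two component bonds are both
# constrained (rigid water) are dropped.
build_bonded_terms <- function(topology, params, constrained = NULL) {
  ap <- atom_params(topology, params)
  bonds <- topology$bonds
  n <- n_atoms(topology)
  adj <- bond_adjacency(n, bonds)
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  con_keys <- character(0)
  if (!is.null(constrained) && nrow(constrained) > 0) {
    con_keys <- pair_key(constrained[, 1], constrained[, 2])
  }
  is_water <- seq_len(n) %in% topology$water

  bt <- list(i = integer(0), j = integer(0), k = numeric(0), r0 = numeric(0))
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (pair_key(i, j) %in% con_keys) next
      if (is_water[i] && is_water[j]) {
        ent <- list(k = params$water$k_bond, r0 = params$water$d_oh)
      } else {
        ent <- lookup_bond(params, ap$type[i], ap$type[j])
      }
      if (ent$k > 0) {
        bt$i <- c(bt$i, i); bt$j <- c(bt$j, j)
        bt$k <- c(bt$k, ent$k); bt$r0 <- c(bt$r0, ent$r0)
      }
    }
  }

  at <- list(i = integer(0), j = integer(0), k = integer(0),
             kth = numeric(0), th0 = numeric(0))
  for (jc in seq_len(n)) {
    nb <- adj[[jc]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) {
      for (b in seq.int(a + 1, length(nb))) {
        i <- nb[a]; k <- nb[b]
        both_con <- pair_key(i, jc) %in% con_keys && pair_key(jc, k) %in% con_keys
        if (both_con) next
        if (is_water[jc]) {
          ent <- list(k = params$water$k_angle, theta0 = params$water$angle)
        } else {
          ent <- lookup_angle(params, ap$type[i], ap$type[jc], ap$type[k])
        }
        if (ent$k > 0) {
          at$i <- c(at$i, i); at$j <- c(at$j, jc); at$k <- c(at$k, k)
          at$kth <- c(at$kth, ent$k)
          at$th0 <- c(at$th0, ent$theta0 * pi / 180)
        }
      }
    }
  }

  dt <- list(i = integer(0), j = integer(0), k = integer(0), l = integer(0),
             kd = numeric(0), n = integer(0), phase = numeric(0))
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      jc <- bonds[b, 1]; kc <- bonds[b, 2]
      for (i in setdiff(adj[[jc]], kc)) {
        for (l in setdiff(adj[[kc]], c(jc, i))) {
          ent <- lookup_dihedral(params, ap$type[i], ap$type[jc],
                                 ap$type[kc], ap$type[l])
          if (ent$k > 0) {
            dt$i <- c(dt$i, i); dt$j <- c(dt$j, jc)
            dt$k <- c(dt$k, kc); dt$l <- c(dt$l, l)
            dt$kd <- c(dt$kd, ent$k); dt$n <- c(dt$n, as.integer(ent$n))
            dt$phase <- c(dt$phase, ent$delta * pi / 180)
          }
        }
      }
    }
  }

  # exclusions: bond-graph distance 1 and 2; distance-3 pairs are the 1-4 list
  excl <- list(i = integer(0), j = integer(0))
  p14 <- list(i = integer(0), j = integer(0))
  seen <- new.env(hash = TRUE)
  add_pair <- function(lst, i, j) {
    k <- pair_key(i, j)
    if (!is.null(seen[[k]])) return(lst)
    assign(k, TRUE, envir = seen)
    lst$i <- c(lst$i, min(i, j)); lst$j <- c(lst$j, max(i, j))
    lst
  }
  for (i in seq_len(n)) {
    for (j in adj[[i]]) if (j > i) excl <- add_pair(excl, i, j)
  }
  for (jc in seq_len(n)) {
    nb <- adj[[jc]]
    if (length(nb) >= 2) {
      for (a in seq_len(length(nb) - 1)) {
        for (b in seq.int(a + 1, length(nb))) {
          excl <- add_pair(excl, nb[a], nb[b])
        }
      }
    }
  }
  # 1-4: endpoints of each dihedral path not already excluded
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      jc <- bonds[b, 1]; kc <- bonds[b, 2]
      for (i in setdiff(adj[[jc]], kc)) {
        for (l in setdiff(adj[[kc]], c(jc, i))) {
          k <- pair_key(i, l)
          if (is.null(seen[[k]])) {
            assign(k, TRUE, envir = seen)
            p14$i <- c(p14$i, min(i, l)); p14$j <- c(p14$j, max(i, l))
          }
        }
      }
    }
  }

  list(atom_params = ap, bonds = bt, angles = at, dihedrals = dt,
       excl = excl, p14 = p14)
}
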