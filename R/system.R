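#' Molecular system (topology)
#'
#' A lightweight topology container: chains, residues and atoms with masses.
#' Per-residue boolean flags (\code{do_tilt}, \code{do_splay}, or any
#' user-named flag) mark the lipids entering the tilt/splay statistics,
#' typically those of the central unit cell after periodic extension.
#'
#' @param atom_name character vector of atom names, one per atom.
#' @param res_name character vector of residue names, one per atom.
#' @param res_number integer vector of residue numbers, one per atom.
#'   Consecutive atoms sharing (chain, number, name) form one residue.
#' @param chain character vector of chain names, one per atom.
#' @param mass numeric vector of atomic masses in amu, or \code{NULL} to
#'   derive them from atom names via [mass_from_name()].
#' @param mass_table optional named numeric vector overriding masses by atom
#'   name (useful for coarse-grained beads).
#' @return An object of class \code{"molecular_system"} with components
#'   \code{atoms} (data.frame: \code{name}, \code{mass}, \code{res} index)
#'   and \code{residues} (data.frame: \code{name}, \code{number},
#'   \code{chain}, \code{do_tilt}, \code{do_splay}).
#' @export
molecular_system <- function(atom_name, res_name, res_number, chain,
                             mass = NULL, mass_table = NULL) {
  n <- length(atom_name)
  stopifnot(length(res_name) == n, length(res_number) == n,
            length(chain) == n)
  if (is.null(mass)) mass <- mass_from_name(atom_name, mass_table)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("all atom masses must be positive and finite")
  key <- paste(chain, res_number, res_name, sep = "\r")
  res_id <- cumsum(c(TRUE, key[-1] != key[-n]))
  first <- !duplicated(res_id)
  residues <- data.frame(name = res_name[first],
                         number = res_number[first],
                         chain = chain[first],
                         do_tilt = FALSE, do_splay = FALSE,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(name = atom_name, mass = as.numeric(mass),
                      res = res_id, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chains\n")
  invisible(x)
}

#' Atomic masses from atom names
#'
#' Looks atom names up in \code{mass_table} first (exact name match, e.g.
#' coarse-grained bead names), then guesses the element from the leading
#' letters of the name and uses a built-in element table.
#'
#' @param name character vector of atom names.
#' @param mass_table optional named numeric vector of per-name masses.
#' @param default mass (amu) used when nothing matches; \code{NA} to error.
#' @return Numeric vector of masses in amu.
#' @export
mass_from_name <- function(name, mass_table = NULL, default = 12.011) {
  elements <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                S = 32.06, NA. = 22.990, CL = 35.45, K = 39.098,
                MG = 24.305, CA = 40.078, FE = 55.845, ZN = 65.38)
  out <- rep(NA_real_, length(name))
  if (!is.null(mass_table)) {
    hit <- match(name, names(mass_table))
    out[!is.na(hit)] <- mass_table[hit[!is.na(hit)]]
  }
  todo <- is.na(out)
  if (any(todo)) {
    stripped <- toupper(gsub("[^A-Za-z].*$", "", name[todo]))
    two <- substr(stripped, 1, 2)
    one <- substr(stripped, 1, 1)
    m <- elements[match(two, names(elements))]
    m[is.na(m)] <- elements[match(one[is.na(m)], names(elements))]
    out[todo] <- m
  }
  if (any(is.na(out))) {
    if (is.na(default)) stop("could not assign a mass to some atom names")
    out[is.na(out)] <- default
  }
  out
}

#' Parse a selection expression
#'
#' Minimal selection dialect: conjunctions of \code{rname=...},
#' \code{aname=...} and \code{cname=...} clauses joined by \code{" and "},
#' each taking a comma-separated list of names (e.g.
#' \code{"rname=DPPC and aname=P,C2"}). This is the subset of query grammar
#' the tilt/splay workflow needs.
#'
#' @param expr selection string.
#' @return A named list with character vectors \code{rname}, \code{aname},
#'   \code{cname} (\code{NULL} when a clause is absent).
#' @export
parse_selection <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1)
  out <- list(rname = NULL, aname = NULL, cname = NULL)
  if (!nzchar(trimws(expr))) return(out)
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    parts <- strsplit(cl, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed selection clause: '", cl, "'")
    key <- trimws(parts[1])
    if (!key %in% c("rname", "aname", "cname"))
      stop("unknown selection key: '", key, "'")
    vals <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    out[[key]] <- unique(c(out[[key]], vals[nzchar(vals)]))
  }
  out
}

#' Select atoms by residue name, atom name and chain
#'
#' @param system a [molecular_system()].
#' @param expr selection string (see [parse_selection()]) or a parsed
#'   selection list.
#' @return Integer vector of atom indices (topology order). An empty match
#'   returns \code{integer(0)} with a message, not an error.
#' @export
select_atoms <- function(system, expr) {
  sel <- if (is.character(expr)) parse_selection(expr) else expr
  keep <- rep(TRUE, nrow(system$atoms))
  if (!is.null(sel$aname))
    keep <- keep & system$atoms$name %in% sel$aname
  if (!is.null(sel$rname))
    keep <- keep & system$residues$name[system$atoms$res] %in% sel$rname
  if (!is.null(sel$cname))
    keep <- keep & system$residues$chain[system$atoms$res] %in% sel$cname
  idx <- which(keep)
  if (length(idx) == 0)
    message("selection matched no atoms: ",
            if (is.character(expr)) expr else "(parsed selection)")
  idx
}

#' Mass-weighted centre of mass
#'
#' @param system a [molecular_system()].
#' @param indices atom indices (non-empty).
#' @param positions Nx3 coordinate matrix for the whole system (one frame).
#' @return Numeric 3-vector.
#' @export
center_of_mass <- function(system, indices, positions) {
  if (length(indices) == 0) stop("center_of_mass of an empty selection")
  w <- system$atoms$mass[indices]
  drop(crossprod(positions[indices, , drop = FALSE], w)) / sum(w)
}

#' Lipid species definitions
#'
#' Per-species selection expressions for the head group (director head and
#' tilt reference point), the tail (director base), and the distance sites
#' (atoms near the pivotal plane used for inter-lipid distances), mirroring
#' the dictionary convention of the underlying method.
#'
#' @param species character vector of lipid residue names.
#' @param head_group,tail,distance named character vectors (one entry per
#'   species) of selection strings, typically \code{"aname=..."}.
#' @param solvent_names character vector of solvent residue names.
#' @return An object of class \code{"lipid_definitions"}.
#' @export
lipid_definitions <- function(species, head_group, tail, distance,
                              solvent_names) {
  for (m in list(head_group, tail, distance)) {
    if (!all(species %in% names(m)) || !all(names(m) %in% species))
      stop("head_group, tail and distance must each have exactly one entry ",
           "per lipid species")
  }
  structure(list(species = species,
                 head_group = head_group[species],
                 tail = tail[species],
                 distance = distance[species],
                 solvent_names = solvent_names),
            class = "lipid_definitions")
}

#' Set per-residue boolean flags from a selection
#'
#' Marks residues whose atoms match \code{expr}; all other residues get
#' \code{FALSE}. Used to restrict tilt/splay statistics, e.g. to the central
#' unit cell after periodic extension, or to one leaflet.
#'
#' @param system a [molecular_system()].
#' @param expr selection string.
#' @param flags character vector of flag column names to set
#'   (default \code{c("do_tilt", "do_splay")}).
#' @return The modified \code{molecular_system}.
#' @export
set_residue_flags <- function(system, expr,
                              flags = c("do_tilt", "do_splay")) {
  idx <- select_atoms(system, expr)
  res <- unique(system$atoms$res[idx])
  for (f in flags) {
    system$residues[[f]] <- FALSE
    system$residues[[f]][res] <- TRUE
  }
  system
}

#' Trajectory container
#'
#' @param system a [molecular_system()].
#' @param frames list of Nx3 coordinate matrices (Angstrom), one per frame.
#' @param cell 3x3 matrix of unit-cell vectors (rows a, b, c, Angstrom),
#'   constant over the trajectory.
#' @return An object of class \code{"trajectory"}.
#' @export
trajectory <- function(system, frames, cell) {
  stopifnot(length(frames) >= 1)
  n <- nrow(system$atoms)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("every frame must be an Nx3 matrix matching the topology")
  cell <- as.matrix(cell)
  stopifnot(all(dim(cell) == c(3, 3)))
  if (abs(det(cell)) < 1e-9)
    stop("unit cell vectors must be linearly independent")
  structure(list(system = system, frames = frames, cell = cell),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      nrow(x$system$atoms), "atoms, cell volume",
      round(abs(det(x$cell)), 1), "A^3\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)
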