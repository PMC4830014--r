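#' Lipid director vector
#'
#' Unit vector pointing from the tail site to the head site of a lipid
#' (typically centres of mass of the last chain carbons and of a few
#' headgroup heavy atoms).
#'
#' @param head_com,tail_com 3-vectors, Angstrom.
#' @return Unit 3-vector.
#' @export
compute_director <- function(head_com, tail_com) {
  v <- head_com - tail_com
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("head and tail sites coincide; director undefined")
  v / n
}

#' Lipid tilt angle
#'
#' Angle between a lipid director and the local interface normal, folded to
#' \code{[0, pi/2]} via the absolute dot product. With solvent-oriented
#' normals, directors of the two leaflets anti-align with the same normal
#' field; folding makes the tilt estimator leaflet-agnostic.
#'
#' @param director,normal unit 3-vectors.
#' @return Tilt angle theta in radians, in \code{[0, pi/2]}.
#' @export
compute_tilt <- function(director, normal) {
  acos(min(1, abs(sum(director * normal))))
}

#' Finite-difference lipid splay for one pair
#'
#' Implements the finite-difference directional derivative combining the
#' director and normal fields between two nearby lipids:
#' \deqn{S_i = [(n_2 - n_1)\cdot e + (N_2 - N_1)\cdot e] / h}
#' where \eqn{e} is the unit vector from lipid 1 to lipid 2 orthogonalized
#' against \eqn{N_1} and \eqn{h} is the tangential (in-plane) distance.
#'
#' @param n1,n2 unit director vectors of the two lipids.
#' @param N1,N2 unit interface normals at the two lipids.
#' @param p1,p2 positions of the two lipids' distance sites.
#' @param normal_sign sign of the normal-difference term; \code{+1} is the
#'   standard finite-difference form (for flat interfaces the term vanishes
#'   and the choice is immaterial).
#' @return A list with \code{s} (splay, 1/Angstrom), \code{h} (tangential
#'   distance, Angstrom) and \code{e} (tangent unit vector), or \code{NULL}
#'   when \code{p2 - p1} has no tangential component.
#' @export
compute_splay <- function(n1, n2, N1, N2, p1, p2, normal_sign = 1) {
  dvec <- p2 - p1
  if (sum(dvec^2) < 1e-24) stop("coincident lipid positions")
  tang <- dvec - sum(dvec * N1) * N1
  h <- sqrt(sum(tang^2))
  if (h < 1e-9) return(NULL)
  e <- tang / h
  s <- (sum((n2 - n1) * e) + normal_sign * sum((N2 - N1) * e)) / h
  list(s = s, h = h, e = e)
}

# Resolve per-lipid site atom indices for every residue of the defined
# species. Returns a list with the lipid table and grouped index vectors.
lipid_site_index <- function(system, defs) {
  res_names <- system$residues$name
  lip_rows <- which(res_names %in% defs$species)
  if (length(lip_rows) == 0) stop("no lipid residues found in the system")
  tab <- data.frame(res = lip_rows,
                    species = res_names[lip_rows],
                    stringsAsFactors = FALSE)
  sites <- list()
  for (role in c("head_group", "tail", "distance")) {
    idx_all <- integer(0)
    grp_all <- integer(0)
    for (sp in unique(tab$species)) {
      if (is.na(defs[[role]][sp]))
        stop("species '", sp, "' missing from the ", role, " mapping")
      sel <- select_atoms(system,
                          paste0("rname=", sp, " and ", defs[[role]][sp]))
      if (length(sel) == 0)
        stop("selection for ", role, " of species '", sp,
             "' matched no atoms")
      res_of <- system$atoms$res[sel]
      rows <- match(res_of, lip_rows)
      missing_res <- setdiff(lip_rows[tab$species == sp], unique(res_of))
      if (length(missing_res) > 0)
        stop("some '", sp, "' residues have no ", role, " atoms")
      idx_all <- c(idx_all, sel)
      grp_all <- c(grp_all, rows)
    }
    sites[[role]] <- list(idx = idx_all, grp = grp_all,
                          w = system$atoms$mass[idx_all])
  }
  list(table = tab, sites = sites)
}

# Mass-weighted COM per lipid for one frame; returns an n_lipids x 3 matrix.
site_com <- function(positions, site, n_lip) {
  p <- positions[site$idx, , drop = FALSE] * site$w
  num <- rowsum(p, site$grp, reorder = TRUE)
  den <- rowsum(site$w, site$grp, reorder = TRUE)
  out <- matrix(NA_real_, n_lip, 3)
  out[as.integer(rownames(num)), ] <- num / den[, 1]
  out
}

#' Per-lipid tilt angles over a trajectory
#'
#' For every frame and every lipid whose tilt flag is set, computes the
#' director from the head/tail site definitions and the tilt against the
#' normal of the interface point nearest to the headgroup centre of mass.
#'
#' @param traj an aligned [trajectory()].
#' @param defs a [lipid_definitions()].
#' @param surface an [interface_surface()] with normals.
#' @param flag name of the residue flag selecting lipids (default
#'   \code{"do_tilt"}).
#' @param frames frame indices to analyze (default all).
#' @return Named list (by species) of data frames with columns
#'   \code{frame}, \code{lipid} (residue row), \code{theta} (radians) and
#'   \code{surf_point}.
#' @export
analyze_tilts <- function(traj, defs, surface, flag = "do_tilt",
                          frames = NULL) {
  if (is.null(surface$normals)) stop("surface has no normals")
  sys <- traj$system
  li <- lipid_site_index(sys, defs)
  flagged <- sys$residues[[flag]][li$table$res]
  if (is.null(flagged)) stop("unknown flag: ", flag)
  keep <- which(flagged)
  if (length(keep) == 0) return(setNames(list(), character(0)))
  if (is.null(frames)) frames <- seq_along(traj$frames)
  n_lip <- nrow(li$table)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- traj$frames[[frames[fi]]]
    head_com <- site_com(f, li$sites$head_group, n_lip)
    tail_com <- site_com(f, li$sites$tail, n_lip)
    hc <- head_com[keep, , drop = FALSE]
    dir_vec <- normalize_rows(hc - tail_com[keep, , drop = FALSE])
    np <- nearest_surface_point(surface, hc)
    nrm <- surface$normals[np, , drop = FALSE]
    theta <- acos(pmin(1, abs(rowSums(dir_vec * nrm))))
    out[[fi]] <- data.frame(frame = frames[fi],
                            lipid = li$table$res[keep],
                            species = li$table$species[keep],
                            theta = theta, surf_point = np,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  if (is.null(all) || nrow(all) == 0)
    return(setNames(list(), character(0)))
  split(all[c("frame", "lipid", "theta", "surf_point")], all$species)
}

#' Pairwise lipid splays over a trajectory
#'
#' Enumerates, per frame, all unordered lipid pairs whose distance-site
#' centres of mass are closer than \code{cutoff} (3-D distance) and of which
#' at least one has the splay flag set, and computes the finite-difference
#' splay of [compute_splay()] for each. Normals are taken at the interface
#' points nearest to each lipid's headgroup.
#'
#' @param traj an aligned [trajectory()].
#' @param defs a [lipid_definitions()].
#' @param surface an [interface_surface()] with normals.
#' @param flag residue flag name (default \code{"do_splay"}).
#' @param cutoff pair distance cutoff in Angstrom (default 10); the 3-D
#'   distance-site separation must be below it, which also bounds the
#'   tangential step h of the finite difference.
#' @param frames frame indices to analyze (default all).
#' @param normal_sign see [compute_splay()].
#' @return Named list (by unordered species pair, \code{"A|B"}) of data
#'   frames with columns \code{frame}, \code{lipid1}, \code{lipid2},
#'   \code{s} (1/Angstrom) and \code{h} (Angstrom).
#' @export
analyze_splays <- function(traj, defs, surface, flag = "do_splay",
                           cutoff = 10, frames = NULL, normal_sign = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(surface$normals)) stop("surface has no normals")
  sys <- traj$system
  li <- lipid_site_index(sys, defs)
  flagged <- sys$residues[[flag]][li$table$res]
  if (is.null(flagged)) stop("unknown flag: ", flag)
  if (is.null(frames)) frames <- seq_along(traj$frames)
  n_lip <- nrow(li$table)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- traj$frames[[frames[fi]]]
    dcom <- site_com(f, li$sites$distance, n_lip)
    pairs <- .pairs_within_cpp(dcom, cutoff, flagged)
    if (nrow(pairs) == 0) next
    head_com <- site_com(f, li$sites$head_group, n_lip)
    tail_com <- site_com(f, li$sites$tail, n_lip)
    dirs <- normalize_rows(head_com - tail_com)
    np <- nearest_surface_point(surface, head_com)
    nrm <- surface$normals[np, , drop = FALSE]
    i <- pairs[, 1]; j <- pairs[, 2]
    dvec <- dcom[j, , drop = FALSE] - dcom[i, , drop = FALSE]
    N1 <- nrm[i, , drop = FALSE]
    tang <- dvec - rowSums(dvec * N1) * N1
    h <- sqrt(rowSums(tang^2))
    okh <- h > 1e-9
    if (!any(okh)) next
    i <- i[okh]; j <- j[okh]; h <- h[okh]
    e <- tang[okh, , drop = FALSE] / h
    dn <- dirs[j, , drop = FALSE] - dirs[i, , drop = FALSE]
    dN <- nrm[j, , drop = FALSE] - nrm[i, , drop = FALSE]
    s <- (rowSums(dn * e) + normal_sign * rowSums(dN * e)) / h
    sp1 <- li$table$species[i]
    sp2 <- li$table$species[j]
    key <- ifelse(sp1 <= sp2, paste(sp1, sp2, sep = "|"),
                  paste(sp2, sp1, sep = "|"))
    out[[fi]] <- data.frame(frame = frames[fi],
                            lipid1 = li$table$res[i],
                            lipid2 = li$table$res[j],
                            s = s, h = h, pair = key,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  if (is.null(all) || nrow(all) == 0)
    return(setNames(list(), character(0)))
  split(all[c("frame", "lipid1", "lipid2", "s", "h")], all$pair)
}

#' Area per lipid from the simulation cell
#'
#' For a planar system, the in-plane area of the unit cell divided by the
#' number of lipids per leaflet, averaged over frames. For lipid mixtures a
#' single shared value is used for all species.
#'
#' @param traj a [trajectory()].
#' @param species lipid residue names (used to count lipids when
#'   \code{lipids_per_leaflet} is not given).
#' @param lipids_per_leaflet lipid count per leaflet; default: number of
#'   residues of the given species divided by 2.
#' @param plane membrane plane, \code{"xy"}, \code{"xz"} or \code{"yz"}.
#' @return Area per lipid in Angstrom^2.
#' @export
analyze_area_per_lipid <- function(traj, species,
                                   lipids_per_leaflet = NULL,
                                   plane = "xy") {
  if (is.null(lipids_per_leaflet)) {
    n <- sum(traj$system$residues$name %in% species)
    lipids_per_leaflet <- n / 2
  }
  if (lipids_per_leaflet <= 0) stop("no lipids in leaflet")
  ij <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3),
               stop("plane must be one of 'xy', 'xz', 'yz'"))
  v1 <- traj$cell[ij[1], ]
  v2 <- traj$cell[ij[2], ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  sqrt(sum(cr^2)) / lipids_per_leaflet
}

#' Partition a system into independently analyzed parts
#'
#' Adds one boolean residue flag per named part (e.g. upper/lower leaflet);
#' tilt/splay analysis is then run once per part by passing the part name as
#' the \code{flag} argument. Selections may use the coordinate predicates
#' \code{x>val}, \code{x<val} (and y, z), evaluated on residue centres of
#' mass in \code{positions}.
#'
#' @param system a [molecular_system()].
#' @param parts named list of selection strings.
#' @param positions Nx3 reference coordinates (needed for coordinate
#'   predicates).
#' @return The system with one new residue flag per part.
#' @export
partition_flags <- function(system, parts, positions = NULL) {
  stopifnot(!is.null(names(parts)), all(nzchar(names(parts))))
  for (pn in names(parts)) {
    expr <- parts[[pn]]
    coord <- extract_coord_predicates(expr)
    idx <- if (nzchar(coord$rest)) select_atoms(system, coord$rest)
           else seq_len(nrow(system$atoms))
    matched_res <- unique(system$atoms$res[idx])
    if (length(coord$preds) > 0) {
      if (is.null(positions))
        stop("coordinate predicates require reference positions")
      keep <- rep(TRUE, length(matched_res))
      for (pi in seq_along(matched_res)) {
        at <- which(system$atoms$res == matched_res[pi])
        com <- center_of_mass(system, at, positions)
        for (pr in coord$preds) {
          v <- com[pr$axis]
          ok <- if (pr$op == ">") v > pr$value else v < pr$value
          if (!ok) keep[pi] <- FALSE
        }
      }
      matched_res <- matched_res[keep]
    }
    system$residues[[pn]] <- FALSE
    system$residues[[pn]][matched_res] <- TRUE
  }
  system
}

# Split "z>0 and rname=DPPC" into coordinate predicates and the remaining
# name-based selection.
extract_coord_predicates <- function(expr) {
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  is_coord <- grepl("^\\s*[xyz]\\s*[<>]", clauses)
  preds <- lapply(clauses[is_coord], function(cl) {
    m <- regmatches(cl, regexec("^\\s*([xyz])\\s*([<>])\\s*(-?[0-9.]+)", cl))[[1]]
    if (length(m) != 4) stop("malformed coordinate predicate: '", cl, "'")
    list(axis = match(m[2], c("x", "y", "z")), op = m[3],
         value = as.numeric(m[4]))
  })
  list(preds = preds, rest = paste(clauses[!is_coord], collapse = " and "))
}

#' Full tilt/splay analysis of an aligned trajectory
#'
#' Convenience driver: computes the time-averaged water and lipid densities,
#' extracts the equal-density interface and its normals, and collects tilt
#' and splay samples. The trajectory must already be aligned (for planar
#' systems, wrapped and COM-centered; for curved systems, density-aligned).
#'
#' @param traj an aligned [trajectory()].
#' @param defs a [lipid_definitions()].
#' @param water_expr selection for the solvent density (default: residues in
#'   \code{defs$solvent_names}).
#' @param lipid_expr selection for the lipid density (default: residues in
#'   \code{defs$species}).
#' @param tilt_flag,splay_flag residue flag names.
#' @param cutoff splay pair cutoff (A).
#' @param resolution density resolution (A).
#' @param density_frames frame indices used for the averaged densities
#'   (default: all frames; a stride is usually sufficient).
#' @param fit_radius normal plane-fit radius (A).
#' @param normal_sign see [compute_splay()].
#' @param outdir optional directory: densities (MRC), interface (PDB +
#'   normals table) and samples (CSV) are written there.
#' @return List with \code{tilts}, \code{splays}, \code{surface},
#'   \code{water_map}, \code{lipid_map}.
#' @export
analyze_lipid_tilt_and_splay <- function(traj, defs,
                                         water_expr = NULL,
                                         lipid_expr = NULL,
                                         tilt_flag = "do_tilt",
                                         splay_flag = "do_splay",
                                         cutoff = 10, resolution = 4,
                                         density_frames = NULL,
                                         fit_radius = 10, normal_sign = 1,
                                         outdir = NULL) {
  if (is.null(water_expr))
    water_expr <- paste0("rname=", paste(defs$solvent_names, collapse = ","))
  if (is.null(lipid_expr))
    lipid_expr <- paste0("rname=", paste(defs$species, collapse = ","))
  widx <- select_atoms(traj$system, water_expr)
  lidx <- select_atoms(traj$system, lipid_expr)
  if (length(widx) == 0 || length(lidx) == 0)
    stop("empty water or lipid selection")
  grid <- density_grid(traj, c(widx, lidx), frames = density_frames)
  wmap <- average_density(traj, water_expr, resolution = resolution,
                          frames = density_frames, grid = grid)
  lmap <- average_density(traj, lipid_expr, resolution = resolution,
                          frames = density_frames, grid = grid)
  surface <- extract_interface(wmap, lmap)
  surface <- compute_normals(surface, wmap, lmap, fit_radius = fit_radius)
  tilts <- analyze_tilts(traj, defs, surface, flag = tilt_flag)
  splays <- analyze_splays(traj, defs, surface, flag = splay_flag,
                           cutoff = cutoff, normal_sign = normal_sign)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mrc(wmap, file.path(outdir, "water_density.mrc"))
    write_mrc(lmap, file.path(outdir, "lipid_density.mrc"))
    write_interface(surface, file.path(outdir, "interface.pdb"),
                    file.path(outdir, "interface_normals.txt"))
    for (sp in names(tilts))
      write.csv(tilts[[sp]],
                file.path(outdir, paste0("tilts_", sp, ".csv")),
                row.names = FALSE)
    for (pr in names(splays))
      write.csv(splays[[pr]],
                file.path(outdir,
                          paste0("splays_", gsub("\\|", "_", pr), ".csv")),
                row.names = FALSE)
  }
  list(tilts = tilts, splays = splays, surface = surface,
       water_map = wmap, lipid_map = lmap)
}
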