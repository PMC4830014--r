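#' Read a PDB topology (plus one frame of coordinates)
#'
#' Thin wrapper around \code{bio3d::read.pdb}. Chain names longer than one
#' character (created by periodic extension, e.g. \code{M1}) are stored in
#' the PDB \code{segid} field on writing and recovered from it here when
#' present.
#'
#' @param file path to a PDB file.
#' @param mass_table optional named numeric vector of per-atom-name masses
#'   (see [mass_from_name()]).
#' @return A list with \code{system} (a [molecular_system()]) and
#'   \code{positions} (Nx3 matrix, Angstrom).
#' @export
read_pdb_system <- function(file, mass_table = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  chain <- at$chain
  if (!is.null(at$segid)) {
    seg <- trimws(at$segid)
    use <- !is.na(seg) & nzchar(seg)
    chain[use] <- seg[use]
  }
  chain[is.na(chain)] <- " "
  sys <- molecular_system(atom_name = at$elety, res_name = at$resid,
                          res_number = at$resno, chain = chain,
                          mass_table = mass_table)
  pos <- cbind(at$x, at$y, at$z)
  colnames(pos) <- c("x", "y", "z")
  list(system = sys, positions = pos)
}

#' Write a system and one frame of coordinates to PDB
#'
#' @param file output path.
#' @param system a [molecular_system()].
#' @param positions Nx3 coordinate matrix.
#' @return The file path, invisibly.
#' @export
write_pdb_system <- function(file, system, positions) {
  res <- system$atoms$res
  chain_full <- system$residues$chain[res]
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(positions)),
                   resno = system$residues$number[res],
                   resid = system$residues$name[res],
                   eleno = seq_len(nrow(system$atoms)),
                   elety = system$atoms$name,
                   chain = substr(chain_full, 1, 1),
                   segid = chain_full, print.segid = TRUE)
  invisible(file)
}

#' Write a trajectory to a (CHARMM-style) DCD file
#'
#' Minimal single-precision DCD writer with per-frame unit-cell records.
#' DCD stores only cell lengths and angles, so only the shape of a
#' (possibly triclinic) cell survives a round trip, not its orientation --
#' one of the reasons the analysis extends systems across periodic images
#' before any other step.
#'
#' @param file output path.
#' @param traj a [trajectory()].
#' @return The file path, invisibly.
#' @export
write_dcd <- function(file, traj) {
  con <- file(file, "wb")
  on.exit(close(con))
  natoms <- nrow(traj$system$atoms)
  nframes <- length(traj$frames)
  wrec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nframes
  icntrl[2] <- 1L   # first step
  icntrl[3] <- 1L   # save frequency
  icntrl[4] <- nframes
  icntrl[11] <- 1L  # unit-cell records present
  icntrl[20] <- 24L # CHARMM version tag
  wrec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl[1:9], c2, size = 4)
    writeBin(1.0, c2, size = 4)  # timestep as float32
    writeBin(icntrl[11:20], c2, size = 4)
  })
  wrec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(formatC("written by tiltsplay", width = 80, flag = "-"),
              c2, nchars = 80, eos = NULL)
  })
  wrec(function(c2) writeBin(natoms, c2, size = 4))
  cp <- cell_parameters(traj$cell)
  xtl <- c(cp[1], cos(cp[6] * pi / 180), cp[2],
           cos(cp[5] * pi / 180), cos(cp[4] * pi / 180), cp[3])
  for (f in traj$frames) {
    wrec(function(c2) writeBin(xtl, c2, size = 8))
    wrec(function(c2) writeBin(as.numeric(f[, 1]), c2, size = 4))
    wrec(function(c2) writeBin(as.numeric(f[, 2]), c2, size = 4))
    wrec(function(c2) writeBin(as.numeric(f[, 3]), c2, size = 4))
  }
  invisible(file)
}

#' Read a DCD trajectory
#'
#' Coordinate reading is delegated to \code{bio3d::read.dcd}; the topology
#' comes from a companion PDB (see [read_pdb_system()]).
#'
#' @param file path to a DCD file.
#' @param system a [molecular_system()] matching the DCD atom count.
#' @param cell optional 3x3 unit-cell matrix. When \code{NULL}, an
#'   orthorhombic-equivalent cell is reconstructed from the first frame's
#'   cell record.
#' @return A [trajectory()].
#' @export
read_dcd <- function(file, system, cell = NULL) {
  xyz <- bio3d::read.dcd(file, verbose = FALSE)
  n <- nrow(system$atoms)
  if (ncol(xyz) != 3 * n)
    stop("DCD atom count does not match the topology")
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  if (is.null(cell)) {
    cp <- tryCatch(
      suppressWarnings(bio3d::read.dcd(file, cell = TRUE, verbose = FALSE)),
      error = function(e) NULL)
    cell <- if (!is.null(cp)) cell_from_parameters(as.numeric(cp[1, ]))
            else diag(3) * (apply(frames[[1]], 2, max) -
                            apply(frames[[1]], 2, min) + 1)
  }
  trajectory(system, frames, cell)
}

#' Cell lengths and angles from cell vectors
#' @param cell 3x3 matrix of cell vectors (rows).
#' @return Numeric vector \code{c(a, b, c, alpha, beta, gamma)} (deg).
#' @export
cell_parameters <- function(cell) {
  len <- sqrt(rowSums(cell^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(len, ang(cell[2, ], cell[3, ]), ang(cell[1, ], cell[3, ]),
    ang(cell[1, ], cell[2, ]))
}

cell_from_parameters <- function(p) {
  # p = (a, b, c, alpha, beta, gamma) in Angstrom / degrees
  a <- p[1]; b <- p[2]; cc <- p[3]
  al <- p[4] * pi / 180; be <- p[5] * pi / 180; ga <- p[6] * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(0, cc^2 - cx^2 - cy^2))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

#' Write a density map in MRC/CCP4 format (mode 2, float32)
#'
#' @param map a [density_map()].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_mrc <- function(map, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  d <- dim(map$values)
  writeBin(as.integer(d), con, size = 4)                  # nx ny nz
  writeBin(2L, con, size = 4)                             # mode 2
  writeBin(integer(3), con, size = 4)                     # nxstart..
  writeBin(as.integer(d), con, size = 4)                  # mx my mz
  writeBin(as.numeric(d * map$spacing), con, size = 4)    # cell lengths
  writeBin(c(90, 90, 90), con, size = 4)                  # cell angles
  writeBin(1:3, con, size = 4)                            # mapc mapr maps
  v <- map$values
  writeBin(c(min(v), max(v), mean(v)), con, size = 4)
  writeBin(integer(2), con, size = 4)                     # ispg nsymbt
  writeBin(integer(25), con, size = 4)                    # extra
  writeBin(as.numeric(map$origin), con, size = 4)         # origin (MRC2014)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(c(68L, 65L, 0L, 0L), con, size = 1)            # machine stamp
  writeBin(sd(as.numeric(v)), con, size = 4)              # rms
  writeBin(0L, con, size = 4)                             # nlabl
  writeBin(raw(800), con)                                 # labels
  writeBin(as.numeric(v), con, size = 4)
  invisible(file)
}

#' Read an MRC/CCP4 density map (mode 2)
#'
#' @param file path to an MRC file written with axis order x, y, z.
#' @return A [density_map()].
#' @export
read_mrc <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", 3, size = 4)
  mode <- readBin(con, "integer", 1, size = 4)
  if (mode != 2) stop("only mode-2 (float32) MRC maps are supported")
  readBin(con, "integer", 3, size = 4)
  m <- readBin(con, "integer", 3, size = 4)
  cella <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  axes <- readBin(con, "integer", 3, size = 4)
  if (!all(axes == 1:3)) stop("unsupported MRC axis order")
  readBin(con, "numeric", 3, size = 4)
  readBin(con, "integer", 2, size = 4)
  readBin(con, "integer", 25, size = 4)
  origin <- readBin(con, "numeric", 3, size = 4)
  seek(con, 1024)
  vals <- readBin(con, "numeric", prod(d), size = 4)
  spacing <- cella[1] / m[1]
  density_map(origin = origin, spacing = spacing,
              values = array(vals, dim = d))
}
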