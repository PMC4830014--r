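# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk.

# A one-residue DPPC-like system with n_atoms atoms, of which the first two
# are P and C2.
dppc_system <- function(n_atoms = 50) {
  molecular_system(
    atom_name = c("P", "C2", paste0("C", seq_len(n_atoms - 2) + 2)),
    res_name = rep("DPPC", n_atoms),
    res_number = rep(1, n_atoms),
    chain = rep("M", n_atoms))
}

# Two chains (M = membrane-like, W = water-like), a few residues each.
two_chain_system <- function() {
  molecular_system(
    atom_name = c("P", "C2", "C3", "OH2", "OH2"),
    res_name = c("DPPC", "DPPC", "DPPC", "TIP3", "TIP3"),
    res_number = c(1, 1, 1, 2, 3),
    chain = c("M", "M", "M", "W", "W"))
}

two_chain_trajectory <- function(edge = 10) {
  sys <- two_chain_system()
  pos <- matrix(seq_len(15), 5, 3)
  trajectory(sys, list(pos), diag(rep(edge, 3)))
}

# Flat interface surface at z = z0 on a 1 A mesh with +z normals.
flat_surface <- function(z0 = 15, half = 20) {
  g <- as.matrix(expand.grid(x = -half:half, y = -half:half))
  pts <- cbind(g, z0)
  colnames(pts) <- c("x", "y", "z")
  interface_surface(pts, matrix(rep(c(0, 0, 1), nrow(pts)),
                                ncol = 3, byrow = TRUE))
}

# Minimal three-site lipid definitions matching the synthetic generators.
pseudo_defs <- function() {
  lipid_definitions("LIP",
                    head_group = c(LIP = "aname=HD"),
                    tail = c(LIP = "aname=TL"),
                    distance = c(LIP = "aname=MD"),
                    solvent_names = "SOL")
}

# A hand-built planar membrane trajectory: lipids at given xy positions with
# prescribed director vectors (n x 3), one frame, no solvent.
membrane_frame <- function(xy, directors, z_mid = 7.5, half_l = 7.5) {
  n <- nrow(xy)
  base <- cbind(xy, z_mid)
  pos <- matrix(0, 3 * n, 3)
  pos[seq(1, 3 * n, 3), ] <- base + half_l * directors
  pos[seq(2, 3 * n, 3), ] <- base
  pos[seq(3, 3 * n, 3), ] <- base - half_l * directors
  sys <- molecular_system(
    atom_name = rep(c("HD", "MD", "TL"), n),
    res_name = rep("LIP", 3 * n),
    res_number = rep(seq_len(n), each = 3),
    chain = rep("M", 3 * n),
    mass_table = c(HD = 100, MD = 300, TL = 300))
  sys <- set_residue_flags(sys, "rname=LIP")
  trajectory(sys, list(pos), diag(c(200, 200, 60)))
}
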