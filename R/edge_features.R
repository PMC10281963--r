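# The 27 per-edge features: a 17-bin one-hot of the Cbeta-Cbeta distance
# and sin/cos of the five inter-residue orientation angles
# (Omega, tau12, tau21, lambda12, lambda21).

#' Discretize an edge distance into the 17-bin one-hot
#'
#' Sixteen half-open 0.5 Angstrom bins cover `[2, 10)`; the 17th bin
#' collects sub-2 Angstrom (steric clash) distances so clashing decoys
#' remain scoreable. Distances at or beyond 10 Angstrom cannot belong to an
#' edge and raise an error.
#'
#' @param d distance(s) in Angstrom, `0 < d < 10`.
#' @return n x 17 binary matrix (single row collapses to a vector is NOT
#'   done; always a matrix).
#' @export
bin_distance <- function(d) {
  if (any(d <= 0)) stop("non-positive distance")
  if (any(d >= 10)) stop("distance >= 10 Angstrom cannot be an edge")
  idx <- ifelse(d < 2, 17L, pmin(floor((d - 2) / 0.5) + 1L, 16L))
  out <- matrix(0, length(d), 17)
  out[cbind(seq_along(d), idx)] <- 1
  colnames(out) <- c(sprintf("d[%.1f,%.1f)", seq(2, 9.5, 0.5),
                             seq(2.5, 10, 0.5)), "d<2")
  out
}

#' Inter-residue orientation angles across the interface
#'
#' Five angles describing the relative orientation of two interface
#' residues' Calpha-Cbeta vectors: the symmetric torsion
#' `Omega = dihedral(CA1, CB1, CB2, CA2)` about the virtual Cbeta-Cbeta
#' axis; the asymmetric torsions `tau12 = dihedral(N1, CA1, CB1, CB2)` and
#' `tau21 = dihedral(N2, CA2, CB2, CB1)`; and the planar angles
#' `lambda12 = angle(CA1, CB1, CB2)` and `lambda21 = angle(CA2, CB2, CB1)`.
#' Swapping the residue order leaves Omega unchanged and exchanges
#' tau12/tau21 and lambda12/lambda21. Degenerate (collinear) geometry
#' yields `NA` for the affected angle.
#'
#' @param frame1,frame2 orientation frames (lists with `N`, `CA`, `CB`
#'   rows; see [orientation_frame()]), vectorized over rows.
#' @return n x 5 matrix with columns `omega, tau12, tau21, lambda12,
#'   lambda21` (radians; dihedrals in `(-pi, pi]`, planar angles in
#'   `[0, pi]`).
#' @export
orientation_angles <- function(frame1, frame2) {
  N1 <- as_mat3(frame1$N); CA1 <- as_mat3(frame1$CA); CB1 <- as_mat3(frame1$CB)
  N2 <- as_mat3(frame2$N); CA2 <- as_mat3(frame2$CA); CB2 <- as_mat3(frame2$CB)
  cbind(omega = dihedral_angle(CA1, CB1, CB2, CA2),
        tau12 = dihedral_angle(N1, CA1, CB1, CB2),
        tau21 = dihedral_angle(N2, CA2, CB2, CB1),
        lambda12 = planar_angle(CA1, CB1, CB2),
        lambda21 = planar_angle(CA2, CB2, CB1))
}

#' Assemble the 27-entry edge feature matrix
#'
#' Concatenates the 17-bin distance one-hot with sin/cos of the five
#' orientation angles, ordered `[sin, cos]` per angle in the order Omega,
#' tau12, tau21, lambda12, lambda21. An undefined angle encodes as (0, 0).
#'
#' @param d numeric vector of edge distances (Angstrom).
#' @param angles n x 5 matrix from [orientation_angles()].
#' @return n x 27 numeric matrix.
#' @export
assemble_edge_features <- function(d, angles) {
  stopifnot(nrow(as_mat3(angles)) == length(d) || nrow(angles) == length(d))
  if (ncol(angles) != 5L) stop("angles must have 5 columns")
  sc <- matrix(0, nrow(angles), 10)
  for (k in 1:5) {
    a <- angles[, k]
    ok <- !is.na(a)
    sc[ok, 2 * k - 1] <- sin(a[ok])
    sc[ok, 2 * k] <- cos(a[ok])
  }
  colnames(sc) <- as.vector(rbind(paste0("sin_", colnames(angles)),
                                  paste0("cos_", colnames(angles))))
  out <- cbind(bin_distance(d), sc)
  stopifnot(ncol(out) == 27L)
  out
}

#' Featurize an interface graph
#'
#' Fills `node_features` (n x 17) and `edge_features` (m x 27) of a graph
#' built by [build_interface_graph()], computing residue classes, relative
#' positions, secondary structure and burial (from DSSP output if supplied,
#' else internally), backbone torsion encodings, evolutionary features from
#' the supplied alignments, edge distance bins and orientation angles.
#'
#' @param graph `interface_graph`.
#' @param cplx the `complex_structure` the graph was built from.
#' @param msa_chain1,msa_chain2,msa_paired optional `iq_msa` objects.
#' @param dssp optional data.frame from [read_dssp()].
#' @param burial_threshold relative SASA burial cutoff.
#' @param sasa_points sphere points for the internal SASA computation.
#' @return the graph with `node_features` and `edge_features` populated.
#' @export
featurize_graph <- function(graph, cplx, msa_chain1 = NULL,
                            msa_chain2 = NULL, msa_paired = NULL,
                            dssp = NULL, burial_threshold = 0.25,
                            sasa_points = 192) {
  stopifnot(inherits(graph, "interface_graph"),
            inherits(cplx, "complex_structure"))
  nodes <- graph$nodes
  ssb <- secondary_structure_features(cplx, dssp = dssp,
                                      burial_threshold = burial_threshold,
                                      sasa_points = sasa_points)
  tors <- lapply(cplx$chains, backbone_torsions)
  n <- nrow(nodes)
  rc <- encode_residue_class(nodes$aa)
  rel <- numeric(n); ssmat <- matrix(0, n, 5); tmat <- matrix(0, n, 4)
  for (ch in 1:2) {
    sel <- nodes$chain == ch
    idx <- nodes$index[sel]
    rel[sel] <- relative_position(idx, chain_length(cplx$chains[[ch]]))
    ssmat[sel, ] <- ssb[[ch]][idx, , drop = FALSE]
    tmat[sel, ] <- torsion_features(tors[[ch]]$phi[idx], tors[[ch]]$psi[idx])
  }
  if (is.null(msa_chain1) && is.null(msa_chain2) && is.null(msa_paired)) {
    evo <- cbind(neff_monomer = numeric(n), neff_paired = numeric(n))
  } else {
    evo <- suppressWarnings(
      node_evolutionary_features(graph, msa_chain1, msa_chain2, msa_paired))
  }
  graph$node_features <- assemble_node_features(rc, rel, ssmat, tmat,
                                                evo[, 1], evo[, 2])
  f1 <- orientation_frame(cplx$chains[[1]], graph$edges$res1)
  f2 <- orientation_frame(cplx$chains[[2]], graph$edges$res2)
  ang <- orientation_angles(f1, f2)
  graph$edge_features <- assemble_edge_features(graph$edges$d_model, ang)
  graph
}
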