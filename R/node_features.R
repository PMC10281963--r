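# The 17 per-node features: residue-class one-hot (5), relative sequence
# position (1), 3-state secondary structure (3) + 2-state burial (2)
# one-hots, sin/cos of phi/psi (4), and two normalized effective-sequence
# counts (2, see msa_features.R).

# Physicochemical partition of the 20 standard residues; anything else
# (e.g. 'X') falls into the 5th, non-standard bin. Configurable via the
# `classes` argument of encode_residue_class().
RESIDUE_CLASSES <- list(
  polar = c("S", "T", "N", "Q", "C", "Y", "W"),
  nonpolar = c("A", "V", "L", "I", "M", "F", "P", "G"),
  positive = c("K", "R", "H"),
  negative = c("D", "E")
)

# Maximum accessible surface areas (Angstrom^2) per residue type
# (Sander & Rost 1994), used to normalize absolute SASA into relative SASA.
MAX_ASA <- c(A = 106, R = 248, N = 157, D = 163, C = 135, Q = 198, E = 194,
             G = 84, H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
             P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142, X = 180)

#' One-hot residue-class encoding
#'
#' Clusters the standard amino acids into polar, non-polar, positively and
#' negatively charged classes, with a fifth bin for non-standard residues.
#'
#' @param aa character vector of one-letter codes.
#' @param classes list of four character vectors (`polar`, `nonpolar`,
#'   `positive`, `negative`) partitioning the standard residues.
#' @return n x 5 binary matrix, columns
#'   `(polar, nonpolar, positive, negative, nonstandard)`.
#' @export
encode_residue_class <- function(aa, classes = RESIDUE_CLASSES) {
  out <- matrix(0, length(aa), 5,
                dimnames = list(NULL, c("polar", "nonpolar", "positive",
                                        "negative", "nonstandard")))
  out[, 1] <- as.numeric(aa %in% classes$polar)
  out[, 2] <- as.numeric(aa %in% classes$nonpolar)
  out[, 3] <- as.numeric(aa %in% classes$positive)
  out[, 4] <- as.numeric(aa %in% classes$negative)
  out[, 5] <- as.numeric(rowSums(out[, 1:4, drop = FALSE]) == 0)
  out
}

#' Relative position of a residue in its chain
#'
#' @param seq_index 1-based residue position(s).
#' @param chain_length length of the residue's own chain.
#' @return `seq_index / chain_length`, in `(0, 1]`.
#' @export
relative_position <- function(seq_index, chain_length) {
  if (any(seq_index < 1L) || any(seq_index > chain_length))
    stop("seq_index out of range 1..", chain_length)
  seq_index / chain_length
}

#' Sinusoidal torsion features
#'
#' `[sin phi, cos phi, sin psi, cos psi]`; an undefined (NA) angle encodes
#' as `(0, 0)`, distinguishable from any real angle since a defined pair
#' satisfies sin^2 + cos^2 = 1.
#'
#' @param phi,psi numeric vectors in radians, `NA` where undefined.
#' @return n x 4 matrix.
#' @export
torsion_features <- function(phi, psi) {
  enc <- function(a) {
    s <- sin(a); cc <- cos(a)
    s[is.na(a)] <- 0; cc[is.na(a)] <- 0
    cbind(s, cc)
  }
  out <- cbind(enc(phi), enc(psi))
  colnames(out) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi")
  out
}

# --- internal secondary-structure assignment (torsion windows) -----------

deg <- function(x) x * 180 / pi

assign_ss3_from_torsions <- function(phi, psi) {
  p <- deg(phi); s <- deg(psi)
  ss <- rep("C", length(phi))
  helix <- !is.na(p) & !is.na(s) & p > -120 & p < -30 & s > -100 & s < 45
  strand <- !is.na(p) & !is.na(s) & p > -180 & p < -45 & (s > 90 | s < -150)
  ss[strand] <- "E"
  ss[helix] <- "H"
  ss
}

# DSSP 8-state to 3-state grouping: helices {H,G,I} -> H, strands {E,B} -> E,
# everything else (T, S, P, blank) -> coil.
ss8_to_ss3 <- function(ss8) {
  out <- rep("C", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "H"
  out[ss8 %in% c("E", "B")] <- "E"
  out
}

# --- Shrake-Rupley solvent accessibility ---------------------------------

# Near-uniform unit sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# van der Waals radii by backbone atom type
VDW_RADII <- c(N = 1.65, CA = 1.87, C = 1.76, O = 1.40, CB = 1.87)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA over the atoms present in the structure (backbone plus
#' Cbeta for typical decoys), with a rolling probe.
#'
#' @param xyz n x 3 atom coordinates.
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius (Angstrom).
#' @param n_points sphere sample points per atom.
#' @return per-atom SASA (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(xyz, radii, probe = 1.4, n_points = 192) {
  xyz <- as_mat3(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  pts <- sphere_points(n_points)
  r <- radii + probe
  out <- numeric(n)
  sq <- rowSums(xyz^2)
  # all-pairs squared distances once; neighbors = spheres that can overlap
  d2 <- outer(sq, sq, "+") - 2 * (xyz %*% t(xyz))
  rsum2 <- outer(r, r, "+")^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * r[i]^2
      next
    }
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")       # n_points x 3
    nbxyz <- xyz[nb, , drop = FALSE]
    # squared distance of every surface point to every neighbor center
    pd2 <- outer(rowSums(surf^2), sq[nb], "+") - 2 * (surf %*% t(nbxyz))
    covered <- pd2 < matrix(r[nb]^2, n_points, length(nb), byrow = TRUE)
    frac <- mean(rowSums(covered) == 0L)
    out[i] <- 4 * pi * r[i]^2 * frac
  }
  out
}

# Per-residue relative SASA of a whole complex, using all atoms present.
complex_relative_sasa <- function(cplx, n_points = 192) {
  atoms <- list(); owner_chain <- integer(0); owner_res <- integer(0)
  radii <- numeric(0)
  for (ch in 1:2) {
    chain <- cplx$chains[[ch]]
    for (el in c("N", "CA", "C", "O", "CB")) {
      m <- chain[[el]]
      fin <- which(is.finite(m[, 1]))
      if (length(fin) > 0L) {
        atoms[[length(atoms) + 1L]] <- m[fin, , drop = FALSE]
        owner_chain <- c(owner_chain, rep(ch, length(fin)))
        owner_res <- c(owner_res, fin)
        radii <- c(radii, rep(VDW_RADII[[el]], length(fin)))
      }
    }
  }
  xyz <- do.call(rbind, atoms)
  asa <- shrake_rupley_sasa(xyz, radii, n_points = n_points)
  lapply(1:2, function(ch) {
    chain <- cplx$chains[[ch]]
    res_asa <- vapply(seq_len(chain_length(chain)), function(r)
      sum(asa[owner_chain == ch & owner_res == r]), numeric(1))
    mx <- MAX_ASA[chain$aa]
    mx[is.na(mx)] <- MAX_ASA[["X"]]
    pmin(res_asa / mx, 1)
  })
}

#' Read a DSSP output file
#'
#' Parses the per-residue block of a classic DSSP file: chain, one-letter
#' residue code, 8-state secondary structure and absolute accessibility.
#'
#' @param path DSSP output file.
#' @return data.frame with columns `chain`, `resno`, `aa`, `ss8`, `acc`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1L) stop("not a DSSP file: ", path)
  body <- lines[(start + 1L):length(lines)]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    aa = substr(body, 14, 14),
    ss8 = sub(" ", "-", substr(body, 17, 17)),
    acc = as.numeric(substr(body, 35, 38)),
    stringsAsFactors = FALSE)
}

#' Secondary-structure and burial features
#'
#' Per-residue 3-state secondary structure and 2-state burial one-hots for
#' both chains of a complex. With a precomputed DSSP file the 8-state
#' assignment is grouped to 3 states and the absolute accessibility is
#' normalized by per-residue maxima; without one, an internal torsion-window
#' assignment and a Shrake-Rupley accessibility computation are used.
#'
#' @param cplx `complex_structure`.
#' @param dssp optional data.frame from [read_dssp()].
#' @param burial_threshold relative SASA below which a residue counts as
#'   buried.
#' @param sasa_points sphere points for the internal SASA fallback.
#' @return list of two matrices (one per chain), each L x 5 with columns
#'   `(helix, strand, coil, buried, exposed)`.
#' @export
secondary_structure_features <- function(cplx, dssp = NULL,
                                         burial_threshold = 0.25,
                                         sasa_points = 192) {
  if (is.null(dssp)) {
    rsasa <- complex_relative_sasa(cplx, n_points = sasa_points)
    ss3 <- lapply(cplx$chains, function(chain) {
      tor <- backbone_torsions(chain)
      assign_ss3_from_torsions(tor$phi, tor$psi)
    })
  } else {
    ss3 <- list(); rsasa <- list()
    for (ch in 1:2) {
      chain <- cplx$chains[[ch]]
      sub <- dssp[dssp$chain == chain$chain_id, , drop = FALSE]
      idx <- match(chain$resno_orig, sub$resno)
      if (any(is.na(idx)))
        stop("DSSP file does not cover chain ", chain$chain_id,
             " residue(s) ", paste(chain$resno_orig[is.na(idx)][1:5],
                                   collapse = ", "))
      if (any(toupper(sub$aa[idx]) != chain$aa &
              !(chain$aa == "X" | grepl("[a-z]", sub$aa[idx]))))
        stop("DSSP/structure residue mismatch on chain ", chain$chain_id)
      ss3[[ch]] <- ss8_to_ss3(sub$ss8[idx])
      mx <- MAX_ASA[chain$aa]; mx[is.na(mx)] <- MAX_ASA[["X"]]
      rsasa[[ch]] <- pmin(sub$acc[idx] / mx, 1)
    }
  }
  lapply(1:2, function(ch) {
    s <- ss3[[ch]]
    out <- cbind(helix = as.numeric(s == "H"),
                 strand = as.numeric(s == "E"),
                 coil = as.numeric(s == "C"),
                 buried = as.numeric(rsasa[[ch]] < burial_threshold),
                 exposed = as.numeric(rsasa[[ch]] >= burial_threshold))
    out
  })
}

#' Assemble the 17-entry node feature matrix
#'
#' Concatenates, in fixed order, residue-class one-hot (5), relative
#' position (1), secondary-structure one-hot (3), burial one-hot (2),
#' torsion sin/cos (4) and the two normalized effective-sequence-count
#' features (2).
#'
#' @param residue_class n x 5 matrix.
#' @param rel_pos length-n vector.
#' @param ss_burial n x 5 matrix (ss3 + burial).
#' @param torsions n x 4 matrix.
#' @param neff_monomer,neff_paired length-n vectors.
#' @return n x 17 numeric matrix.
#' @export
assemble_node_features <- function(residue_class, rel_pos, ss_burial,
                                   torsions, neff_monomer, neff_paired) {
  n <- length(rel_pos)
  if (nrow(residue_class) != n || ncol(residue_class) != 5L ||
      nrow(ss_burial) != n || ncol(ss_burial) != 5L ||
      nrow(torsions) != n || ncol(torsions) != 4L ||
      length(neff_monomer) != n || length(neff_paired) != n)
    stop("node feature component dimensions do not match (n = ", n, ")")
  out <- cbind(residue_class, rel_pos = rel_pos, ss_burial, torsions,
               neff_monomer = neff_monomer, neff_paired = neff_paired)
  stopifnot(ncol(out) == 17L)
  out
}
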