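# Representation of dimeric complex structures and the coordinate primitives
# (interaction coordinate, virtual Cbeta, backbone torsions) used downstream.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

# Ideal Cbeta internal coordinates: bond CA-CB, planar angle N-CA-CB,
# dihedral C-N-CA-CB (rotation about the N-CA axis).
CB_BOND <- 1.522
CB_ANGLE <- 110.4 * pi / 180
CB_TORSION <- -122.6 * pi / 180

#' Construct one chain of a dimeric complex
#'
#' @param chain_id single-character chain label.
#' @param aa character vector of one-letter residue codes.
#' @param N,CA,C,O,CB L x 3 coordinate matrices (Angstrom); `O` and `CB` may
#'   be `NULL` or contain `NA` rows for missing atoms.
#' @param resno_orig original author residue numbering (metadata only);
#'   defaults to `1:L`.
#' @return object of class `iq_chain`.
#' @export
new_chain <- function(chain_id, aa, N, CA, C, O = NULL, CB = NULL,
                      resno_orig = NULL) {
  L <- length(aa)
  N <- as_mat3(N); CA <- as_mat3(CA); C <- as_mat3(C)
  stopifnot(nrow(N) == L, nrow(CA) == L, nrow(C) == L)
  if (is.null(O)) O <- matrix(NA_real_, L, 3) else O <- as_mat3(O)
  if (is.null(CB)) CB <- matrix(NA_real_, L, 3) else CB <- as_mat3(CB)
  if (is.null(resno_orig)) resno_orig <- seq_len(L)
  structure(list(chain_id = chain_id, aa = aa, N = N, CA = CA, C = C,
                 O = O, CB = CB, resno_orig = as.integer(resno_orig)),
            class = "iq_chain")
}

chain_length <- function(chain) length(chain$aa)

#' Construct a dimeric complex structure
#'
#' Chain 1 is the receptor, chain 2 the ligand (the distinction matters only
#' to ligand-RMSD evaluation).
#'
#' @param chain1,chain2 `iq_chain` objects.
#' @param target_id label for reporting.
#' @return object of class `complex_structure` with fields `chains`,
#'   `target_id`, `L1`, `L2`.
#' @export
new_complex_structure <- function(chain1, chain2, target_id = "target") {
  stopifnot(inherits(chain1, "iq_chain"), inherits(chain2, "iq_chain"))
  if (chain_length(chain1) < 1L || chain_length(chain2) < 1L)
    stop("both chains must be non-empty")
  structure(list(chains = list(chain1, chain2), target_id = target_id,
                 L1 = chain_length(chain1), L2 = chain_length(chain2)),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", x$target_id, ": chains ",
      x$chains[[1]]$chain_id, " (", x$L1, " res), ",
      x$chains[[2]]$chain_id, " (", x$L2, " res)\n", sep = "")
  invisible(x)
}

#' Ideal Cbeta from backbone atoms
#'
#' Rebuilds a tetrahedral Cbeta from N, CA and C using ideal internal
#' coordinates (bond 1.522 Angstrom, angle 110.4 degrees, dihedral
#' -122.6 degrees about the backbone frame). Used for glycine virtual
#' Cbeta atoms and for side-chain-less decoys.
#'
#' @param N,CA,C 3-vectors or n x 3 matrices.
#' @return 3-vector or n x 3 matrix of Cbeta coordinates.
#' @export
ideal_cbeta <- function(N, CA, C) {
  N <- as_mat3(N); CA <- as_mat3(CA); C <- as_mat3(C)
  out <- matrix(NA_real_, nrow(N), 3)
  for (i in seq_len(nrow(N)))
    out[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], CB_BOND, CB_ANGLE,
                           CB_TORSION)
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Interaction coordinate of a residue
#'
#' The point used for interface detection and distance features: the Cbeta
#' atom, or the Calpha atom for glycine. A missing Cbeta on a non-glycine
#' residue is rebuilt with [ideal_cbeta()] when `reconstruct` is `TRUE`.
#'
#' @param chain `iq_chain`.
#' @param idx residue index (1-based) within the chain; vectorized.
#' @param reconstruct rebuild missing Cbeta atoms from the backbone.
#' @return n x 3 matrix (or 3-vector for a single index).
#' @export
interaction_coordinate <- function(chain, idx = seq_along(chain$aa),
                                   reconstruct = TRUE) {
  out <- chain$CB[idx, , drop = FALSE]
  gly <- chain$aa[idx] == "G"
  out[gly, ] <- chain$CA[idx[gly], , drop = FALSE]
  miss <- !gly & !is.finite(out[, 1])
  if (any(miss)) {
    if (!reconstruct)
      stop("missing Cbeta for non-glycine residue(s) ",
           paste0(chain$chain_id, ":", idx[miss], collapse = ", "),
           " and reconstruction is disabled")
    mi <- idx[miss]
    out[miss, ] <- as_mat3(ideal_cbeta(chain$N[mi, , drop = FALSE],
                                       chain$CA[mi, , drop = FALSE],
                                       chain$C[mi, , drop = FALSE]))
  }
  if (length(idx) == 1L) as.numeric(out) else out
}

#' Orientation frame atoms for a residue
#'
#' N, CA and Cbeta positions used by the inter-residue orientation angles.
#' Glycine (or a residue lacking a Cbeta) gets a virtual ideal Cbeta so a
#' Calpha-Cbeta direction always exists.
#'
#' @param chain `iq_chain`.
#' @param idx residue indices.
#' @return list of `N`, `CA`, `CB` (n x 3 matrices).
#' @export
orientation_frame <- function(chain, idx = seq_along(chain$aa)) {
  CB <- chain$CB[idx, , drop = FALSE]
  miss <- chain$aa[idx] == "G" | !is.finite(CB[, 1])
  if (any(miss)) {
    mi <- idx[miss]
    CB[miss, ] <- as_mat3(ideal_cbeta(chain$N[mi, , drop = FALSE],
                                      chain$CA[mi, , drop = FALSE],
                                      chain$C[mi, , drop = FALSE]))
  }
  list(N = chain$N[idx, , drop = FALSE],
       CA = chain$CA[idx, , drop = FALSE],
       CB = CB)
}

#' Backbone torsion angles of a chain
#'
#' Standard phi (C(i-1)-N-CA-C) and psi (N-CA-C-N(i+1)) dihedrals. Phi is
#' undefined (`NA`) for the first residue and psi for the last; a chain
#' break (consecutive Calpha atoms farther than `break_cutoff` apart) makes
#' the spanning angles undefined as well.
#'
#' @param chain `iq_chain`.
#' @param break_cutoff CA-CA distance (Angstrom) above which consecutive
#'   residues are treated as disconnected.
#' @return list with numeric vectors `phi` and `psi` (radians, `NA` where
#'   undefined).
#' @export
backbone_torsions <- function(chain, break_cutoff = 4.5) {
  L <- chain_length(chain)
  phi <- rep(NA_real_, L)
  psi <- rep(NA_real_, L)
  if (L >= 2L) {
    gap <- row_norm(chain$CA[-1L, , drop = FALSE] -
                    chain$CA[-L, , drop = FALSE]) > break_cutoff
    if (any(gap))
      message("chain ", chain$chain_id, ": ", sum(gap),
              " chain break(s); torsions undefined at the break")
    i <- 2:L
    phi[i] <- dihedral_angle(chain$C[i - 1L, , drop = FALSE],
                             chain$N[i, , drop = FALSE],
                             chain$CA[i, , drop = FALSE],
                             chain$C[i, , drop = FALSE])
    phi[i][gap] <- NA_real_
    j <- 1:(L - 1L)
    psi[j] <- dihedral_angle(chain$N[j, , drop = FALSE],
                             chain$CA[j, , drop = FALSE],
                             chain$C[j, , drop = FALSE],
                             chain$N[j + 1L, , drop = FALSE])
    psi[j][gap] <- NA_real_
  }
  list(phi = phi, psi = psi)
}

#' Read a dimeric complex from a PDB file
#'
#' Parses ATOM records only (HETATM ignored; MSE read as methionine via the
#' standard residue table when present as ATOM). Alternate locations are
#' resolved to the highest occupancy (first on ties); residues missing any
#' of N, CA or C are dropped with a warning; insertion codes are folded into
#' a sequential 1-based internal numbering per chain, the author numbering
#' being kept as metadata.
#'
#' @param path PDB file.
#' @param chain_ids optional character pair selecting (receptor, ligand)
#'   chains; defaults to the two largest chains by residue count, in file
#'   order on ties.
#' @param target_id label; defaults to the file name.
#' @return `complex_structure`.
#' @export
read_complex_pdb <- function(path, chain_ids = NULL, target_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- " "
  avail <- unique(at$chain)
  if (is.null(chain_ids)) {
    sizes <- vapply(avail, function(ch) {
      sub <- at[at$chain == ch & at$elety == "CA", , drop = FALSE]
      nrow(unique(sub[, c("resno", "insert")]))
    }, integer(1))
    if (sum(sizes > 0L) < 2L)
      stop("fewer than two parseable chains in ", path,
           " (chains found: ", paste(avail, collapse = ", "), ")")
    chain_ids <- avail[order(-sizes)][1:2]
    # keep file order between the two selected chains
    chain_ids <- avail[avail %in% chain_ids][1:2]
  } else {
    missing_ch <- setdiff(chain_ids, avail)
    if (length(missing_ch) > 0L)
      stop("chain(s) ", paste(missing_ch, collapse = ", "), " not in ", path,
           "; available: ", paste(avail, collapse = ", "))
  }
  chains <- lapply(chain_ids, function(ch)
    parse_chain_atoms(at[at$chain == ch, , drop = FALSE], ch, path))
  if (is.null(target_id)) target_id <- sub("\\.pdb$", "", basename(path))
  new_complex_structure(chains[[1]], chains[[2]], target_id = target_id)
}

parse_chain_atoms <- function(at, chain_id, path) {
  # resolve altlocs: keep highest occupancy per (resno, insert, elety)
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(-at$o)  # stable: first record wins on occupancy ties
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "|")
  # restore file order of residues
  at <- at[order(match(rkey, unique(paste(at$resno, at$insert, sep = "|")))), ,
           drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "|")
  res_keys <- unique(rkey)
  L <- length(res_keys)
  aa <- character(L); resno_orig <- integer(L)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, L, 3)
  for (r in seq_len(L)) {
    sub <- at[rkey == res_keys[r], , drop = FALSE]
    resid3 <- sub$resid[1]
    aa[r] <- if (resid3 %in% names(AA3TO1)) AA3TO1[[resid3]] else "X"
    resno_orig[r] <- sub$resno[1]
    for (el in c("N", "CA", "C", "O", "CB")) {
      hit <- which(sub$elety == el)
      if (length(hit) > 0L) {
        m <- switch(el, N = , CA = , C = , O = , CB = el)
        coords <- as.numeric(sub[hit[1], c("x", "y", "z")])
        if (el == "N") N[r, ] <- coords
        if (el == "CA") CA[r, ] <- coords
        if (el == "C") C[r, ] <- coords
        if (el == "O") O[r, ] <- coords
        if (el == "CB") CB[r, ] <- coords
      }
    }
  }
  ok <- is.finite(N[, 1]) & is.finite(CA[, 1]) & is.finite(C[, 1])
  if (any(!ok))
    warning("chain ", chain_id, " in ", basename(path), ": dropped ",
            sum(!ok), " residue(s) missing backbone atoms")
  if (!any(ok)) stop("chain ", chain_id, " in ", path,
                     " has no residues with complete backbone")
  new_chain(chain_id, aa[ok], N[ok, , drop = FALSE], CA[ok, , drop = FALSE],
            C[ok, , drop = FALSE], O[ok, , drop = FALSE],
            CB[ok, , drop = FALSE], resno_orig = resno_orig[ok])
}

#' Write a dimeric complex to a PDB file
#'
#' Plain ATOM records with the internal sequential residue numbering; the
#' counterpart of [read_complex_pdb()] used by the synthetic generator.
#'
#' @param cplx `complex_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(cplx, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (chain in cplx$chains) {
    for (r in seq_len(chain_length(chain))) {
      aa3 <- if (chain$aa[r] %in% names(AA1TO3)) AA1TO3[[chain$aa[r]]] else "UNK"
      for (el in c("N", "CA", "C", "O", "CB")) {
        xyz <- chain[[el]][r, ]
        if (!all(is.finite(xyz))) next
        serial <- serial + 1L
        elem <- substr(el, 1, 1)
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", el), aa3, chain$chain_id, r,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem), con)
      }
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %3s %1s%4d", serial,
                       if (chain$aa[chain_length(chain)] %in% names(AA1TO3))
                         AA1TO3[[chain$aa[chain_length(chain)]]] else "UNK",
                       chain$chain_id, chain_length(chain)), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Apply a rigid-body transform to a whole chain
#'
#' @param chain `iq_chain`.
#' @param rotation 3 x 3 matrix.
#' @param translation length-3 vector.
#' @return transformed `iq_chain`.
#' @export
transform_chain <- function(chain, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  for (el in c("N", "CA", "C", "O", "CB")) {
    m <- chain[[el]]
    fin <- is.finite(m[, 1])
    if (any(fin))
      m[fin, ] <- apply_transform(m[fin, , drop = FALSE], rotation, translation)
    chain[[el]] <- m
  }
  chain
}

#' Sequence of a chain as a single string
#' @param chain `iq_chain`.
#' @return character scalar of one-letter codes.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")
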