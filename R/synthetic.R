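# Self-contained synthetic fixtures: toy native dimers built from ideal
# backbone geometry, graded rigid-body decoy sets, and synthetic
# alignments of controllable depth and divergence. Everything is
# deterministic from the specification seed.

STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic decoy-set specification
#'
#' The default values define the package's reference study conditions:
#' 20 targets of two 40-60 residue chains, 30 decoys per target spanning
#' six rigid-body perturbation levels from near-native (within 2 degrees /
#' 1 Angstrom) to fully displaced, and 50-row alignments at 35 percent
#' per-position divergence.
#'
#' @param n_targets number of complex targets.
#' @param chain_length_range inclusive range of residues per chain.
#' @param decoys_per_target decoys generated for each target.
#' @param perturbation_grid list of `c(rot_min_deg, rot_max_deg, trans_min_A,
#'   trans_max_A)` levels cycled over the decoys; must include a
#'   near-native level (rotation within 2 degrees, translation within 1
#'   Angstrom).
#' @param msa_depth rows per synthetic alignment.
#' @param msa_mutation_rate per-position substitution probability for
#'   non-query rows.
#' @param jitter_sd per-coordinate Gaussian backbone jitter (Angstrom)
#'   added to decoys.
#' @param seed master seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_targets = 20L,
                           chain_length_range = c(40L, 60L),
                           decoys_per_target = 30L,
                           perturbation_grid = list(
                             c(0, 2, 0, 0.5),
                             c(2, 8, 0.5, 1.5),
                             c(8, 20, 1.5, 4),
                             c(20, 45, 4, 8),
                             c(45, 90, 8, 15),
                             c(90, 180, 15, 30)),
                           msa_depth = 50L, msa_mutation_rate = 0.35,
                           jitter_sd = 0.05, seed = 1L) {
  stopifnot(n_targets >= 1L, decoys_per_target >= 1L,
            chain_length_range[1] >= 5L,
            msa_depth >= 1L, msa_mutation_rate >= 0, msa_mutation_rate < 1,
            jitter_sd <= 0.2)
  near <- vapply(perturbation_grid,
                 function(lv) lv[2] <= 2 && lv[4] <= 1, logical(1))
  if (!any(near))
    stop("perturbation grid must include a near-native level ",
         "(rotation <= 2 degrees, translation <= 1 Angstrom)")
  structure(list(n_targets = as.integer(n_targets),
                 chain_length_range = as.integer(chain_length_range),
                 decoys_per_target = as.integer(decoys_per_target),
                 perturbation_grid = perturbation_grid,
                 msa_depth = as.integer(msa_depth),
                 msa_mutation_rate = msa_mutation_rate,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# ideal backbone internal coordinates
BB_N_CA <- 1.458; BB_CA_C <- 1.525; BB_C_N <- 1.329; BB_C_O <- 1.231
ANG_N_CA_C <- 111.2 * pi / 180
ANG_CA_C_N <- 116.2 * pi / 180
ANG_C_N_CA <- 121.7 * pi / 180
ANG_CA_C_O <- 120.8 * pi / 180

# torsion templates per secondary-structure element (degrees)
SS_TORSIONS <- list(helix = c(-57, -47), strand = c(-140, 135),
                    turn1 = c(-60, -30), turn2 = c(80, 0))

# random phi/psi schedule: alternating helix/strand segments joined by
# two-residue turns, with small Gaussian noise
sample_torsion_schedule <- function(L, noise_deg = 4) {
  phi <- numeric(0); psi <- numeric(0)
  while (length(phi) < L) {
    type <- if (stats::runif(1) < 0.6) "helix" else "strand"
    seg <- sample(6:12, 1)
    t <- SS_TORSIONS[[type]]
    phi <- c(phi, rep(t[1], seg)); psi <- c(psi, rep(t[2], seg))
    phi <- c(phi, SS_TORSIONS$turn1[1], SS_TORSIONS$turn2[1])
    psi <- c(psi, SS_TORSIONS$turn1[2], SS_TORSIONS$turn2[2])
  }
  phi <- (phi[seq_len(L)] + stats::rnorm(L, 0, noise_deg)) * pi / 180
  psi <- (psi[seq_len(L)] + stats::rnorm(L, 0, noise_deg)) * pi / 180
  list(phi = phi, psi = psi)
}

# build one chain backbone from a phi/psi schedule (omega fixed trans)
build_chain_from_torsions <- function(aa, phi, psi, chain_id) {
  L <- length(aa)
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_N_CA, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], BB_CA_C, ANG_N_CA_C,
                       stats::runif(1, -pi, pi))
  for (i in 2:L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], BB_C_N,
                         ANG_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], BB_N_CA,
                          ANG_C_N_CA, pi)       # omega = 180 (trans)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], BB_CA_C, ANG_N_CA_C,
                         phi[i])
  }
  for (i in 1:(L - 1))
    O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], BB_C_O, ANG_CA_C_O, pi)
  O[L, ] <- place_atom(N[L, ], CA[L, ], C[L, ], BB_C_O, ANG_CA_C_O, pi)
  CB <- as_mat3(ideal_cbeta(N, CA, C))
  CB[aa == "G", ] <- NA_real_
  new_chain(chain_id, aa, N, CA, C, O, CB)
}

# reject self-intersecting backbones
chain_self_avoiding <- function(chain, min_sep = 3.5) {
  CA <- chain$CA
  L <- nrow(CA)
  if (L < 6L) return(TRUE)
  d <- as.matrix(stats::dist(CA))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  min(d[sep > 3]) > min_sep
}

generate_chain <- function(L, chain_id, max_tries = 50) {
  for (k in seq_len(max_tries)) {
    aa <- sample(STANDARD_AA, L, replace = TRUE)
    sched <- sample_torsion_schedule(L)
    chain <- build_chain_from_torsions(aa, sched$phi, sched$psi, chain_id)
    if (chain_self_avoiding(chain)) return(chain)
  }
  stop("failed to generate a self-avoiding backbone after ", max_tries,
       " attempts")
}

min_cross_distance <- function(x1, x2) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
  sqrt(max(min(d2), 0))
}

count_contacts <- function(x1, x2, cutoff) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * (x1 %*% t(x2))
  sum(d2 < cutoff^2)
}

# dock chain2 against chain1 by sliding along a random direction until the
# closest interaction-coordinate pair reaches `approach` Angstrom
dock_chains <- function(chain1, chain2, approach = 4.0, min_contacts = 10,
                        max_tries = 60) {
  x1 <- as_mat3(interaction_coordinate(chain1))
  for (k in seq_len(max_tries)) {
    R <- random_rotation()
    cand <- transform_chain(chain2, R,
                            -as.numeric(colMeans(chain2$CA) %*% t(R)))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    base <- colMeans(chain1$CA)
    x2 <- as_mat3(interaction_coordinate(cand))
    f <- function(t) min_cross_distance(x1, sweep(x2, 2, base + t * u, "+"))
    lo <- 0; hi <- 100
    if (f(hi) < approach || f(lo) > approach) next
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (f(mid) < approach) lo <- mid else hi <- mid
    }
    t_star <- (lo + hi) / 2
    placed <- transform_chain(cand, diag(3), base + t_star * u)
    xp <- as_mat3(interaction_coordinate(placed))
    ca_ok <- min_cross_distance(chain1$CA, placed$CA) > 3.0
    if (count_contacts(x1, xp, 8.0) >= min_contacts && ca_ok)
      return(placed)
  }
  stop("failed to dock chains with >= ", min_contacts,
       " contacts after ", max_tries, " attempts")
}

#' Generate a synthetic native dimer
#'
#' Two self-avoiding ideal-geometry backbones (alternating helical and
#' extended segments with randomized turns), docked so the interface has at
#' least 10 residue pairs within 8 Angstrom. Deterministic given
#' `(spec$seed, target_index)`. The first target of a bundle carries one
#' non-standard 'X' residue so the fifth residue-class bin is exercised.
#'
#' @param spec `synthetic_spec`.
#' @param target_index 1-based target number.
#' @return `complex_structure` with all backbone and ideal Cbeta atoms.
#' @export
generate_native <- function(spec, target_index) {
  set.seed((spec$seed %% 99991L) * 20011L + target_index * 7L)
  rng <- spec$chain_length_range
  L1 <- sample(rng[1]:rng[2], 1)
  L2 <- sample(rng[1]:rng[2], 1)
  chain1 <- generate_chain(L1, "A")
  if (target_index == 1L) {
    pos <- min(3L, L1)
    chain1$aa[pos] <- "X"   # keep its CB: treated as an ALA-like unknown
  }
  chain2 <- generate_chain(L2, "B")
  chain2 <- dock_chains(chain1, chain2)
  new_complex_structure(chain1, chain2,
                        target_id = sprintf("T%03d", target_index))
}

jitter_chain <- function(chain, sd) {
  if (sd <= 0) return(chain)
  for (el in c("N", "CA", "C", "O", "CB")) {
    m <- chain[[el]]
    fin <- is.finite(m[, 1])
    m[fin, ] <- m[fin, ] + stats::rnorm(sum(fin) * 3, 0, sd)
    chain[[el]] <- m
  }
  chain
}

#' Generate a graded decoy set for one native
#'
#' Each decoy is the native with its ligand chain rigidly rotated about its
#' centroid and translated, with magnitudes drawn from one level of the
#' perturbation grid (levels are cycled over decoys), plus a small Gaussian
#' backbone jitter on both chains. The true DockQ of every decoy is
#' computed against the native.
#'
#' @param native `complex_structure`.
#' @param spec `synthetic_spec`.
#' @param seed integer seed for the decoy draws.
#' @return list of class `decoy_set`: `native`, `decoys` (list of
#'   `complex_structure`), `info` (data.frame: decoy, level, rot_deg,
#'   trans_A, fnat, lrms, irms, dockq, capri_class).
#' @export
generate_decoys <- function(native, spec, seed = spec$seed) {
  set.seed(seed %% 2100000000L)
  n <- spec$decoys_per_target
  levels_ix <- rep(seq_along(spec$perturbation_grid), length.out = n)
  decoys <- vector("list", n)
  info <- data.frame(decoy = sprintf("%s_d%03d", native$target_id, 1:n),
                     level = levels_ix, rot_deg = NA_real_,
                     trans_A = NA_real_, fnat = NA_real_, lrms = NA_real_,
                     irms = NA_real_, dockq = NA_real_,
                     capri_class = NA_character_,
                     stringsAsFactors = FALSE)
  for (d in seq_len(n)) {
    lv <- spec$perturbation_grid[[levels_ix[d]]]
    rot <- stats::runif(1, lv[1], lv[2])
    tr <- stats::runif(1, lv[3], lv[4])
    R <- rotation_matrix(stats::rnorm(3), rot * pi / 180)
    lig <- native$chains[[2]]
    cen <- colMeans(lig$CA)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    # rotate about the ligand centroid, then translate
    lig2 <- transform_chain(lig, R,
                            as.numeric(cen - cen %*% t(R)) + tr * u)
    dec <- new_complex_structure(jitter_chain(native$chains[[1]],
                                              spec$jitter_sd),
                                 jitter_chain(lig2, spec$jitter_sd),
                                 target_id = native$target_id)
    dq <- dockq_score(dec, native)
    decoys[[d]] <- dec
    info$rot_deg[d] <- rot; info$trans_A[d] <- tr
    info$fnat[d] <- dq$fnat; info$lrms[d] <- dq$lrms
    info$irms[d] <- dq$irms; info$dockq[d] <- dq$dockq
    info$capri_class[d] <- dq$capri_class
  }
  structure(list(native = native, decoys = decoys, info = info),
            class = "decoy_set")
}

#' Generate a synthetic alignment
#'
#' The query plus `depth - 1` rows mutated independently at each position
#' with probability `mutation_rate` (substitution uniform over the other 19
#' standard residues), so the expected row-to-query identity is
#' `1 - mutation_rate`. No gaps are introduced.
#'
#' @param sequence query sequence (character scalar).
#' @param depth number of rows.
#' @param mutation_rate per-position substitution probability.
#' @param seed optional seed.
#' @return `iq_msa`.
#' @export
generate_msa <- function(sequence, depth, mutation_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed %% 2100000000L)
  q <- strsplit(sequence, "")[[1]]
  rows <- c(sequence, vapply(seq_len(max(depth - 1L, 0L)), function(i) {
    mut <- stats::runif(length(q)) < mutation_rate
    r <- q
    r[mut] <- vapply(which(mut), function(p)
      sample(setdiff(STANDARD_AA, q[p]), 1), character(1))
    paste(r, collapse = "")
  }, character(1)))
  new_msa(rows, c("query", sprintf("hom%03d", seq_len(length(rows) - 1L))))
}

#' Row-wise paired alignment of two chain alignments
#'
#' Concatenates rows matched by index, emulating a coupled inter-chain
#' alignment; the query length is the sum of the two chain lengths.
#'
#' @param msa1,msa2 `iq_msa` objects.
#' @return `iq_msa`.
#' @export
pair_msas <- function(msa1, msa2) {
  depth <- min(length(msa1$sequences), length(msa2$sequences))
  new_msa(paste0(msa1$sequences[seq_len(depth)],
                 msa2$sequences[seq_len(depth)]),
          paste0("pair", seq_len(depth)))
}

#' Simulate a full decoy bundle in memory
#'
#' Natives, graded decoy sets and per-chain plus paired alignments for
#' every target, deterministic from the specification seed.
#'
#' @param spec `synthetic_spec`.
#' @return list of class `decoy_bundle`; one element per target with
#'   `native`, `decoy_set`, `msa1`, `msa2`, `msa_paired`.
#' @export
simulate_bundle <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  dseeds <- sample.int(1e9, 2 * spec$n_targets)
  out <- lapply(seq_len(spec$n_targets), function(i) {
    native <- generate_native(spec, i)
    ds <- generate_decoys(native, spec, seed = dseeds[2 * i - 1])
    set.seed(dseeds[2 * i])
    msa1 <- generate_msa(chain_sequence(native$chains[[1]]), spec$msa_depth,
                         spec$msa_mutation_rate)
    msa2 <- generate_msa(chain_sequence(native$chains[[2]]), spec$msa_depth,
                         spec$msa_mutation_rate)
    list(target_id = native$target_id, native = native, decoy_set = ds,
         msa1 = msa1, msa2 = msa2, msa_paired = pair_msas(msa1, msa2))
  })
  structure(out, class = "decoy_bundle")
}

#' Write a decoy bundle as a file tree
#'
#' Per target: the native PDB, decoy PDBs, per-chain FASTA, per-chain and
#' paired A3M alignments; plus one manifest TSV listing every decoy with
#' its perturbation level and true DockQ components.
#'
#' @param spec `synthetic_spec`.
#' @param out_dir output directory (created).
#' @param bundle optional pre-simulated `decoy_bundle` (re-simulated from
#'   `spec` when `NULL`).
#' @return path to the manifest TSV, invisibly.
#' @export
write_fixture_bundle <- function(spec, out_dir, bundle = NULL) {
  if (is.null(bundle)) bundle <- simulate_bundle(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (tg in bundle) {
    tdir <- file.path(out_dir, tg$target_id)
    dir.create(tdir, showWarnings = FALSE)
    write_complex_pdb(tg$native, file.path(tdir, "native.pdb"))
    for (d in seq_along(tg$decoy_set$decoys))
      write_complex_pdb(tg$decoy_set$decoys[[d]],
                        file.path(tdir, sprintf("decoy_%03d.pdb", d)))
    seqinr::write.fasta(list(chain_sequence(tg$native$chains[[1]])),
                        names = paste0(tg$target_id, "_A"),
                        file.out = file.path(tdir, "chainA.fasta"),
                        nbchar = 1e6)
    seqinr::write.fasta(list(chain_sequence(tg$native$chains[[2]])),
                        names = paste0(tg$target_id, "_B"),
                        file.out = file.path(tdir, "chainB.fasta"),
                        nbchar = 1e6)
    write_msa(tg$msa1, file.path(tdir, "chainA.a3m"))
    write_msa(tg$msa2, file.path(tdir, "chainB.a3m"))
    write_msa(tg$msa_paired, file.path(tdir, "paired.a3m"))
    mi <- tg$decoy_set$info
    mi$target <- tg$target_id
    mi$path <- file.path(tg$target_id, sprintf("decoy_%03d.pdb",
                                               seq_len(nrow(mi))))
    manifest[[length(manifest) + 1L]] <- mi
  }
  manifest <- do.call(rbind, manifest)
  path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
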