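# Independent reference implementations ("oracles") used across the test
# files. These deliberately re-derive each quantity with different code
# paths than the package.

# Dihedral via projection onto the plane perpendicular to the central bond
# (independent of the package's cross-product formulation).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  atan2(sum(cr * b), sum(u * w))
}

# naive O(L1*L2) interface edge scan
oracle_edge_set <- function(cplx, cutoff = 10) {
  x1 <- interaction_coordinate(cplx$chains[[1]])
  x2 <- interaction_coordinate(cplx$chains[[2]])
  out <- NULL
  for (i in seq_len(nrow(x1)))
    for (j in seq_len(nrow(x2))) {
      d <- sqrt(sum((x1[i, ] - x2[j, ])^2))
      if (d < cutoff) out <- rbind(out, c(i, j, d))
    }
  out
}

# slow, loop-based Shrake-Rupley at high sphere resolution
oracle_sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  r <- radii + probe
  out <- numeric(n)
  for (a in seq_len(n)) {
    acc <- 0L
    for (s in seq_len(n_points)) {
      p <- xyz[a, ] + r[a] * pts[s, ]
      buried <- FALSE
      for (bb in seq_len(n)) {
        if (bb == a) next
        if (sum((p - xyz[bb, ])^2) < r[bb]^2) { buried <- TRUE; break }
      }
      if (!buried) acc <- acc + 1L
    }
    out[a] <- 4 * pi * r[a]^2 * acc / n_points
  }
  out
}

# brute-force pairwise-identity Neff
oracle_neff <- function(sequences, threshold = 0.8) {
  mat <- do.call(rbind, strsplit(sequences, ""))
  L <- sum(mat[1, ] != "-")
  N <- nrow(mat)
  total <- 0
  for (i in seq_len(N)) {
    cl <- 0L
    for (j in seq_len(N)) {
      idij <- sum(mat[i, ] == mat[j, ] & mat[i, ] != "-" & mat[j, ] != "-") / L
      if (idij > threshold) cl <- cl + 1L
    }
    total <- total + 1 / cl
  }
  total
}

# brute-force per-target top-N ranking metrics
oracle_sr_hr <- function(tab, N, threshold = 0.23) {
  targets <- unique(tab$target)
  succ <- 0L; hits <- 0L
  for (tg in targets) {
    sub <- tab[tab$target == tg, , drop = FALSE]
    ord <- order(-sub$score)   # stable ties by input order
    top <- sub$dockq[ord][seq_len(min(N, nrow(sub)))]
    if (any(top >= threshold)) succ <- succ + 1L
    hits <- hits + sum(top >= threshold)
  }
  M <- sum(tab$dockq >= threshold)
  list(sr = 100 * succ / length(targets), hr = 100 * hits / M)
}

# AUC by exhaustive pair enumeration (ties count half)
oracle_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Spearman rho via explicit average ranks and the Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v)
    vapply(v, function(vi) mean(which(sort(v) == vi)), numeric(1))
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ideal Cbeta rebuilt with explicit Rodrigues rotations (same internal
# coordinates as the package -- bond CA-CB, angle N-CA-CB, dihedral
# C-N-CA-CB -- but independent frame algebra)
oracle_ideal_cb <- function(N, CA, C, bond = 1.522, ang = 110.4 * pi / 180,
                            tor = -122.6 * pi / 180) {
  rot <- function(v, axis, th) {
    u <- axis / sqrt(sum(axis^2))
    v * cos(th) + c(u[2] * v[3] - u[3] * v[2],
                    u[3] * v[1] - u[1] * v[3],
                    u[1] * v[2] - u[2] * v[1]) * sin(th) +
      u * sum(u * v) * (1 - cos(th))
  }
  e1 <- (N - CA) / sqrt(sum((N - CA)^2))
  v2 <- C - CA
  nrm <- c(e1[2] * v2[3] - e1[3] * v2[2],
           e1[3] * v2[1] - e1[1] * v2[3],
           e1[1] * v2[2] - e1[2] * v2[1])
  # in-plane direction at the bond angle from CA->N
  d0 <- rot(e1, nrm, ang)
  # current torsion about the N-CA axis, then rotate to the target torsion
  t0 <- oracle_dihedral(C, N, CA, CA + d0)
  d <- rot(d0, -e1, tor - t0)
  CA + bond * d
}

# minimal hand-built residue pair on opposite chains at a controlled
# Cbeta-Cbeta distance (non-glycine, full backbone)
toy_residue_chain <- function(chain_id, cb_at, aa = "A") {
  # build a backbone around the requested CB position
  CA <- cb_at + c(1.522, 0, 0)
  N <- CA + c(0.5, 1.35, 0)
  C <- CA + c(0.6, -1.2, 0.6)
  O <- C + c(1.0, -0.5, 0)
  new_chain(chain_id, aa, N, CA, C, O, cb_at)
}

# small deterministic bundle reused by several files (cached per session)
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_bundle(synthetic_spec(n_targets = 3,
                                               decoys_per_target = 8,
                                               seed = 77))
    cache
  }
})

tiny_graph <- function(featurized = TRUE, labeled = TRUE) {
  b <- tiny_bundle()
  dec <- b[[1]]$decoy_set$decoys[[2]]
  g <- build_interface_graph(dec)
  if (featurized)
    g <- featurize_graph(g, dec, msa_chain1 = b[[1]]$msa1,
                         msa_chain2 = b[[1]]$msa2,
                         msa_paired = b[[1]]$msa_paired, sasa_points = 92)
  if (labeled) g <- label_graph(g, b[[1]]$native)
  g
}
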