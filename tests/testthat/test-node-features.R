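test_that("residue classes partition the standard alphabet", {
  std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  enc <- encode_residue_class(std)
  expect_true(all(rowSums(enc) == 1))
  expect_true(all(enc[, 5] == 0))            # no standard residue in bin 5
  expect_equal(colSums(enc)[1:4], c(polar = 7, nonpolar = 8, positive = 3,
                                    negative = 2))
  expect_equal(as.numeric(encode_residue_class("K")), c(0, 0, 1, 0, 0))
  expect_equal(as.numeric(encode_residue_class("X")), c(0, 0, 0, 0, 1))
  expect_equal(as.numeric(encode_residue_class("B")), c(0, 0, 0, 0, 1))
})

test_that("relative position is seq_index over own-chain length", {
  expect_equal(relative_position(100, 100), 1.0)
  expect_equal(relative_position(1, 100), 0.01)
  expect_equal(relative_position(46, 92), 0.5)
  expect_error(relative_position(0, 10), "out of range")
  expect_error(relative_position(11, 10), "out of range")
})

test_that("torsion features encode angles and absence", {
  expect_equal(as.numeric(torsion_features(0, 0)), c(0, 1, 0, 1))
  expect_equal(as.numeric(torsion_features(pi / 2, NA)), c(1, 0, 0, 0))
  got <- torsion_features(-57 * pi / 180, -47 * pi / 180)
  expect_equal(as.numeric(got), c(-0.8387, 0.5446, -0.7314, 0.6820),
               tolerance = 1e-3)
  # sin^2+cos^2 is 1 for defined pairs, 0 for absent ones
  tf <- unname(torsion_features(c(1.1, NA), c(NA, -2.2)))
  expect_equal(tf[1, 1]^2 + tf[1, 2]^2, 1)
  expect_equal(tf[1, 3]^2 + tf[1, 4]^2, 0)
  expect_equal(tf[2, 1]^2 + tf[2, 2]^2, 0)
  expect_equal(tf[2, 3]^2 + tf[2, 4]^2, 1)
})

test_that("DSSP records map to 3-state and burial one-hots", {
  b <- tiny_bundle()
  native <- b[[1]]$native
  # synthesize a DSSP file covering the native with fixed assignments
  hdr <- c("==== Secondary Structure Definition ====", "  # chains",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  mk_line <- function(i, resno, ch, aa, ss, acc)   # fixed DSSP columns
    sprintf("%5d%5d %s %s  %s%s%4d", i, resno, ch, aa, ss,
            strrep(" ", 17), acc)
  rows <- character(0); i <- 0
  for (ch in 1:2) {
    chain <- native$chains[[ch]]
    for (r in seq_len(chain$resno_orig[length(chain$aa)])) {
      i <- i + 1
      ss <- c("E", "H", "S")[(r - 1) %% 3 + 1]   # cycles E, H, S
      acc <- if (r %% 2 == 0) 10 else 150    # buried / exposed
      rows <- c(rows, mk_line(i, r, chain$chain_id, chain$aa[r], ss, acc))
    }
  }
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(hdr, rows), path)
  dssp <- read_dssp(path)
  expect_named(dssp, c("chain", "resno", "aa", "ss8", "acc"))
  feats <- secondary_structure_features(native, dssp = dssp)
  ch1 <- feats[[1]]
  # residue 1: ss 'E' (1 %% 3 = 1 -> "E"), acc 150 exposed
  expect_equal(as.numeric(ch1[1, ]), c(0, 1, 0, 0, 1))
  # residue 2: ss 'H', acc 10 -> buried (10/maxasa < 0.25)
  expect_equal(as.numeric(ch1[2, c("helix", "buried")]), c(1, 1))
  # residue 3: ss 'S' -> coil
  expect_equal(as.numeric(ch1[3, c("coil")]), 1)
  # one-hot blocks sum to one everywhere
  for (m in feats) {
    expect_true(all(rowSums(m[, 1:3, drop = FALSE]) == 1))
    expect_true(all(rowSums(m[, 4:5, drop = FALSE]) == 1))
  }
})

test_that("8-state grouping sends helices, strands and the rest as documented", {
  map <- ifaceqe:::ss8_to_ss3(c("H", "G", "I", "E", "B", "T", "S", "-", "P"))
  expect_equal(map, c("H", "H", "H", "E", "E", "C", "C", "C", "C"))
})

test_that("internal fallback calls an extended peptide strand with exposed termini", {
  build <- ifaceqe:::build_chain_from_torsions
  ch <- build(rep("A", 25), rep(-140 * pi / 180, 25),
              rep(135 * pi / 180, 25), "A")
  # a lone extended peptide needs a partner chain to form a complex; put a
  # far-away copy so the interface does not alter chain A's accessibility
  far <- transform_chain(ch, diag(3), c(500, 0, 0))
  far$chain_id <- "B"
  cplx <- new_complex_structure(ch, far, "ext")
  feats <- secondary_structure_features(cplx, sasa_points = 192)
  ch1 <- feats[[1]]
  expect_true(all(ch1[2:24, "strand"] == 1))
  expect_equal(unname(ch1[1, "exposed"]), 1)
  expect_equal(unname(ch1[25, "exposed"]), 1)
})

test_that("internal accessibility matches a 960-point Shrake-Rupley oracle", {
  set.seed(41)
  # small random atom cluster
  xyz <- matrix(rnorm(3 * 12, sd = 3), 12, 3)
  radii <- runif(12, 1.4, 1.9)
  fast <- shrake_rupley_sasa(xyz, radii, n_points = 960)
  slow <- oracle_sasa(xyz, radii, n_points = 960)
  expect_equal(fast, slow, tolerance = 1e-9)
  # resolution convergence: 192 points within a few percent of 960 points
  lo <- shrake_rupley_sasa(xyz, radii, n_points = 192)
  expect_lt(max(abs(lo - slow)) / max(slow), 0.05)
})

test_that("the assembled node feature matrix has the documented layout", {
  g <- tiny_graph()
  X <- g$node_features
  expect_equal(ncol(X), 17L)
  expect_equal(nrow(X), nrow(g$nodes))
  expect_true(all(rowSums(X[, 1:5, drop = FALSE]) == 1))   # residue class
  expect_true(all(X[, 6] > 0 & X[, 6] <= 1))               # rel_pos
  expect_true(all(rowSums(X[, 7:9, drop = FALSE]) == 1))   # ss3
  expect_true(all(rowSums(X[, 10:11, drop = FALSE]) == 1)) # burial
  s2 <- X[, 12]^2 + X[, 13]^2
  expect_true(all(abs(s2 - 1) < 1e-9 | s2 == 0))           # phi pair
  expect_true(all(X[, 16] >= 0 & X[, 17] >= 0))            # Neff features
  expect_error(assemble_node_features(X[, 1:5], X[, 6], X[, 7:11],
                                      X[1:3, 12:15], X[, 16], X[, 17]),
               "dimensions")
})

test_that("only the evolutionary entries react to the alignments", {
  b <- tiny_bundle()
  dec <- b[[1]]$decoy_set$decoys[[1]]
  g0 <- build_interface_graph(dec)
  g1 <- featurize_graph(g0, dec, msa_chain1 = b[[1]]$msa1,
                        msa_chain2 = b[[1]]$msa2,
                        msa_paired = b[[1]]$msa_paired, sasa_points = 92)
  g2 <- suppressWarnings(featurize_graph(g0, dec, sasa_points = 92))
  diffs <- which(colSums(abs(g1$node_features - g2$node_features)) > 0)
  expect_equal(unname(sort(diffs)), c(16L, 17L))
  expect_true(all(g2$node_features[, 16:17] == 0))
})

test_that("featurization is deterministic", {
  g1 <- tiny_graph()
  g2 <- tiny_graph()
  expect_identical(g1$node_features, g2$node_features)
  expect_identical(g1$edge_features, g2$edge_features)
})
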