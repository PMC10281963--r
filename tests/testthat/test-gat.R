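# hand-built featurized graphs for network tests: k nodes on chain 1 and
# chain 2 with prescribed edges and small deterministic features
mini_graph <- function(edges, n1, n2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  nodes <- data.frame(chain = rep(1:2, c(n1, n2)),
                      index = c(seq_len(n1), seq_len(n2)),
                      aa = rep("A", n))
  m <- nrow(edges)
  g <- structure(list(
    target_id = "mini",
    nodes = nodes,
    edges = data.frame(i = edges[, 1], j = edges[, 2],
                       res1 = nodes$index[edges[, 1]],
                       res2 = nodes$index[edges[, 2]],
                       d_model = runif(m, 3, 9)),
    node_features = matrix(rnorm(n * 17, sd = 0.5), n, 17),
    edge_features = matrix(rnorm(m * 27, sd = 0.5), m, 27),
    edge_label = runif(m, 0.05, 1)), class = "interface_graph")
  g
}

test_that("configuration derives the documented layer dimensions", {
  cfg <- gat_config()
  expect_equal(cfg$hidden, c(32L, 16L, 8L, 4L))
  expect_equal(cfg$in_dims, c(17L, 128L, 64L, 32L))
  expect_equal(cfg$heads, c(4L, 4L, 4L, 1L))
})

test_that("initialization is Xavier-shaped and reproducible from the seed", {
  cfg <- gat_config()
  p1 <- gat_init(cfg, seed = 9)
  p2 <- gat_init(cfg, seed = 9)
  expect_identical(p1, p2)
  expect_equal(dim(p1$layers[[1]]$W), c(128L, 17L + 27L))
  expect_equal(dim(p1$layers[[4]]$W), c(4L, 32L + 27L))
  lim <- sqrt(6 / (17 + 27 + 32))
  expect_lte(max(abs(p1$layers[[1]]$W)), lim)
  # the Xavier bound is essentially reached on 128 x 44 draws
  expect_gt(max(abs(p1$layers[[1]]$W)), 0.95 * lim)
})

test_that("a single-neighbor node gets attention one and its message verbatim", {
  g <- mini_graph(cbind(1, 2), 1, 1, seed = 2)
  p <- gat_init(gat_config(), seed = 3)
  res <- layer_forward(g$node_features, g$edge_features, p, 1, graph = g,
                       keep_cache = TRUE)
  expect_true(all(abs(res$cache$alpha - 1) < 1e-12))
  # node update reduces to elu of its single embedded message
  x_src <- c(g$node_features[2, ], g$edge_features[1, ])
  z <- as.numeric(p$layers[[1]]$W %*% x_src)
  expect_equal(unname(res$H_out[1, ]), ifelse(z > 0, z, exp(z) - 1),
               tolerance = 1e-12)
})

test_that("identical neighbors with identical edges split attention evenly", {
  g <- mini_graph(rbind(c(1, 2), c(1, 3)), 1, 2, seed = 4)
  g$node_features[3, ] <- g$node_features[2, ]
  g$edge_features[2, ] <- g$edge_features[1, ]
  p <- gat_init(gat_config(), seed = 5)
  res <- layer_forward(g$node_features, g$edge_features, p, 1, graph = g,
                       keep_cache = TRUE)
  alpha1 <- res$cache$alpha[c(1, 2), ]   # both directed edges into node 1
  expect_equal(unname(alpha1[1, ]), rep(0.5, 4), tolerance = 1e-12)
  expect_equal(unname(alpha1[2, ]), rep(0.5, 4), tolerance = 1e-12)
})

test_that("a layer forward pass matches an explicit step-by-step computation", {
  # 4-node graph, one head, tiny dimensions, hand-set weights
  cfg <- gat_config(n_layers = 1L, heads = 1L, hidden_input = 3L,
                    node_dim = 2L, edge_dim = 2L,
                    final_activation = "elu")
  edges <- rbind(c(1, 3), c(1, 4), c(2, 3))
  g <- mini_graph(edges, 2, 2, seed = 6)
  g$node_features <- matrix(c(0.1, -0.2, 0.3, 0.4,
                              0.5, 0.2, -0.1, 0.6), 4, 2)
  g$edge_features <- matrix(c(0.3, -0.5, 0.2,
                              0.7, 0.1, -0.4), 3, 2)
  p <- gat_init(cfg, seed = 7)
  p$layers[[1]]$W <- matrix(c(0.2, -0.1, 0.4, 0.3,
                              -0.3, 0.5, 0.1, -0.2,
                              0.6, 0.2, -0.4, 0.1), 3, 4, byrow = TRUE)
  p$layers[[1]]$a1 <- c(0.3, -0.2, 0.5)
  p$layers[[1]]$a2 <- c(-0.4, 0.1, 0.2)
  got <- layer_forward(g$node_features, g$edge_features, p, 1, graph = g)
  # explicit loops, scalar arithmetic only
  elu1 <- function(x) if (x > 0) x else exp(x) - 1
  leaky1 <- function(x) if (x > 0) x else 0.2 * x
  dir_dst <- c(edges[, 1], edges[, 2])
  dir_src <- c(edges[, 2], edges[, 1])
  dir_eid <- c(1:3, 1:3)
  ref <- matrix(0, 4, 3)
  for (node in 1:4) {
    incoming <- which(dir_dst == node)
    logits <- numeric(length(incoming)); msgs <- list()
    for (t in seq_along(incoming)) {
      e <- incoming[t]
      zs <- as.numeric(p$layers[[1]]$W %*%
                         c(g$node_features[dir_src[e], ],
                           g$edge_features[dir_eid[e], ]))
      zd <- as.numeric(p$layers[[1]]$W %*%
                         c(g$node_features[dir_dst[e], ],
                           g$edge_features[dir_eid[e], ]))
      logits[t] <- leaky1(sum(p$layers[[1]]$a1 * zd) +
                          sum(p$layers[[1]]$a2 * zs))
      msgs[[t]] <- zs
    }
    w <- exp(logits - max(logits)); w <- w / sum(w)
    s <- Reduce(`+`, Map(`*`, msgs, w))
    ref[node, ] <- vapply(s, elu1, numeric(1))
  }
  expect_equal(unname(got), ref, tolerance = 1e-6)
})

test_that("edge scores squash endpoint dot products logistically", {
  F <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 1, 0))
  expect_equal(edge_score(F, 1, 2), 0.5)               # orthogonal
  expect_equal(edge_score(F, 3, 3), 1 / (1 + exp(-3))) # ||h||^2 = 3
  expect_equal(edge_score(F, 1, 2, raw_dot = TRUE), 0)
  # monotone in the angle at fixed norms
  ang <- seq(0, pi, length.out = 10)
  sc <- vapply(ang, function(a)
    edge_score(rbind(c(1, 0), c(cos(a), sin(a))), 1, 2), numeric(1))
  expect_true(all(diff(sc) < 0))
})

test_that("quality aggregation is the order-invariant mean", {
  expect_equal(aggregate_quality(c(1, 1, 1)), 1)
  expect_equal(aggregate_quality(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(aggregate_quality(c(0.6, 0.2, 0.4)), 0.4)
  expect_error(aggregate_quality(numeric(0)), "no edge scores")
})

test_that("the forward pass is deterministic and bounded", {
  g <- tiny_graph()
  p <- gat_init(gat_config(), seed = 11)
  f1 <- model_forward(g, p)
  f2 <- model_forward(g, p)
  expect_identical(f1$Q, f2$Q)
  expect_true(f1$Q > 0 && f1$Q < 1)
  expect_true(all(f1$edge_scores > 0 & f1$edge_scores < 1))
})

test_that("attention weights over each neighborhood sum to one", {
  g <- tiny_graph()
  p <- gat_init(gat_config(), seed = 12)
  fw <- model_forward(g, p, return_attention = TRUE)
  for (att in fw$attention) {
    sums <- rowsum(att$alpha, att$dst)
    expect_equal(unname(sums), matrix(1, nrow(sums), ncol(sums)),
                 tolerance = 1e-9)
  }
})

test_that("Q is invariant to node relabeling of the input graph", {
  g <- tiny_graph()
  p <- gat_init(gat_config(), seed = 13)
  q0 <- model_forward(g, p)$Q
  set.seed(14)
  perm <- sample(nrow(g$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  g2 <- g
  g2$nodes <- g$nodes[perm, ]
  g2$node_features <- g$node_features[perm, ]
  g2$edges$i <- inv[g$edges$i]
  g2$edges$j <- inv[g$edges$j]
  fw2 <- model_forward(g2, p)
  expect_equal(fw2$Q, q0, tolerance = 1e-6)
  # node embeddings permute along (equivariance)
  fw0 <- model_forward(g, p)
  expect_equal(fw2$embeddings, fw0$embeddings[perm, ], tolerance = 1e-6)
})

test_that("analytic gradients match numerical differentiation", {
  # 6-node graph spanning several attention neighborhoods
  edges <- rbind(c(1, 4), c(1, 5), c(2, 4), c(2, 6), c(3, 5), c(3, 6))
  g <- mini_graph(edges, 3, 3, seed = 15)
  p <- gat_init(gat_config(), seed = 16)
  for (engine in c("r", "cpp")) {
    lg <- ifaceqe:::model_loss_grad(g, p, engine = engine)
    eps <- 1e-6
    set.seed(17)
    for (l in c(1L, 4L)) {
      # a few random entries of W plus one attention entry per layer
      idx <- cbind(sample(nrow(p$layers[[l]]$W), 4),
                   sample(ncol(p$layers[[l]]$W), 4))
      for (r in seq_len(nrow(idx))) {
        pp <- p; pm <- p
        pp$layers[[l]]$W[idx[r, 1], idx[r, 2]] <-
          pp$layers[[l]]$W[idx[r, 1], idx[r, 2]] + eps
        pm$layers[[l]]$W[idx[r, 1], idx[r, 2]] <-
          pm$layers[[l]]$W[idx[r, 1], idx[r, 2]] - eps
        num <- (ifaceqe:::model_loss_grad(g, pp, engine = engine)$loss -
                ifaceqe:::model_loss_grad(g, pm, engine = engine)$loss) /
          (2 * eps)
        ana <- lg$grads[[l]]$W[idx[r, 1], idx[r, 2]]
        expect_equal(ana, num, tolerance = 1e-4)
      }
      k <- sample(length(p$layers[[l]]$a1), 1)
      pp <- p; pm <- p
      pp$layers[[l]]$a1[k] <- pp$layers[[l]]$a1[k] + eps
      pm$layers[[l]]$a1[k] <- pm$layers[[l]]$a1[k] - eps
      num <- (ifaceqe:::model_loss_grad(g, pp, engine = engine)$loss -
              ifaceqe:::model_loss_grad(g, pm, engine = engine)$loss) /
        (2 * eps)
      expect_equal(lg$grads[[l]]$a1[k], num, tolerance = 1e-4)
    }
  }
})

test_that("the compiled kernel reproduces the reference implementation", {
  g <- tiny_graph()
  p <- gat_init(gat_config(), seed = 18)
  a <- ifaceqe:::model_loss_grad(g, p, engine = "r")
  b <- ifaceqe:::model_loss_grad(g, p, engine = "cpp")
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  expect_equal(a$Q, b$Q, tolerance = 1e-12)
  for (l in 1:4) {
    expect_equal(a$grads[[l]]$W, b$grads[[l]]$W, tolerance = 1e-10)
    expect_equal(a$grads[[l]]$a1, b$grads[[l]]$a1, tolerance = 1e-10)
    expect_equal(a$grads[[l]]$a2, b$grads[[l]]$a2, tolerance = 1e-10)
  }
})

test_that("checkpoints round-trip and refuse version mismatches", {
  p <- gat_init(gat_config(), seed = 19)
  path <- withr::local_tempfile(fileext = ".json")
  save_gat_checkpoint(p, path)
  q <- load_gat_checkpoint(path)
  expect_equal(q$layers, p$layers, tolerance = 1e-12)
  expect_equal(q$config$hidden, p$config$hidden)
  g <- tiny_graph()
  expect_equal(model_forward(g, q)$Q, model_forward(g, p)$Q,
               tolerance = 1e-12)
  # tamper with the feature version tag
  obj <- jsonlite::read_json(path)
  obj$feature_version <- "other/v9"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_gat_checkpoint(path), "feature version")
})

test_that("sum-reduced loss behaves as a sum", {
  expect_equal(edge_regression_loss(c(0.5), c(1.0)), 0.25)
  expect_equal(edge_regression_loss(c(0.2, 0.8), c(0.2, 0.8)), 0)
  x <- c(0.3, 0.9); z <- c(0.5, 0.4)
  expect_equal(edge_regression_loss(c(x, x), c(z, z)),
               2 * edge_regression_loss(x, z))
  expect_error(edge_regression_loss(1:3 / 10, 1:2 / 10), "mismatch")
})
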