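# Multi-head graph attention network for edge-level interface quality
# regression. Four layers; intermediate layers use four attention heads
# whose outputs are concatenated, the output layer a single head. Per
# directed edge (dst i <- src j) and head:
#   z_{i,ij} = W [h_i || e_ij],  z_{j,ij} = W [h_j || e_ij]
#   logit_ij = leakyrelu(a . [z_{i,ij} || z_{j,ij}])
#   alpha_ij = softmax over j in N(i)
#   h_i'     = elu( sum_j alpha_ij z_{j,ij} )   (identity at the output layer)
# Edge scores are logistic-squashed dot products of the final endpoint
# embeddings; Q is their mean. All heads of a layer are fused into one
# weight matrix (rows stacked head-major) so a layer is a handful of dense
# matrix products; grouped sums over neighborhoods go through precomputed
# 0/1 aggregation matrices (BLAS) rather than rowsum().

LOGIT_CLAMP <- 50  # numerical safeguard on attention logits before exp()

#' Network architecture configuration
#'
#' @param n_layers number of attention layers.
#' @param heads attention heads per layer.
#' @param hidden_input per-head hidden dimension of the first layer.
#' @param hidden_scale per-layer multiplicative scaling of the hidden
#'   dimension.
#' @param node_dim,edge_dim input feature dimensions.
#' @param leaky_slope negative slope of the leaky rectifier on attention
#'   logits.
#' @param final_activation node-update nonlinearity of the output layer:
#'   `"identity"` (linear output embeddings, the default, so edge dot
#'   products take both signs and the logistic edge score does not
#'   saturate) or `"elu"` as in the intermediate layers.
#' @param raw_dot if `TRUE`, report raw (unsquashed) edge dot products
#'   instead of logistic-squashed scores.
#' @return list of class `gat_config` with derived per-layer dimensions
#'   `hidden` (per head) and `in_dims`.
#' @export
gat_config <- function(n_layers = 4L, heads = c(4L, 4L, 4L, 1L),
                       hidden_input = 32L, hidden_scale = 0.5,
                       node_dim = 17L, edge_dim = 27L, leaky_slope = 0.2,
                       final_activation = c("identity", "elu"),
                       raw_dot = FALSE) {
  stopifnot(length(heads) == n_layers)
  final_activation <- match.arg(final_activation)
  hidden <- as.integer(hidden_input * hidden_scale^(seq_len(n_layers) - 1))
  in_dims <- c(node_dim, (heads * hidden)[-n_layers])
  structure(list(n_layers = n_layers, heads = as.integer(heads),
                 hidden = hidden, in_dims = in_dims,
                 node_dim = as.integer(node_dim),
                 edge_dim = as.integer(edge_dim),
                 leaky_slope = leaky_slope,
                 final_activation = final_activation, raw_dot = raw_dot),
            class = "gat_config")
}

#' Xavier-initialized network parameters
#'
#' Per layer: a fused embedding weight matrix `W` of shape
#' `(heads * hidden) x (in_dim + edge_dim)` (head blocks stacked row-wise)
#' and attention vectors `a1`, `a2` (destination/source halves), all drawn
#' from the Xavier uniform distribution. The output layer's embedding
#' weights are additionally scaled by `output_scale` so that initial edge
#' dot products start near zero (edge scores near 0.5) instead of deep in
#' the logistic tails, which would stall the edge-score regression.
#'
#' @param config `gat_config`.
#' @param seed optional integer seed for reproducible initialization.
#' @param output_scale multiplier on the output layer's Xavier weights.
#' @return list of class `gat_params` with elements `layers` (per-layer
#'   `W`, `a1`, `a2`) and `config`.
#' @export
gat_init <- function(config = gat_config(), seed = NULL, output_scale = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    K <- config$heads[l]; h <- config$hidden[l]
    fan_in <- config$in_dims[l] + config$edge_dim
    limW <- sqrt(6 / (fan_in + h))
    W <- matrix(stats::runif(K * h * fan_in, -limW, limW), K * h, fan_in)
    if (l == config$n_layers) W <- W * output_scale
    lima <- sqrt(6 / (2 * h + 1))
    layers[[l]] <- list(
      W = W,
      a1 = stats::runif(K * h, -lima, lima),
      a2 = stats::runif(K * h, -lima, lima))
  }
  structure(list(layers = layers, config = config), class = "gat_params")
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_prime <- function(x) {
  out <- x
  neg <- x < 0
  out[!neg] <- 1
  out[neg] <- exp(x[neg])
  out
}
leaky <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
leaky_prime <- function(x, slope) {
  out <- x
  neg <- x < 0
  out[!neg] <- 1
  out[neg] <- slope
  out
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# Directed-edge index arrays for message passing: each undirected
# inter-chain edge contributes both directions.
graph_directed <- function(graph) {
  m <- nrow(graph$edges)
  list(dst = c(graph$edges$i, graph$edges$j),
       src = c(graph$edges$j, graph$edges$i),
       eid = c(seq_len(m), seq_len(m)),
       n_nodes = nrow(graph$nodes))
}

# Static per-graph structures reused across every forward/backward pass:
# directed indices, 0/1 aggregation matrices (node x directed-edge) for
# destination- and source-grouped sums, the repeated edge-feature block and
# the static layer-1 inputs.
build_gat_cache <- function(graph) {
  dirs <- graph_directed(graph)
  n <- dirs$n_nodes; Tn <- length(dirs$dst)
  Ad <- matrix(0, n, Tn); Ad[cbind(dirs$dst, seq_len(Tn))] <- 1
  As <- matrix(0, n, Tn); As[cbind(dirs$src, seq_len(Tn))] <- 1
  E <- graph$edge_features[dirs$eid, , drop = FALSE]
  H0 <- graph$node_features
  list(dirs = dirs, Ad = Ad, As = As, E = E,
       X1d = cbind(H0[dirs$dst, , drop = FALSE], E),
       X1s = cbind(H0[dirs$src, , drop = FALSE], E))
}

# expand a T x K per-head matrix to T x (K*h) by repeating head columns
expand_heads <- function(x, h) x[, rep(seq_len(ncol(x)), each = h),
                                 drop = FALSE]

# per-head attention contraction matrices (K*h x K block diagonal)
attention_blocks <- function(a1, a2, K, h) {
  A1 <- matrix(0, K * h, K); A2 <- matrix(0, K * h, K)
  for (k in seq_len(K)) {
    rows <- ((k - 1) * h + 1):(k * h)
    A1[rows, k] <- a1[rows]
    A2[rows, k] <- a2[rows]
  }
  list(A1 = A1, A2 = A2)
}

# core of one attention layer given prepared inputs Xd/Xs
layer_forward_core <- function(Xd, Xs, P, K, h, cfg, layer_index, gc,
                               keep_cache) {
  Zd <- tcrossprod(Xd, P$W)               # T x K*h
  Zs <- tcrossprod(Xs, P$W)
  ab <- attention_blocks(P$a1, P$a2, K, h)
  pre <- Zd %*% ab$A1 + Zs %*% ab$A2      # T x K
  L <- leaky(pre, cfg$leaky_slope)
  expL <- exp(pmin(pmax(L, -LOGIT_CLAMP), LOGIT_CLAMP))
  denom <- gc$Ad %*% expL                 # n x K
  alpha <- expL / denom[gc$dirs$dst, , drop = FALSE]
  alphaE <- expand_heads(alpha, h)
  S <- gc$Ad %*% (alphaE * Zs)            # n x K*h
  linear_out <- layer_index == cfg$n_layers &&
    identical(cfg$final_activation, "identity")
  H_out <- if (linear_out) S else elu(S)
  if (!keep_cache) return(list(H_out = H_out))
  list(H_out = H_out,
       cache = list(Xd = Xd, Xs = Xs, Zd = Zd, Zs = Zs, pre = pre, L = L,
                    alpha = alpha, S = S, K = K, h = h))
}

#' One attention layer forward pass
#'
#' @param H n x d node embedding matrix.
#' @param E m x edge_dim static edge feature matrix.
#' @param params `gat_params`.
#' @param layer_index layer number (1-based).
#' @param graph `interface_graph` defining the connectivity.
#' @param keep_cache retain intermediates for the backward pass.
#' @return updated n x (heads*hidden) embedding matrix; with
#'   `keep_cache = TRUE` a list `(H_out, cache)`.
#' @export
layer_forward <- function(H, E, params, layer_index, graph,
                          keep_cache = FALSE) {
  cfg <- params$config
  gc <- build_gat_cache_with(graph, H, E)
  P <- params$layers[[layer_index]]
  K <- cfg$heads[layer_index]; h <- cfg$hidden[layer_index]
  Eexp <- E[gc$dirs$eid, , drop = FALSE]
  Xd <- cbind(H[gc$dirs$dst, , drop = FALSE], Eexp)
  Xs <- cbind(H[gc$dirs$src, , drop = FALSE], Eexp)
  res <- layer_forward_core(Xd, Xs, P, K, h, cfg, layer_index, gc, keep_cache)
  if (keep_cache) res else res$H_out
}

# cache builder for arbitrary (H, E) inputs (public layer_forward path)
build_gat_cache_with <- function(graph, H, E) {
  dirs <- graph_directed(graph)
  n <- dirs$n_nodes; Tn <- length(dirs$dst)
  Ad <- matrix(0, n, Tn); Ad[cbind(dirs$dst, seq_len(Tn))] <- 1
  As <- matrix(0, n, Tn); As[cbind(dirs$src, seq_len(Tn))] <- 1
  list(dirs = dirs, Ad = Ad, As = As)
}

# backward through one layer; returns list(dH, dW, da1, da2)
layer_backward <- function(dH_out, params, layer_index, gc, cache) {
  cfg <- params$config
  P <- params$layers[[layer_index]]
  K <- cache$K; h <- cache$h
  p <- cfg$in_dims[layer_index]
  linear_out <- layer_index == cfg$n_layers &&
    identical(cfg$final_activation, "identity")
  dS <- if (linear_out) dH_out else dH_out * elu_prime(cache$S)  # n x K*h
  dM <- dS[gc$dirs$dst, , drop = FALSE]              # T x K*h
  alphaE <- expand_heads(cache$alpha, h)
  # d alpha (per head): sum over the head's columns of dM * Zs
  prodMZ <- dM * cache$Zs
  dalpha <- matrix(0, nrow(dM), K)
  for (k in seq_len(K)) {
    cols <- ((k - 1) * h + 1):(k * h)
    dalpha[, k] <- rowSums(prodMZ[, cols, drop = FALSE])
  }
  dZs <- dM * alphaE
  # softmax backward (grouped by destination node)
  inner <- gc$Ad %*% (cache$alpha * dalpha)          # n x K
  dL <- cache$alpha * (dalpha - inner[gc$dirs$dst, , drop = FALSE])
  dL[abs(cache$L) > LOGIT_CLAMP] <- 0                # clamp region
  dpre <- dL * leaky_prime(cache$pre, cfg$leaky_slope)
  dpreE <- expand_heads(dpre, h)                     # T x K*h
  a1E <- matrix(P$a1, nrow(dpreE), K * h, byrow = TRUE)
  a2E <- matrix(P$a2, nrow(dpreE), K * h, byrow = TRUE)
  dZd <- dpreE * a1E
  dZs <- dZs + dpreE * a2E
  da1 <- colSums(cache$Zd * dpreE)
  da2 <- colSums(cache$Zs * dpreE)
  dW <- unname(crossprod(dZs, cache$Xs) + crossprod(dZd, cache$Xd))
  dXs <- dZs %*% P$W
  dXd <- dZd %*% P$W
  dH <- gc$As %*% dXs[, seq_len(p), drop = FALSE] +
        gc$Ad %*% dXd[, seq_len(p), drop = FALSE]
  list(dH = dH, dW = dW, da1 = da1, da2 = da2)
}

#' Edge score from final node embeddings
#'
#' Dot product of the two endpoint embeddings, logistic-squashed into
#' `(0, 1)` (or returned raw when the configuration sets `raw_dot`).
#'
#' @param final_embeds n x d matrix of last-layer node embeddings.
#' @param i,j node indices of the edge endpoints (vectorized).
#' @param raw_dot skip the logistic squashing.
#' @return numeric vector of edge scores.
#' @export
edge_score <- function(final_embeds, i, j, raw_dot = FALSE) {
  prod <- rowSums(final_embeds[i, , drop = FALSE] *
                  final_embeds[j, , drop = FALSE])
  if (raw_dot) prod else sigmoid(prod)
}

#' Aggregate edge scores into the interface quality Q
#'
#' The probabilistic combination is the arithmetic mean of the per-edge
#' scores.
#'
#' @param edge_scores numeric vector, length >= 1.
#' @return Q in `[0, 1]` (for squashed scores).
#' @export
aggregate_quality <- function(edge_scores) {
  if (length(edge_scores) == 0L) stop("no edge scores to aggregate")
  mean(edge_scores)
}

# internal forward over a prepared cache
forward_cached <- function(graph, params, gc, keep_cache = FALSE) {
  cfg <- params$config
  H <- graph$node_features
  caches <- if (keep_cache) vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    P <- params$layers[[l]]
    if (l == 1L) {
      Xd <- gc$X1d; Xs <- gc$X1s
    } else {
      Xd <- cbind(H[gc$dirs$dst, , drop = FALSE], gc$E)
      Xs <- cbind(H[gc$dirs$src, , drop = FALSE], gc$E)
    }
    res <- layer_forward_core(Xd, Xs, P, cfg$heads[l], cfg$hidden[l], cfg, l,
                              gc, keep_cache)
    if (keep_cache) caches[[l]] <- res$cache
    H <- res$H_out
    if (anyNA(H) || any(is.infinite(H)))
      stop("non-finite embedding after layer ", l)
  }
  scores <- edge_score(H, graph$edges$i, graph$edges$j, raw_dot = cfg$raw_dot)
  list(edge_scores = scores, Q = aggregate_quality(scores), embeddings = H,
       caches = caches)
}

#' Full network forward pass
#'
#' @param graph featurized `interface_graph`.
#' @param params `gat_params`.
#' @param keep_cache retain all intermediates.
#' @param return_attention also return per-layer attention weights with
#'   their destination-node grouping.
#' @param gc precomputed graph cache (internal; built when `NULL`).
#' @return list with `edge_scores` (per undirected edge, model order), `Q`,
#'   `embeddings` (final layer); plus `caches`/`attention` on request.
#' @export
model_forward <- function(graph, params, keep_cache = FALSE,
                          return_attention = FALSE, gc = NULL) {
  stopifnot(inherits(graph, "interface_graph"), inherits(params, "gat_params"))
  if (is.null(graph$node_features) || is.null(graph$edge_features))
    stop("graph is not featurized; call featurize_graph() first")
  if (is.null(gc)) gc <- build_gat_cache(graph)
  out <- forward_cached(graph, params, gc,
                        keep_cache = keep_cache || return_attention)
  if (return_attention)
    out$attention <- lapply(out$caches, function(cc)
      list(alpha = cc$alpha, dst = gc$dirs$dst))
  if (!keep_cache) out$caches <- NULL
  out$gc <- gc
  out
}

#' Sum-reduced squared-error loss over edges
#'
#' @param pred_scores predicted per-edge scores.
#' @param labels ground-truth z labels.
#' @return sum of squared differences (sum reduction, not mean).
#' @export
edge_regression_loss <- function(pred_scores, labels) {
  if (length(pred_scores) != length(labels))
    stop("length mismatch: ", length(pred_scores), " predictions vs ",
         length(labels), " labels")
  sum((pred_scores - labels)^2)
}

# Forward + analytic backward for one labeled graph. The compiled kernel
# (src/gat_core.cpp) is the default engine; engine = "r" runs the base-R
# reference path, and the two are asserted equal in the test suite.
# Returns list(loss, grads, Q) where grads mirrors params$layers.
model_loss_grad <- function(graph, params, gc = NULL,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- params$config
  if (is.null(gc)) gc <- build_gat_cache(graph)
  if (engine == "cpp") {
    z <- graph$edge_label
    if (is.null(z)) stop("graph has no edge labels")
    res <- .gat_core(lapply(params$layers, `[[`, "W"),
                     lapply(params$layers, `[[`, "a1"),
                     lapply(params$layers, `[[`, "a2"),
                     graph$node_features, gc$E, gc$dirs$dst, gc$dirs$src,
                     graph$edges$i, graph$edges$j, gc$dirs$n_nodes,
                     cfg$heads, cfg$hidden, cfg$leaky_slope,
                     identical(cfg$final_activation, "identity"),
                     cfg$raw_dot, TRUE, z)
    grads <- lapply(seq_len(cfg$n_layers), function(l)
      list(W = res$gW[[l]], a1 = as.numeric(res$ga1[[l]]),
           a2 = as.numeric(res$ga2[[l]])))
    return(list(loss = res$loss, grads = grads, Q = res$Q))
  }
  fw <- forward_cached(graph, params, gc, keep_cache = TRUE)
  z <- graph$edge_label
  if (is.null(z)) stop("graph has no edge labels")
  scores <- fw$edge_scores
  loss <- edge_regression_loss(scores, z)
  dscore <- 2 * (scores - z)
  dprod <- if (cfg$raw_dot) dscore else dscore * scores * (1 - scores)
  Ffin <- fw$embeddings
  i <- graph$edges$i; j <- graph$edges$j
  contrib <- rbind(dprod * Ffin[j, , drop = FALSE],
                   dprod * Ffin[i, , drop = FALSE])
  dH <- rowsum(contrib, c(i, j))          # n x d (all nodes touch >=1 edge)
  grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    bk <- layer_backward(dH, params, l, gc, fw$caches[[l]])
    grads[[l]] <- list(W = bk$dW, a1 = bk$da1, a2 = bk$da2)
    dH <- bk$dH
  }
  list(loss = loss, grads = grads, Q = fw$Q)
}

#' Save network parameters to a portable checkpoint
#'
#' JSON text file carrying the architecture configuration, all weights and
#' a feature-order version tag; [load_gat_checkpoint()] refuses to load a
#' checkpoint whose tag does not match the package's current feature
#' layout.
#'
#' @param params `gat_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_gat_checkpoint <- function(params, path) {
  cfg <- params$config
  obj <- list(
    format = "ifaceqe-gat/1",
    feature_version = feature_version(),
    config = unclass(cfg),
    layers = lapply(params$layers, function(P)
      list(W = P$W, a1 = P$a1, a2 = P$a2)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# tag describing the exact feature layout the network was trained on
feature_version <- function() "node17(rc5,relpos,ss3,bur2,tor4,neff2)+edge27(d17,ori10)/v1"

#' Load network parameters from a checkpoint
#'
#' @param path file written by [save_gat_checkpoint()].
#' @return `gat_params`.
#' @export
load_gat_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "ifaceqe-gat/1"))
    stop("not an ifaceqe checkpoint: ", path)
  if (!identical(obj$feature_version, feature_version()))
    stop("checkpoint feature version ", obj$feature_version,
         " does not match this package (", feature_version(), ")")
  cfgl <- obj$config
  scale <- if (cfgl$n_layers > 1) cfgl$hidden[2] / cfgl$hidden[1] else 0.5
  cfg <- gat_config(n_layers = cfgl$n_layers, heads = cfgl$heads,
                    hidden_input = cfgl$hidden[1], hidden_scale = scale,
                    node_dim = cfgl$node_dim, edge_dim = cfgl$edge_dim,
                    leaky_slope = cfgl$leaky_slope,
                    final_activation = cfgl$final_activation %||% "identity",
                    raw_dot = cfgl$raw_dot)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    P <- obj$layers[[l]]
    W <- if (is.matrix(P$W)) P$W else
      matrix(unlist(P$W), nrow = cfg$heads[l] * cfg$hidden[l], byrow = TRUE)
    stopifnot(nrow(W) == cfg$heads[l] * cfg$hidden[l],
              ncol(W) == cfg$in_dims[l] + cfg$edge_dim)
    list(W = W, a1 = as.numeric(unlist(P$a1)), a2 = as.numeric(unlist(P$a2)))
  })
  structure(list(layers = layers, config = cfg), class = "gat_params")
}
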