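#' Model configuration
#'
#' Architecture hyperparameters of the multi-view Nm classifier. The
#' defaults are the fixed operating point of the method: 64 convolution
#' kernels of width 3 per CNN branch, embedding dimension 64 shared by
#' the CNN outputs and the graph attention network, 8 attention heads
#' (averaged, so `embed_dim` need not be divisible by `n_heads`),
#' max-pooling of size 2, dropout 0.2, LeakyReLU slope 0.2 in the GAT
#' attention, and a 64-unit hidden layer in the fully connected head.
#' `use_seq`/`use_chem`/`use_str` are the ablation switches: they
#' enable/disable the one-hot sequence branch, the chemical-property
#' branch and the structure-graph branch.
#'
#' @param n_kernels convolution kernels per CNN branch
#' @param kernel_size convolution width
#' @param embed_dim shared embedding dimension (CNN outputs, GAT, cross-attention)
#' @param n_heads GAT attention heads per layer
#' @param n_gat_layers stacked GAT layers
#' @param pool_size max-pooling window (= stride)
#' @param dropout dropout rate on the head's hidden layer (training only)
#' @param leaky_slope negative slope of the GAT attention LeakyReLU
#' @param fc_hidden hidden units of the classification head
#' @param use_seq,use_chem,use_str feature-view switches
#' @return A list of class `nm_config`.
#' @export
nm_config <- function(n_kernels = 64, kernel_size = 3, embed_dim = 64,
                      n_heads = 8, n_gat_layers = 2, pool_size = 2,
                      dropout = 0.2, leaky_slope = 0.2, fc_hidden = 64,
                      use_seq = TRUE, use_chem = TRUE, use_str = TRUE) {
  cfg <- list(n_kernels = n_kernels, kernel_size = kernel_size,
              embed_dim = embed_dim, n_heads = n_heads,
              n_gat_layers = n_gat_layers, pool_size = pool_size,
              dropout = dropout, leaky_slope = leaky_slope,
              fc_hidden = fc_hidden, use_seq = use_seq,
              use_chem = use_chem, use_str = use_str)
  stopifnot(all(vapply(cfg[1:9], function(v) v >= 0, logical(1))))
  if (!use_seq && !use_chem && !use_str) {
    stop("at least one feature view must be enabled", call. = FALSE)
  }
  structure(cfg, class = "nm_config")
}

# which vectors are concatenated into the classification head, per the
# ablation switches; the fused vector O replaces the seq/str pair when
# both are present, and a lone structure branch is flattened over nodes
# (position-preserving)
head_parts <- function(config) {
  parts <- character(0)
  if (config$use_seq && config$use_str) parts <- c(parts, "fused")
  else {
    if (config$use_seq) parts <- c(parts, "seq")
    if (config$use_str) parts <- c(parts, "str_flat")
  }
  if (config$use_chem) parts <- c(parts, "chem")
  parts
}

head_input_dim <- function(config, window_len) {
  E <- config$embed_dim
  sum(vapply(head_parts(config), function(p) {
    if (p == "str_flat") window_len * E else E
  }, numeric(1)))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform initialisation of every weight matrix, zero biases.
#' Draws from R's RNG, so wrap in `set.seed()` for reproducibility.
#'
#' @param config an [nm_config()]
#' @param window_len window length L (default 51)
#' @return Named list of class `nm_params` holding all weight arrays.
#' @export
nm_init_params <- function(config, window_len = 51) {
  L <- window_len
  ks <- config$kernel_size
  K <- config$n_kernels
  E <- config$embed_dim
  H <- config$n_heads
  pool_len <- L %/% config$pool_size
  flat <- pool_len * K
  gat_W <- function(fin) {
    a <- array(0, dim = c(fin, E, H))
    for (h in seq_len(H)) a[, , h] <- glorot(fin, E)
    a
  }
  p <- list(
    conv_seq_W = glorot(ks * 4, K), conv_seq_b = numeric(K),
    fc_seq_W = glorot(flat, E), fc_seq_b = numeric(E),
    conv_chem_W = glorot(ks * 3, K), conv_chem_b = numeric(K),
    fc_chem_W = glorot(flat, E), fc_chem_b = numeric(E),
    gat1_W = gat_W(4), gat1_asrc = glorot(E, H), gat1_adst = glorot(E, H),
    gat2_W = gat_W(E), gat2_asrc = glorot(E, H), gat2_adst = glorot(E, H),
    wq = glorot(E, E), wk = glorot(E, E), wv = glorot(E, E),
    fc1_W = glorot(head_input_dim(config, L), config$fc_hidden),
    fc1_b = numeric(config$fc_hidden),
    fc2_W = glorot(config$fc_hidden, 1), fc2_b = numeric(1)
  )
  structure(p, class = "nm_params", window_len = L)
}

relu <- function(x) pmax(x, 0)
elu <- function(x) ifelse(x > 0, x, expm1(pmin(x, 0)))
leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' CNN branch: convolution, pooling, projection
#'
#' One 1-D convolution along the window (C input channels, `n_kernels`
#' filters of width `kernel_size`, zero same-padding) with ReLU, then
#' max-pooling of window `pool_size` with equal stride (a trailing
#' position that does not fill a window is dropped), then flattening and
#' a linear projection to `embed_dim`. This produces the deep sequence
#' representation (for the one-hot view) or the deep chemical-property
#' representation.
#'
#' @param x `L x C` input matrix (C = 4 for sequence, 3 for chemistry)
#' @param conv_W `(kernel_size*C) x n_kernels` kernel matrix (taps
#'   outermost: rows are tap 1 channels 1..C, tap 2 channels 1..C, ...)
#' @param conv_b,fc_W,fc_b bias / projection parameters
#' @param config an [nm_config()]
#' @return `embed_dim` vector.
#' @export
cnn_branch <- function(x, conv_W, conv_b, fc_W, fc_b, config) {
  L <- nrow(x); C <- ncol(x); ks <- config$kernel_size
  stopifnot(L >= ks, nrow(conv_W) == ks * C)
  half <- (ks - 1L) %/% 2L
  xpad <- rbind(matrix(0, half, C), x, matrix(0, ks - 1L - half, C))
  xcol <- matrix(0, L, ks * C)
  for (t in seq_len(ks)) {
    xcol[, ((t - 1) * C + 1):(t * C)] <- xpad[t:(t + L - 1), , drop = FALSE]
  }
  z <- relu(sweep(xcol %*% conv_W, 2, conv_b, "+"))
  ps <- config$pool_size
  pool_len <- L %/% ps
  pooled <- matrix(0, pool_len, ncol(z))
  for (p in seq_len(pool_len)) {
    rows <- ((p - 1) * ps + 1):(p * ps)
    pooled[p, ] <- apply(z[rows, , drop = FALSE], 2, max)
  }
  drop(crossprod(fc_W, as.vector(pooled))) + fc_b
}

#' One multi-head graph attention layer
#'
#' For each head k with weight `W_k` and attention vector
#' `a = (a_src, a_dst)`, the unnormalised attention logit from node i to
#' neighbour j is `LeakyReLU(a_src . W_k h_i + a_dst . W_k h_j)`
#' (the single-layer feed-forward attention on the concatenation
#' `[W_k h_i || W_k h_j]`); logits are softmax-normalised over each
#' node's neighbourhood, neighbour features `W_k h_j` are averaged with
#' those weights, head outputs are averaged across heads, and an ELU is
#' applied.
#'
#' @param node_feats `N x F` node feature matrix
#' @param edges two-column 1-based integer matrix of directed edges
#'   `(i, j)` meaning j is in i's neighbourhood; must include self-loops
#' @param W `F x F' x n_heads` array of head weights
#' @param a_src,a_dst `F' x n_heads` halves of each head's attention vector
#' @param config an [nm_config()] (uses `leaky_slope`, `n_heads`)
#' @return `N x F'` matrix of new node features; the per-head attention
#'   matrices (rows summing to 1 over each neighbourhood) are attached
#'   as attribute `"attention"`.
#' @export
gat_layer <- function(node_feats, edges, W, a_src, a_dst, config) {
  N <- nrow(node_feats)
  if (!all(seq_len(N) %in% edges[, 1])) {
    stop("every node needs at least one out-edge (add self-loops)",
         call. = FALSE)
  }
  adj <- matrix(FALSE, N, N)
  adj[edges] <- TRUE
  out <- matrix(0, N, dim(W)[2])
  H <- config$n_heads
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    Wh <- node_feats %*% W[, , h]
    f <- drop(Wh %*% a_src[, h])
    g <- drop(Wh %*% a_dst[, h])
    E <- leaky_relu(outer(f, g, "+"), config$leaky_slope)
    E[!adj] <- -Inf
    E <- E - apply(E, 1, max)
    A <- exp(E)
    A <- A / rowSums(A)
    attn[[h]] <- A
    out <- out + A %*% Wh
  }
  structure(elu(out / H), attention = attn)
}

# directed edge list of the structure graph: base pairs + backbone
# (i, i±1) + self-loops, 1-based
structure_edges <- function(x_str) {
  L <- nrow(x_str)
  adj <- (x_str != 0)
  idx <- seq_len(L - 1)
  adj[cbind(idx, idx + 1)] <- TRUE
  adj[cbind(idx + 1, idx)] <- TRUE
  diag(adj) <- TRUE
  which(adj, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

#' GAT branch over the base-pair graph
#'
#' Builds the structure graph — one node per window position carrying
#' its one-hot base identity, edges given by the base-pair matrix plus
#' backbone edges (i, i±1) and self-loops so unpaired bases are never
#' isolated — and applies the stacked multi-head attention layers.
#'
#' @param x_str `L x L` symmetric binary base-pair matrix
#' @param node_onehot `L x 4` one-hot node features (base identities)
#' @param params an `nm_params` list
#' @param config an [nm_config()]
#' @return `L x embed_dim` matrix of per-node structure features.
#' @export
gat_branch <- function(x_str, node_onehot, params, config) {
  if (!isTRUE(all.equal(x_str, t(x_str)))) {
    stop("x_str must be symmetric", call. = FALSE)
  }
  edges <- structure_edges(x_str)
  h <- gat_layer(node_onehot, edges, params$gat1_W, params$gat1_asrc,
                 params$gat1_adst, config)
  gat_layer(h, edges, params$gat2_W, params$gat2_asrc,
            params$gat2_adst, config)
}

#' Scaled-dot-product cross-attention
#'
#' Queries come from the deep sequence representation, keys and values
#' from the deep structure representation:
#' `Q = X_seq2 Wq`, `K = X_str2 Wk`, `V = X_str2 Wv`,
#' `A = softmax(Q K^T / sqrt(Dk))`, `O = A V`. Every row of `A` sums
#' to 1.
#'
#' @param x_seq2 `N x Dx` query-side features
#' @param x_str2 `M x Dy` key/value-side features
#' @param wq,wk,wv projection matrices (`Dx x Dk`, `Dy x Dk`, `Dy x Dv`)
#' @return `N x Dv` fused matrix `O`, with the attention matrix in
#'   attribute `"attention"`.
#' @export
cross_attention <- function(x_seq2, x_str2, wq, wk, wv) {
  Q <- x_seq2 %*% wq
  K <- x_str2 %*% wk
  V <- x_str2 %*% wv
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1, max)
  A <- exp(S)
  A <- A / rowSums(A)
  O <- A %*% V
  attr(O, "attention") <- A
  O
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]` for numerical stability.
#'
#' @param probs predicted probabilities in `[0, 1]`
#' @param labels 0/1 labels
#' @param eps clamp constant
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length", call. = FALSE)
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log1p(-p))
}

#' Reference forward pass (single sample, evaluation mode)
#'
#' A plain-R evaluation of the full network used as the readable
#' reference implementation; training uses the compiled path, which is
#' tested to agree with this one. Dropout is inactive (identity), so the
#' output is deterministic given the parameters.
#'
#' The fusion follows the ablation switches: with both the sequence and
#' structure views on, the cross-attention output `O` (a single query:
#' the pooled sequence vector) replaces them; a lone structure view is
#' flattened over nodes, preserving position; the chemical vector is
#' concatenated last. The
#' concatenation feeds FC(`fc_hidden`) + ReLU and FC(1) + sigmoid.
#'
#' @param x_seq `L x 4` one-hot view
#' @param x_chem `L x 3` chemical view
#' @param x_str `L x L` base-pair view
#' @param params an `nm_params`
#' @param config an [nm_config()]
#' @param x_node node features for the structure graph (defaults to
#'   `x_seq`; kept separate so ablation of the sequence view does not
#'   blind the graph)
#' @return Probability that the center site is methylated.
#' @export
nm_forward <- function(x_seq, x_chem, x_str, params, config,
                       x_node = x_seq) {
  vecs <- list()
  if (config$use_seq) {
    xs2 <- cnn_branch(x_seq, params$conv_seq_W, params$conv_seq_b,
                      params$fc_seq_W, params$fc_seq_b, config)
  }
  if (config$use_chem) {
    vec_chem <- cnn_branch(x_chem, params$conv_chem_W, params$conv_chem_b,
                           params$fc_chem_W, params$fc_chem_b, config)
  }
  if (config$use_str) {
    xstr2 <- gat_branch(x_str, x_node, params, config)
  }
  for (part in head_parts(config)) {
    vecs[[part]] <- switch(part,
      fused = {
        O <- cross_attention(matrix(xs2, nrow = 1), xstr2,
                             params$wq, params$wk, params$wv)
        colMeans(O)  # mean over the (single) query axis
      },
      seq = xs2,
      chem = vec_chem,
      str_flat = as.vector(xstr2)  # column-major, position-preserving
    )
  }
  h <- unlist(vecs, use.names = FALSE)
  hid <- relu(drop(crossprod(params$fc1_W, h)) + params$fc1_b)
  logit <- sum(params$fc2_W * hid) + params$fc2_b
  unname(sigmoid(logit))
}
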