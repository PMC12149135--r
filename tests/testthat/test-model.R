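cfg_default <- nm_config()

test_that("CNN branch has the contracted output and handles zero input", {
  cfg <- nm_config(n_kernels = 4, embed_dim = 6)
  for (L in c(3, 10, 51)) {
    set.seed(1)
    convW <- matrix(rnorm(3 * 4 * 4), 12, 4)
    fcW <- matrix(rnorm((L %/% 2) * 4 * 6), (L %/% 2) * 4, 6)
    out <- cnn_branch(matrix(0, L, 4), convW, numeric(4), fcW,
                      numeric(6), cfg)
    expect_length(out, 6)
    # zero input, zero biases -> zero output
    expect_equal(unname(out), rep(0, 6))
  }
})

test_that("an identity-like filter localises an impulse through pooling", {
  # L = 6, one channel-0 detector kernel (center tap only), one kernel
  cfg <- nm_config(n_kernels = 1, embed_dim = 3, kernel_size = 3)
  convW <- matrix(0, 12, 1)  # rows: tap-major blocks of the 4 channels
  convW[5, 1] <- 1           # center tap, channel 1 (A)
  x <- matrix(0, 6, 4)
  x[5, 1] <- 1               # impulse at position 5
  fcW <- diag(3)          # pool length 3 -> embed 3, identity readout
  out <- cnn_branch(x, convW, numeric(1), fcW, numeric(3), cfg)
  # hand convolution: response 1 at position 5 only; pooling windows
  # (1,2), (3,4), (5,6) -> third pooled cell carries it
  expect_equal(unname(out), c(0, 0, 1))
})

test_that("graph attention handles degenerate neighbourhoods exactly", {
  cfg <- nm_config(n_heads = 1)
  set.seed(2)
  W <- array(rnorm(3 * 4), dim = c(3, 4, 1))
  a_src <- matrix(rnorm(4), 4, 1)
  a_dst <- matrix(rnorm(4), 4, 1)
  # single node, self-loop only: softmax over one element -> alpha = 1
  h <- matrix(rnorm(3), 1, 3)
  out <- gat_layer(h, cbind(1L, 1L), W, a_src, a_dst, cfg)
  manual <- h %*% W[, , 1]
  expect_equal(unname(unclass(out)), unname(ifelse(manual > 0, manual,
                                                   expm1(manual))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(out, "attention")[[1]][1, 1], 1)
  # two nodes, complete graph, identical features -> uniform attention
  h2 <- rbind(h, h)
  edges <- as.matrix(expand.grid(1:2, 1:2))
  out2 <- gat_layer(h2, edges, W, a_src, a_dst, cfg)
  A <- attr(out2, "attention")[[1]]
  expect_equal(A[!is.na(A)], rep(0.5, 4), ignore_attr = TRUE)
  # empty neighbourhood is a contract violation
  expect_error(gat_layer(h2, cbind(1L, 1L), W, a_src, a_dst, cfg),
               "self-loops")
})

test_that("graph attention equals the brute-force oracle on random graphs", {
  set.seed(7)
  for (rep in 1:20) {
    N <- 5
    n_heads <- sample(1:3, 1)
    Fin <- sample(2:4, 1)
    Fp <- sample(3:6, 1)
    cfg <- nm_config(n_heads = n_heads)
    W <- array(rnorm(Fin * Fp * n_heads), dim = c(Fin, Fp, n_heads))
    a_src <- matrix(rnorm(Fp * n_heads), Fp, n_heads)
    a_dst <- matrix(rnorm(Fp * n_heads), Fp, n_heads)
    H <- matrix(rnorm(N * Fin), N, Fin)
    # random symmetric adjacency plus guaranteed self-loops
    adj <- matrix(stats::runif(N * N) < 0.4, N, N)
    adj <- adj | t(adj); diag(adj) <- TRUE
    edges <- which(adj, arr.ind = TRUE)
    got <- gat_layer(H, edges, W, a_src, a_dst, cfg)
    want <- oracle_gat(H, edges, W, a_src, a_dst, cfg$leaky_slope)
    expect_equal(unclass(got), want, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("GAT attention rows sum to one on randomized inputs", {
  set.seed(17)
  for (rep in 1:10) {
    w <- simulate_nm(n_per_class = 1, seed = rep, struct_signal = 1)
    enc <- encode_windows(w)
    set.seed(rep); p <- nm_init_params(cfg_default, 51)
    edges <- nmview:::structure_edges(enc$x_str[, , 1])
    out <- gat_layer(enc$x_seq[, , 1], edges, p$gat1_W, p$gat1_asrc,
                     p$gat1_adst, cfg_default)
    for (A in attr(out, "attention")) {
      expect_equal(rowSums(A, na.rm = TRUE), rep(1, 51),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("the structure branch respects the graph contracts", {
  set.seed(23)
  p <- nm_init_params(cfg_default, 11)
  node <- encode_onehot(random_rna(11))
  # no pairs: path graph with self-loops, finite output of the right shape
  out <- gat_branch(matrix(0, 11, 11), node, p, cfg_default)
  expect_equal(dim(out), c(11, 64))
  expect_true(all(is.finite(out)))
  # paired nodes place positive attention on the pair edge
  db <- "((....)).."
  xs <- pairs_to_matrix(parse_dotbracket(paste0(db, ".")), 11)
  edges <- nmview:::structure_edges(xs)
  l1 <- gat_layer(node, edges, p$gat1_W, p$gat1_asrc, p$gat1_adst,
                  cfg_default)
  A <- attr(l1, "attention")[[1]]
  expect_gt(A[1, 8], 0)  # pair (0,7) in 0-based coordinates
  expect_error(gat_branch(matrix(c(0, 1, 0, 0), 2, 2), node[1:2, ], p,
                          cfg_default), "symmetric")
})

test_that("graph attention is permutation-equivariant", {
  set.seed(29)
  cfg <- nm_config(n_heads = 2)
  N <- 7; Fin <- 4; Fp <- 5
  W <- array(rnorm(Fin * Fp * 2), dim = c(Fin, Fp, 2))
  a_src <- matrix(rnorm(Fp * 2), Fp, 2)
  a_dst <- matrix(rnorm(Fp * 2), Fp, 2)
  H <- matrix(rnorm(N * Fin), N, Fin)
  adj <- matrix(stats::runif(N * N) < 0.4, N, N)
  adj <- adj | t(adj); diag(adj) <- TRUE
  edges <- which(adj, arr.ind = TRUE)
  out <- gat_layer(H, edges, W, a_src, a_dst, cfg)
  perm <- sample(N)
  inv <- order(perm)
  edges_p <- cbind(inv[edges[, 1]], inv[edges[, 2]])
  out_p <- gat_layer(H[perm, ], edges_p, W, a_src, a_dst, cfg)
  expect_equal(unclass(out_p), unclass(out)[perm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("cross-attention reduces to closed forms in degenerate cases", {
  set.seed(31)
  wq <- matrix(rnorm(16), 4, 4); wk <- matrix(rnorm(16), 4, 4)
  wv <- matrix(rnorm(16), 4, 4)
  xq <- matrix(rnorm(8), 2, 4)
  # single key: O is V's single row regardless of the queries
  xk <- matrix(rnorm(4), 1, 4)
  O <- cross_attention(xq, xk, wq, wk, wv)
  expect_equal(unclass(O)[1, ], unclass(O)[2, ], ignore_attr = TRUE)
  expect_equal(unname(unclass(O)[1, ]), unname(drop(xk %*% wv)))
  O2 <- cross_attention(xq * 3 - 1, xk, wq, wk, wv)
  expect_equal(unclass(O), unclass(O2), ignore_attr = TRUE)
  # identical keys: uniform attention
  xk5 <- matrix(rep(rnorm(4), each = 5), 5, 4)
  O3 <- cross_attention(xq, xk5, wq, wk, wv)
  expect_equal(attr(O3, "attention"),
               matrix(0.2, 2, 5), ignore_attr = TRUE)
})

test_that("cross-attention equals hand matrix algebra on random inputs", {
  set.seed(37)
  for (rep in 1:5) {
    xq <- matrix(rnorm(12), 3, 4)
    xk <- matrix(rnorm(20), 5, 4)
    wq <- matrix(rnorm(16), 4, 4); wk <- matrix(rnorm(16), 4, 4)
    wv <- matrix(rnorm(16), 4, 4)
    got <- cross_attention(xq, xk, wq, wk, wv)
    Q <- xq %*% wq; K <- xk %*% wk; V <- xk %*% wv
    S <- Q %*% t(K) / sqrt(4)
    A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
    expect_equal(unclass(got), A %*% V, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rowSums(attr(got, "attention")), rep(1, 3),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("binary cross-entropy matches closed forms", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce_loss(rep(0.5, 10), rep_len(c(0, 1), 10)), log(2))
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)))
  expect_error(bce_loss(c(0.5), c(1, 0)), "length")
})

test_that("forward pass is deterministic, strictly inside (0,1)", {
  enc <- make_tiny_encoded()
  set.seed(5); p <- nm_init_params(cfg_default, 51)
  p1 <- nm_forward(enc$x_seq[, , 1], enc$x_chem[, , 1], enc$x_str[, , 1],
                   p, cfg_default)
  p2 <- nm_forward(enc$x_seq[, , 1], enc$x_chem[, , 1], enc$x_str[, , 1],
                   p, cfg_default)
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lt(p1, 1)
})

test_that("disabling a view makes the forward pass invariant to it", {
  enc <- make_tiny_encoded()
  xs <- enc$x_seq[, , 1]; xc <- enc$x_chem[, , 1]; xt <- enc$x_str[, , 1]
  node <- enc$x_node[, , 1]
  alt_str <- enc$x_str[, , 2]
  alt_seq <- enc$x_seq[, , 3]
  alt_chem <- enc$x_chem[, , 3]
  combos <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                 c(FALSE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
                 c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE))
  for (v in combos) {
    cfg <- nm_config(use_seq = v[1], use_chem = v[2], use_str = v[3])
    set.seed(6); p <- nm_init_params(cfg, 51)
    base <- nm_forward(xs, xc, xt, p, cfg, x_node = node)
    if (!v[1]) {
      expect_equal(nm_forward(alt_seq, xc, xt, p, cfg, x_node = node), base)
    }
    if (!v[2]) {
      expect_equal(nm_forward(xs, alt_chem, xt, p, cfg, x_node = node), base)
    }
    if (!v[3]) {
      expect_equal(nm_forward(xs, xc, alt_str, p, cfg, x_node = node), base)
    }
  }
  expect_error(nm_config(use_seq = FALSE, use_chem = FALSE,
                         use_str = FALSE), "at least one")
})

test_that("the sequence-only configuration is a plain CNN classifier", {
  enc <- make_tiny_encoded()
  cfg <- nm_config(use_seq = TRUE, use_chem = FALSE, use_str = FALSE)
  set.seed(8); p <- nm_init_params(cfg, 51)
  got <- nm_forward(enc$x_seq[, , 1], enc$x_chem[, , 1], enc$x_str[, , 1],
                    p, cfg)
  # by hand: CNN branch -> FC head, nothing else
  v <- cnn_branch(enc$x_seq[, , 1], p$conv_seq_W, p$conv_seq_b,
                  p$fc_seq_W, p$fc_seq_b, cfg)
  hid <- pmax(drop(crossprod(p$fc1_W, v)) + p$fc1_b, 0)
  want <- 1 / (1 + exp(-(sum(p$fc2_W * hid) + p$fc2_b)))
  expect_equal(got, unname(want))
})

test_that("compiled and reference forward passes agree across all view configs", {
  enc <- make_tiny_encoded()
  n <- length(enc$label)
  for (i in seq_len(nrow(nmview:::ABLATION_GRID))) {
    g <- nmview:::ABLATION_GRID[i, ]
    cfg <- nm_config(use_seq = g$use_seq, use_chem = g$use_chem,
                     use_str = g$use_str)
    set.seed(40 + i); p <- nm_init_params(cfg, 51)
    fast <- nmview:::cpp_predict_probs(enc$x_seq, enc$x_chem, enc$x_str,
                                       enc$x_node, p,
                                       nmview:::config_for_cpp(cfg))
    slow <- vapply(seq_len(n), function(s) {
      nm_forward(enc$x_seq[, , s], enc$x_chem[, , s], enc$x_str[, , s],
                 p, cfg, x_node = enc$x_node[, , s])
    }, numeric(1))
    expect_equal(as.numeric(fast), slow, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  enc <- make_tiny_encoded(4, seed = 77)
  cfg <- cfg_default
  set.seed(50); p <- nm_init_params(cfg, 51)
  cfgc <- nmview:::config_for_cpp(cfg)
  lossf <- function(pp) {
    nmview:::cpp_batch_grad(enc$x_seq, enc$x_chem, enc$x_str, enc$x_node,
                            enc$label, pp, cfgc, FALSE)$loss
  }
  res <- nmview:::cpp_batch_grad(enc$x_seq, enc$x_chem, enc$x_str,
                                 enc$x_node, enc$label, p, cfgc, FALSE)
  set.seed(51)
  eps <- 1e-4
  checked <- 0
  while (checked < 10) {
    nm <- sample(names(p), 1)
    j <- sample(length(p[[nm]]), 1)
    an <- res$grads[[nm]][j]
    if (abs(an) < 1e-7) next  # skip numerically dead coordinates
    pp <- p
    pp[[nm]][j] <- pp[[nm]][j] + eps
    up <- lossf(pp)
    pp[[nm]][j] <- pp[[nm]][j] - 2 * eps
    dn <- lossf(pp)
    fd <- (up - dn) / (2 * eps)
    expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
    checked <- checked + 1
  }
})
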