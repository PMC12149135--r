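# Independent oracles used to cross-check the implementation. These are
# deliberately written in the most literal way possible (explicit loops,
# memoised recursion) and share no code with the package internals.

# Brute-force multi-head graph attention layer: per head k,
# e_ij = LeakyReLU(a^T [W_k h_i || W_k h_j]) over j in N(i),
# alpha = softmax over the neighbourhood, output = ELU of the head-mean
# of sum_j alpha_ij W_k h_j.
oracle_gat <- function(H, edges, W, a_src, a_dst, leaky_slope = 0.2) {
  N <- nrow(H)
  n_heads <- dim(W)[3]
  Fp <- dim(W)[2]
  acc <- matrix(0, N, Fp)
  for (h in seq_len(n_heads)) {
    Wh <- H %*% W[, , h]
    for (i in seq_len(N)) {
      nbr <- edges[edges[, 1] == i, 2]
      e <- numeric(length(nbr))
      for (t in seq_along(nbr)) {
        j <- nbr[t]
        concat <- c(Wh[i, ], Wh[j, ])
        raw <- sum(c(a_src[, h], a_dst[, h]) * concat)
        e[t] <- if (raw > 0) raw else leaky_slope * raw
      }
      alpha <- exp(e - max(e))
      alpha <- alpha / sum(alpha)
      for (t in seq_along(nbr)) {
        acc[i, ] <- acc[i, ] + alpha[t] * Wh[nbr[t], ] / n_heads
      }
    }
  }
  ifelse(acc > 0, acc, exp(pmin(acc, 0)) - 1)
}

# Memoised recursive maximum base-pairing count (Nussinov objective).
oracle_max_pairs <- function(bases, min_loop = 3) {
  chars <- strsplit(bases, "")[[1]]
  L <- length(chars)
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(chars[i], chars[k])) {
        best <- max(best, rec(i + 1L, k - 1L) + 1L + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  if (L < min_loop + 2) 0L else rec(1L, L)
}

# Rank-based AUC: Mann-Whitney U / (n_pos * n_neg) with average ranks,
# i.e. P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc_mw <- function(probs, labels) {
  r <- rank(probs)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Random balanced dot-bracket string (nested, possibly with unpaired
# positions) of length L.
random_dotbracket <- function(L) {
  out <- character(0)
  depth <- 0
  for (i in seq_len(L)) {
    remaining <- L - i + 1
    if (depth >= remaining) {
      out <- c(out, ")")
      depth <- depth - 1
    } else {
      ch <- sample(c("(", ")", "."), 1, prob = c(0.3, 0.3, 0.4))
      if (ch == ")" && depth == 0) ch <- "."
      if (ch == "(") depth <- depth + 1
      if (ch == ")") depth <- depth - 1
      out <- c(out, ch)
    }
  }
  # unmatched opening brackets become dots
  stack <- integer(0)
  for (i in seq_along(out)) {
    if (out[i] == "(") stack <- c(stack, i)
    if (out[i] == ")") stack <- stack[-length(stack)]
  }
  out[stack] <- "."
  paste(out, collapse = "")
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# small encoded dataset shared by model-level tests
make_tiny_encoded <- function(n_per_class = 6, seed = 402) {
  encode_windows(simulate_nm(n_per_class = n_per_class, seed = seed,
                             struct_signal = 0.5))
}
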