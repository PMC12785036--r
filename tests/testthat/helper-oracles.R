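# Independent oracles used across tests.

# Naive dense-attention encoder forward, written position-by-position with
# no masking; the oracle for local-attention equivalence on inputs short
# enough that the sliding window covers every pair.
dense_forward_oracle <- function(params, cfg, ids) {
  L <- length(ids)
  d <- cfg$embedding_dim
  nh <- cfg$num_attention_heads
  dh <- d / nh
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  pe <- matrix(0, L, d)
  for (pos in 0:(L - 1)) {
    for (i2 in seq(0, d - 2, by = 2)) {
      pe[pos + 1, i2 + 1] <- sin(pos / 10000^(i2 / d))
      pe[pos + 1, i2 + 2] <- cos(pos / 10000^(i2 / d))
    }
  }
  H <- params$tok_emb[ids + 1, , drop = FALSE] + pe
  for (l in seq_len(cfg$num_hidden_layers)) {
    p <- function(nm) params[[paste0("l", l, "_", nm)]]
    x1 <- ln(H, p("ln1_g"), p("ln1_b"))
    Q <- sweep(x1 %*% p("Wq"), 2, p("bq"), "+")
    K <- sweep(x1 %*% p("Wk"), 2, p("bk"), "+")
    V <- sweep(x1 %*% p("Wv"), 2, p("bv"), "+")
    O <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      for (i in seq_len(L)) {
        scores <- sapply(seq_len(L), function(j) {
          sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
        })
        a <- exp(scores - max(scores))
        a <- a / sum(a)
        O[i, cols] <- colSums(a * V[, cols, drop = FALSE])
      }
    }
    H <- H + sweep(O %*% p("Wo"), 2, p("bo"), "+")
    x2 <- ln(H, p("ln2_g"), p("ln2_b"))
    Z1 <- sweep(x2 %*% p("W1"), 2, p("b1"), "+")
    G <- Z1 * pnorm(Z1)
    H <- H + sweep(G %*% p("W2"), 2, p("b2"), "+")
  }
  Hf <- ln(H, params$lnf_g, params$lnf_b)
  drop(Hf[1, ] %*% params$head_W) + params$head_b
}

# Brute-force per-class metrics computed directly from label pairs, the
# oracle for the confusion-matrix path.
brute_force_metrics <- function(true, pred, classes) {
  t(sapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
  }))
}

# small helper: random DNA string
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# tiny model builder shared by model/trainer tests
tiny_model <- function(num_classes = 3, dim = 8, layers = 2, heads = 2,
                       window = 4, globals = 0L, seed = 7,
                       max_embeddings = 64, dropout = 0) {
  build_model(model_config(
    num_classes = num_classes, kmer_size = 5L, embedding_dim = dim,
    num_hidden_layers = layers, num_attention_heads = heads,
    intermediate_size = 2 * dim, max_embeddings = max_embeddings,
    local_attention_window = window, global_att_tokens = globals,
    dropout = dropout, seed = seed))
}

# Table 4 printed per-class values: the fixed inputs for the metric-formula
# checks (Group, Precision, Recall, F1, Support)
table4 <- data.frame(
  group = c("Copia", "Crypton", "ERV", "Gypsy", "hAT", "Helitron", "Jockey",
            "L1/L2", "Maverick", "Merlin", "P", "Pao", "RTE", "SINE",
            "TcMar", "Transib"),
  precision = c(0.69, 0.62, 0.86, 0.81, 0.84, 0.72, 0.61, 0.89, 0.56, 0.64,
                0.35, 0.71, 0.76, 0.76, 0.76, 0.67),
  recall = c(0.60, 0.69, 0.91, 0.71, 0.82, 0.81, 0.71, 0.80, 0.64, 0.70,
             0.60, 0.70, 0.78, 0.80, 0.77, 0.75),
  f1 = c(0.64, 0.65, 0.88, 0.76, 0.83, 0.76, 0.66, 0.84, 0.60, 0.67, 0.44,
         0.70, 0.77, 0.78, 0.76, 0.71),
  support = c(3716, 1090, 12318, 15934, 22941, 9796, 2840, 22741, 1443, 594,
              938, 4438, 8700, 6391, 17385, 855))
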