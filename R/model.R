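#' Encoder model configuration
#'
#' Hyperparameters of the encoder-only transformer. Defaults follow the
#' full-scale configuration (8 layers, 8 heads, 2048-token embedding budget,
#' global attention at positions 0/256/512, feed-forward width 3078,
#' 5-mers); `embedding_dim` and `local_attention_window` default to 256.
#' Global-attention positions are 0-based token coordinates in the
#' CLS-prefixed chunk (so position 0 is the CLS anchor itself); positions
#' beyond a chunk's length are ignored for that chunk.
#'
#' @param num_classes Number of output classes (default 16).
#' @param kmer_size k-mer length (default 5).
#' @param embedding_dim Token embedding width; divisible by
#'   `num_attention_heads`.
#' @param num_hidden_layers Encoder layers (default 8).
#' @param num_attention_heads Attention heads per layer (default 8).
#' @param intermediate_size Feed-forward hidden width (default 3078).
#' @param max_embeddings Maximum tokens per chunk including CLS
#'   (default 2048).
#' @param local_attention_window Even sliding-window width w; token i
#'   attends token j iff |i - j| <= w/2, unless either is global.
#' @param global_att_tokens Integer vector of 0-based global-attention
#'   positions (default c(0, 256, 512)).
#' @param dropout Dropout probability applied to each sub-layer output
#'   during training (default 0.1).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_classes = 16L, kmer_size = 5L,
                         embedding_dim = 256L, num_hidden_layers = 8L,
                         num_attention_heads = 8L,
                         intermediate_size = 3078L,
                         max_embeddings = 2048L,
                         local_attention_window = 256L,
                         global_att_tokens = c(0L, 256L, 512L),
                         dropout = 0.1, seed = 1L) {
  if (embedding_dim %% num_attention_heads != 0L) {
    stop("embedding_dim must be divisible by num_attention_heads")
  }
  if (local_attention_window %% 2L != 0L || local_attention_window < 2L) {
    stop("local_attention_window must be even and >= 2")
  }
  if (any(global_att_tokens >= max_embeddings)) {
    stop("global attention positions must be < max_embeddings")
  }
  if (kmer_size <= 2L) stop("kmer_size must be at least 3")
  structure(list(num_classes = as.integer(num_classes),
                 kmer_size = as.integer(kmer_size),
                 vocab_size = 5L^as.integer(kmer_size) + 3L,
                 embedding_dim = as.integer(embedding_dim),
                 num_hidden_layers = as.integer(num_hidden_layers),
                 num_attention_heads = as.integer(num_attention_heads),
                 intermediate_size = as.integer(intermediate_size),
                 max_embeddings = as.integer(max_embeddings),
                 local_attention_window = as.integer(local_attention_window),
                 global_att_tokens = as.integer(global_att_tokens),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Sinusoidal positional encoding
#'
#' The standard fixed encoding added to token embeddings:
#' `PE[pos, 2i] = sin(pos / 10000^(2i/dim))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/dim))` (positions and `i` 0-based).
#' Values lie in \[-1, 1\] and carry absolute token-position information
#' independent of the input length.
#'
#' @param length Number of positions.
#' @param dim Embedding dimension (even).
#' @return `length` x `dim` numeric matrix.
#' @export
positional_encoding <- function(length, dim) {
  if (dim %% 2L != 0L) stop("dim must be even")
  pos <- 0:(length - 1L)
  i2 <- seq(0L, dim - 2L, by = 2L)          # the 2i exponents
  freq <- 1 / 10000^(i2 / dim)
  ang <- outer(pos, freq)                   # length x dim/2
  pe <- matrix(0, length, dim)
  pe[, i2 + 1L] <- sin(ang)
  pe[, i2 + 2L] <- cos(ang)
  pe
}

#' Numerically stable softmax
#'
#' @param logits Finite numeric vector.
#' @return Probability vector summing to 1.
#' @examples
#' softmax(c(log(2), 0))  # 2/3, 1/3
#' @export
softmax <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# truncated normal init (sigma = 0.02, truncated at 2 sigma)
.trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

#' Build an encoder model with seeded random initialization
#'
#' Weight matrices are truncated-normal (sd 0.02), biases zero, layer-norm
#' gains one. Initialization is fully determined by `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `te_encoder`: list with `config` and `params`
#'   (flat named list of matrices/vectors).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$embedding_dim
  m <- config$intermediate_size
  V <- config$vocab_size
  C <- config$num_classes
  params <- list()
  with_local_seed(config$seed, {
    params[["tok_emb"]] <- matrix(.trunc_normal(V * d), V, d)
    for (l in seq_len(config$num_hidden_layers)) {
      p <- function(nm) paste0("l", l, "_", nm)
      params[[p("Wq")]] <- matrix(.trunc_normal(d * d), d, d)
      params[[p("Wk")]] <- matrix(.trunc_normal(d * d), d, d)
      params[[p("Wv")]] <- matrix(.trunc_normal(d * d), d, d)
      params[[p("Wo")]] <- matrix(.trunc_normal(d * d), d, d)
      params[[p("bq")]] <- numeric(d)
      params[[p("bk")]] <- numeric(d)
      params[[p("bv")]] <- numeric(d)
      params[[p("bo")]] <- numeric(d)
      params[[p("ln1_g")]] <- rep(1, d)
      params[[p("ln1_b")]] <- numeric(d)
      params[[p("ln2_g")]] <- rep(1, d)
      params[[p("ln2_b")]] <- numeric(d)
      params[[p("W1")]] <- matrix(.trunc_normal(d * m), d, m)
      params[[p("b1")]] <- numeric(m)
      params[[p("W2")]] <- matrix(.trunc_normal(m * d), m, d)
      params[[p("b2")]] <- numeric(d)
    }
    params[["lnf_g"]] <- rep(1, d)
    params[["lnf_b"]] <- numeric(d)
    params[["head_W"]] <- matrix(.trunc_normal(d * C), d, C)
    params[["head_b"]] <- numeric(C)
  })
  structure(list(config = config, params = params), class = "te_encoder")
}

#' Local + global attention mask
#'
#' Boolean L x L matrix of allowed attention pairs: token i may attend
#' token j iff |i - j| <= window/2, or i or j is one of the designated
#' global positions (which attend to, and are attended by, every token).
#'
#' @param length Number of tokens in the chunk.
#' @param window Even local attention window width.
#' @param global_positions 0-based global token positions (positions beyond
#'   `length` are ignored).
#' @return Logical `length` x `length` matrix.
#' @export
attention_mask <- function(length, window, global_positions = integer()) {
  idx <- seq_len(length)
  allowed <- abs(outer(idx, idx, "-")) <= window / 2
  g <- global_positions[global_positions < length] + 1L
  if (length(g) > 0) {
    allowed[g, ] <- TRUE
    allowed[, g] <- TRUE
  }
  allowed
}

# row-wise softmax with -Inf masking; exp(-Inf) = 0 handles masked cells
.row_softmax <- function(S) {
  L <- nrow(S)
  m <- S[cbind(seq_len(L), max.col(S, ties.method = "first"))]
  P <- exp(S - m)
  P / rowSums(P)
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# layer norm over the feature dimension, with cache for backprop
.layernorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' Forward pass of the encoder on one token chunk
#'
#' Token embeddings plus sinusoidal positional encodings pass through the
#' stack of pre-norm encoder layers (multi-head attention restricted by the
#' local/global mask, then a GELU feed-forward block, each wrapped in a
#' residual connection), a final layer norm, and the linear classification
#' head applied to the CLS position. PAD positions are excluded from
#' attention entirely.
#'
#' @param model A `te_encoder`.
#' @param chunk A `token_chunk` (or a bare integer vector of 0-based token
#'   ids whose first element is the CLS id).
#' @param train If TRUE, dropout is applied (drawing from the global RNG)
#'   and intermediate activations are cached for the backward pass.
#' @param return_attention If TRUE, the per-layer, per-head attention
#'   matrices are returned.
#' @return List with `logits` (length `num_classes`), `probs` (softmax of
#'   logits), and optionally `cache` / `attention`.
#' @export
model_forward <- function(model, chunk, train = FALSE,
                          return_attention = FALSE) {
  cfg <- model$config
  par <- model$params
  ids <- if (inherits(chunk, "token_chunk")) chunk$ids[seq_len(chunk$n)] else as.integer(chunk)
  L <- length(ids)
  if (L > cfg$max_embeddings) stop("chunk longer than max_embeddings")
  d <- cfg$embedding_dim
  nh <- cfg$num_attention_heads
  dh <- d %/% nh
  H <- par$tok_emb[ids + 1L, , drop = FALSE] + positional_encoding(L, d)
  allowed <- attention_mask(L, cfg$local_attention_window,
                            cfg$global_att_tokens)
  maskM <- matrix(0, L, L)
  maskM[!allowed] <- -Inf
  p_drop <- if (train) cfg$dropout else 0
  cache <- if (train) list(ids = ids, L = L) else NULL
  attn_out_all <- if (return_attention) vector("list", cfg$num_hidden_layers) else NULL

  for (l in seq_len(cfg$num_hidden_layers)) {
    p <- function(nm) paste0("l", l, "_", nm)
    H_in <- H
    ln1 <- .layernorm(H, par[[p("ln1_g")]], par[[p("ln1_b")]])
    x1 <- ln1$y
    Q <- .add_bias(x1 %*% par[[p("Wq")]], par[[p("bq")]])
    K <- .add_bias(x1 %*% par[[p("Wk")]], par[[p("bk")]])
    Vv <- .add_bias(x1 %*% par[[p("Wv")]], par[[p("bv")]])
    O <- matrix(0, L, d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
        sqrt(dh) + maskM
      A <- .row_softmax(S)
      A_heads[[h]] <- A
      O[, cols] <- A %*% Vv[, cols, drop = FALSE]
    }
    attn_out <- .add_bias(O %*% par[[p("Wo")]], par[[p("bo")]])
    drop1 <- NULL
    if (p_drop > 0) {
      drop1 <- matrix(stats::rbinom(L * d, 1L, 1 - p_drop), L, d) / (1 - p_drop)
      attn_out <- attn_out * drop1
    }
    H <- H_in + attn_out
    H_mid <- H
    ln2 <- .layernorm(H, par[[p("ln2_g")]], par[[p("ln2_b")]])
    x2 <- ln2$y
    Z1 <- .add_bias(x2 %*% par[[p("W1")]], par[[p("b1")]])
    G <- .gelu(Z1)
    FF <- .add_bias(G %*% par[[p("W2")]], par[[p("b2")]])
    drop2 <- NULL
    if (p_drop > 0) {
      drop2 <- matrix(stats::rbinom(L * d, 1L, 1 - p_drop), L, d) / (1 - p_drop)
      FF <- FF * drop2
    }
    H <- H_mid + FF
    if (train) {
      cache[[paste0("layer", l)]] <- list(
        ln1 = ln1, x1 = x1, Q = Q, K = K, V = Vv, A = A_heads, O = O,
        drop1 = drop1, H_mid = H_mid, ln2 = ln2, x2 = x2, Z1 = Z1, G = G,
        drop2 = drop2)
    }
    if (return_attention) attn_out_all[[l]] <- A_heads
  }
  lnf <- .layernorm(H, par$lnf_g, par$lnf_b)
  cls <- lnf$y[1L, ]
  logits <- drop(cls %*% par$head_W) + par$head_b
  if (train) {
    cache$lnf <- lnf
    cache$cls <- cls
  }
  out <- list(logits = logits, probs = softmax(logits))
  if (train) out$cache <- cache
  if (return_attention) out$attention <- attn_out_all
  out
}

#' Trace token attention back to nucleotides
#'
#' Maps one attention value per k-mer token to a per-nucleotide attention
#' profile over the source sequence by linear interpolation between token
#' midpoints (positions before the first midpoint and after the last take
#' the boundary value). With `renormalize = TRUE` the profile is rescaled so
#' its total mass equals the total token attention.
#'
#' @param token_attention Numeric vector, one value per k-mer token of the
#'   chunk (CLS excluded).
#' @param chunk The `token_chunk` the values belong to.
#' @param renormalize If TRUE, rescale so the nucleotide profile sums to the
#'   token attention total.
#' @return Numeric vector of length `chunk$seq_len`.
#' @export
attention_rollback <- function(token_attention, chunk, renormalize = FALSE) {
  stopifnot(inherits(chunk, "token_chunk"))
  n_tok <- length(chunk$starts)
  if (length(token_attention) != n_tok) {
    stop("need exactly one attention value per k-mer token")
  }
  mids <- chunk$starts + (chunk$k - 1) / 2
  pos <- 0:(chunk$seq_len - 1L)
  out <- if (n_tok == 1L) {
    rep(token_attention, chunk$seq_len)
  } else {
    stats::approx(mids, token_attention, xout = pos, rule = 2)$y
  }
  if (renormalize) {
    total <- sum(token_attention)
    s <- sum(out)
    if (s > 0) out <- out * total / s
  }
  out
}
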