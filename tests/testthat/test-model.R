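test_that("sinusoidal positional encoding has the closed form and range", {
  pe <- positional_encoding(16, 4)
  expect_equal(pe[1, c(1, 3)], c(0, 0))       # sin 0
  expect_equal(pe[1, c(2, 4)], c(1, 1))       # cos 0
  expect_equal(pe[2, 1], sin(1))
  expect_equal(pe[2, 2], cos(1))
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 4)))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 3), "even")
})

test_that("softmax normalizes with the max-shift guard", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(1)
  for (i in 1:10) {
    p <- softmax(rnorm(8, sd = 100))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))  # no overflow
})

test_that("forward produces a probability vector of num_classes entries", {
  m <- tiny_model(num_classes = 5)
  v <- build_vocabulary(5)
  ch <- tokenize(random_dna(60), v, 64)[[1]]
  fw <- model_forward(m, ch)
  expect_length(fw$logits, 5)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  # zero classification head => uniform class probabilities
  m0 <- m
  m0$params$head_W[] <- 0
  m0$params$head_b[] <- 0
  expect_equal(model_forward(m0, ch)$probs, rep(0.2, 5))
})

test_that("compiled forward agrees with the base-R reference engine", {
  v <- build_vocabulary(5)
  set.seed(21)
  for (i in 1:10) {
    m <- tiny_model(num_classes = sample(2:6, 1), dim = 8,
                    layers = sample(1:3, 1), heads = sample(c(1, 2, 4), 1),
                    window = sample(c(4, 8, 64), 1), seed = i)
    ch <- tokenize(random_dna(sample(20:120, 1)), v, 64)[[1]]
    ids <- ch$ids[seq_len(ch$n)]
    r_logits <- model_forward(m, ch)$logits
    c_logits <- wickerformer:::cpp_forward_attention(m$params, m$config,
                                                     ids)$logits
    expect_equal(r_logits, c_logits, tolerance = 1e-10)
  }
})

test_that("local attention equals dense attention when the window covers the input", {
  v <- build_vocabulary(5)
  set.seed(31)
  for (i in 1:20) {
    L_target <- sample(5:12, 1)
    # window >= 2L makes every pair local; oracle has no mask at all
    m <- tiny_model(num_classes = 3, dim = 8, layers = 2, heads = 2,
                    window = 64, globals = integer(0), seed = 100 + i)
    s <- random_dna(2 * L_target + 3)
    ch <- tokenize(s, v, 64)[[1]]
    ids <- ch$ids[seq_len(ch$n)]
    oracle <- dense_forward_oracle(m$params, m$config, ids)
    via_cpp <- wickerformer:::cpp_forward_attention(m$params, m$config,
                                                    ids)$logits
    expect_equal(via_cpp, oracle, tolerance = 1e-8)
    expect_equal(model_forward(m, ch)$logits, oracle, tolerance = 1e-8)
  }
})

test_that("attention is exactly zero outside the local window", {
  expect_true(all(diag(attention_mask(10, 4))))
  am <- attention_mask(10, 4, integer(0))
  expect_false(am[1, 4])   # |i-j| = 3 > w/2 = 2
  expect_true(am[1, 3])
  g <- attention_mask(10, 4, global_positions = 7L)
  expect_true(all(g[8, ]) && all(g[, 8]))

  m <- tiny_model(num_classes = 3, dim = 8, layers = 2, heads = 2,
                  window = 4, globals = integer(0))
  v <- build_vocabulary(5)
  ch <- tokenize(random_dna(50), v, 64)[[1]]
  ids <- ch$ids[seq_len(ch$n)]
  fw <- wickerformer:::cpp_forward_attention(m$params, m$config, ids)
  L <- length(ids)
  far <- abs(outer(seq_len(L), seq_len(L), "-")) > 2
  for (l in seq_along(fw$attention)) {
    for (A in fw$attention[[l]]) {
      expect_true(all(A[far] == 0))
      expect_equal(rowSums(A), rep(1, L), tolerance = 1e-9)
    }
  }
})

test_that("positional encoding makes the model order-sensitive", {
  m <- tiny_model(num_classes = 3, dim = 8, window = 64)
  v <- build_vocabulary(5)
  ch <- tokenize("ACGTACGTTTGCAACGTACGAATTGGCC", v, 64)[[1]]
  ids <- ch$ids[seq_len(ch$n)]
  set.seed(2)
  perm <- c(ids[1], sample(ids[-1]))
  l1 <- model_forward(m, ids)$logits
  l2 <- model_forward(m, perm)$logits
  expect_gt(max(abs(l1 - l2)), 1e-8)
})

test_that("initialization and forward are deterministic given the seed", {
  m1 <- tiny_model(seed = 33)
  m2 <- tiny_model(seed = 33)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 34)
  expect_false(identical(m1$params, m3$params))
  v <- build_vocabulary(5)
  ch <- tokenize(random_dna(40), v, 64)[[1]]
  expect_identical(model_forward(m1, ch)$logits,
                   model_forward(m1, ch)$logits)
})

test_that("analytic gradients match central finite differences", {
  v <- build_vocabulary(5)
  set.seed(44)
  m <- tiny_model(num_classes = 3, dim = 8, layers = 2, heads = 2,
                  window = 4, globals = 0L, seed = 7)
  ch <- tokenize(random_dna(30), v, 32)[[1]]
  ids <- ch$ids[seq_len(ch$n)]
  y <- 2L
  bg <- wickerformer:::cpp_batch_grad(m$params, m$config, list(ids),
                                      y - 1L, 1.0)
  loss_at <- function(params) {
    p <- wickerformer:::cpp_predict_probs(params, m$config, list(ids))
    -log(p[1, y])
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    g <- bg$grads[[nm]]
    idx <- which(abs(g) == max(abs(g)))[1]
    p2 <- m$params; p2[[nm]][idx] <- p2[[nm]][idx] + eps; up <- loss_at(p2)
    p2 <- m$params; p2[[nm]][idx] <- p2[[nm]][idx] - eps; dn <- loss_at(p2)
    num <- (up - dn) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("attention rollback interpolates token values onto nucleotides", {
  v <- build_vocabulary(5)
  ch <- tokenize("ACGTACGTACGTA", v, 64)[[1]]  # starts 0,2,4,6,8; k 5
  n_tok <- length(ch$starts)
  # uniform token attention stays uniform per nucleotide
  u <- attention_rollback(rep(0.2, n_tok), ch)
  expect_length(u, 13)
  expect_true(all(abs(u - 0.2) < 1e-12))
  # a single token spreads its value over all covered positions
  one <- tokenize("AAAAA", v, 64)[[1]]
  expect_equal(attention_rollback(0.7, one), rep(0.7, 5))
  # two tokens 0 and 1 at step 2: linear ramp between midpoints 2 and 4
  two <- tokenize("ACGTACG", v, 64)[[1]]
  out <- attention_rollback(c(0, 1), two)
  expect_equal(out, c(0, 0, 0, 0.5, 1, 1, 1))
  # renormalized profile preserves total token attention mass
  set.seed(3)
  a <- runif(n_tok)
  out2 <- attention_rollback(a, ch, renormalize = TRUE)
  expect_equal(sum(out2), sum(a), tolerance = 1e-6)
})
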