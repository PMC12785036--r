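# Analytic backward pass through the encoder, mirroring model_forward().
# Verified against central finite differences in the test suite.

# layer norm backward; cache from .layernorm
.layernorm_backward <- function(dy, cache, g) {
  L <- nrow(dy)
  dxhat <- dy * rep(g, each = L)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx,
       dg = colSums(dy * cache$xhat),
       db = colSums(dy))
}

# gradient of all parameters for a single chunk given d(loss)/d(logits)
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  par <- model$params
  L <- cache$L
  d <- cfg$embedding_dim
  nh <- cfg$num_attention_heads
  dh <- d %/% nh
  grads <- list()

  grads$head_W <- outer(cache$cls, dlogits)
  grads$head_b <- dlogits
  dcls <- drop(par$head_W %*% dlogits)
  dHf <- matrix(0, L, d)
  dHf[1L, ] <- dcls
  lb <- .layernorm_backward(dHf, cache$lnf, par$lnf_g)
  dH <- lb$dx
  grads$lnf_g <- lb$dg
  grads$lnf_b <- lb$db

  for (l in rev(seq_len(cfg$num_hidden_layers))) {
    p <- function(nm) paste0("l", l, "_", nm)
    cc <- cache[[paste0("layer", l)]]

    # feed-forward block: H = H_mid + drop2 * FF(x2), x2 = LN2(H_mid)
    dFF <- if (is.null(cc$drop2)) dH else dH * cc$drop2
    dG <- tcrossprod(dFF, par[[p("W2")]])
    grads[[p("W2")]] <- crossprod(cc$G, dFF)
    grads[[p("b2")]] <- colSums(dFF)
    dZ1 <- dG * .gelu_grad(cc$Z1)
    grads[[p("W1")]] <- crossprod(cc$x2, dZ1)
    grads[[p("b1")]] <- colSums(dZ1)
    dx2 <- tcrossprod(dZ1, par[[p("W1")]])
    lb <- .layernorm_backward(dx2, cc$ln2, par[[p("ln2_g")]])
    grads[[p("ln2_g")]] <- lb$dg
    grads[[p("ln2_b")]] <- lb$db
    dH <- dH + lb$dx            # gradient w.r.t. H_mid

    # attention block: H_mid = H_in + drop1 * (O Wo + bo), O from x1 = LN1(H_in)
    dattn <- if (is.null(cc$drop1)) dH else dH * cc$drop1
    dO <- tcrossprod(dattn, par[[p("Wo")]])
    grads[[p("Wo")]] <- crossprod(cc$O, dattn)
    grads[[p("bo")]] <- colSums(dattn)
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (crossprod(dS, cc$Q[, cols, drop = FALSE])) / sqrt(dh)
    }
    grads[[p("Wq")]] <- crossprod(cc$x1, dQ)
    grads[[p("bq")]] <- colSums(dQ)
    grads[[p("Wk")]] <- crossprod(cc$x1, dK)
    grads[[p("bk")]] <- colSums(dK)
    grads[[p("Wv")]] <- crossprod(cc$x1, dV)
    grads[[p("bv")]] <- colSums(dV)
    dx1 <- tcrossprod(dQ, par[[p("Wq")]]) + tcrossprod(dK, par[[p("Wk")]]) +
      tcrossprod(dV, par[[p("Wv")]])
    lb <- .layernorm_backward(dx1, cc$ln1, par[[p("ln1_g")]])
    grads[[p("ln1_g")]] <- lb$dg
    grads[[p("ln1_b")]] <- lb$db
    dH <- dH + lb$dx            # gradient w.r.t. H_in
  }

  # embedding gather: accumulate rows by token id
  acc <- rowsum(dH, group = cache$ids)
  dEmb <- matrix(0, cfg$vocab_size, d)
  dEmb[as.integer(rownames(acc)) + 1L, ] <- acc
  grads$tok_emb <- dEmb
  grads
}

# accumulate g2 into g1 elementwise (both named lists; g1 may be empty)
.grad_add <- function(g1, g2, scale = 1) {
  if (length(g1) == 0L) {
    return(lapply(g2, function(x) x * scale))
  }
  for (nm in names(g2)) g1[[nm]] <- g1[[nm]] + g2[[nm]] * scale
  g1
}
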