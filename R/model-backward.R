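# Reverse-mode gradients for the network. Structured exactly like the
# forward pass in model.R: head backward, then blocks in reverse order with
# the residual pre-softmax scores threading gradients backwards (block t's
# scores receive gradient both from its own softmax and, additively, from
# every later block through the residual-score chain).

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# a and b share structure; match by name where names exist, by position in
# unnamed lists (the per-block list).
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  keys <- if (is.null(names(b))) seq_along(b) else names(b)
  for (k in keys) {
    a[[k]] <- if (is.list(b[[k]])) add_grads(a[[k]], b[[k]])
              else a[[k]] + b[[k]]
  }
  a
}

# dz: gradient of the loss w.r.t. the pre-activation output z (length M).
# Returns list(grads, dX0) where dX0 is the gradient on the (dropout-applied)
# embedded input rows.
backward_sample <- function(cache, dz, params, cfg) {
  hp <- params$head
  hd <- cache$head
  V <- cache$V
  n <- nrow(V)
  g_head <- list()
  if (cfg$use_localization_attention) {
    ctx <- hd$ctx; A <- hd$A
    if (cfg$per_label_output) {
      dctx <- t(hp$W_s) * dz                     # M x d
      g_head$W_s <- t(ctx * dz)
      g_head$b_s <- dz
    } else {
      dctx <- dz %o% drop(hp$W_s)                # M x d
      g_head$W_s <- crossprod(ctx, dz)
      g_head$b_s <- sum(dz)
    }
    dA <- V %*% t(dctx)                          # n x M
    dV <- A %*% dctx                             # n x d
    dlog <- matrix(0, n, ncol(A))
    for (j in seq_len(ncol(A))) {
      a <- A[, j]
      dlog[, j] <- a * (dA[, j] - sum(a * dA[, j]))
    }
    g_head$W_a <- crossprod(V, dlog)
    g_head$b_a <- colSums(dlog)
    dV <- dV + dlog %*% t(hp$W_a)
  } else {
    pooled <- hd$pooled
    g_head$W_p <- pooled %o% dz
    g_head$b_p <- dz
    dV <- matrix(drop(hp$W_p %*% dz), n, cfg$hidden, byrow = TRUE) / n
  }

  dX <- dV
  H <- cfg$n_heads; dh <- cfg$head_dim
  sc <- 1 / sqrt(dh)
  beta_sc <- if (cfg$scale_alpha) 1 else sc
  dS_next <- rep(list(NULL), H)     # accumulated score gradient from later blocks
  g_blocks <- vector("list", cfg$n_blocks)
  for (t in rev(seq_len(cfg$n_blocks))) {
    bp <- params$blocks[[t]]
    bc <- cache$blocks[[t]]
    gb <- list()
    l2 <- ln_backward(dX, bc$ln2, bp$ln2_g)
    gb$ln2_g <- l2$dg; gb$ln2_b <- l2$db
    dA1 <- l2$dU
    dFo <- if (is.null(bc$dm2)) l2$dU else l2$dU * bc$dm2
    dHr <- dFo %*% t(bp$W2)
    gb$W2 <- crossprod(bc$Hr, dFo); gb$b2 <- colSums(dFo)
    dH1 <- dHr * (bc$H1 > 0)
    gb$W1 <- crossprod(bc$A1, dH1); gb$b1 <- colSums(dH1)
    dA1 <- dA1 + dH1 %*% t(bp$W1)
    l1 <- ln_backward(dA1, bc$ln1, bp$ln1_g)
    gb$ln1_g <- l1$dg; gb$ln1_b <- l1$db
    dXin <- l1$dU
    dCp <- if (is.null(bc$dm1)) l1$dU else l1$dU * bc$dm1
    dCtx <- dCp %*% t(bp$W_o)
    gb$W_o <- crossprod(bc$Ctx, dCp); gb$b_o <- colSums(dCp)

    n_r <- nrow(bc$X)
    dQall <- matrix(0, n_r, H * dh); dKall <- dQall; dVall <- dQall
    gb$alpha <- bp$alpha * 0; gb$beta <- bp$beta * 0
    dS_cur <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- head_cols(h, dh)
      Q <- bc$Qall[, idx, drop = FALSE]; K <- bc$Kall[, idx, drop = FALSE]
      Vh <- bc$Vall[, idx, drop = FALSE]
      Wt <- bc$W_list[[h]]
      dCh <- dCtx[, idx, drop = FALSE]
      dWt <- dCh %*% t(Vh)
      dVall[, idx] <- crossprod(Wt, dCh)
      dS <- Wt * (dWt - rowSums(dWt * Wt))
      if (!is.null(dS_next[[h]])) dS <- dS + dS_next[[h]]
      dS_cur[[h]] <- dS
      if (cfg$use_positional_encoding) {
        raw <- tcrossprod(Q, K)
        bm <- bc$bm
        acc <- rowsum(cbind(as.vector(dS * raw), as.vector(dS)),
                      group = as.vector(bm))
        ix <- as.integer(rownames(acc))
        gb$alpha[h, ix] <- acc[, 1L] * sc
        gb$beta[h, ix] <- acc[, 2L] * beta_sc
        draw <- dS * (sc * matrix(bp$alpha[h, ][bm], n_r, n_r))
      } else {
        draw <- dS * sc
      }
      dQall[, idx] <- draw %*% K
      dKall[, idx] <- crossprod(draw, Q)
    }
    dS_next <- dS_cur
    gb$W_q <- crossprod(bc$X, dQall)
    gb$W_k <- crossprod(bc$X, dKall)
    gb$W_v <- crossprod(bc$X, dVall)
    dXin <- dXin + dQall %*% t(bp$W_q) + dKall %*% t(bp$W_k) +
      dVall %*% t(bp$W_v)
    g_blocks[[t]] <- gb
    dX <- dXin
  }
  if (!is.null(cache$dme)) dX <- dX * cache$dme
  list(grads = list(blocks = g_blocks, head = g_head), dX0 = dX)
}
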