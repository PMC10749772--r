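#' Model configuration
#'
#' Hyperparameters of the localization Transformer. The defaults are the
#' full-scale settings: eight residual-attention blocks with eight heads,
#' hidden size 128, query/key/value widened to 64 per head, position-wise
#' feed-forward width 512, relative positions clipped at distance 25, 512
#' subsequence positions, and a sigmoid multi-label output over four
#' compartments.
#'
#' @param n_blocks Number of Transformer blocks.
#' @param n_heads Attention heads per block.
#' @param hidden Model width d (must equal the embedding dimension).
#' @param head_dim Per-head query/key/value width (widened dense maps, not
#'   `hidden / n_heads`).
#' @param ffn_dim Inner width of the position-wise feed-forward network.
#' @param max_rel_dist Clip radius of the signed relative distance used to
#'   index the learnable positional scale/bias tables.
#' @param n_max Number of model positions (padded subsequence count).
#' @param n_labels Number of output compartments M.
#' @param dropout_embed Dropout rate on the embedded input rows.
#' @param dropout_other Dropout rate inside the blocks.
#' @param use_localization_attention If `FALSE`, the label-wise attention
#'   head is replaced by masked mean-pooling plus a dense layer (ablation);
#'   per-label attention weights are then unavailable.
#' @param use_positional_encoding If `FALSE`, the relative positional
#'   scale/bias terms are dropped (plain scaled dot-product plus residual
#'   scores).
#' @param output_mode `"sigmoid"` for multi-label outputs, `"softmax"` for
#'   the multi-class variant.
#' @param k k-mer size of the embedding stage.
#' @param finetune_embedding Whether the k-mer lookup table is trained
#'   further during supervised training.
#' @param per_label_output If `TRUE`, each label gets its own output
#'   projection instead of the default shared one.
#' @param scale_alpha If `TRUE` (default) the learnable positional scale
#'   multiplies the \eqn{1/\sqrt{d_{head}}}-scaled dot product; if `FALSE`,
#'   the unscaled product.
#' @param label_names Ordered label names.
#' @return An object of class `lncloc_config`.
#' @export
lncloc_config <- function(n_blocks = 8L, n_heads = 8L, hidden = 128L,
                          head_dim = 64L, ffn_dim = 512L, max_rel_dist = 25L,
                          n_max = 512L, n_labels = 4L,
                          dropout_embed = 0.2, dropout_other = 0.1,
                          use_localization_attention = TRUE,
                          use_positional_encoding = TRUE,
                          output_mode = c("sigmoid", "softmax"),
                          k = 3L, finetune_embedding = TRUE,
                          per_label_output = FALSE, scale_alpha = TRUE,
                          label_names = NULL) {
  output_mode <- match.arg(output_mode)
  cfg <- list(n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
              hidden = as.integer(hidden), head_dim = as.integer(head_dim),
              ffn_dim = as.integer(ffn_dim),
              max_rel_dist = as.integer(max_rel_dist),
              n_max = as.integer(n_max), n_labels = as.integer(n_labels),
              dropout_embed = dropout_embed, dropout_other = dropout_other,
              use_localization_attention = isTRUE(use_localization_attention),
              use_positional_encoding = isTRUE(use_positional_encoding),
              output_mode = output_mode, k = as.integer(k),
              finetune_embedding = isTRUE(finetune_embedding),
              per_label_output = isTRUE(per_label_output),
              scale_alpha = isTRUE(scale_alpha),
              label_names = if (is.null(label_names)) {
                if (n_labels == 4L) lncloc_labels()
                else paste0("label", seq_len(n_labels))
              } else label_names)
  counts <- unlist(cfg[c("n_blocks", "n_heads", "hidden", "head_dim",
                         "ffn_dim", "max_rel_dist", "n_max", "n_labels", "k")])
  if (any(counts < 1L)) stop("all model dimensions must be positive")
  if (length(cfg$label_names) != cfg$n_labels)
    stop("label_names must have length n_labels")
  structure(cfg, class = "lncloc_config")
}

#' @export
print.lncloc_config <- function(x, ...) {
  cat(sprintf(paste0("<lncloc_config> %d blocks, %d heads, hidden %d, ",
                     "head_dim %d, ffn %d, n_max %d, rel.dist %d, %d labels (%s)\n"),
              x$n_blocks, x$n_heads, x$hidden, x$head_dim, x$ffn_dim,
              x$n_max, x$max_rel_dist, x$n_labels, x$output_mode))
  invisible(x)
}

#' Clipped signed relative distance
#'
#' The bucket index used by the relative positional encoding:
#' `clamp(i - j, -max_rel_dist, +max_rel_dist)`.
#'
#' @param i,j 0- or 1-based positions (only the difference matters);
#'   vectorized.
#' @param max_rel_dist Clip radius.
#' @return Integer vector of clipped signed distances.
#' @export
rel_bucket <- function(i, j, max_rel_dist = 25L) {
  as.integer(pmin(pmax(i - j, -max_rel_dist), max_rel_dist))
}

# n x n matrix of 1-based table indices (bucket -R..R -> 1..2R+1)
bucket_matrix <- function(n, max_rel_dist) {
  d <- outer(seq_len(n), seq_len(n), "-")
  pmin(pmax(d, -max_rel_dist), max_rel_dist) + max_rel_dist + 1L
}

#' Pre-softmax attention scores with relative positional encoding
#'
#' Computes `S[i,j] = alpha[b(i,j)] * (q_i . k_j) / sqrt(head_dim) +
#' beta[b(i,j)] + prev[i,j]` where `b(i,j)` is the clipped signed distance
#' bucket. The returned matrix excludes any masking penalty: the same `S` is
#' softmaxed (with masking) for this layer's attention weights and handed
#' forward unmasked as the next layer's residual `prev` scores.
#'
#' @param Q,K `n x head_dim` query/key matrices.
#' @param prev `n x n` residual pre-softmax scores from the previous layer
#'   (`NULL` or 0 for the first layer).
#' @param alpha,beta Length-`2*max_rel_dist+1` learnable positional scale and
#'   bias tables for this head (`NULL` to disable positional encoding).
#' @param max_rel_dist Clip radius.
#' @param scale_alpha Whether `alpha` multiplies the scaled dot product.
#' @return `n x n` matrix of pre-softmax scores.
#' @export
attention_scores <- function(Q, K, prev = NULL, alpha = NULL, beta = NULL,
                             max_rel_dist = 25L, scale_alpha = TRUE) {
  if (!is.null(prev) && any(!is.finite(prev)))
    stop("non-finite residual attention scores")
  n <- nrow(Q)
  raw <- tcrossprod(Q, K)
  if (scale_alpha) raw <- raw / sqrt(ncol(Q))
  if (!is.null(alpha)) {
    bm <- bucket_matrix(n, max_rel_dist)
    S <- matrix(alpha[bm], n, n) * raw + matrix(beta[bm], n, n)
    if (!scale_alpha) S <- S / sqrt(ncol(Q))
  } else {
    S <- if (scale_alpha) raw else raw / sqrt(ncol(Q))
  }
  if (!is.null(prev)) S <- S + prev
  S
}

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

head_cols <- function(h, head_dim) ((h - 1L) * head_dim + 1L):(h * head_dim)

#' Initialize model parameters
#'
#' Gaussian initialization for all projections, positional scales started at
#' 1 and biases at 0 (so the untrained model reduces to plain scaled
#' dot-product attention), layer-norm gains 1.
#'
#' @param config An [lncloc_config()].
#' @param seed Integer seed.
#' @param embed Optional `(4^k + 1) x hidden` embedding matrix (last row is
#'   the frozen null vector) placed into the parameter set for end-to-end
#'   training.
#' @return Nested list of parameter arrays.
#' @export
lncloc_init_params <- function(config, seed = 1L, embed = NULL) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  d <- config$hidden; H <- config$n_heads; dh <- config$head_dim
  f <- config$ffn_dim; M <- config$n_labels
  nb <- 2L * config$max_rel_dist + 1L
  gm <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  blocks <- lapply(seq_len(config$n_blocks), function(t) {
    list(W_q = gm(d, H * dh, 1 / sqrt(d)), W_k = gm(d, H * dh, 1 / sqrt(d)),
         W_v = gm(d, H * dh, 1 / sqrt(d)),
         W_o = gm(H * dh, d, 1 / sqrt(H * dh)), b_o = numeric(d),
         alpha = matrix(1, H, nb), beta = matrix(0, H, nb),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = gm(d, f, sqrt(2 / d)), b1 = numeric(f),
         W2 = gm(f, d, 1 / sqrt(f)), b2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  })
  head <- if (config$use_localization_attention) {
    list(W_a = gm(d, M, 1 / sqrt(d)), b_a = numeric(M),
         W_s = if (config$per_label_output) gm(d, M, 1 / sqrt(d))
               else gm(d, 1L, 1 / sqrt(d)),
         b_s = if (config$per_label_output) numeric(M) else 0)
  } else {
    list(W_p = gm(d, M, 1 / sqrt(d)), b_p = numeric(M))
  }
  params <- list(blocks = blocks, head = head)
  if (!is.null(embed)) params$embed <- embed
  params
}

#' Number of trainable parameters
#'
#' A pure function of the configuration (embedding table excluded).
#'
#' @param config An [lncloc_config()].
#' @return Integer parameter count.
#' @export
param_count <- function(config) {
  p <- lncloc_init_params(config, seed = 1L)
  sum(vapply(rapply(p, length, how = "unlist"), identity, numeric(1)))
}

ln_forward <- function(U, g, b, eps = 1e-5) {
  n <- nrow(U)
  mu <- rowMeans(U)
  xc <- U - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(Y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, sd = sd)
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = n)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dU <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dU = dU, dg = dg, db = db)
}

drop_mask <- function(n, d, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
}

# One block on an all-real (unpadded) n x d input. prev: list of n x n per
# head. Returns X', this block's pre-softmax scores, and a backward cache.
block_forward_core <- function(X, prev, bp, cfg, train = FALSE,
                               want_cache = FALSE) {
  n <- nrow(X); H <- cfg$n_heads; dh <- cfg$head_dim
  Qall <- X %*% bp$W_q; Kall <- X %*% bp$W_k; Vall <- X %*% bp$W_v
  S_list <- vector("list", H)
  W_list <- if (want_cache) vector("list", H)
  Ctx <- matrix(0, n, H * dh)
  bm <- if (cfg$use_positional_encoding) bucket_matrix(n, cfg$max_rel_dist)
  sc <- 1 / sqrt(dh)
  beta_sc <- if (cfg$scale_alpha) 1 else sc    # where the 1/sqrt(d) attaches
  for (h in seq_len(H)) {
    idx <- head_cols(h, dh)
    raw <- tcrossprod(Qall[, idx, drop = FALSE], Kall[, idx, drop = FALSE])
    S <- if (cfg$use_positional_encoding)
      sc * matrix(bp$alpha[h, ][bm], n, n) * raw +
        beta_sc * matrix(bp$beta[h, ][bm], n, n)
    else sc * raw
    if (!is.null(prev[[h]])) S <- S + prev[[h]]
    Wt <- row_softmax(S)
    Ctx[, idx] <- Wt %*% Vall[, idx, drop = FALSE]
    S_list[[h]] <- S
    if (want_cache) W_list[[h]] <- Wt
  }
  Cp <- Ctx %*% bp$W_o + rep(bp$b_o, each = n)
  dm1 <- if (train) drop_mask(n, cfg$hidden, cfg$dropout_other)
  CpD <- if (is.null(dm1)) Cp else Cp * dm1
  ln1 <- ln_forward(X + CpD, bp$ln1_g, bp$ln1_b)
  A1 <- ln1$Y
  H1 <- A1 %*% bp$W1 + rep(bp$b1, each = n)
  Hr <- pmax(H1, 0)
  Fo <- Hr %*% bp$W2 + rep(bp$b2, each = n)
  dm2 <- if (train) drop_mask(n, cfg$hidden, cfg$dropout_other)
  FoD <- if (is.null(dm2)) Fo else Fo * dm2
  ln2 <- ln_forward(A1 + FoD, bp$ln2_g, bp$ln2_b)
  cache <- if (want_cache)
    list(X = X, Qall = Qall, Kall = Kall, Vall = Vall, Ctx = Ctx,
         S_list = S_list, W_list = W_list, bm = bm, dm1 = dm1, dm2 = dm2,
         A1 = A1, H1 = H1, Hr = Hr, ln1 = ln1, ln2 = ln2)
  list(X = ln2$Y, S_list = S_list, cache = cache)
}

# Label-wise attention + probabilities on an all-real V. Returns list with
# alpha (M x n), probs, z, ctx.
head_forward_core <- function(V, hp, cfg) {
  n <- nrow(V); M <- cfg$n_labels
  if (cfg$use_localization_attention) {
    logits <- V %*% hp$W_a + rep(hp$b_a, each = n)   # n x M
    A <- apply(logits, 2L, function(l) { e <- exp(l - max(l)); e / sum(e) })
    A <- matrix(A, n, M)
    ctx <- crossprod(A, V)                           # M x d
    z <- if (cfg$per_label_output) rowSums(ctx * t(hp$W_s)) + hp$b_s
         else drop(ctx %*% hp$W_s) + hp$b_s
    alpha <- t(A)
  } else {
    pooled <- colMeans(V)
    z <- drop(pooled %*% hp$W_p) + hp$b_p
    alpha <- NULL; A <- NULL; ctx <- NULL
  }
  probs <- if (cfg$output_mode == "softmax") {
    e <- exp(z - max(z)); e / sum(e)
  } else 1 / (1 + exp(-z))
  list(alpha = alpha, A = A, ctx = ctx, z = as.numeric(z),
       pooled = if (!cfg$use_localization_attention) pooled,
       probs = as.numeric(probs))
}

#' Residual multi-head attention (one layer)
#'
#' Runs every head's [attention_scores()] with the threaded residual scores,
#' softmaxes them over unmasked positions, pools values, and projects the
#' concatenated heads. Returns both the context and the new residual state
#' (this layer's pre-softmax scores, unmasked).
#'
#' @param X `n x hidden` input rows.
#' @param state List of per-head `n x n` residual score matrices (or `NULL`).
#' @param params Block parameter list (fields `W_q`, `W_k`, `W_v`, `W_o`,
#'   `b_o`, `alpha`, `beta`).
#' @param mask Logical validity vector (default all true).
#' @param config An [lncloc_config()].
#' @return List with `context` (`n x hidden`) and `state` (per-head scores).
#' @export
multihead_attention <- function(X, state = NULL, params, mask = NULL, config) {
  n <- nrow(X); H <- config$n_heads; dh <- config$head_dim
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(state)) state <- rep(list(NULL), H)
  Xr <- X[mask, , drop = FALSE]
  pr <- lapply(state, function(s) if (is.null(s)) NULL
               else s[mask, mask, drop = FALSE])
  Qall <- Xr %*% params$W_q; Kall <- Xr %*% params$W_k; Vall <- Xr %*% params$W_v
  Ctx <- matrix(0, nrow(Xr), H * dh)
  new_state <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- head_cols(h, dh)
    S <- attention_scores(Qall[, idx, drop = FALSE], Kall[, idx, drop = FALSE],
                          prev = pr[[h]],
                          alpha = if (config$use_positional_encoding)
                            params$alpha[h, ],
                          beta = if (config$use_positional_encoding)
                            params$beta[h, ],
                          max_rel_dist = config$max_rel_dist,
                          scale_alpha = config$scale_alpha)
    Wt <- row_softmax(S)
    Ctx[, idx] <- Wt %*% Vall[, idx, drop = FALSE]
    Sfull <- matrix(0, n, n)
    Sfull[mask, mask] <- S
    new_state[[h]] <- Sfull
  }
  ctx_full <- matrix(0, n, config$hidden)
  ctx_full[mask, ] <- Ctx %*% params$W_o + rep(params$b_o, each = nrow(Xr))
  list(context = ctx_full, state = new_state)
}

#' One Transformer block
#'
#' Residual multi-head attention with threaded pre-softmax scores, followed
#' by add-and-norm, a position-wise ReLU feed-forward network, and a second
#' add-and-norm (post-norm ordering). Deterministic in eval mode.
#'
#' @inheritParams multihead_attention
#' @param params Full block parameter list.
#' @return List with `X` (`n x hidden` output; masked rows zero) and `state`.
#' @export
transformer_block <- function(X, state = NULL, params, mask = NULL, config) {
  n <- nrow(X)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(state)) state <- rep(list(NULL), config$n_heads)
  pr <- lapply(state, function(s) if (is.null(s)) NULL
               else s[mask, mask, drop = FALSE])
  out <- block_forward_core(X[mask, , drop = FALSE], pr, params, config)
  Xf <- matrix(0, n, config$hidden)
  Xf[mask, ] <- out$X
  new_state <- lapply(out$S_list, function(S) {
    Sf <- matrix(0, n, n); Sf[mask, mask] <- S; Sf
  })
  list(X = Xf, state = new_state)
}

#' Localization-specific attention weights
#'
#' One softmax attention distribution over sequence positions per label:
#' `alpha_j = softmax(V W_a[,j] + b_a[j])` over unmasked positions, zero on
#' masked positions.
#'
#' @param V `n x hidden` final-block representation.
#' @param params Head parameter list (`W_a`, `b_a`).
#' @param mask Logical validity vector (default all true).
#' @return `M x n` matrix of attention weights; each row sums to 1.
#' @export
localization_attention <- function(V, params, mask = NULL) {
  n <- nrow(V); M <- ncol(params$W_a)
  if (is.null(mask)) mask <- rep(TRUE, n)
  Vr <- V[mask, , drop = FALSE]
  logits <- Vr %*% params$W_a + rep(params$b_a, each = nrow(Vr))
  A <- apply(logits, 2L, function(l) { e <- exp(l - max(l)); e / sum(e) })
  alpha <- matrix(0, M, n)
  alpha[, mask] <- t(matrix(A, nrow(Vr), M))
  alpha
}

#' Per-label localization probabilities
#'
#' Pools the representation with each label's attention weights and applies
#' the shared output projection: `s_j = sigmoid(alpha_j' V w_s + b_s)`
#' (softmaxed across labels instead in `"softmax"` output mode).
#'
#' @param V `n x hidden` representation.
#' @param alpha `M x n` attention weights from [localization_attention()].
#' @param params Head parameter list (`W_s`, `b_s`).
#' @param output_mode `"sigmoid"` or `"softmax"`.
#' @param per_label_output Whether `W_s`/`b_s` are per-label.
#' @return Numeric vector of M probabilities.
#' @export
localization_probabilities <- function(V, alpha, params,
                                       output_mode = "sigmoid",
                                       per_label_output = FALSE) {
  ctx <- alpha %*% V                                  # M x d
  z <- if (per_label_output) rowSums(ctx * t(params$W_s)) + params$b_s
       else drop(ctx %*% params$W_s) + params$b_s
  if (output_mode == "softmax") { e <- exp(z - max(z)); e / sum(e) }
  else 1 / (1 + exp(-z))
}

# Forward pass for one embedded sample (values already n_max x d).
# Returns probs, alpha (M x n_max, zero on masked), plus caches if asked.
forward_sample <- function(values, mask, params, cfg, train = FALSE,
                           want_cache = FALSE) {
  n_eff <- sum(mask)
  X <- values[seq_len(n_eff), , drop = FALSE]
  dme <- if (train) drop_mask(n_eff, cfg$hidden, cfg$dropout_embed)
  if (!is.null(dme)) X <- X * dme
  X0 <- X
  prev <- rep(list(NULL), cfg$n_heads)
  caches <- if (want_cache) vector("list", cfg$n_blocks)
  for (t in seq_len(cfg$n_blocks)) {
    out <- block_forward_core(X, prev, params$blocks[[t]], cfg,
                              train = train, want_cache = want_cache)
    X <- out$X
    prev <- out$S_list
    if (want_cache) caches[[t]] <- out$cache
  }
  hd <- head_forward_core(X, params$head, cfg)
  alpha_full <- NULL
  if (cfg$use_localization_attention) {
    alpha_full <- matrix(0, cfg$n_labels, length(mask))
    alpha_full[, seq_len(n_eff)] <- hd$alpha
  }
  list(probs = hd$probs, alpha = alpha_full, n_eff = n_eff,
       cache = if (want_cache)
         list(X0 = X0, dme = dme, blocks = caches, V = X, head = hd))
}

#' Full network forward pass
#'
#' Embedded inputs through all Transformer blocks (residual scores threaded,
#' initial residual = 0), the localization-specific attention head, and
#' per-label probabilities; binary calls use the strict `s > 0.5` rule.
#' Samples are processed independently, so results do not depend on how a
#' batch is assembled.
#'
#' @param tensors A single [embed_sequence()] result or a list of them.
#' @param params Parameters from [lncloc_init_params()] (or a trained fit).
#' @param config An [lncloc_config()].
#' @return A list of prediction results, each with `probabilities`, `calls`,
#'   `label_attention` (`M x n_max`, `NULL` in the pooled-head ablation) and
#'   `layout`.
#' @export
lncloc_forward <- function(tensors, params, config) {
  if (!is.null(tensors$values)) tensors <- list(tensors)
  lapply(tensors, function(tn) {
    fw <- forward_sample(tn$values, tn$mask, params, config)
    probs <- stats::setNames(fw$probs, config$label_names)
    list(probabilities = probs,
         calls = stats::setNames(as.integer(probs > 0.5), config$label_names),
         label_attention = fw$alpha, layout = tn$layout)
  })
}
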