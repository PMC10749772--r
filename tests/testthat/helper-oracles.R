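# Independent brute-force oracles used to verify the vectorized
# implementations. Everything here is deliberately written as plain nested
# loops over the defining formulas and shares no code with the package
# internals.

clamp <- function(x, lo, hi) max(lo, min(hi, x))

naive_attention_scores <- function(Q, K, prev, alpha, beta, R,
                                   scale_alpha = TRUE) {
  n <- nrow(Q); dh <- ncol(Q)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dot <- 0
      for (u in seq_len(dh)) dot <- dot + Q[i, u] * K[j, u]
      b <- clamp(i - j, -R, R) + R + 1L
      S[i, j] <- if (is.null(alpha)) {
        dot / sqrt(dh)
      } else if (scale_alpha) {
        alpha[b] * dot / sqrt(dh) + beta[b]
      } else {
        (alpha[b] * dot + beta[b]) / sqrt(dh)
      }
      if (!is.null(prev)) S[i, j] <- S[i, j] + prev[i, j]
    }
  }
  S
}

naive_softmax_row <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

naive_layernorm <- function(U, g, b, eps = 1e-5) {
  Y <- U
  for (i in seq_len(nrow(U))) {
    mu <- mean(U[i, ])
    v <- mean((U[i, ] - mu)^2)
    Y[i, ] <- g * (U[i, ] - mu) / sqrt(v + eps) + b
  }
  Y
}

# Full residual-attention block evaluated with explicit loops.
naive_transformer_block <- function(X, prev_list, bp, cfg) {
  n <- nrow(X); d <- cfg$hidden; H <- cfg$n_heads; dh <- cfg$head_dim
  heads <- matrix(0, n, H * dh)
  S_list <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Q <- matrix(0, n, dh); K <- Q; V <- Q
    for (i in seq_len(n)) for (u in seq_len(dh)) {
      Q[i, u] <- sum(X[i, ] * bp$W_q[, cols[u]])
      K[i, u] <- sum(X[i, ] * bp$W_k[, cols[u]])
      V[i, u] <- sum(X[i, ] * bp$W_v[, cols[u]])
    }
    S <- naive_attention_scores(Q, K, prev_list[[h]],
                                if (cfg$use_positional_encoding)
                                  bp$alpha[h, ],
                                if (cfg$use_positional_encoding) bp$beta[h, ],
                                cfg$max_rel_dist, cfg$scale_alpha)
    S_list[[h]] <- S
    for (i in seq_len(n)) {
      w <- naive_softmax_row(S[i, ])
      for (u in seq_len(dh)) heads[i, cols[u]] <- sum(w * V[, u])
    }
  }
  Ctx <- matrix(0, n, d)
  for (i in seq_len(n)) for (v in seq_len(d))
    Ctx[i, v] <- sum(heads[i, ] * bp$W_o[, v]) + bp$b_o[v]
  A1 <- naive_layernorm(X + Ctx, bp$ln1_g, bp$ln1_b)
  Fo <- matrix(0, n, d)
  for (i in seq_len(n)) {
    hvec <- pmax(as.numeric(A1[i, ] %*% bp$W1) + bp$b1, 0)
    Fo[i, ] <- as.numeric(hvec %*% bp$W2) + bp$b2
  }
  list(X = naive_layernorm(A1 + Fo, bp$ln2_g, bp$ln2_b), S_list = S_list)
}

# ---- evaluation-metric oracles (direct enumeration) ----

oracle_ave_f1 <- function(y, y_hat) {
  N <- nrow(y)
  pre <- c(); rec <- c()
  for (i in seq_len(N)) {
    tp <- sum(y[i, ] == 1 & y_hat[i, ] == 1)
    if (sum(y_hat[i, ]) > 0) pre <- c(pre, tp / sum(y_hat[i, ]))
    rec <- c(rec, tp / sum(y[i, ]))
  }
  if (!length(pre)) return(NA_real_)
  ap <- mean(pre); ar <- mean(rec)
  if (ap + ar == 0) 0 else 2 * ap * ar / (ap + ar)
}

oracle_micro <- function(y, y_hat) {
  tp <- 0; ncall <- 0; ntrue <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    tp <- tp + y[i, j] * y_hat[i, j]
    ncall <- ncall + y_hat[i, j]
    ntrue <- ntrue + y[i, j]
  }
  mip <- if (ncall == 0) NA_real_ else tp / ncall
  mir <- tp / ntrue
  mif <- if (is.na(mip)) NA_real_ else if (mip + mir == 0) 0 else
    2 * mip * mir / (mip + mir)
  c(mip, mir, mif)
}

oracle_p_at_k <- function(y, s, k) {
  tot <- 0
  for (i in seq_len(nrow(y))) {
    ord <- order(-s[i, ], seq_len(ncol(s)))
    tot <- tot + sum(y[i, ord[1:k]]) / k
  }
  tot / nrow(y)
}

oracle_multiclass <- function(y, s) {
  N <- nrow(y); M <- ncol(y)
  acc <- 0
  tp <- numeric(M); ncall <- numeric(M); ntrue <- numeric(M)
  for (i in seq_len(N)) {
    pred <- which.max(s[i, ])
    if (y[i, pred] == 1) acc <- acc + 1
    ncall[pred] <- ncall[pred] + 1
    for (j in seq_len(M)) if (y[i, j] == 1) ntrue[j] <- ntrue[j] + 1
    if (y[i, pred] == 1) tp[pred] <- tp[pred] + 1
  }
  prec <- ifelse(ncall == 0, 0, tp / ncall)
  rec <- ifelse(ntrue == 0, 0, tp / ntrue)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  c(acc / N, mean(prec), mean(rec), mean(f1))
}

oracle_auc <- function(scores, truth) {
  pos <- which(truth == 1); neg <- which(truth == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (scores[p] > scores[q]) 1
                 else if (scores[p] == scores[q]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# ---- IUPAC motif-scan oracle ----

iupac_table <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T", "N"))

oracle_iupac <- function(sequence, pattern) {
  sq <- strsplit(sequence, "")[[1]]
  pt <- strsplit(pattern, "")[[1]]
  w <- length(pt); L <- length(sq)
  out <- integer(0)
  if (L >= w) {
    for (s in 0:(L - w)) {
      ok <- TRUE
      for (u in seq_len(w)) {
        if (!(sq[s + u] %in% iupac_table[[pt[u]]])) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, s)
    }
  }
  out
}

# ---- shared tiny fixtures ----

random_record <- function(id, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_rec <- getFromNamespace("new_record", "lncloc")
  new_rec(id, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = ""))
}

tiny_config <- function(...) {
  base <- list(n_blocks = 2L, n_heads = 2L, hidden = 8L, head_dim = 4L,
               ffn_dim = 16L, n_max = 8L, max_rel_dist = 3L, k = 1L,
               dropout_embed = 0, dropout_other = 0)
  do.call(lncloc_config, utils::modifyList(base, list(...)))
}
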