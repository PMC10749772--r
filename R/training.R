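#' Binary cross-entropy loss
#'
#' Mean over all `N x M` entries of `-(y log s + (1 - y) log(1 - s))`, with
#' probabilities clipped to `[eps, 1 - eps]`. In softmax output mode use
#' [categorical_ce()] instead.
#'
#' @param probabilities `N x M` matrix (or vector) of predicted
#'   probabilities.
#' @param labels Binary matrix (or vector) of the same shape.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(probabilities, labels, eps = 1e-7) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels have different shapes")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Categorical cross-entropy loss
#'
#' Mean over samples of `-sum_j y_j log s_j` for one-hot rows (the loss of
#' the multi-class softmax variant).
#'
#' @inheritParams bce_loss
#' @return Scalar loss.
#' @export
categorical_ce <- function(probabilities, labels, eps = 1e-7) {
  p <- pmin(pmax(probabilities, eps), 1)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  -mean(rowSums(labels * log(p)))
}

#' Learning-rate schedule
#'
#' Linear warm-up from 0 to `lr_peak` over the first `warmup_epochs`, then
#' linear decay to 0 at `max_epochs`; continuous and piecewise linear in the
#' global step.
#'
#' @param step Global step (0-based).
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param control An [lncloc_control()].
#' @return Learning rate at `step`.
#' @export
lr_at <- function(step, steps_per_epoch, control) {
  warm <- control$warmup_epochs * steps_per_epoch
  total <- control$max_epochs * steps_per_epoch
  ifelse(step < warm & warm > 0,
         control$lr_peak * step / warm,
         control$lr_peak * pmax(total - step, 0) / max(total - warm, 1))
}

#' Training control parameters
#'
#' @param lr_peak Peak Adam learning rate (default 3e-4).
#' @param warmup_epochs Linear warm-up length in epochs (default 4).
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs, on validation micro-F1
#'   (ignored when there is no validation split).
#' @param val_fraction Fraction of the training set held out for validation.
#' @param seed Master seed for initialization, splitting, shuffling and
#'   dropout.
#' @param grad_clip Optional global gradient max-norm (`NULL` = off).
#' @param max_len Truncation cap in nucleotides.
#' @param verbose Print per-epoch progress.
#' @return An object of class `lncloc_control`.
#' @export
lncloc_control <- function(lr_peak = 3e-4, warmup_epochs = 4L, batch_size = 64L,
                           max_epochs = 100L, patience = 10L,
                           val_fraction = 0.2, seed = 1L, grad_clip = NULL,
                           max_len = 8196L, verbose = FALSE) {
  if (max_epochs < 1L) stop("nothing to train: max_epochs must be >= 1")
  if (warmup_epochs >= max_epochs)
    stop("warmup_epochs must be smaller than max_epochs")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr_peak = lr_peak, warmup_epochs = as.integer(warmup_epochs),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = as.integer(seed), grad_clip = grad_clip,
                 max_len = as.integer(max_len), verbose = isTRUE(verbose)),
            class = "lncloc_control")
}

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params),
                                   t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grad_norm <- function(g) sqrt(sum(rapply(g, function(x) sum(x * x),
                                         how = "unlist")))

scale_grads <- function(g, s) rapply(g, function(x) x * s, how = "replace")

# Precompute per-record layout and sparse bin/k-mer matrix restricted to the
# n_eff real rows.
prepare_inputs <- function(records, config, max_len) {
  lapply(records, function(r) {
    r <- truncate_record(r, max_len)
    layout <- split_subsequences(r, n_max = config$n_max, k = config$k)
    C <- bin_kmer_matrix(r, layout, config$k)[seq_len(layout$n_eff), ,
                                              drop = FALSE]
    list(id = r$id, layout = layout, C = C)
  })
}

loss_and_grads <- function(inputs, y, params, cfg, train = TRUE) {
  E <- params$embed
  n_b <- length(inputs)
  probs <- matrix(0, n_b, cfg$n_labels)
  grads <- NULL
  dE <- if (cfg$finetune_embedding) E * 0
  for (b in seq_len(n_b)) {
    values <- as.matrix(inputs[[b]]$C %*% E)
    fw <- forward_sample(values, rep(TRUE, nrow(values)), params, cfg,
                         train = train, want_cache = TRUE)
    probs[b, ] <- fw$probs
    dz <- if (cfg$output_mode == "softmax")
      (fw$probs - y[b, ]) / n_b
    else (fw$probs - y[b, ]) / (n_b * cfg$n_labels)
    bw <- backward_sample(fw$cache, dz, params, cfg)
    grads <- add_grads(grads, bw$grads)
    if (cfg$finetune_embedding)
      dE <- dE + as.matrix(Matrix::crossprod(inputs[[b]]$C, bw$dX0))
  }
  if (cfg$finetune_embedding) {
    dE[nrow(dE), ] <- 0                     # null k-mer vector stays frozen
    grads$embed <- dE
  }
  loss <- if (cfg$output_mode == "softmax") categorical_ce(probs, y)
          else bce_loss(probs, y)
  list(loss = loss, grads = grads, probs = probs)
}

predict_probs <- function(inputs, params, cfg) {
  E <- params$embed
  out <- lapply(inputs, function(inp) {
    values <- as.matrix(inp$C %*% E)
    forward_sample(values, rep(TRUE, nrow(values)), params, cfg)
  })
  probs <- do.call(rbind, lapply(out, `[[`, "probs"))
  colnames(probs) <- cfg$label_names
  rownames(probs) <- vapply(inputs, `[[`, character(1), "id")
  list(probs = probs, forward = out)
}

# Core supervised training loop: Adam, warm-up + linear decay, per-epoch
# reshuffling reseeded from the master seed, best-validation checkpointing.
train_core <- function(inputs, y, config, control, embed0) {
  n <- length(inputs)
  if (n == 0L) stop("empty dataset")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(control$seed)
  params <- lncloc_init_params(config, seed = control$seed, embed = embed0)
  n_val <- floor(control$val_fraction * n)
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 1L) stop("no training samples left after the split")
  steps_per_epoch <- max(1L, ceiling(length(tr_idx) / control$batch_size))
  state <- adam_init(params)
  step <- 0L
  best <- list(metric = -Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  hist <- vector("list", control$max_epochs)
  for (epoch in seq_len(control$max_epochs)) {
    set.seed(control$seed + epoch)
    order_ep <- sample(tr_idx)
    ep_loss <- 0
    for (s in seq_len(steps_per_epoch)) {
      take <- order_ep[((s - 1L) * control$batch_size + 1L):
                         min(s * control$batch_size, length(order_ep))]
      take <- take[!is.na(take)]
      lg <- loss_and_grads(inputs[take], y[take, , drop = FALSE], params,
                           config, train = TRUE)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch, ", step ", s)
      g <- lg$grads
      if (!is.null(control$grad_clip)) {
        gn <- grad_norm(g)
        if (gn > control$grad_clip) g <- scale_grads(g, control$grad_clip / gn)
      }
      lr <- lr_at(step, steps_per_epoch, control)
      upd <- adam_step(params, g, state, lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(take)
      step <- step + 1L
    }
    ep_loss <- ep_loss / length(tr_idx)
    val_loss <- NA_real_; val_mif <- NA_real_
    if (length(val_idx)) {
      pv <- predict_probs(inputs[val_idx], params, config)$probs
      yv <- y[val_idx, , drop = FALSE]
      val_loss <- if (config$output_mode == "softmax") categorical_ce(pv, yv)
                  else bce_loss(pv, yv)
      val_mif <- micro_prf(yv, pv)["MiF"]
      if (is.na(val_mif)) val_mif <- 0
      if (val_mif > best$metric) {
        best <- list(metric = val_mif, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else bad_epochs <- bad_epochs + 1L
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val_loss, val_micro_f1 = val_mif,
                                lr = lr_at(step - 1L, steps_per_epoch, control))
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f  val_loss %s  val MiF %s",
                      epoch, ep_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                      ifelse(is.na(val_mif), "-", sprintf("%.3f", val_mif))))
    if (length(val_idx) && bad_epochs >= control$patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (length(val_idx) && best$epoch > 0L) params <- best$params
  list(params = params, history = history, best_epoch = best$epoch,
       val_idx = val_idx)
}
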