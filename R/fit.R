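LNCLOC_FORMAT_VERSION <- "lncloc-checkpoint-1"

#' Fit the localization Transformer
#'
#' The single fitting entry point: embeds the training sequences
#' (pre-training k-mer vectors if none are supplied), trains the
#' residual-attention Transformer with the localization-specific head under
#' the configured optimizer schedule, and returns a fitted model with
#' `print`, `summary`, `coef`, `predict`, `plot` and `residuals` methods.
#'
#' @param records A FASTA path or a list of sequence records.
#' @param labels A label TSV path or a binary matrix with rownames matching
#'   the record ids (every training row must have at least one positive).
#' @param config An [lncloc_config()].
#' @param control An [lncloc_control()].
#' @param embeddings Optional pre-trained [train_kmer_embeddings()] table
#'   (dimension must equal `config$hidden`); trained on the input corpus
#'   when `NULL`.
#' @return An object of class `lncloc_fit`.
#' @export
lncloc <- function(records, labels, config = lncloc_config(),
                   control = lncloc_control(), embeddings = NULL) {
  if (is.character(records)) records <- read_fasta(records, min_length = config$k)
  if (length(records) == 0L) stop("empty dataset")
  ids <- vapply(records, `[[`, character(1), "id")
  if (is.character(labels))
    labels <- read_labels(labels, config$label_names, ids = ids)
  missing_ids <- setdiff(ids, rownames(labels))
  if (length(missing_ids))
    stop("no labels for sequence id(s): ", paste(missing_ids, collapse = ", "))
  y <- labels[ids, , drop = FALSE]
  if (any(rowSums(y) == 0))
    stop("training samples without any positive label: ",
         paste(ids[rowSums(y) == 0], collapse = ", "))
  if (is.null(embeddings))
    embeddings <- train_kmer_embeddings(records, k = config$k,
                                        d = config$hidden,
                                        seed = control$seed)
  if (embeddings$d != config$hidden)
    stop("embedding dimension (", embeddings$d, ") must equal hidden (",
         config$hidden, ")")
  if (embeddings$k != config$k)
    stop("embedding k (", embeddings$k, ") must equal config k (", config$k, ")")
  inputs <- prepare_inputs(records, config, control$max_len)
  embed0 <- rbind(embeddings$vectors, 0)
  tr <- train_core(inputs, y, config, control, embed0)
  fitted_probs <- predict_probs(inputs, tr$params, config)$probs
  structure(list(params = tr$params, config = config, control = control,
                 embeddings = embeddings[c("k", "d", "vocabulary", "window",
                                           "negative", "epochs", "seed")],
                 history = tr$history, best_epoch = tr$best_epoch,
                 ids = ids, y = y, fitted = fitted_probs,
                 val_idx = tr$val_idx, version = LNCLOC_FORMAT_VERSION),
            class = "lncloc_fit")
}

#' @export
print.lncloc_fit <- function(x, ...) {
  cat("Localization Transformer fit\n")
  print(x$config)
  cat(sprintf("  trained on %d sequences, %d epochs run%s\n",
              length(x$ids), nrow(x$history),
              if (x$best_epoch > 0)
                sprintf(" (best validation epoch %d)", x$best_epoch) else ""))
  cat(sprintf("  final training loss %.4f\n",
              x$history$train_loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.lncloc_fit <- function(object, ...) {
  cat("Localization Transformer fit\n\n")
  print(object$config)
  cat(sprintf("  parameters: %s (+ %d embedding weights)\n",
              format(param_count(object$config), big.mark = ","),
              length(object$params$embed)))
  cat(sprintf("  training sequences: %d  (validation: %d)\n",
              length(object$ids) - length(object$val_idx),
              length(object$val_idx)))
  h <- object$history
  cat(sprintf("  epochs run: %d;  final train loss %.4f", nrow(h),
              h$train_loss[nrow(h)]))
  if (any(!is.na(h$val_micro_f1)))
    cat(sprintf(";  best val micro-F1 %.3f (epoch %d)",
                max(h$val_micro_f1, na.rm = TRUE), object$best_epoch))
  cat("\n  label prevalence:",
      paste(colnames(object$y), colMeans(object$y), collapse = "  "), "\n")
  invisible(object)
}

#' @export
coef.lncloc_fit <- function(object, ...) object$params

#' @export
fitted.lncloc_fit <- function(object, ...) object$fitted

#' Training-set residuals
#'
#' Raw residuals `y - fitted probability` on the training sequences.
#'
#' @param object A fitted `lncloc_fit`.
#' @param ... Unused.
#' @return `N x M` numeric matrix.
#' @export
residuals.lncloc_fit <- function(object, ...) object$y - object$fitted

#' Plot training history
#'
#' Training (and validation) loss per epoch, plus validation micro-F1 when
#' a validation split was used.
#'
#' @param x A fitted `lncloc_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lncloc_fit <- function(x, ...) {
  h <- x$history
  has_val <- any(!is.na(h$val_loss))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  if (has_val) {
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}

#' Predict subcellular localization for new sequences
#'
#' Runs the fitted network in eval mode. Results are independent of batch
#' composition and ordered as the inputs; binary calls use the strict
#' `probability > 0.5` rule.
#'
#' @param object A fitted `lncloc_fit`.
#' @param records A FASTA path, a list of sequence records, or a single
#'   record.
#' @param ... Unused.
#' @return An object of class `lncloc_predictions`: `ids`, `probabilities`
#'   (`N x M`), `calls` (`N x M`), and `results` (per-record list with
#'   `probabilities`, `calls`, `label_attention`, `layout`).
#' @export
predict.lncloc_fit <- function(object, records, ...) {
  cfg <- object$config
  if (is.character(records)) records <- read_fasta(records, min_length = cfg$k)
  if (!is.null(records$id)) records <- list(records)
  if (length(records) == 0L)
    return(structure(list(ids = character(0),
                          probabilities = matrix(0, 0, cfg$n_labels),
                          calls = matrix(0L, 0, cfg$n_labels),
                          results = list(),
                          label_names = cfg$label_names),
                     class = "lncloc_predictions"))
  inputs <- prepare_inputs(records, cfg, object$control$max_len)
  results <- lapply(seq_along(inputs), function(i) {
    inp <- inputs[[i]]
    values <- as.matrix(inp$C %*% object$params$embed)
    fw <- forward_sample(values, rep(TRUE, nrow(values)), object$params, cfg)
    att <- NULL
    if (cfg$use_localization_attention) {
      att <- matrix(0, cfg$n_labels, inp$layout$n_max,
                    dimnames = list(cfg$label_names, NULL))
      att[, seq_len(fw$n_eff)] <- fw$alpha
    }
    probs <- stats::setNames(fw$probs, cfg$label_names)
    list(id = inp$id, probabilities = probs,
         calls = stats::setNames(as.integer(probs > 0.5), cfg$label_names),
         label_attention = att, layout = inp$layout)
  })
  probs <- do.call(rbind, lapply(results, `[[`, "probabilities"))
  calls <- do.call(rbind, lapply(results, `[[`, "calls"))
  ids <- vapply(results, `[[`, character(1), "id")
  rownames(probs) <- rownames(calls) <- ids
  structure(list(ids = ids, probabilities = probs, calls = calls,
                 results = results, label_names = cfg$label_names),
            class = "lncloc_predictions")
}

#' @export
print.lncloc_predictions <- function(x, digits = 3, ...) {
  cat(sprintf("<lncloc_predictions> %d sequence(s)\n", length(x$ids)))
  if (length(x$ids))
    print(round(x$probabilities, digits))
  invisible(x)
}

#' Save a fitted model checkpoint
#'
#' Single-file bundle of configuration, parameters, embedding metadata and a
#' format-version string; [load_lncloc()] refuses mismatched versions.
#'
#' @param object A fitted `lncloc_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_lncloc <- function(object, path) {
  stopifnot(inherits(object, "lncloc_fit"))
  saveRDS(object, path)
  invisible(path)
}

#' Load a checkpoint written by [save_lncloc()]
#'
#' @param path Checkpoint file.
#' @return The `lncloc_fit` object.
#' @export
load_lncloc <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "lncloc_fit") ||
      !identical(obj$version, LNCLOC_FORMAT_VERSION))
    stop("incompatible checkpoint format (expected ", LNCLOC_FORMAT_VERSION,
         ")")
  obj
}
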