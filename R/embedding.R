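#' @useDynLib lncloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Enumerate the k-mer vocabulary
#'
#' All `4^k` k-mers over \{A,C,G,T\} in lexicographic order. K-mers
#' containing N are not part of the vocabulary; they map to a dedicated null
#' (all-zero) vector.
#'
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @export
kmer_vocabulary <- function(k = 3L) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, bases, simplify = FALSE)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' Extract overlapping k-mers from a sequence
#'
#' Returns the `L - k + 1` stride-one windows of the sequence, in order.
#' K-mers containing N are included in the stream but flagged as null via
#' the `"null"` attribute.
#'
#' @param sequence Canonical nucleotide string.
#' @param k k-mer length.
#' @return Character vector of k-mers with a logical `"null"` attribute.
#' @export
extract_kmers <- function(sequence, k = 3L) {
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k = ", k)
  starts <- seq_len(L - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  structure(km, null = grepl("N", km, fixed = TRUE))
}

# 1-based vocabulary index per k-mer; NA for k-mers containing N.
kmer_ids <- function(kmers, k) {
  base <- match(strsplit(paste(kmers, collapse = ""), "")[[1]],
                c("A", "C", "G", "T")) - 1L
  mat <- matrix(base, nrow = k)
  ids <- as.integer(colSums(mat * 4L^((k - 1L):0L))) + 1L
  ids  # NA propagates from non-ACGT characters
}

#' Train skip-gram k-mer embeddings
#'
#' Treats each record's ordered overlapping k-mer stream as one sentence and
#' trains skip-gram with negative sampling (the word2vec objective) over the
#' corpus. K-mers absent from the corpus receive small seeded random
#' vectors; k-mers containing N map to a frozen all-zero null vector.
#' Deterministic given `(corpus, parameters, seed)` on a single worker.
#'
#' @param corpus List of sequence records.
#' @param k k-mer length (default 3).
#' @param d Embedding dimension (default 128).
#' @param window Context radius (default 5).
#' @param negative Negative samples per context pair (default 5).
#' @param epochs Training epochs over the corpus (default 10).
#' @param seed Integer seed.
#' @return Object of class `lncloc_embeddings`: list with `k`, `d`,
#'   `vocabulary`, `vectors` (`4^k x d` matrix, rownames = k-mers),
#'   `null_vector`, and the training parameters.
#' @export
train_kmer_embeddings <- function(corpus, k = 3L, d = 128L, window = 5L,
                                  negative = 5L, epochs = 10L, seed = 1L) {
  if (length(corpus) == 0L) stop("empty corpus")
  vocab <- kmer_vocabulary(k)
  sentences <- lapply(corpus, function(r) {
    km <- extract_kmers(r$sequence, k)
    ids <- kmer_ids(km, k)
    ids <- ids[!is.na(ids)]        # null k-mers carry no vector
    as.integer(ids - 1L)
  })
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) stop("corpus contains no unambiguous k-mers")
  vec <- .sgns_train(sentences, length(vocab), as.integer(d),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), 0.025, 1e-4, as.integer(seed))
  # seeded fallback for k-mers never seen in the corpus
  seen <- sort(unique(unlist(sentences))) + 1L
  unseen <- setdiff(seq_along(vocab), seen)
  if (length(unseen)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    vec[unseen, ] <- matrix(stats::rnorm(length(unseen) * d, sd = 0.5 / d),
                            length(unseen), d)
  }
  rownames(vec) <- vocab
  structure(list(k = as.integer(k), d = as.integer(d), vocabulary = vocab,
                 vectors = vec, null_vector = numeric(d),
                 window = as.integer(window), negative = as.integer(negative),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "lncloc_embeddings")
}

# save/restore the global RNG state without disturbing user code
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lncloc_embeddings <- function(x, ...) {
  cat(sprintf("<lncloc_embeddings> %d-mers, d = %d (+ null vector)\n",
              x$k, x$d))
  invisible(x)
}

#' Build the subsequence-embedding tensor for one record
#'
#' Row `p` of the result is the arithmetic mean of the embedding vectors of
#' the overlapping k-mers lying inside bin `p` of the layout; k-mers
#' containing N contribute the zero null vector and are counted in the
#' denominator. Masked (padding) rows are exactly zero.
#'
#' @param record A sequence record.
#' @param layout Its [split_subsequences()] layout.
#' @param table An `lncloc_embeddings` table.
#' @return List with `values` (`n_max x d` matrix), `mask`, `layout`.
#' @export
embed_sequence <- function(record, layout, table) {
  C <- bin_kmer_matrix(record, layout, table$k)
  E <- rbind(table$vectors, 0)       # last row = null vector
  values <- as.matrix(C %*% E)
  dimnames(values) <- NULL
  list(values = values, mask = layout$mask, layout = layout)
}

# Sparse n_max x (4^k + 1) matrix of per-bin k-mer proportions; column
# 4^k + 1 collects null k-mers (frozen zero vector). values = C %*% E.
bin_kmer_matrix <- function(record, layout, k) {
  km <- extract_kmers(substr(record$sequence, 1L, layout$length), k)
  ids <- kmer_ids(km, k)
  null_id <- 4L^k + 1L
  ids[is.na(ids)] <- null_id
  # k-mer starting at 0-based position s belongs to the bin containing s
  pos <- seq_along(ids) - 1L
  bin <- findInterval(pos, layout$starts)    # 1-based bin index
  keep <- bin <= layout$n_eff                # k-mers spilling past last bin boundary
  # every k-mer starts inside some bin; k-mers near a bin's right edge
  # overlap the next bin but are assigned to their start bin
  counts <- Matrix::sparseMatrix(i = bin[keep], j = ids[keep], x = 1,
                                 dims = c(layout$n_max, null_id))
  tot <- Matrix::rowSums(counts)
  tot[tot == 0] <- 1
  Matrix::Diagonal(x = 1 / tot) %*% counts
}

#' Serialize an embedding table
#'
#' Writes the word2vec text format (header `V d`, then one `kmer v1 ... vd`
#' line per k-mer) plus a JSON sidecar `<path>.json` recording
#' `{k, d, seed, window, negative, epochs}`.
#'
#' @param table An `lncloc_embeddings` table.
#' @param path Output path for the vector table.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$d), con)
  writeLines(paste(rownames(table$vectors),
                   apply(table$vectors, 1L, function(v)
                     paste(formatC(v, format = "g", digits = 17), collapse = " "))),
             con)
  jsonlite::write_json(table[c("k", "d", "seed", "window", "negative", "epochs")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an embedding table written by [write_embeddings()]
#'
#' @param path Path to the vector table (expects the `<path>.json` sidecar).
#' @return An `lncloc_embeddings` table.
#' @export
read_embeddings <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path)
  header <- as.integer(strsplit(lines[1L], " ")[[1]])
  parts <- strsplit(lines[-1L], " ")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(header[2L])))
  rownames(vec) <- vocab
  structure(list(k = meta$k, d = meta$d, vocabulary = vocab, vectors = vec,
                 null_vector = numeric(meta$d), window = meta$window,
                 negative = meta$negative, epochs = meta$epochs,
                 seed = meta$seed),
            class = "lncloc_embeddings")
}
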