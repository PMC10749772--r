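# Seeded generator of multi-label sequence datasets with label-specific
# planted motifs and recorded ground-truth coordinates. It emulates the
# sequence-determinant structure the model is meant to learn (compartment-
# specific short motifs recurring in localized transcripts) on an i.i.d.
# background; it is the package's stand-in for a curated localization corpus.

#' Synthetic dataset configuration
#'
#' @param n_samples Number of sequences.
#' @param length_range Uniform sequence-length range in nucleotides.
#' @param background Nucleotide sampling weights for A, C, G, T.
#' @param label_motifs Named list label -> single IUPAC pattern planted for
#'   that label. The nucleus and cytoplasm defaults are literature motifs
#'   (AGCCC, RCCTCCC); the chromatin and insoluble-cytoplasm defaults are
#'   arbitrary fixture 6-mers chosen to be mutually non-matching.
#' @param label_marginals Independent inclusion probability per label.
#' @param copies_per_label Planted occurrences per active label.
#' @param seed Integer seed.
#' @return Object of class `lncloc_synth_config`.
#' @export
synthetic_config <- function(n_samples = 100L,
                             length_range = c(300L, 3000L),
                             background = c(A = 1, C = 1, G = 1, T = 1),
                             label_motifs = list(
                               nucleus = "AGCCC",
                               cytoplasm = "RCCTCCC",
                               chromatin = "TGGAAT",
                               insoluble_cytoplasm = "CACGTG"),
                             label_marginals = c(0.6, 0.5, 0.2, 0.15),
                             copies_per_label = 3L, seed = 1L) {
  if (any(label_marginals <= 0) || any(label_marginals > 1))
    stop("label_marginals must lie in (0, 1]")
  maxpat <- max(nchar(unlist(label_motifs)))
  if (length_range[1L] < copies_per_label * maxpat * 4L)
    stop("minimum length too short for non-overlapping motif placement")
  structure(list(n_samples = as.integer(n_samples),
                 length_range = as.integer(length_range),
                 background = background / sum(background),
                 label_motifs = label_motifs,
                 label_marginals = label_marginals,
                 copies_per_label = as.integer(copies_per_label),
                 seed = as.integer(seed)),
            class = "lncloc_synth_config")
}

# rejection-resampled independent label draws: at least one active label
sample_labels <- function(marginals) {
  repeat {
    yv <- as.integer(stats::runif(length(marginals)) < marginals)
    if (sum(yv) > 0L) return(yv)
  }
}

#' Plant an IUPAC motif into a sequence
#'
#' Degenerate codes are resolved uniformly at random (R becomes A or G);
#' characters are written in place at a 0-based position. Overlap with a
#' previously planted span is an error.
#'
#' @param sequence Character string.
#' @param pattern IUPAC pattern.
#' @param position 0-based start.
#' @param occupied Optional two-column matrix of existing 0-based half-open
#'   spans to collide against.
#' @return List with the modified `sequence` and the realized `insert`.
#' @export
plant_motif <- function(sequence, pattern, position, occupied = NULL) {
  w <- nchar(pattern)
  if (position + w > nchar(sequence))
    stop("motif does not fit at position ", position)
  if (!is.null(occupied) && nrow(occupied) &&
      any(position < occupied[, 2L] & position + w > occupied[, 1L]))
    stop("overlap with an existing planted motif at position ", position)
  sets <- IUPAC_SETS[strsplit(toupper(chartr("U", "T", pattern)), "")[[1]]]
  if (anyNA(sets)) stop("invalid IUPAC character in pattern ", pattern)
  insert <- paste(vapply(strsplit(sets, ""), function(ch)
    ch[sample.int(length(ch), 1L)], character(1)), collapse = "")
  substr(sequence, position + 1L, position + w) <- insert
  list(sequence = sequence, insert = insert)
}

#' Generate a synthetic planted-motif dataset
#'
#' For each sample: draw a length uniformly, an i.i.d. background sequence,
#' an active-label set from the marginals (resampled until non-empty), and
#' plant `copies_per_label` non-overlapping occurrences of each active
#' label's motif at uniform positions. Ground-truth motif coordinates are
#' recorded per record and label. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `lncloc_dataset`: list with `records`, `labels`
#'   (binary matrix), `truth` (id -> label -> matrix of 0-based half-open
#'   intervals), and `config`.
#' @export
lncloc_simulate <- function(config = synthetic_config()) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  labs <- names(config$label_motifs)
  records <- vector("list", config$n_samples)
  y <- matrix(0L, config$n_samples, length(labs),
              dimnames = list(NULL, labs))
  truth <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    L <- sample(config$length_range[1L]:config$length_range[2L], 1L)
    seqc <- paste(sample(names(config$background), L, replace = TRUE,
                         prob = config$background), collapse = "")
    yv <- sample_labels(config$label_marginals)
    occupied <- matrix(integer(0), 0L, 2L)
    tr <- list()
    for (j in which(yv == 1L)) {
      pat <- config$label_motifs[[j]]
      w <- nchar(pat)
      spans <- matrix(integer(0), 0L, 2L)
      for (cp in seq_len(config$copies_per_label)) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          pos <- sample.int(L - w + 1L, 1L) - 1L
          if (!nrow(occupied) ||
              !any(pos < occupied[, 2L] & pos + w > occupied[, 1L])) {
            res <- plant_motif(seqc, pat, pos, occupied = NULL)
            seqc <- res$sequence
            occupied <- rbind(occupied, c(pos, pos + w))
            spans <- rbind(spans, c(pos, pos + w))
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place motif ", pat, " without overlap; ",
               "sequence too short for the requested copies")
      }
      tr[[labs[j]]] <- spans[order(spans[, 1L]), , drop = FALSE]
    }
    id <- sprintf("synth_%04d", i)
    records[[i]] <- new_record(id, seqc)
    y[i, ] <- yv
    truth[[i]] <- tr
  }
  rownames(y) <- vapply(records, `[[`, character(1), "id")
  names(truth) <- rownames(y)
  structure(list(records = records, labels = y, truth = truth,
                 config = config),
            class = "lncloc_dataset")
}

#' @export
print.lncloc_dataset <- function(x, ...) {
  cat(sprintf("<lncloc_dataset> %d sequences (%d-%d nt), labels: %s\n",
              length(x$records), x$config$length_range[1L],
              x$config$length_range[2L],
              paste(colnames(x$labels), colSums(x$labels), collapse = ", ")))
  invisible(x)
}

#' Write a dataset as plain-text fixture files
#'
#' Emits `sequences.fasta`, `labels.tsv` (binary columns) and `truth.json`
#' (id -> label -> list of 0-based half-open intervals) into a directory.
#'
#' @param dataset An `lncloc_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "sequences.fasta")
  tsv <- file.path(out_dir, "labels.tsv")
  js <- file.path(out_dir, "truth.json")
  write_fasta(dataset$records, fa)
  write_labels(dataset$labels, tsv)
  truth <- lapply(dataset$truth, function(tr)
    lapply(tr, function(m) lapply(seq_len(nrow(m)),
                                  function(r) as.integer(m[r, ]))))
  jsonlite::write_json(truth, js, auto_unbox = FALSE)
  invisible(c(fasta = fa, labels = tsv, truth = js))
}

#' Occurrence-count scanning baseline
#'
#' A trivial per-label classifier: predict a label active when its motif
#' occurs at least `copies` times in the sequence. Used to certify that a
#' generated dataset carries learnable signal.
#'
#' @param dataset An `lncloc_dataset`.
#' @param copies Count threshold (default the config's `copies_per_label`).
#' @return Binary call matrix shaped like `dataset$labels`.
#' @export
scan_classifier <- function(dataset, copies = NULL) {
  if (is.null(copies)) copies <- dataset$config$copies_per_label
  labs <- colnames(dataset$labels)
  calls <- vapply(labs, function(lab) {
    pat <- dataset$config$label_motifs[[lab]]
    vapply(dataset$records, function(r)
      as.integer(nrow(match_iupac(r$sequence, pat)) >= copies), integer(1))
  }, integer(length(dataset$records)))
  dimnames(calls) <- dimnames(dataset$labels)
  calls
}
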