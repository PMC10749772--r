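#' Canonical compartment labels
#'
#' The four subcellular compartments predicted by the model, in the fixed
#' column order used by every label matrix in the package.
#'
#' @return Character vector of length four.
#' @export
lncloc_labels <- function() {
  c("nucleus", "cytoplasm", "chromatin", "insoluble_cytoplasm")
}

#' Canonicalize a nucleotide string
#'
#' Uppercases, strips whitespace, maps U to T (the package works in a single
#' DNA-style alphabet whether users paste RNA or DNA), and maps every other
#' character outside \{A,C,G,T\} to N. Total and idempotent.
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of canonical sequences over \{A,C,G,T,N\}.
#' @export
#' @examples
#' canonicalize("augc")   # "ATGC"
#' canonicalize("ACGXN")  # "ACGNN"
canonicalize <- function(raw) {
  s <- toupper(gsub("[[:space:]]+", "", as.character(raw)))
  s <- chartr("U", "T", s)
  gsub("[^ACGT]", "N", s)
}

new_record <- function(id, sequence) {
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "lncloc_record")
}

#' @export
print.lncloc_record <- function(x, ...) {
  cat(sprintf("<lncloc_record> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

#' Read lncRNA sequences from a FASTA file
#'
#' Sequences are canonicalized on input (see [canonicalize()]); identifiers
#' are the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param min_length Minimum canonical length accepted; records shorter than
#'   this (default `k = 3`, the k-mer size) are an error.
#' @return A list of records, each with fields `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path, min_length = 3L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence identifiers: ", paste(dup, collapse = ", "))
  seqs <- canonicalize(as.character(set))
  short <- nchar(seqs) < min_length
  if (any(short))
    stop("sequences shorter than ", min_length, " nt: ",
         paste(ids[short], collapse = ", "))
  mapply(new_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA
#'
#' @param records List of sequence records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Truncate a record to a maximum length
#'
#' The model keeps at most `max_len` nucleotides per lncRNA (default 8196)
#' and discards the 3' remainder.
#'
#' @param record A sequence record.
#' @param max_len Maximum retained length in nucleotides.
#' @return The (possibly truncated) record.
#' @export
truncate_record <- function(record, max_len = 8196L) {
  if (record$length <= max_len) return(record)
  new_record(record$id, substr(record$sequence, 1L, max_len))
}

#' Partition a sequence into consecutive subsequence bins
#'
#' Splits the first `L` nucleotides of a record into
#' `n_eff = min(n_max, floor(L / k))` consecutive, non-overlapping bins whose
#' lengths differ by at most one (the longer bins come first), so that every
#' bin yields at least one k-mer. Layouts shorter than `n_max` are padded
#' with masked positions.
#'
#' @param record A sequence record (or a single integer length).
#' @param n_max Number of model positions (default 512).
#' @param k k-mer size; every bin is at least `k` long.
#' @return An object of class `lncloc_layout` with fields `starts`, `ends`
#'   (0-based half-open bin intervals), `n_eff`, `n_max`, `mask`, `length`.
#' @export
split_subsequences <- function(record, n_max = 512L, k = 3L) {
  L <- if (is.numeric(record)) as.integer(record) else record$length
  if (L < k) stop("sequence too short: length ", L, " < k = ", k)
  n_eff <- min(as.integer(n_max), L %/% as.integer(k))
  base <- L %/% n_eff
  extra <- L %% n_eff           # first `extra` bins are one longer
  lens <- rep(base, n_eff)
  if (extra > 0L) lens[seq_len(extra)] <- base + 1L
  ends <- cumsum(lens)
  structure(list(starts = c(0L, ends[-n_eff]), ends = as.integer(ends),
                 n_eff = n_eff, n_max = as.integer(n_max),
                 mask = seq_len(n_max) <= n_eff, length = L),
            class = "lncloc_layout")
}

#' @export
print.lncloc_layout <- function(x, ...) {
  cat(sprintf("<lncloc_layout> %d nt in %d/%d bins (%d-%d nt each)\n",
              x$length, x$n_eff, x$n_max,
              min(x$ends - x$starts), max(x$ends - x$starts)))
  invisible(x)
}

#' Read a multi-label annotation table
#'
#' Accepts two tab-separated layouts, both with a header line:
#' one binary 0/1 column per label
#' (`id<TAB>nucleus<TAB>cytoplasm<TAB>chromatin<TAB>insoluble_cytoplasm`), or
#' a two-column form `id<TAB>labels` where `labels` is a comma-separated list
#' of label names.
#'
#' @param path Path to the TSV file.
#' @param label_names Ordered label set (default [lncloc_labels()]).
#' @param ids Optional character vector of sequence ids that must cover the
#'   table (unknown ids are an error when supplied).
#' @return Binary integer matrix with one row per table row (rownames = ids)
#'   and one column per label.
#' @export
read_labels <- function(path, label_names = lncloc_labels(), ids = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stop("no rows in label file: ", path)
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate ids in label file: ",
         paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
  M <- length(label_names)
  binary_form <- all(label_names %in% colnames(tab))
  if (!binary_form && ncol(tab) != 2L)
    stop("label file must have one 0/1 column per label or an `id<TAB>labels` pair")
  if (!binary_form) {
    y <- matrix(0L, nrow(tab), M, dimnames = list(tab[[1L]], label_names))
    for (i in seq_len(nrow(tab))) {
      given <- trimws(strsplit(tab[[2L]][i], ",")[[1]])
      given <- given[nzchar(given)]
      bad <- setdiff(given, label_names)
      if (length(bad))
        stop("unknown label name(s) for id ", tab[[1L]][i], ": ",
             paste(bad, collapse = ", "))
      y[i, given] <- 1L
    }
  } else {
    missing_cols <- setdiff(label_names, colnames(tab))
    if (length(missing_cols))
      stop("label file lacks column(s): ", paste(missing_cols, collapse = ", "))
    y <- vapply(label_names, function(l) as.integer(tab[[l]]), integer(nrow(tab)))
    y <- matrix(y, nrow = nrow(tab), dimnames = list(tab[[1L]], label_names))
    if (any(is.na(y)) || any(!y %in% c(0L, 1L)))
      stop("label columns must be binary 0/1")
  }
  if (!is.null(ids)) {
    unknown <- setdiff(rownames(y), ids)
    if (length(unknown))
      stop("label ids absent from the sequence set: ",
           paste(unknown, collapse = ", "))
  }
  y
}

#' Write a binary label matrix as TSV
#'
#' @param labels Binary matrix with rownames (ids) and label colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(id = rownames(labels), labels, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
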