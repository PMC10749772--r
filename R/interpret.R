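# Attention-threshold interpretation: positions whose label-wise attention
# exceeds the uniform expectation 1/n_eff are flagged, mapped back to
# nucleotide intervals through the subsequence layout, merged, scanned for
# IUPAC motifs, and optionally exported as MEME-ready FASTA.

#' Attention flagging threshold
#'
#' The expectation of a uniform attention distribution over the `n_eff`
#' real positions: `1 / n_eff`. Positions are flagged only when their
#' weight strictly exceeds it, so uniform attention flags nothing.
#'
#' @param n_eff Number of unmasked attention positions.
#' @return Scalar threshold.
#' @export
attention_threshold <- function(n_eff) {
  if (n_eff < 1) stop("n_eff must be >= 1")
  1 / n_eff
}

#' Flag attention positions above threshold
#'
#' @param alpha_j Attention weight vector (one label's row; zero on masked
#'   positions).
#' @param threshold Flagging threshold (strict inequality).
#' @param mask Optional validity vector; masked positions are never flagged.
#' @return Logical vector of flags.
#' @export
flag_positions <- function(alpha_j, threshold, mask = NULL) {
  fl <- alpha_j > threshold
  if (!is.null(mask)) fl <- fl & mask
  fl
}

#' Map flagged positions to nucleotide regions
#'
#' Each flagged subsequence position contributes its bin interval; touching
#' or adjacent intervals are merged (gap tolerance 0 by default).
#'
#' @param flags Logical vector of length `n_max` (or `n_eff`).
#' @param layout The record's [split_subsequences()] layout.
#' @param gap Maximum gap (in nucleotides) across which regions are still
#'   merged.
#' @return Data frame with 0-based half-open `start`, `end` columns, sorted
#'   and disjoint.
#' @export
regions_from_flags <- function(flags, layout, gap = 0L) {
  idx <- which(flags[seq_len(layout$n_eff)])
  if (!length(idx))
    return(data.frame(start = integer(0), end = integer(0)))
  st <- layout$starts[idx]
  en <- layout$ends[idx]
  keep_start <- c(TRUE, st[-1L] > en[-length(en)] + gap)
  grp <- cumsum(keep_start)
  data.frame(start = as.integer(tapply(st, grp, min)),
             end = as.integer(tapply(en, grp, max)), row.names = NULL)
}

IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for an IUPAC motif
#'
#' All (possibly overlapping) matches of a degenerate IUPAC pattern
#' (e.g. R = A/G) against a canonical sequence, as 0-based half-open
#' intervals. An N in the sequence matches only an N in the pattern.
#'
#' @param sequence Canonical nucleotide string.
#' @param pattern IUPAC pattern string.
#' @return Data frame with `start`, `end`, `match` columns.
#' @export
match_iupac <- function(sequence, pattern) {
  pat <- toupper(chartr("U", "T", pattern))
  bad <- setdiff(strsplit(pat, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  empty <- data.frame(start = integer(0), end = integer(0),
                      match = character(0))
  if (nchar(sequence) < nchar(pat)) return(empty)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                Biostrings::DNAString(sequence),
                                fixed = "subject")
  if (length(m) == 0L) return(empty)
  data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
             match = as.character(m))
}

#' Default label-to-motif library
#'
#' Literature motifs for the nucleus compartment (the AGCCC nuclear
#' localization signal and the repeated RCCTCCC element); the other
#' compartments carry no documented motifs and default to empty.
#'
#' @return Named list of IUPAC pattern vectors.
#' @export
default_motif_library <- function() {
  list(nucleus = c("AGCCC", "RCCTCCC"), cytoplasm = character(0),
       chromatin = character(0), insoluble_cytoplasm = character(0))
}

#' Interpret per-label attention as regions and motif hits
#'
#' For every prediction and label: threshold the attention row at
#' `1 / n_eff`, map flagged positions to merged nucleotide regions, scan
#' each region for the label's library motifs, and optionally export all
#' flagged-region subsequences as MEME-ready FASTA (a JSON sidecar records
#' the suggested motif width 9 and E-value cut-off 0.05).
#'
#' @param results List of prediction results (from [predict.lncloc_fit()] or
#'   [lncloc_forward()]); each must carry `label_attention` and `layout`.
#' @param records The matching list of sequence records.
#' @param motif_library Named list label -> IUPAC patterns (default
#'   [default_motif_library()]).
#' @param labels Label names (default taken from attention rownames order of
#'   the library).
#' @param active_only Restrict to labels called positive (default `FALSE`:
#'   all labels reported).
#' @param meme_fasta Optional path; when given, flagged-region subsequences
#'   are written there in FASTA plus a `.json` sidecar.
#' @param gap Region-merge gap tolerance in nucleotides.
#' @return List with data frames `regions` (id, label, start, end,
#'   mean_attention) and `hits` (id, label, pattern, start, end, match), and
#'   `meme_fasta` (path or `NULL`).
#' @export
interpret_predictions <- function(results, records,
                                  motif_library = default_motif_library(),
                                  labels = lncloc_labels(),
                                  active_only = FALSE, meme_fasta = NULL,
                                  gap = 0L) {
  if (!is.null(results$probabilities)) results <- list(results)
  if (!is.null(records$id)) records <- list(records)
  stopifnot(length(results) == length(records))
  regions <- list(); hits <- list(); export <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]; rec <- records[[i]]
    if (is.null(res$label_attention))
      stop("no attention available: the model was trained without ",
           "localization-specific attention")
    layout <- res$layout
    thr <- attention_threshold(layout$n_eff)
    for (j in seq_len(nrow(res$label_attention))) {
      lab <- labels[j]
      if (active_only && res$calls[j] == 0L) next
      fl <- flag_positions(res$label_attention[j, ], thr, layout$mask)
      reg <- regions_from_flags(fl, layout, gap = gap)
      if (!nrow(reg)) next
      att <- res$label_attention[j, seq_len(layout$n_eff)]
      reg$mean_attention <- vapply(seq_len(nrow(reg)), function(r) {
        inb <- layout$starts >= reg$start[r] & layout$ends <= reg$end[r]
        mean(att[inb & fl[seq_len(layout$n_eff)]])
      }, numeric(1))
      reg <- data.frame(id = rec$id, label = lab, reg)
      regions[[length(regions) + 1L]] <- reg
      for (r in seq_len(nrow(reg))) {
        sub <- substr(rec$sequence, reg$start[r] + 1L, reg$end[r])
        export[[length(export) + 1L]] <-
          list(id = sprintf("%s|%s|%d-%d", rec$id, lab, reg$start[r],
                            reg$end[r]),
               seq = sub)
        for (pat in motif_library[[lab]]) {
          mh <- match_iupac(sub, pat)
          if (nrow(mh))
            hits[[length(hits) + 1L]] <-
              data.frame(id = rec$id, label = lab, pattern = pat,
                         start = mh$start + reg$start[r],
                         end = mh$end + reg$start[r], match = mh$match)
        }
      }
    }
  }
  empty_r <- data.frame(id = character(0), label = character(0),
                        start = integer(0), end = integer(0),
                        mean_attention = numeric(0))
  empty_h <- data.frame(id = character(0), label = character(0),
                        pattern = character(0), start = integer(0),
                        end = integer(0), match = character(0))
  regions <- if (length(regions)) do.call(rbind, regions) else empty_r
  hits <- if (length(hits)) do.call(rbind, hits) else empty_h
  if (!is.null(meme_fasta) && length(export)) {
    recs <- lapply(export, function(e) new_record(e$id, e$seq))
    write_fasta(recs, meme_fasta)
    jsonlite::write_json(list(motif_width = 9L, evalue = 0.05,
                              n_regions = length(export)),
                         paste0(meme_fasta, ".json"), auto_unbox = TRUE)
  } else meme_fasta <- NULL
  list(regions = regions, hits = hits, meme_fasta = meme_fasta)
}

#' Attention enrichment over planted motifs
#'
#' For every (record, active label) pair of a synthetic dataset with known
#' planted-motif coordinates, compares the attention-threshold flag rate of
#' nucleotides inside the planted motifs with the flag rate of all other
#' nucleotides, pooled over the dataset. An enrichment well above 1 means
#' the label-wise attention concentrates on the sequence determinants of
#' that label.
#'
#' @param predictions An `lncloc_predictions` object for `dataset$records`.
#' @param dataset An `lncloc_dataset` with ground-truth motif coordinates.
#' @return List with `motif_flag_rate`, `background_flag_rate`,
#'   `enrichment`, and per-label rates.
#' @export
attention_enrichment <- function(predictions, dataset) {
  labs <- colnames(dataset$labels)
  fm <- m <- fb <- bg <- 0
  per_label <- matrix(0, length(labs), 4,
                      dimnames = list(labs, c("fm", "m", "fb", "bg")))
  for (i in seq_along(predictions$results)) {
    res <- predictions$results[[i]]
    if (is.null(res$label_attention))
      stop("no attention available: the model was trained without ",
           "localization-specific attention")
    tr <- dataset$truth[[res$id]]
    layout <- res$layout
    L <- layout$length
    thr <- attention_threshold(layout$n_eff)
    for (j in seq_along(labs)) {
      if (dataset$labels[res$id, j] != 1L || is.null(tr[[labs[j]]])) next
      fl <- flag_positions(res$label_attention[j, ], thr, layout$mask)
      nt_flag <- rep(fl[seq_len(layout$n_eff)],
                     times = layout$ends - layout$starts)
      motif <- rep(FALSE, L)
      spans <- tr[[labs[j]]]
      for (r in seq_len(nrow(spans))) {
        lo <- min(spans[r, 1L] + 1L, L)
        motif[lo:min(spans[r, 2L], L)] <- TRUE
      }
      upd <- c(sum(nt_flag & motif), sum(motif),
               sum(nt_flag & !motif), sum(!motif))
      per_label[j, ] <- per_label[j, ] + upd
      fm <- fm + upd[1]; m <- m + upd[2]; fb <- fb + upd[3]; bg <- bg + upd[4]
    }
  }
  mr <- fm / m; br <- fb / bg
  list(motif_flag_rate = mr, background_flag_rate = br,
       enrichment = mr / br,
       per_label = data.frame(
         label = labs,
         motif_rate = per_label[, "fm"] / pmax(per_label[, "m"], 1),
         background_rate = per_label[, "fb"] / pmax(per_label[, "bg"], 1),
         row.names = NULL))
}
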