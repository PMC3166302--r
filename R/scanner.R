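# Sequence scanning: log-odds scoring of fixed-width windows under a PWM
# or TPWM against an order-0 background, one best hit per sequence, and
# negative-set cutoff calibration at a target false positive rate.

#' Order-0 background model for log-odds scoring
#'
#' @param probs Length-4 nucleotide probabilities in `A,C,G,T` order, all
#'   strictly positive and summing to 1.  Default uniform.
#' @return An object of class `background_model`.
#' @export
background_model <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L || any(probs <= 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("background probabilities must be 4 positive values summing to 1",
         call. = FALSE)
  }
  structure(list(probs = setNames(probs, DNA_LETTERS)),
            class = "background_model")
}

#' Background estimated from sequence composition
#'
#' Pools the mononucleotide counts of a set of sequences (typically the
#' negative set); letters outside ACGT are ignored.  A pseudocount of 1
#' per letter keeps all probabilities positive.
#'
#' @param sequences Character vector of DNA sequences.
#' @return A [background_model()].
#' @export
background_from_sequences <- function(sequences) {
  codes <- unlist(lapply(sequences, seq_to_int), use.names = FALSE)
  counts <- tabulate(codes[codes > 0L], nbins = 4L) + 1
  background_model(counts / sum(counts))
}

as_background <- function(background) {
  if (is.null(background)) background_model() else background
}

#' Log-odds score of one motif-width word
#'
#' `log2( P(word | model) / prod_i background(word_i) )` in bits, where the
#' model probability is the column product for a plain PWM and
#' [composite_probability()] for a TPWM.
#'
#' @param model A `pwm` or `tpwm`.
#' @param word ACGT string of the model width.
#' @param background A [background_model()]; default uniform.
#' @return Score in bits (`-Inf` when the model probability is 0).
#' @export
score_window <- function(model, word, background = NULL) {
  background <- as_background(background)
  codes <- check_word(word, model$width)
  log2(composite_probability(model, word)) -
    sum(log2(background$probs[codes]))
}

#' Best-scoring window of each sequence
#'
#' Scans every offset of every sequence (and, by default, the
#' reverse-complement reading of every window) and keeps the single
#' best-scoring window per sequence, mirroring the modelling assumption
#' that a bound sequence contains at most one site.  Ties are broken
#' toward the smaller start, then the forward strand.  Windows containing
#' letters outside ACGT are skipped.
#'
#' @param model A `pwm` or `tpwm`.
#' @param sequences Character vector of DNA sequences, each at least as
#'   long as the model width.  Names, if present, become `sequence_id`.
#' @param background A [background_model()]; default uniform.
#' @param both_strands Scan reverse-complement windows too (default TRUE;
#'   ChIP-Seq peaks are unstranded).
#' @return A data.frame with one row per sequence: `sequence_id`, `start`
#'   (0-based forward-strand offset), `strand` (`"+"`/`"-"`, `NA` if no
#'   valid window), `score` (bits), `word` (the matched string in motif
#'   orientation).
#' @export
best_hits <- function(model, sequences, background = NULL,
                      both_strands = TRUE) {
  codes <- lapply(sequences, seq_to_int)
  res <- scan_codes(model, codes, as_background(background), both_strands)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  hit <- res$strand > 0L
  W <- model$width
  word <- rep(NA_character_, length(sequences))
  word[hit] <- hit_words(sequences[hit], res$start[hit], res$strand[hit], W)
  data.frame(sequence_id = ids,
             start = ifelse(hit, res$start, NA_integer_),
             strand = c(NA_character_, "+", "-")[res$strand + 1L],
             score = res$score, word = word,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Scan pre-encoded sequences (list of integer code vectors); the training
# loop caches the encodings across its many scan passes.
scan_codes <- function(model, codes, background, both_strands) {
  W <- model$width
  lens <- lengths(codes)
  if (any(lens < W)) {
    stop(sprintf("sequence %d is shorter (%d) than the model width (%d)",
                 which(lens < W)[1L], min(lens), W), call. = FALSE)
  }
  paths <- tpwm_paths(model)
  scan_best_cpp(codes, paths$mats, paths$weights,
                as.numeric(background$probs), both_strands)
}

# Matched words in motif orientation for hit rows (strand 1 = +, 2 = -).
hit_words <- function(sequences, start, strand, W) {
  w <- toupper(substr(sequences, start + 1L, start + W))
  rev <- strand == 2L
  if (any(rev)) w[rev] <- vapply(w[rev], revcomp_word, "", USE.NAMES = FALSE)
  w
}

#' @rdname best_hits
#' @param sequence A single DNA sequence string.
#' @return `best_hit()` returns a one-row data.frame, or `NULL` when every
#'   window of the sequence is invalidated by non-ACGT letters.
#' @export
best_hit <- function(model, sequence, background = NULL,
                     both_strands = TRUE) {
  h <- best_hits(model, sequence, background = background,
                 both_strands = both_strands)
  if (is.na(h$strand[1L])) return(NULL)
  h
}

#' Score cutoff at a target false positive rate
#'
#' Given the best-hit scores of the negative set, chooses the cutoff that
#' flags `k = floor(r * m)` negative sequences, i.e. the k-th largest
#' score; classification everywhere in the package uses `score >= cutoff`.
#' With `k = 0` the cutoff is placed above the largest negative score and
#' nothing is flagged.  Tied scores at the cutoff can push the empirical
#' rate above `r`; the realized rate is recorded, not hidden.
#'
#' @param neg_best_scores Numeric best-hit scores of the negative
#'   sequences (`NA`, from sequences without a valid window, is treated as
#'   `-Inf`).
#' @param r Target false positive rate in `(0, 1]`.
#' @return An object of class `cutoff_result`: list with `fpr_requested`,
#'   `cutoff`, `fpr_empirical` and `k` (number of negatives at/above the
#'   cutoff).
#' @export
cutoff_at_fpr <- function(neg_best_scores, r) {
  if (length(neg_best_scores) == 0L) {
    stop("no negative scores supplied", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    stop("false positive rate r must lie in (0, 1]", call. = FALSE)
  }
  scores <- as.numeric(neg_best_scores)
  scores[is.na(scores)] <- -Inf
  m <- length(scores)
  k <- floor(r * m + 1e-9)
  if (k == 0) {
    top <- max(scores)
    cutoff <- if (is.finite(top)) top + 1e-6 else 0
  } else {
    cutoff <- sort(scores, decreasing = TRUE)[k]
  }
  structure(list(fpr_requested = r, cutoff = cutoff,
                 fpr_empirical = mean(scores >= cutoff),
                 k = sum(scores >= cutoff)),
            class = "cutoff_result")
}

#' Write hits as BED-like TSV
#'
#' Six columns, 0-based half-open: sequence_id, start, end, name (the
#' matched word), score, strand.  Rows without a hit are dropped.
#'
#' @param hits Data.frame from [best_hits()].
#' @param width Motif width (used for the end coordinate).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, width, path) {
  h <- hits[!is.na(hits$strand), , drop = FALSE]
  out <- data.frame(h$sequence_id, h$start, h$start + width, h$word,
                    h$score, h$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
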