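# Internal constructor: probs is a 4 x width matrix (rows A,C,G,T) whose
# columns each sum to 1; counts (same shape, or NULL) records provenance.
new_pwm <- function(probs, counts = NULL, pseudocount = 0) {
  dimnames(probs) <- list(DNA_LETTERS, NULL)
  if (!is.null(counts)) dimnames(counts) <- list(DNA_LETTERS, NULL)
  structure(list(width = ncol(probs), probs = probs, counts = counts,
                 pseudocount = pseudocount),
            class = "pwm")
}

validate_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"), x$width >= 1L)
  cs <- colSums(x$probs)
  if (any(abs(cs - 1) > 1e-9) || any(x$probs < 0) || any(x$probs > 1)) {
    stop("invalid PWM: columns must be probability distributions",
         call. = FALSE)
  }
  invisible(x)
}

#' Estimate a position weight matrix from aligned sites
#'
#' Counts nucleotides per motif position and converts them to column
#' probabilities with an additive pseudocount: position `i`, letter `a`
#' receives `(n_i(a) + pc) / (n + 4 pc)` where `n` is the number of sites.
#'
#' @param sites A [site_alignment()] (or character vector of equal-length
#'   ACGT words, which is coerced).
#' @param pseudocount Non-negative real added to every cell before
#'   normalization.  Default 0.5.
#' @return A `pwm` object: `probs` is a 4 x width matrix (rows `A,C,G,T`),
#'   `counts` holds the raw per-position counts.
#' @examples
#' estimate_pwm(site_alignment(c("AA", "AC", "CA", "CC")), pseudocount = 1)
#' @export
estimate_pwm <- function(sites, pseudocount = 0.5) {
  if (!inherits(sites, "site_alignment")) sites <- site_alignment(sites)
  stopifnot(pseudocount >= 0)
  m <- sites_to_int(sites)
  counts <- vapply(seq_len(sites$width),
                   function(j) tabulate(m[, j], nbins = 4L),
                   numeric(4L))
  probs <- (counts + pseudocount) / (sites$count + 4 * pseudocount)
  new_pwm(probs, counts = counts, pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat(sprintf("pwm: width %d%s\n", x$width,
              if (!is.null(x$counts))
                sprintf(" (from %.0f sites, pseudocount %g)",
                        sum(x$counts[, 1L]), x$pseudocount) else ""))
  print(round(x$probs, digits))
  invisible(x)
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps complementary rows (A with T, C with
#' G), yielding the matrix describing the same motif read on the opposite
#' strand.
#'
#' @param pwm A `pwm` object.
#' @return A `pwm` object of the same width.
#' @export
reverse_complement_pwm <- function(pwm) {
  validate_pwm(pwm)
  flip <- function(m) m[DNA_COMPLEMENT, rev(seq_len(ncol(m))), drop = FALSE]
  new_pwm(flip(pwm$probs),
          counts = if (!is.null(pwm$counts)) flip(pwm$counts),
          pseudocount = pwm$pseudocount)
}

#' Consensus word of a PWM
#'
#' @param pwm A `pwm` object.
#' @return The string of per-column most probable letters (ties broken in
#'   `A<C<G<T` order).
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_LETTERS[apply(pwm$probs, 2L, which.max)], collapse = "")
}
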