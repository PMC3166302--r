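# Pairwise dependency between motif positions.
#
# For positions i and j the statistic is the L1 distance between the joint
# dinucleotide distribution and the product of the marginals,
#   D(i,j) = sum_{a,b} | p_ij(a,b) - p_i(a) p_j(b) |,
# estimated from raw site frequencies (no pseudocount, so that an observed
# zero stays a zero).  D is 0 for independent columns and attains its
# maximum 1.5 for uniformly distributed, perfectly correlated columns.

#' Pairwise position dependency statistic
#'
#' L1 distance between the empirical joint distribution of the nucleotides
#' at two motif positions and the product of the two marginal distributions.
#' Larger values indicate stronger dependency; the statistic lies in
#' `[0, 1.5]`.
#'
#' @param sites A [site_alignment()].
#' @param i,j Distinct 1-based motif positions.
#' @return Non-negative scalar `D(i, j)`; symmetric in `i` and `j`.
#' @examples
#' pairwise_dependency(site_alignment(c("AA", "AA", "CC", "CC")), 1, 2)
#' @export
pairwise_dependency <- function(sites, i, j) {
  if (!inherits(sites, "site_alignment")) sites <- site_alignment(sites)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("positions i and j must differ", call. = FALSE)
  if (i < 1L || j < 1L || i > sites$width || j > sites$width) {
    stop("positions out of range 1..", sites$width, call. = FALSE)
  }
  m <- sites_to_int(sites)
  dep_pair_counts(m[, i], m[, j])
}

# D from two integer code vectors.
dep_pair_counts <- function(x, y) {
  n <- length(x)
  joint <- tabulate((x - 1L) * 4L + y, nbins = 16L) / n
  px <- tabulate(x, nbins = 4L) / n
  py <- tabulate(y, nbins = 4L) / n
  # joint index order: (a-1)*4 + b, i.e. b varies fastest
  prod <- as.vector(t(outer(px, py)))
  sum(abs(joint - prod))
}

#' Dependency matrix and per-position dependency sums
#'
#' Fills the symmetric matrix of [pairwise_dependency()] values for all
#' position pairs, plus the row sums `s[i] = sum_j D(i, j)` that quantify
#' how strongly position `i` depends on the rest of the motif.
#'
#' @param sites A [site_alignment()] of width at least 2.
#' @return An object of class `dep_matrix`: list with `width`, `d`
#'   (width x width symmetric matrix, zero diagonal) and `s` (row sums).
#' @export
dependency_matrix <- function(sites) {
  if (!inherits(sites, "site_alignment")) sites <- site_alignment(sites)
  if (sites$width < 2L) {
    stop("dependency matrix needs width >= 2", call. = FALSE)
  }
  m <- sites_to_int(sites)
  dependency_matrix_int(m)
}

dependency_matrix_int <- function(m, positions = seq_len(ncol(m))) {
  w <- length(positions)
  d <- matrix(0, w, w)
  if (w >= 2L) {
    for (ii in 1:(w - 1L)) {
      for (jj in (ii + 1L):w) {
        v <- dep_pair_counts(m[, positions[ii]], m[, positions[jj]])
        d[ii, jj] <- v
        d[jj, ii] <- v
      }
    }
  }
  structure(list(width = w, positions = positions, d = d, s = rowSums(d)),
            class = "dep_matrix")
}

#' Maximal dependent position
#'
#' The position with the largest dependency sum `s[i]`, restricted to
#' positions that are dependent with at least one other position, i.e. whose
#' largest pairwise value exceeds `threshold`.  Returns `NA` when no
#' position passes the gate, which signals that the alignment shows no
#' significant intra-motif dependency.
#'
#' @param dep A `dep_matrix` from [dependency_matrix()].
#' @param threshold Dependency gate on the L1 scale; a pair `(i, j)` is
#'   called dependent when `d[i, j] > threshold`.
#' @return 1-based motif position, or `NA_integer_` if no position passes.
#'   Ties in `s` are broken toward the lowest position index.
#' @export
maximal_dependent_position <- function(dep, threshold) {
  stopifnot(inherits(dep, "dep_matrix"))
  gate <- apply(dep$d, 1L, max) > threshold
  if (!any(gate)) return(NA_integer_)
  s <- ifelse(gate, dep$s, -Inf)
  dep$positions[which.max(s)]  # which.max takes the first maximum
}
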