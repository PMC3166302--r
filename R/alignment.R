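#' Aligned binding-site set
#'
#' Bundles a set of equal-length, gap-free DNA words (candidate transcription
#' factor binding sites, one per training sequence) into a validated
#' container.  All model estimation in the package starts from such an
#' alignment.
#'
#' @param sites Character vector of equal-length strings over the strict
#'   alphabet `A`, `C`, `G`, `T`.  Ambiguity codes are rejected: a site with
#'   an `N` cannot be attributed to a nucleotide subset during tree building.
#' @return An object of class `site_alignment` with elements `sites`
#'   (character vector), `width` (site length) and `count` (number of sites).
#' @examples
#' aln <- site_alignment(c("ACGT", "ACGG", "ACTT"))
#' aln$width
#' @export
site_alignment <- function(sites) {
  if (length(sites) == 0L) {
    stop("no sites: an alignment needs at least one site", call. = FALSE)
  }
  sites <- toupper(as.character(sites))
  w <- unique(nchar(sites))
  if (length(w) != 1L) {
    stop("sites must all have the same length; saw widths ",
         paste(sort(w), collapse = ", "), call. = FALSE)
  }
  bad <- grep("[^ACGT]", sites)
  if (length(bad) > 0L) {
    s <- sites[bad[1L]]
    p <- regexpr("[^ACGT]", s)
    stop(sprintf("non-ACGT character '%s' in site %d at position %d",
                 substr(s, p, p), bad[1L], p), call. = FALSE)
  }
  structure(list(sites = sites, width = as.integer(w),
                 count = length(sites)),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("site_alignment: %d sites of width %d\n", x$count, x$width))
  show <- utils::head(x$sites, 5L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (x$count > 5L) cat(sprintf("  ... and %d more\n", x$count - 5L))
  invisible(x)
}

# Encode an alignment (or any character vector of equal-length ACGT words)
# as an integer matrix, one row per site, codes 1..4 = A,C,G,T.
sites_to_int <- function(sites) {
  if (inherits(sites, "site_alignment")) sites <- sites$sites
  n <- length(sites)
  w <- nchar(sites[1L])
  m <- matrix(match(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
                    DNA_LETTERS),
              nrow = n, ncol = w, byrow = TRUE)
  m
}

int_to_sites <- function(m) {
  apply(m, 1L, function(r) paste(DNA_LETTERS[r], collapse = ""))
}

# Byte lookup table mapping ASCII codes of A/C/G/T (either case) to 1..4;
# every other letter maps to 0 and later invalidates windows covering it.
SEQ_LUT <- local({
  lut <- integer(256L)
  lut[utf8ToInt("ACGTacgt")] <- rep(1:4, 2L)
  lut
})

# Encode one DNA sequence string as an integer vector of codes 1..4 / 0.
seq_to_int <- function(s) {
  SEQ_LUT[utf8ToInt(s)]
}

# Reverse complement for strict-ACGT words on the integer-code level;
# fast path used by the scanner (no Biostrings object churn).
revcomp_word <- function(word) {
  rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", word))))
}

#' Reverse complement of a DNA string
#'
#' @param s Character scalar (IUPAC letters beyond ACGT are passed through
#'   complemented where defined, otherwise left as `N`).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
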