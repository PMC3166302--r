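# Readers and writers: FASTA, TRANSFAC/JASPAR count matrices, IUPAC
# consensus initialization, motif-model YAML/JSON, and the TPWM JSON
# schema.  Readers reject rather than repair malformed input and name the
# offending location.

#' Read / write FASTA
#'
#' @param path FASTA file.
#' @return `read_fasta()` returns a named character vector of uppercased
#'   sequences; duplicate record ids and empty files are errors.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- anyDuplicated(ids)
  if (dup) {
    stop(sprintf("duplicate FASTA id '%s' in %s", ids[dup], path),
         call. = FALSE)
  }
  setNames(toupper(as.character(set)), ids)
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(records, path, width = 70L) {
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_along(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(records)) {
    writeLines(paste0(">", ids[k]), con)
    s <- records[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a TRANSFAC or JASPAR motif count matrix
#'
#' Accepts the TRANSFAC block dialect (`P0`/`PO` header line naming the
#' nucleotide column order, numbered count rows, `XX`/`CC`/metadata lines
#' ignored) and the JASPAR PFM dialect (four lines `A [ 1 2 ... ]`, with
#' or without brackets, optional `>` header).
#'
#' @param path Matrix file.
#' @param pseudocount Pseudocount used to convert counts to probabilities
#'   (same rule as [estimate_pwm()]); default 0.5.
#' @return A `pwm` with `counts` retained.
#' @export
read_transfac <- function(path, pseudocount = 0.5) {
  lines <- readLines(path, warn = FALSE)
  jaspar <- grep("^[ACGT]\\s*[\\[0-9]", trimws(lines))
  counts <- if (length(jaspar) >= 4L) {
    parse_jaspar(lines, path)
  } else {
    parse_transfac(lines, path)
  }
  if (any(counts < 0)) {
    stop("negative count in matrix file ", path, call. = FALSE)
  }
  n <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2L, n + 4 * pseudocount, "/")
  new_pwm(probs, counts = counts, pseudocount = pseudocount)
}

parse_transfac <- function(lines, path) {
  hdr <- grep("^\\s*P[0O]\\b", lines)
  if (length(hdr) == 0L) {
    stop("no P0/PO matrix header found in ", path, call. = FALSE)
  }
  hdr <- hdr[1L]
  letters <- strsplit(trimws(lines[hdr]), "\\s+")[[1L]][-1L]
  if (!setequal(letters, DNA_LETTERS)) {
    stop(sprintf("line %d of %s: header must name A, C, G, T", hdr, path),
         call. = FALSE)
  }
  rows <- list()
  for (ln in seq(hdr + 1L, length(lines))) {
    txt <- trimws(lines[ln])
    if (txt == "" || grepl("^(XX|//)", txt)) break
    if (!grepl("^[0-9]", txt)) next  # CC and other metadata
    tok <- strsplit(txt, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok[2:5]))
    if (length(tok) < 5L || any(is.na(vals))) {
      stop(sprintf("line %d of %s: expected 4 numeric counts", ln, path),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- vals[match(DNA_LETTERS, letters)]
  }
  if (length(rows) == 0L) {
    stop("no count rows found in ", path, call. = FALSE)
  }
  matrix(unlist(rows), nrow = 4L,
         dimnames = list(DNA_LETTERS, NULL))
}

parse_jaspar <- function(lines, path) {
  got <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    m <- regmatches(txt, regexec("^([ACGT])\\s*\\[?\\s*([-0-9. \t]+?)\\s*\\]?\\s*$",
                                 txt))[[1L]]
    if (length(m) == 3L) {
      vals <- suppressWarnings(as.numeric(strsplit(m[3L], "\\s+")[[1L]]))
      if (any(is.na(vals))) {
        stop(sprintf("line %d of %s: malformed JASPAR row", ln, path),
             call. = FALSE)
      }
      got[[m[2L]]] <- vals
    }
  }
  if (!setequal(names(got), DNA_LETTERS)) {
    stop("JASPAR matrix in ", path, " must have one row each for A, C, G, T",
         call. = FALSE)
  }
  w <- unique(lengths(got))
  if (length(w) != 1L) {
    stop("ragged JASPAR rows in ", path, call. = FALSE)
  }
  do.call(rbind, got[DNA_LETTERS])
}

#' Write a PWM in TRANSFAC format or as plain TSV
#'
#' @param pwm A `pwm`.
#' @param path Output file.
#' @param what `"counts"` (default when present) or `"probs"`.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwm, path, what = c("auto", "counts", "probs")) {
  what <- match.arg(what)
  m <- if ((what == "auto" && !is.null(pwm$counts)) || what == "counts") {
    if (is.null(pwm$counts)) stop("PWM carries no counts", call. = FALSE)
    pwm$counts
  } else pwm$probs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ID motif", "BF unknown", "P0\tA\tC\tG\tT"), con)
  for (j in seq_len(ncol(m))) {
    writeLines(paste(c(sprintf("%02d", j), format(m[, j], trim = TRUE)),
                     collapse = "\t"), con)
  }
  writeLines(c("XX", "//"), con)
  invisible(path)
}

#' @rdname write_transfac
#' @export
write_pwm_tsv <- function(pwm, path) {
  df <- data.frame(base = DNA_LETTERS, pwm$probs, check.names = FALSE)
  colnames(df) <- c("base", sprintf("pos%d", seq_len(pwm$width)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' PWM from an IUPAC consensus string
#'
#' Each consensus letter contributes a column: the nucleotides the code
#' denotes share `match_prob` equally, the remaining nucleotides share
#' `1 - match_prob` equally (an `N` column is uniform).
#'
#' @param iupac Consensus string over the IUPAC nucleotide alphabet.
#' @param match_prob Probability mass placed on the denoted nucleotides,
#'   in `(0.25, 1]`; default 0.8.
#' @return A `pwm` (probabilities only, no counts).
#' @examples
#' consensus_to_pwm("TGASTCA")$probs
#' @export
consensus_to_pwm <- function(iupac, match_prob = 0.8) {
  stopifnot(match_prob > 0.25, match_prob <= 1)
  letters_ <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  if (length(letters_) == 0L) stop("empty consensus", call. = FALSE)
  cols <- vapply(seq_along(letters_), function(k) {
    code <- IUPAC_CODES[[letters_[k]]]
    if (is.null(code)) {
      stop(sprintf("invalid IUPAC letter '%s' at position %d",
                   letters_[k], k), call. = FALSE)
    }
    if (length(code) == 4L) return(rep(0.25, 4L))
    v <- rep((1 - match_prob) / (4L - length(code)), 4L)
    v[match(code, DNA_LETTERS)] <- match_prob / length(code)
    v
  }, numeric(4L))
  new_pwm(cols)
}

# ---- TPWM JSON schema -------------------------------------------------

TPWM_JSON_FORMAT <- "tpwm-json"
TPWM_JSON_VERSION <- 1L

pwm_to_doc <- function(pwm) {
  if (is.null(pwm)) return(NULL)
  doc <- list(probs = unname(pwm$probs), pseudocount = pwm$pseudocount)
  if (!is.null(pwm$counts)) doc$counts <- unname(pwm$counts)
  doc
}

pwm_from_doc <- function(doc) {
  if (is.null(doc)) return(NULL)
  probs <- matrix(unlist(doc$probs), nrow = 4L, byrow = TRUE)
  counts <- if (!is.null(doc$counts)) {
    matrix(unlist(doc$counts), nrow = 4L, byrow = TRUE)
  }
  new_pwm(probs, counts = counts,
          pseudocount = if (is.null(doc$pseudocount)) 0 else doc$pseudocount)
}

#' Serialize / deserialize a TPWM as JSON
#'
#' The document stores the build configuration and a flat node table:
#' `{format, version, width, min_leaf, dep_threshold, pseudocount,
#' n_sites, root_id, nodes: [{id, is_leaf, n_sites, fixed, split_position,
#' branch_probs, children (nucleotide -> node id), pwm, fallback_pwm}]}`.
#' Probabilities are written at full precision, so a round trip is exact.
#'
#' @param model A `tpwm`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `tpwm_to_json()`: `path` (invisibly) or the JSON string.
#'   `tpwm_from_json()`: the reconstructed `tpwm`; schema violations
#'   (wrong format/version, dangling child references) are errors.
#' @export
tpwm_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "tpwm"))
  nodes <- list()
  walk <- function(node) {
    doc <- list(id = node$node_id, is_leaf = node$is_leaf,
                n_sites = node$n_sites,
                fixed = as.list(setNames(DNA_LETTERS[node$fixed],
                                         names(node$fixed))))
    if (node$is_leaf) {
      doc$pwm <- pwm_to_doc(node$leaf_pwm)
    } else {
      doc$split_position <- node$split_position
      doc$branch_probs <- as.list(node$branch_probs)
      doc$children <- lapply(node$children, `[[`, "node_id")
      doc$fallback_pwm <- pwm_to_doc(node$fallback_pwm)
    }
    nodes[[length(nodes) + 1L]] <<- doc
    if (!node$is_leaf) for (ch in node$children) walk(ch)
  }
  walk(model$root)
  doc <- list(format = TPWM_JSON_FORMAT, version = TPWM_JSON_VERSION,
              width = model$width, min_leaf = model$min_leaf,
              dep_threshold = model$dep_threshold,
              pseudocount = model$pseudocount, n_sites = model$n_sites,
              root_id = model$root$node_id, nodes = nodes)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname tpwm_to_json
#' @param input Path to a JSON file, or a JSON string.
#' @export
tpwm_from_json <- function(input) {
  doc <- jsonlite::fromJSON(input, simplifyVector = FALSE)
  if (!identical(doc$format, TPWM_JSON_FORMAT)) {
    stop("not a TPWM JSON document (at $format)", call. = FALSE)
  }
  if (!identical(as.integer(doc$version), TPWM_JSON_VERSION)) {
    stop(sprintf("unsupported TPWM JSON version %s (at $version)",
                 doc$version), call. = FALSE)
  }
  byid <- list()
  for (nd in doc$nodes) byid[[as.character(nd$id)]] <- nd
  build <- function(id) {
    nd <- byid[[as.character(id)]]
    if (is.null(nd)) {
      stop(sprintf("dangling node reference %s (at $nodes children)", id),
           call. = FALSE)
    }
    fixed <- setNames(match(unlist(nd$fixed), DNA_LETTERS),
                      names(nd$fixed))
    if (length(fixed) == 0L) fixed <- setNames(integer(0), character(0))
    if (isTRUE(nd$is_leaf)) {
      list(node_id = nd$id, is_leaf = TRUE, n_sites = nd$n_sites,
           fixed = fixed, leaf_pwm = pwm_from_doc(nd$pwm))
    } else {
      children <- lapply(nd$children, build)
      list(node_id = nd$id, is_leaf = FALSE, n_sites = nd$n_sites,
           fixed = fixed, split_position = as.integer(nd$split_position),
           branch_probs = setNames(as.numeric(unlist(nd$branch_probs)),
                                   DNA_LETTERS),
           children = children,
           fallback_pwm = pwm_from_doc(nd$fallback_pwm))
    }
  }
  structure(list(width = as.integer(doc$width), root = build(doc$root_id),
                 min_leaf = doc$min_leaf, dep_threshold = doc$dep_threshold,
                 pseudocount = doc$pseudocount, n_sites = doc$n_sites),
            class = "tpwm")
}

# ---- Motif model files (YAML or JSON) --------------------------------

#' Read / write a motif model description
#'
#' YAML (`.yaml`/`.yml`) or JSON file with fields `width`, `columns` (a
#' list of four length-`width` rows in `A,C,G,T` order; entries at block
#' positions may be null) and `blocks` (each with `positions` and `joint`,
#' the joint table flattened with the first position varying fastest).
#'
#' @param path Model file.
#' @return `read_motif_model()` returns a [motif_model()].
#' @export
read_motif_model <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  width <- as.integer(doc$width)
  rows <- lapply(doc$columns, function(r) {
    as.numeric(vapply(r, function(x) if (is.null(x)) NA_real_ else x,
                      numeric(1L)))
  })
  columns <- do.call(rbind, rows)
  if (!is.matrix(columns) || nrow(columns) != 4L || ncol(columns) != width) {
    stop("motif model 'columns' must be 4 rows of length width", call. = FALSE)
  }
  blocks <- lapply(doc$blocks, function(b) {
    list(positions = as.integer(unlist(b$positions)),
         joint = as.numeric(unlist(b$joint)))
  })
  motif_model(columns, blocks = blocks)
}

#' @rdname read_motif_model
#' @param model A [motif_model()].
#' @export
write_motif_model <- function(model, path) {
  doc <- list(width = model$width,
              columns = lapply(seq_len(4L), function(r)
                as.numeric(model$columns[r, ])),
              blocks = lapply(model$blocks, function(b)
                list(positions = b$positions,
                     joint = as.numeric(as.vector(b$joint)))))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
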