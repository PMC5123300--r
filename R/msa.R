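#' @useDynLib dcmsa, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois setNames p.adjust t.test pt qgamma sd
#' @importFrom utils head tail
NULL

GAP <- "-"
DNA_CORE <- c("A", "C", "G", "T")
# IUPAC ambiguity codes tolerated (treated as mismatches everywhere)
DNA_AMBIG <- c("U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Construct a multiple sequence alignment object
#'
#' An `msa` is a rectangular gapped character matrix over named sequences.
#' The gap character is `'-'` (`'.'` is rejected). Uppercase letters mark
#' homologous cells; lowercase letters mark non-homologous insertion cells
#' (the convention used by the HMM-ensemble extension stage, where each
#' lowercase cell forms its own singleton column for scoring purposes).
#'
#' @param x Named character vector of equal-length gapped strings, or a
#'   character matrix of single characters with row names.
#' @param strict If `TRUE`, IUPAC ambiguity codes are rejected rather than
#'   tolerated with a warning.
#' @return An object of class `msa`: a character matrix with one row per
#'   sequence and one column per alignment column.
#' @export
msa <- function(x, strict = FALSE) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("alignment rows must be named with non-empty sequence ids")
    }
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      stop("ragged alignment: rows have lengths ", paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    if (length(x) > 0L && lens[1] == 0L) m <- matrix(character(0), nrow = length(x), ncol = 0, dimnames = list(names(x)))
  }
  if (is.null(rownames(m)) || any(!nzchar(rownames(m)))) {
    stop("alignment rows must be named with non-empty sequence ids")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sequence ids: ", paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  validate_alignment_chars(m, strict = strict)
  structure(m, class = "msa")
}

validate_alignment_chars <- function(m, strict = FALSE) {
  ch <- unique(as.vector(m))
  if (any(ch == ".")) {
    stop("'.' found in alignment; the only supported gap character is '-'")
  }
  up <- toupper(ch)
  bad <- ch[!(up %in% c(DNA_CORE, DNA_AMBIG, GAP))]
  if (length(bad)) {
    stop("invalid residue characters: ", paste(bad, collapse = " "))
  }
  amb <- ch[up %in% DNA_AMBIG]
  if (length(amb)) {
    if (strict) stop("ambiguity codes present in strict mode: ", paste(amb, collapse = " "))
    warning("ambiguity codes present (treated as mismatches): ", paste(sort(unique(toupper(amb))), collapse = " "))
  }
  invisible(TRUE)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", nrow(x), ncol(x)))
  shown <- head(rownames(x), 6L)
  for (id in shown) {
    row <- paste(x[id, seq_len(min(60L, ncol(x)))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", id, row, if (ncol(x) > 60L) "..." else ""))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
as.character.msa <- function(x, ...) {
  out <- apply(unclass(x), 1L, paste, collapse = "")
  if (ncol(x) == 0L) out <- setNames(rep("", nrow(x)), rownames(x))
  out
}

is_msa <- function(x) inherits(x, "msa")

msa_ids <- function(aln) rownames(aln)

#' Remove gaps from alignment rows
#'
#' @param aln An `msa`.
#' @param keep_case Keep the homology case flags; by default residues are
#'   restored to canonical uppercase.
#' @return Named character vector of ungapped sequences.
#' @export
ungap <- function(aln, keep_case = FALSE) {
  stopifnot(is_msa(aln))
  m <- unclass(aln)
  out <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    paste(r[r != GAP], collapse = "")
  }, character(1))
  names(out) <- rownames(m)
  if (!keep_case) out <- toupper(out)
  out
}

#' Construct a set of unaligned sequences
#'
#' @param x Named character vector; residues are canonicalized to uppercase.
#' @param strict Reject ambiguity codes.
#' @return Named character vector of class `dcm_seqs`.
#' @export
new_seqs <- function(x, strict = FALSE) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("sequences must have non-empty ids")
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence ids: ", paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  if (any(grepl("-", x, fixed = TRUE))) stop("unaligned sequences must not contain gap characters")
  x <- toupper(x)
  ch <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  bad <- ch[!(ch %in% c(DNA_CORE, DNA_AMBIG))]
  if (length(bad)) stop("invalid residue characters: ", paste(bad, collapse = " "))
  amb <- ch[ch %in% DNA_AMBIG]
  if (length(amb) && strict) stop("ambiguity codes present in strict mode: ", paste(amb, collapse = " "))
  structure(x, class = "dcm_seqs")
}

#' Read a FASTA file
#'
#' Records are parsed with the id taken as the header up to the first
#' whitespace. If all records have equal length and any contains a gap
#' character the file is returned as an [msa]; otherwise as an unaligned
#' sequence set.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject ambiguity codes.
#' @return An `msa` or a `dcm_seqs` named character vector, order preserved.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- as.character(set)
  names(x) <- ids
  if (any(grepl(".", x, fixed = TRUE))) {
    stop("'.' found in ", path, "; the only supported gap character is '-'")
  }
  has_gap <- any(grepl("-", x, fixed = TRUE))
  lens <- nchar(x)
  if (has_gap) {
    if (length(unique(lens)) > 1L) {
      stop("ragged aligned records in ", path, " (gapped records of unequal length)")
    }
    msa(x, strict = strict)
  } else {
    new_seqs(x, strict = strict)
  }
}

#' Write sequences or an alignment to FASTA
#'
#' Lines wrap at 80 columns.
#'
#' @param x An `msa` or named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is_msa(x)) x <- as.character(x)
  set <- Biostrings::BStringSet(unclass(x))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Restrict an alignment to a subset of its sequences
#'
#' All-gap columns arising from the restriction are removed; homology case
#' flags are preserved. The attribute `colmap` on the result gives, for each
#' retained column, its (1-based) column index in the input alignment.
#'
#' @param aln An `msa`.
#' @param subset Character vector of sequence ids, a non-empty subset of
#'   `rownames(aln)`.
#' @return The induced `msa` on `subset` (input row order).
#' @export
induced_subalignment <- function(aln, subset) {
  stopifnot(is_msa(aln))
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  unknown <- setdiff(subset, rownames(aln))
  if (length(unknown)) stop("unknown sequence ids: ", paste(unknown, collapse = ", "))
  keep_rows <- rownames(aln)[rownames(aln) %in% subset]
  m <- unclass(aln)[keep_rows, , drop = FALSE]
  nongap <- colSums(m != GAP) > 0L
  res <- msa_quiet(m[, nongap, drop = FALSE])
  attr(res, "colmap") <- which(nongap)
  res
}

# internal constructor skipping character re-validation warnings
msa_quiet <- function(m) {
  structure(m, class = "msa")
}

#' Extract alignment columns as support maps
#'
#' Each column is represented by its support map: a named integer vector
#' giving, for every sequence with a residue in the column, the 0-based
#' ungapped site index of that residue.
#'
#' @param aln An `msa`.
#' @return List of named integer vectors, one per column, left to right.
#' @export
columns_of <- function(aln) {
  stopifnot(is_msa(aln))
  m <- unclass(aln)
  sitemat <- site_index_matrix(m)
  lapply(seq_len(ncol(m)), function(j) {
    rows <- which(m[, j] != GAP)
    setNames(sitemat[rows, j], rownames(m)[rows])
  })
}

# matrix of 0-based ungapped site indices (NA at gaps)
site_index_matrix <- function(m) {
  res <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    ng <- m[i, ] != GAP
    s <- cumsum(ng) - 1L
    s[!ng] <- NA_integer_
    res[i, ] <- s
  }
  res
}

column_key <- function(support) {
  if (length(support) == 0L) return("")
  o <- order(names(support))
  paste(names(support)[o], support[o], sep = ":", collapse = "|")
}

#' Homologous site pairs of an alignment
#'
#' Two sites are paired iff they occupy the same column and both cells are
#' flagged homologous (uppercase). Lowercase insertion cells contribute no
#' pairs.
#'
#' @param aln An `msa`.
#' @return Character vector of canonical pair keys `"idA:siteA|idB:siteB"`
#'   with `idA < idB`; sites are 0-based ungapped indices.
#' @export
homology_pairs <- function(aln) {
  stopifnot(is_msa(aln))
  m <- unclass(aln)
  sitemat <- site_index_matrix(m)
  hom <- m != GAP & m == toupper(m)
  out <- vector("list", ncol(m))
  ids <- rownames(m)
  for (j in seq_len(ncol(m))) {
    rows <- which(hom[, j])
    if (length(rows) < 2L) next
    o <- rows[order(ids[rows])]
    labs <- paste(ids[o], sitemat[o, j], sep = ":")
    cmb <- utils::combn(labs, 2L)
    out[[j]] <- paste(cmb[1L, ], cmb[2L, ], sep = "|")
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dump alignment columns as JSON
#'
#' Debugging aid: writes the list of column support maps.
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_columns_json <- function(aln, path) {
  cols <- columns_of(aln)
  jsonlite::write_json(lapply(cols, as.list), path, auto_unbox = TRUE)
  invisible(path)
}
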