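#' Scoring parameters for the built-in aligner
#'
#' @param match,mismatch Residue pair scores (ambiguity codes score as
#'   mismatches against everything, including themselves).
#' @param gap_open,gap_extend Affine gap penalties (negative); a gap run of
#'   length k costs `gap_open + (k-1) * gap_extend`, scaled by the non-gap
#'   occupancy of the profile column being gapped against.
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = -10, gap_extend = -0.5) {
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# 5 x L residue frequency matrix (A,C,G,T,X ambiguity) and occupancy vector
profile_of <- function(aln) {
  m <- toupper(unclass(aln))
  n <- nrow(m)
  L <- ncol(m)
  C <- matrix(0, 5, L, dimnames = list(c(DNA_CORE, "X"), NULL))
  for (b in seq_len(4)) C[b, ] <- colSums(m == DNA_CORE[b])
  gapc <- colSums(m == GAP)
  C[5, ] <- n - gapc - colSums(C[1:4, , drop = FALSE])
  list(freq = C / n, occ = 1 - gapc / n)
}

substitution_matrix <- function(params) {
  S <- matrix(params$mismatch, 5, 5)
  diag(S)[1:4] <- params$match  # ambiguity (X) mismatches even against itself
  S
}

#' Merge two alignments by profile-profile alignment
#'
#' Columns of the two alignments are interleaved or stacked, never split,
#' so the result restricted to either input's sequences reproduces that
#' input exactly. Column pair scores are expected sum-of-pairs residue
#' scores under the column residue frequencies; gap penalties are scaled by
#' column occupancy. Traceback ties prefer stacking over gapping B over
#' gapping A.
#'
#' @param A,B `msa` objects over disjoint sequence id sets.
#' @param params An [align_params()].
#' @return An `msa` over the union of the ids (A's rows first).
#' @export
profile_profile_align <- function(A, B, params = align_params()) {
  stopifnot(is_msa(A), is_msa(B))
  if (length(intersect(rownames(A), rownames(B)))) {
    stop("profiles share sequence ids: ",
         paste(intersect(rownames(A), rownames(B)), collapse = ", "))
  }
  pa <- profile_of(A); pb <- profile_of(B)
  SM <- substitution_matrix(params)
  S <- t(pa$freq) %*% SM %*% pb$freq
  ops <- profile_dp_path(S, pa$occ, pb$occ, params$gap_open, params$gap_extend)
  build_merged(A, B, ops)
}

build_merged <- function(A, B, ops) {
  ma <- unclass(A); mb <- unclass(B)
  na <- nrow(ma); nb <- nrow(mb)
  out <- matrix(GAP, na + nb, length(ops),
                dimnames = list(c(rownames(ma), rownames(mb)), NULL))
  i <- 0L; j <- 0L
  for (p in seq_along(ops)) {
    op <- ops[p]
    if (op != 3L) { i <- i + 1L; out[seq_len(na), p] <- ma[, i] }
    if (op != 2L) { j <- j + 1L; out[na + seq_len(nb), p] <- mb[, j] }
  }
  res <- msa_quiet(out)
  attr(res, "score") <- attr(ops, "score")
  res
}

# k-mer count vectors and cosine distances for guide-tree estimation
kmer_distances <- function(seqs, k = 5L) {
  k <- min(k, min(nchar(seqs)))
  counts <- lapply(unclass(seqs), function(s) {
    n <- nchar(s)
    kmers <- substring(s, seq_len(n - k + 1L), k:n)
    table(kmers)
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  norms <- vapply(counts, function(tb) sqrt(sum(as.numeric(tb)^2)), 1)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- intersect(names(counts[[i]]), names(counts[[j]]))
      dot <- sum(as.numeric(counts[[i]][shared]) * as.numeric(counts[[j]][shared]))
      D[i, j] <- D[j, i] <- 1 - dot / (norms[i] * norms[j])
    }
  }
  D
}

# deterministic rooted guide tree from a distance matrix
guide_tree_from_dist <- function(D) {
  ids <- sort(rownames(D))
  D <- D[ids, ids]
  if (length(ids) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:1,%s:1);", ids[1L], ids[2L]))
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::root(ape::unroot(tr), outgroup = ids[1L], resolve.root = TRUE)
}

#' Align a set of sequences with the built-in progressive aligner
#'
#' Guide tree by neighbor joining on k-mer cosine distances (k = 5),
#' followed by progressive profile-profile merging in deterministic
#' postorder.
#'
#' @param seqs A `dcm_seqs` vector (>= 1 sequence).
#' @param params An [align_params()].
#' @return An `msa` over exactly the input ids.
#' @export
progressive_align <- function(seqs, params = align_params()) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  if (n == 1L) return(msa(setNames(unclass(seqs), names(seqs))))
  if (n == 2L) {
    a <- msa(setNames(unclass(seqs)[1L], names(seqs)[1L]))
    b <- msa(setNames(unclass(seqs)[2L], names(seqs)[2L]))
    return(reorder_rows(profile_profile_align(a, b, params), names(seqs)))
  }
  D <- kmer_distances(seqs)
  gt <- guide_tree_from_dist(D)
  aln <- progressive_from_tree(seqs, gt, params)
  reorder_rows(aln, names(seqs))
}

reorder_rows <- function(aln, ids) {
  msa_quiet(unclass(aln)[ids, , drop = FALSE])
}

progressive_from_tree <- function(seqs, rooted_tree, params) {
  ntip <- length(rooted_tree$tip.label)
  children <- split(seq_len(nrow(rooted_tree$edge)), rooted_tree$edge[, 1L])
  min_label <- character(ntip + rooted_tree$Nnode)

  align_node <- function(node) {
    if (node <= ntip) {
      id <- rooted_tree$tip.label[node]
      min_label[node] <<- id
      return(msa(setNames(unclass(seqs)[id], id)))
    }
    kid_edges <- children[[as.character(node)]]
    kids <- rooted_tree$edge[kid_edges, 2L]
    profs <- lapply(kids, align_node)
    o <- order(min_label[kids])
    profs <- profs[o]
    min_label[node] <<- min(min_label[kids])
    acc <- profs[[1L]]
    for (p in profs[-1L]) acc <- profile_profile_align(acc, p, params)
    acc
  }
  align_node(ntip + 1L)
}
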