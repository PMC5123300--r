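#' Read a guide tree from a Newick file
#'
#' @param path Newick file containing a single tree.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 leaves")
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# unit-length edge-count distances between all nodes of a phylo
node_hop_distances <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  ape::dist.nodes(t2)
}

# leaf labels on the child side of every edge
edge_child_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; chd <- tr$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below[[tree$edge[k, 2L]]])
}

#' Find the centroid edge of a tree
#'
#' The centroid edge is the edge whose removal minimizes the larger of the
#' two resulting components' leaf counts. Ties are broken by the smaller
#' absolute difference of the component sizes, then by the lexicographically
#' smallest leaf label in the canonical component, making the choice fully
#' deterministic.
#'
#' @param tree A `phylo` with >= 2 leaves (treated as unrooted; branch
#'   lengths are ignored).
#' @return List with `edge` (row index into `tree$edge`), `side1` and
#'   `side2` (leaf label sets; `side1` is the smaller — or on equal sizes the
#'   lexicographically first — component).
#' @export
centroid_edge <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  sets <- edge_child_leafsets(tree)
  all_leaves <- tree$tip.label
  best <- NULL
  for (k in seq_along(sets)) {
    a <- sets[[k]]
    b <- setdiff(all_leaves, a)
    if (length(b) == 0L) next  # root edge artifact: child side holds everything
    big <- max(length(a), length(b))
    dif <- abs(length(a) - length(b))
    if (length(a) < length(b) || (length(a) == length(b) && min(a) <= min(b))) {
      s1 <- a; s2 <- b
    } else {
      s1 <- b; s2 <- a
    }
    key <- list(big = big, dif = dif, lab = min(s1))
    if (is.null(best) || key$big < best$key$big ||
        (key$big == best$key$big && key$dif < best$key$dif) ||
        (key$big == best$key$big && key$dif == best$key$dif && key$lab < best$key$lab)) {
      best <- list(edge = k, side1 = sort(s1), side2 = sort(s2), key = key)
    }
  }
  best$key <- NULL
  best
}

#' Centroid-edge decomposition of a guide tree
#'
#' Repeatedly deletes centroid edges until every component holds at most
#' `max_size` leaves. Each deleted edge contributes one adjacency between
#' the final subsets on its two sides: the adjacency attaches to the subset
#' containing the leaf nearest (in edge counts) to the deleted edge on that
#' side, ties broken lexicographically.
#'
#' @param tree A `phylo` guide tree.
#' @param max_size Maximum leaves per subset (>= 2).
#' @return List with `subsets` (list of sorted leaf-label vectors),
#'   `adjacency` (two-column integer matrix of subset-index pairs forming a
#'   spanning tree; zero rows when there is a single subset), and `history`
#'   (list of deleted-edge records with the two anchor leaves).
#' @export
decompose_tree <- function(tree, max_size) {
  if (max_size < 2L) stop("max_size must be >= 2")
  subsets <- list()
  anchors <- list()  # pairs of leaf labels, one per deleted edge

  recurse <- function(tr) {
    leaves <- sort(tr$tip.label)
    if (length(leaves) <= max_size) {
      subsets[[length(subsets) + 1L]] <<- leaves
      return(invisible(NULL))
    }
    ce <- centroid_edge(tr)
    d <- node_hop_distances(tr)
    par_node <- tr$edge[ce$edge, 1L]
    chd_node <- tr$edge[ce$edge, 2L]
    child_set <- edge_child_leafsets(tr)[[ce$edge]]
    other_set <- setdiff(tr$tip.label, child_set)
    anchor_of <- function(side_labels, node) {
      idx <- match(side_labels, tr$tip.label)
      hops <- d[node, idx]
      cand <- side_labels[hops == min(hops)]
      sort(cand)[1L]
    }
    a_child <- anchor_of(child_set, chd_node)
    a_other <- anchor_of(other_set, par_node)
    anchors[[length(anchors) + 1L]] <<- c(a_child, a_other)
    for (side in list(child_set, other_set)) {
      if (length(side) == 1L) {
        subsets[[length(subsets) + 1L]] <<- side
      } else {
        recurse(ape::keep.tip(tr, side))
      }
    }
    invisible(NULL)
  }

  recurse(tree)
  leaf2subset <- integer(0)
  for (i in seq_along(subsets)) {
    leaf2subset[subsets[[i]]] <- i
  }
  adj <- matrix(integer(0), ncol = 2L)
  if (length(anchors)) {
    adj <- do.call(rbind, lapply(anchors, function(p) {
      sort(c(leaf2subset[[p[1L]]], leaf2subset[[p[2L]]]))
    }))
  }
  list(subsets = subsets,
       adjacency = adj,
       history = lapply(anchors, function(p) list(anchor_a = p[1L], anchor_b = p[2L])))
}

#' Pairwise distances from an alignment
#'
#' p-distance over mutually non-gap aligned positions, optionally with the
#' Jukes-Cantor correction. Ambiguity codes count as mismatches.
#'
#' @param aln An `msa`.
#' @param correction `"p"` or `"jc"`.
#' @return A symmetric distance matrix with sequence ids as dimnames.
#' @export
alignment_distances <- function(aln, correction = c("p", "jc")) {
  correction <- match.arg(correction)
  m <- toupper(unclass(aln))
  n <- nrow(m)
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- m == GAP
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        stop("sequences ", ids[i], " and ", ids[j], " share no ungapped positions")
      }
      p <- sum(m[i, ok] != m[j, ok]) / nc
      d <- p
      if (correction == "jc") {
        # JC correction saturates at p = 3/4; cap for deterministic output
        d <- if (p >= 0.749) 5 else -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining guide tree from an alignment
#'
#' A deterministic built-in stand-in for an external maximum-likelihood tree
#' estimator. Rows are ordered by sequence id before the NJ pass so the
#' result does not depend on input order; negative NJ branch lengths are
#' clamped to zero.
#'
#' @param aln An `msa` with >= 3 sequences.
#' @param correction Distance correction, `"p"` or `"jc"` (see
#'   [alignment_distances()]).
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(aln, correction = c("jc", "p")) {
  correction <- match.arg(correction)
  stopifnot(is_msa(aln))
  if (nrow(aln) < 3L) stop("nj_tree needs at least 3 sequences")
  o <- order(rownames(aln))
  aln_sorted <- msa_quiet(unclass(aln)[o, , drop = FALSE])
  D <- alignment_distances(aln_sorted, correction)
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' @importFrom stats as.dist
NULL
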