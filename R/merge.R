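#' Build the merge graph for a decomposition
#'
#' One node per subset alignment; one edge per decomposition adjacency,
#' carrying the pairwise profile-profile merge of the two subset
#' alignments. Each edge merge induces both endpoint alignments exactly
#' (asserted).
#'
#' @param subalns List of `msa` objects over pairwise disjoint id sets.
#' @param adjacency Two-column integer matrix of subset index pairs forming
#'   a spanning tree (as produced by [decompose_tree()]).
#' @param params An [align_params()] used for the pairwise merges.
#' @return An object of class `merge_graph`.
#' @export
merge_graph <- function(subalns, adjacency, params = align_params()) {
  adjacency <- matrix(as.integer(adjacency), ncol = 2L)
  edges <- vector("list", nrow(adjacency))
  for (e in seq_len(nrow(adjacency))) {
    i <- adjacency[e, 1L]; j <- adjacency[e, 2L]
    merged <- profile_profile_align(subalns[[i]], subalns[[j]], params)
    edges[[e]] <- list(i = i, j = j, aln = merged)
  }
  g <- structure(list(subalns = subalns, edges = edges), class = "merge_graph")
  check_merge_graph(g)
  g
}

check_merge_graph <- function(g) {
  for (e in g$edges) {
    for (end in c("i", "j")) {
      sub <- g$subalns[[e[[end]]]]
      ind <- induced_subalignment(e$aln, rownames(sub))
      ind <- reorder_rows(ind, rownames(sub))
      if (!identical(as.character(ind), as.character(sub))) {
        stop("edge merge does not induce subset alignment ", e[[end]])
      }
    }
  }
  invisible(TRUE)
}

# map from "id:site" cell keys to column index for one alignment
cell_to_column <- function(aln) {
  m <- unclass(aln)
  sitemat <- site_index_matrix(m)
  keys <- character(0); cols <- integer(0)
  for (i in seq_len(nrow(m))) {
    jj <- which(m[i, ] != GAP)
    keys <- c(keys, paste0(rownames(m)[i], ":", sitemat[i, jj]))
    cols <- c(cols, jj)
  }
  setNames(cols, keys)
}

#' Merge overlapping subset alignments into one alignment by transitivity
#'
#' Columns equated through the edge merges are identified with union-find;
#' the resulting column classes are ordered topologically under the column
#' orders of every subset alignment and every edge merge (Kahn's algorithm
#' with a deterministic smallest-identifier tie-break). For a tree-structured
#' merge graph the precedence relation is acyclic; a cycle raises an error.
#'
#' @param graph A [merge_graph()], connected.
#' @return An `msa` over the union of all subset ids in which the
#'   restriction to every subset reproduces that subset's alignment
#'   (asserted).
#' @export
transitivity_merge <- function(graph) {
  stopifnot(inherits(graph, "merge_graph"))
  subalns <- graph$subalns
  ns <- length(subalns)
  if (ns > 1L) {
    deg_nodes <- sort(unique(unlist(lapply(graph$edges, function(e) c(e$i, e$j)))))
    if (!identical(deg_nodes, seq_len(ns)) || length(graph$edges) < ns - 1L) {
      stop("merge graph is not connected")
    }
  }
  ncols <- vapply(subalns, ncol, 1L)
  offset <- c(0L, cumsum(ncols))[seq_len(ns)]
  total <- sum(ncols)
  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }

  cellmaps <- lapply(subalns, cell_to_column)
  sub_of_id <- integer(0)
  for (s in seq_len(ns)) sub_of_id[rownames(subalns[[s]])] <- s

  # member global column ids of each edge-merge column, in merge column order
  edge_chains <- vector("list", length(graph$edges))
  for (ei in seq_along(graph$edges)) {
    e <- graph$edges[[ei]]
    mcols <- columns_of(e$aln)
    chain <- integer(length(mcols))
    for (j in seq_along(mcols)) {
      sup <- mcols[[j]]
      gids <- integer(0)
      for (s in unique(sub_of_id[names(sup)])) {
        idx <- names(sup)[sub_of_id[names(sup)] == s]
        key <- paste0(idx[1L], ":", sup[[idx[1L]]])
        gids <- c(gids, offset[s] + cellmaps[[s]][[key]])
      }
      if (length(gids) == 2L) union_(gids[1L], gids[2L])
      chain[j] <- gids[1L]
    }
    edge_chains[[ei]] <- chain
  }

  cls <- vapply(seq_len(total), find, 1L)
  # a class must not contain two columns of the same subset
  for (s in seq_len(ns)) {
    gids <- offset[s] + seq_len(ncols[s])
    if (anyDuplicated(cls[gids])) stop("conflicting column identification within subset ", s)
  }

  # precedence: consecutive columns within each subset and each edge merge
  from <- integer(0); to <- integer(0)
  for (s in seq_len(ns)) {
    gids <- cls[offset[s] + seq_len(ncols[s])]
    if (length(gids) > 1L) {
      from <- c(from, gids[-length(gids)]); to <- c(to, gids[-1L])
    }
  }
  for (chain in edge_chains) {
    gids <- cls[chain]
    if (length(gids) > 1L) {
      from <- c(from, gids[-length(gids)]); to <- c(to, gids[-1L])
    }
  }
  eset <- unique(cbind(from, to))

  nodes <- sort(unique(cls))
  ord <- topo_order(nodes, eset)
  if (length(ord) < length(nodes)) stop("cyclic ordering conflict among merged columns")

  # build output
  ids <- unlist(lapply(subalns, rownames))
  out <- matrix(GAP, length(ids), length(ord), dimnames = list(ids, NULL))
  members <- split(seq_len(total), cls)
  pos_of <- match(cls, ord)  # column class -> output position, per global col
  for (s in seq_len(ns)) {
    m <- unclass(subalns[[s]])
    p <- pos_of[offset[s] + seq_len(ncols[s])]
    out[rownames(m), p] <- m
  }
  res <- msa_quiet(out)
  for (s in seq_len(ns)) {
    ind <- reorder_rows(induced_subalignment(res, rownames(subalns[[s]])),
                        rownames(subalns[[s]]))
    if (!identical(as.character(ind), as.character(subalns[[s]]))) {
      stop("internal error: transitivity merge does not induce subset ", s)
    }
  }
  res
}

# Kahn's algorithm; deterministic tie-break on smallest node id
topo_order <- function(nodes, edges) {
  idx <- match(nodes, nodes)
  n <- length(nodes)
  efrom <- match(edges[, 1L], nodes)
  eto <- match(edges[, 2L], nodes)
  adj <- split(eto, factor(efrom, levels = seq_len(n)))
  indeg <- tabulate(eto, nbins = n)
  avail <- which(indeg == 0L)
  ord <- integer(0)
  while (length(avail)) {
    v <- min(avail)
    avail <- avail[avail != v]
    ord <- c(ord, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  nodes[ord]
}
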