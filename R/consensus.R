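#' Tally the columns of a sample of alignments
#'
#' Every column of every sample is counted by its support map (which
#' sequences it contains and at which ungapped sites); columns with
#' identical support are merged, so which sequences are gapped in a column
#' does not enter its identity. Singleton-support columns are included.
#'
#' @param samples List of `msa` objects over the identical sequence set
#'   (same ids and same ungapped residues).
#' @return Object of class `weighted_columns`: `columns` (list of support
#'   maps), `weight` (integer counts), `seqs` (the common ungapped
#'   sequences), `n_samples`, and `sample_weight` (total column weight of
#'   each input sample under the final tally).
#' @export
collect_columns <- function(samples) {
  if (length(samples) == 0L) stop("no samples")
  ref <- ungap(samples[[1L]])
  ref <- ref[order(names(ref))]
  for (k in seq_along(samples)) {
    if (!is_msa(samples[[k]])) stop("sample ", k, " is not an alignment")
    u <- ungap(samples[[k]])
    u <- u[order(names(u))]
    if (!identical(u, ref)) {
      stop("sample ", k, " aligns a different sequence set than sample 1")
    }
  }
  keys_by_sample <- lapply(seq_along(samples), function(k) {
    keys <- vapply(columns_of(samples[[k]]), column_key, character(1))
    if (any(keys == "")) stop("sample ", k, " contains an all-gap column")
    keys
  })
  all_keys <- unlist(keys_by_sample, use.names = FALSE)
  tab <- table(all_keys)
  uniq <- names(tab)
  first_sample <- samples[[1L]]
  # reconstruct support maps from keys
  columns <- lapply(uniq, function(k) {
    parts <- strsplit(strsplit(k, "|", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    setNames(vapply(parts, function(p) as.integer(p[2L]), 1L),
             vapply(parts, `[[`, character(1), 1L))
  })
  w <- as.integer(tab)
  sample_weight <- vapply(keys_by_sample, function(kk) {
    sum(w[match(kk, uniq)])
  }, 1)
  structure(list(columns = columns, weight = w, seqs = ref,
                 n_samples = length(samples),
                 sample_keys = keys_by_sample,
                 sample_weight = sample_weight),
            class = "weighted_columns")
}

# precedence among a set of columns: u precedes v if some shared sequence
# has its u-site before its v-site; returns NULL on a direct order conflict
column_precedence <- function(columns) {
  n <- length(columns)
  from <- integer(0); to <- integer(0)
  seq_cols <- list()
  for (i in seq_len(n)) {
    for (id in names(columns[[i]])) {
      seq_cols[[id]] <- rbind(seq_cols[[id]], c(i, columns[[i]][[id]]))
    }
  }
  for (id in names(seq_cols)) {
    sc <- seq_cols[[id]]
    o <- order(sc[, 2L])
    sc <- sc[o, , drop = FALSE]
    if (nrow(sc) > 1L) {
      from <- c(from, sc[-nrow(sc), 1L]); to <- c(to, sc[-1L, 1L])
    }
  }
  unique(cbind(from, to))
}

columns_acyclic <- function(columns) {
  e <- column_precedence(columns)
  length(topo_order(seq_along(columns), e)) == length(columns)
}

# do the chosen columns use disjoint (id, site) cells?
columns_disjoint <- function(columns) {
  cells <- unlist(lapply(columns, function(s) paste0(names(s), ":", s)))
  !anyDuplicated(cells)
}

#' Posterior-decoding consensus alignment
#'
#' Selects a maximum-weight set of pairwise compatible columns (disjoint
#' cells, acyclic precedence) from the tally and emits them in topological
#' order as a single valid alignment; any sequence sites not covered by a
#' selected column are re-inserted as weight-0 singleton columns at the
#' earliest topologically valid position.
#'
#' `greedy` (the default) adds columns in order of decreasing weight
#' (ties: larger support, then lexicographic key) whenever compatible, and
#' falls back to the best single input sample when that sample's total
#' column weight beats the greedy selection, so the output weight is never
#' below the best sample's. `exact` computes the provably maximum-weight
#' selection by a frontier dynamic program over per-sequence positions and
#' is intended as a small-instance oracle (at most 6 sequences of length at
#' most 25).
#'
#' @param wcs A [collect_columns()] tally.
#' @param mode `"greedy"` or `"exact"`.
#' @return An `msa`; attribute `total_weight` holds the summed weight of
#'   the selected columns.
#' @export
pd_alignment <- function(wcs, mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  sel <- if (mode == "greedy") pd_select_greedy(wcs) else pd_select_exact(wcs)
  build_pd_alignment(wcs, sel)
}

pd_select_greedy <- function(wcs) {
  keys <- vapply(wcs$columns, column_key, character(1))
  sizes <- lengths(wcs$columns)
  o <- order(-wcs$weight, -sizes, keys)
  chosen <- integer(0)
  used_cells <- character(0)
  for (i in o) {
    cells <- paste0(names(wcs$columns[[i]]), ":", wcs$columns[[i]])
    if (any(cells %in% used_cells)) next
    cand <- c(chosen, i)
    if (columns_acyclic(wcs$columns[cand])) {
      chosen <- cand
      used_cells <- c(used_cells, cells)
    }
  }
  greedy_w <- sum(wcs$weight[chosen])
  best_sample <- which.max(wcs$sample_weight)
  if (wcs$sample_weight[best_sample] > greedy_w) {
    all_keys <- vapply(wcs$columns, column_key, character(1))
    chosen <- match(wcs$sample_keys[[best_sample]], all_keys)
  }
  chosen
}

pd_select_exact <- function(wcs) {
  lens <- nchar(wcs$seqs)
  if (length(lens) > 6L || max(lens) > 25L) {
    stop("exact mode is limited to <= 6 sequences of length <= 25; use greedy")
  }
  ids <- names(wcs$seqs)
  n <- length(ids)
  # candidate columns grouped by frontier applicability
  cols <- wcs$columns
  w <- wcs$weight
  memo <- new.env(hash = TRUE, parent = emptyenv())
  target <- unname(lens[ids])

  best <- function(state) {
    key <- paste(state, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (all(state == target)) {
      res <- list(w = 0, pick = integer(0))
    } else {
      res <- NULL
      # advance a single sequence (weight-0 singleton)
      for (s in seq_len(n)) {
        if (state[s] < target[s]) {
          st2 <- state; st2[s] <- st2[s] + 1L
          sub <- best(st2)
          if (is.null(res) || sub$w > res$w) res <- list(w = sub$w, pick = sub$pick)
        }
      }
      # apply any candidate column sitting exactly on the frontier
      for (ci in seq_along(cols)) {
        sup <- cols[[ci]]
        si <- match(names(sup), ids)
        if (all(state[si] == sup)) {
          st2 <- state; st2[si] <- st2[si] + 1L
          sub <- best(st2)
          cand_w <- w[ci] + sub$w
          if (cand_w > res$w) res <- list(w = cand_w, pick = c(ci, sub$pick))
        }
      }
    }
    memo[[key]] <- res
    res
  }
  best(rep(0L, n))$pick
}

build_pd_alignment <- function(wcs, chosen) {
  ids <- names(wcs$seqs)
  lens <- nchar(wcs$seqs)
  cols <- wcs$columns[chosen]
  weights <- wcs$weight[chosen]
  # re-insert uncovered cells as weight-0 singletons
  covered <- lapply(setNames(ids, ids), function(id) integer(0))
  for (s in cols) for (id in names(s)) covered[[id]] <- c(covered[[id]], s[[id]])
  for (id in ids) {
    missing <- setdiff(seq_len(lens[[id]]) - 1L, covered[[id]])
    for (site in missing) {
      cols[[length(cols) + 1L]] <- setNames(site, id)
      weights <- c(weights, 0L)
    }
  }
  e <- column_precedence(cols)
  # Kahn with preference for weight-0 singletons as soon as they become
  # available (earliest valid position), then smallest serialized key
  keys <- vapply(cols, column_key, character(1))
  n <- length(cols)
  efrom <- e[, 1L]; eto <- e[, 2L]
  indeg <- tabulate(eto, nbins = n)
  adj <- split(eto, factor(efrom, levels = seq_len(n)))
  avail <- which(indeg == 0L)
  ord <- integer(0)
  while (length(avail)) {
    singles <- avail[weights[avail] == 0L]
    pool <- if (length(singles)) singles else avail
    v <- pool[order(keys[pool])][1L]
    avail <- avail[avail != v]
    ord <- c(ord, v)
    for (nb in adj[[v]]) {
      indeg[nb] <- indeg[nb] - 1L
      if (indeg[nb] == 0L) avail <- c(avail, nb)
    }
  }
  if (length(ord) < n) stop("internal error: selected columns are not compatible")
  mat <- matrix(GAP, length(ids), n, dimnames = list(ids, NULL))
  chars <- strsplit(unname(wcs$seqs[ids]), "", fixed = TRUE)
  names(chars) <- ids
  for (p in seq_along(ord)) {
    sup <- cols[[ord[p]]]
    for (id in names(sup)) mat[id, p] <- chars[[id]][sup[[id]] + 1L]
  }
  res <- msa_quiet(mat)
  attr(res, "total_weight") <- sum(weights[ord])
  ures <- ungap(res)
  if (!identical(ures[names(wcs$seqs)], wcs$seqs)) {
    stop("internal error: consensus alignment does not reproduce the sequences")
  }
  res
}
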