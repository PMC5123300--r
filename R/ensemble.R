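#' Split sequences into a backbone and queries
#'
#' The backbone is a uniform random subset without replacement,
#' deterministic given the seed. Optionally only sequences within 25 % of
#' the median length are eligible (a full-length filter for fragmentary
#' data).
#'
#' @param seqs A `dcm_seqs` vector (>= 4 sequences).
#' @param size Backbone size; capped at the number of (eligible) sequences.
#' @param seed Integer RNG seed.
#' @param full_length_filter Restrict the backbone to sequences within 25 %
#'   of the median length.
#' @return List with `backbone` and `queries` (disjoint id vectors whose
#'   union is all ids).
#' @export
select_backbone <- function(seqs, size, seed = 1L, full_length_filter = FALSE) {
  if (length(seqs) < 4L) stop("need at least 4 sequences")
  if (size < 4L) stop("backbone size must be >= 4")
  set.seed(seed)
  ids <- names(seqs)
  eligible <- ids
  if (full_length_filter) {
    lens <- nchar(seqs)
    med <- stats::median(lens)
    eligible <- ids[abs(lens - med) <= 0.25 * med]
    if (length(eligible) < 4L) eligible <- ids
  }
  k <- min(size, length(eligible))
  backbone <- sort(sample(eligible, k))
  list(backbone = backbone, queries = setdiff(ids, backbone))
}

#' Build an ensemble of profile HMMs on a backbone alignment
#'
#' The backbone tree is decomposed recursively by centroid edges, retaining
#' every intermediate subset: the full set, each centroid half, and so on
#' while a side still holds at least `min_subset` leaves. One HMM is built
#' per retained subset on the induced subalignment.
#'
#' @param backbone_aln The backbone `msa`.
#' @param backbone_tree A `phylo` whose leaf set equals the alignment ids.
#' @param min_subset Smallest subset to retain (>= 2; default 10).
#' @param pseudocount Passed to [build_hmm()].
#' @return Object of class `hmm_ensemble`: a list of entries, each with
#'   `ids`, `hmm`, and `colmap` (backbone column index of each HMM match
#'   state).
#' @export
build_ensemble <- function(backbone_aln, backbone_tree, min_subset = 10L,
                           pseudocount = 0.1) {
  if (min_subset < 2L) stop("min_subset must be >= 2")
  if (!setequal(backbone_tree$tip.label, rownames(backbone_aln))) {
    stop("backbone tree leaves do not match alignment ids")
  }
  entries <- list()
  add_entry <- function(ids) {
    sub <- induced_subalignment(backbone_aln, ids)
    colmap_sub <- attr(sub, "colmap")
    hmm <- build_hmm(sub, pseudocount)
    entries[[length(entries) + 1L]] <<-
      list(ids = sort(ids), hmm = hmm, colmap = colmap_sub[hmm$match_cols])
  }
  recurse <- function(tr) {
    add_entry(tr$tip.label)
    if (length(tr$tip.label) < 2L) return(invisible(NULL))
    ce <- centroid_edge(tr)
    for (side in list(ce$side1, ce$side2)) {
      if (length(side) >= min_subset) recurse(ape::keep.tip(tr, side))
    }
    invisible(NULL)
  }
  recurse(backbone_tree)
  structure(entries, class = "hmm_ensemble")
}

#' Place one query sequence on the backbone via its best-bitscore HMM
#'
#' The query is scored against every HMM in the ensemble by forward
#' bitscore; the best model (ties: larger subset, then lexicographically
#' smallest subset) aligns the query by Viterbi. Match-state residues map
#' to the corresponding backbone columns (uppercase, homologous);
#' insert-state residues become lowercase non-homologous insertions
#' anchored between their flanking match columns.
#'
#' @param q Named length-1 character vector (or `dcm_seqs` element); the id
#'   must not be a backbone id.
#' @param ens A [build_ensemble()].
#' @param backbone_aln The backbone `msa`.
#' @return List of class `query_placement`: `id`, `hmm_index`, `bitscore`,
#'   `cols` (backbone column of each match-placed residue, with the
#'   residue), `inserts` (list of `after_col` / `residues` runs).
#' @export
place_query <- function(q, ens, backbone_aln) {
  id <- names(q)
  if (is.null(id) || !nzchar(id)) stop("query must be named")
  if (id %in% rownames(backbone_aln)) stop("query id collides with backbone: ", id)
  s <- toupper(unclass(q)[[1L]])
  scores <- vapply(ens, function(e) score_query(e$hmm, s), 1)
  sizes <- vapply(ens, function(e) length(e$ids), 1L)
  keys <- vapply(ens, function(e) paste(e$ids, collapse = ","), character(1))
  best <- order(-scores, -sizes, keys)[1L]
  entry <- ens[[best]]
  vit <- viterbi_query(entry$hmm, s)
  path <- vit$path
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  match_rows <- path[, "state"] == 0L
  cols <- data.frame(col = entry$colmap[path[match_rows, "slot"]],
                     residue = chars[path[match_rows, "qpos"]])
  ins_rows <- which(path[, "state"] == 1L)
  inserts <- list()
  if (length(ins_rows)) {
    anchor <- vapply(ins_rows, function(r) {
      slot <- path[r, "slot"]
      if (slot == 0L) 0L else entry$colmap[[slot]]
    }, 1L)
    runs <- split(ins_rows, cumsum(c(1L, diff(ins_rows) != 1L | diff(anchor) != 0L)))
    for (rn in runs) {
      inserts[[length(inserts) + 1L]] <-
        list(after_col = if (path[rn[1L], "slot"] == 0L) 0L else entry$colmap[[path[rn[1L], "slot"]]],
             residues = tolower(paste(chars[path[rn, "qpos"]], collapse = "")))
    }
  }
  structure(list(id = id, hmm_index = best, bitscore = scores[best],
                 cols = cols, inserts = inserts),
            class = "query_placement")
}

#' Align a large sequence set by backbone extension
#'
#' Selects a random backbone, aligns it with the iterative divide-and-
#' conquer pipeline, builds the HMM ensemble on the backbone alignment and
#' tree, places every remaining query independently with its best-bitscore
#' HMM, and merges all extended rows. Backbone columns are unchanged in the
#' output; insert-state residues appear as lowercase singleton columns.
#'
#' @param seqs A `dcm_seqs` vector (>= 5 sequences).
#' @param backbone_size Number of backbone sequences (default
#'   `min(1000, n)`).
#' @param config A [pasta_config()] for the backbone alignment.
#' @param min_subset Ensemble granularity (see [build_ensemble()]).
#' @param seed Integer RNG seed for backbone selection.
#' @param full_length_filter Passed to [select_backbone()].
#' @return List of class `upp_result`: `alignment` (full `msa`),
#'   `backbone_alignment`, `backbone_tree`, `placements`.
#' @export
upp_align <- function(seqs, backbone_size = min(1000L, length(seqs)),
                      config = pasta_config(), min_subset = 10L, seed = 1L,
                      full_length_filter = FALSE) {
  if (length(seqs) < 5L) stop("need at least 5 sequences")
  split <- select_backbone(seqs, backbone_size, seed = seed,
                           full_length_filter = full_length_filter)
  bb_seqs <- new_seqs(unclass(seqs)[split$backbone])
  bb <- tryCatch(pasta_iterate(bb_seqs, config),
                 error = function(e) stop("backbone alignment stage failed: ",
                                          conditionMessage(e)))
  if (length(split$queries) == 0L) {
    return(structure(list(alignment = bb$alignment,
                          backbone_alignment = bb$alignment,
                          backbone_tree = bb$tree, placements = list()),
                     class = "upp_result"))
  }
  ens <- tryCatch(build_ensemble(bb$alignment, bb$tree, min_subset = min_subset),
                  error = function(e) stop("ensemble stage failed: ",
                                           conditionMessage(e)))
  placements <- lapply(sort(split$queries), function(qid) {
    tryCatch(place_query(setNames(unclass(seqs)[qid], qid), ens, bb$alignment),
             error = function(e) stop("placement stage failed for ", qid, ": ",
                                      conditionMessage(e)))
  })
  aln <- assemble_extended(bb$alignment, placements)
  structure(list(alignment = aln, backbone_alignment = bb$alignment,
                 backbone_tree = bb$tree, placements = placements),
            class = "upp_result")
}

# merge placements onto the immutable backbone columns
assemble_extended <- function(backbone_aln, placements) {
  bm <- unclass(backbone_aln)
  nb <- ncol(bm)
  # insertion runs grouped by anchor column (0 = before the first column),
  # ordered by query id for determinism
  ins_by_anchor <- vector("list", nb + 1L)
  for (p in placements) {
    for (run in p$inserts) {
      a <- run$after_col + 1L
      ins_by_anchor[[a]] <- c(ins_by_anchor[[a]],
                              setNames(list(run$residues), p$id))
    }
  }
  qids <- vapply(placements, `[[`, character(1), "id")
  width <- nb + sum(vapply(placements, function(p) {
    sum(vapply(p$inserts, function(r) nchar(r$residues), 1L))
  }, 1L))
  all_ids <- c(rownames(bm), qids)
  out <- matrix(GAP, length(all_ids), width, dimnames = list(all_ids, NULL))
  qcol_of_bbcol <- integer(nb)  # backbone col -> output col
  pos <- 0L
  emit_inserts <- function(anchor, pos) {
    runs <- ins_by_anchor[[anchor]]
    if (is.null(runs)) return(pos)
    for (qid in sort(names(runs))) {
      res <- strsplit(runs[[qid]], "", fixed = TRUE)[[1L]]
      for (ch in res) {
        pos <- pos + 1L
        out[qid, pos] <<- ch
      }
    }
    pos
  }
  pos <- emit_inserts(1L, pos)
  for (j in seq_len(nb)) {
    pos <- pos + 1L
    out[seq_len(nrow(bm)), pos] <- bm[, j]
    qcol_of_bbcol[j] <- pos
    pos <- emit_inserts(j + 1L, pos)
  }
  stopifnot(pos == width)
  for (k in seq_along(placements)) {
    p <- placements[[k]]
    if (nrow(p$cols)) out[p$id, qcol_of_bbcol[p$cols$col]] <- toupper(p$cols$residue)
  }
  msa_quiet(out)
}
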