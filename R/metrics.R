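# cell table of homologous (uppercase) cells: keys "id:site" -> column index
homologous_cells <- function(aln) {
  m <- unclass(aln)
  sitemat <- site_index_matrix(m)
  hom <- m != GAP & m == toupper(m)
  keys <- character(0); cols <- integer(0)
  for (i in seq_len(nrow(m))) {
    jj <- which(hom[i, ])
    keys <- c(keys, paste0(rownames(m)[i], ":", sitemat[i, jj]))
    cols <- c(cols, jj)
  }
  list(keys = keys, cols = cols)
}

#' Alignment precision, recall and total-column score
#'
#' Recall (SP score, 1 - SPFN) is the fraction of the reference alignment's
#' homologous site pairs present in the estimated alignment; precision
#' (modeller score, 1 - SPFP) is the fraction of the estimated alignment's
#' pairs that are in the reference; the TC score is the fraction of
#' reference columns whose full support is reproduced as a column of the
#' estimate. Lowercase (insertion) cells contribute no pairs and are
#' excluded from column identity. All values are percentages.
#'
#' @param est,ref `msa` objects over the same sequences (same ids and
#'   ungapped residues).
#' @return List with `precision_pct`, `recall_pct`, `tc_pct`, and the raw
#'   pair counts.
#' @export
alignment_scores <- function(est, ref) {
  stopifnot(is_msa(est), is_msa(ref))
  ue <- ungap(est); ur <- ungap(ref)
  ue <- ue[order(names(ue))]; ur <- ur[order(names(ur))]
  if (!identical(ue, ur)) {
    stop("estimated and reference alignments are over different sequence sets")
  }
  ce <- homologous_cells(est)
  cr <- homologous_cells(ref)
  pairs_of <- function(cells) {
    k <- tabulate(cells$cols)
    sum(choose(k[k > 1L], 2))
  }
  n_ref <- pairs_of(cr)
  if (n_ref == 0) stop("reference alignment has no homologous pairs")
  n_est <- pairs_of(ce)
  # cells homologous in both, tagged by their (ref column, est column) pair
  common <- intersect(cr$keys, ce$keys)
  rc <- cr$cols[match(common, cr$keys)]
  ec <- ce$cols[match(common, ce$keys)]
  joint <- table(paste(rc, ec))
  n_shared <- sum(choose(joint[joint > 1L], 2))
  # TC over reference columns with >= 1 homologous cell
  key_of_cols <- function(cells) {
    sp <- split(cells$keys, cells$cols)
    vapply(sp, function(v) paste(sort(v), collapse = "|"), character(1))
  }
  rk <- key_of_cols(cr)
  ek <- key_of_cols(ce)
  tc <- 100 * sum(rk %in% ek) / length(rk)
  list(precision_pct = 100 * n_shared / n_est,
       recall_pct = 100 * n_shared / n_ref,
       tc_pct = tc,
       shared_pairs = n_shared, est_pairs = n_est, ref_pairs = n_ref)
}

# canonical non-trivial bipartitions of an unrooted tree, as sorted label
# strings of the side not containing the reference (first sorted) leaf
tree_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1L]
  sets <- edge_child_leafsets(tree)
  n <- length(labs)
  keys <- vapply(sets, function(side) {
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds error of an estimated tree
#'
#' By default the asymmetric normalization: the percentage of the reference
#' tree's non-trivial bipartitions that are missing from the estimated
#' tree. `symmetric = TRUE` instead returns the normalized symmetric RF
#' distance.
#'
#' @param est,ref `phylo` objects on identical leaf sets (>= 4 leaves).
#' @param symmetric Use the symmetric Robinson-Foulds distance.
#' @return Percentage in \[0, 100\].
#' @export
rf_error <- function(est, ref, symmetric = FALSE) {
  if (!setequal(est$tip.label, ref$tip.label)) stop("trees have different leaf sets")
  if (length(ref$tip.label) < 4L) stop("need at least 4 leaves")
  br <- tree_bipartitions(ref)
  be <- tree_bipartitions(est)
  if (length(br) == 0L) stop("reference tree has no non-trivial bipartition")
  if (!symmetric) {
    100 * length(setdiff(br, be)) / length(br)
  } else {
    100 * (length(setdiff(br, be)) + length(setdiff(be, br))) /
      (length(br) + length(be))
  }
}

#' Change in RF error attributable to alignment estimation error
#'
#' RF error (against the true tree) of the tree computed on the estimated
#' alignment, minus the RF error of the tree computed on the true
#' alignment. Negative values mean the estimated alignment led to a better
#' tree.
#'
#' @param est_aln_tree,true_aln_tree,true_tree `phylo` objects on the same
#'   leaves.
#' @return Signed percentage points.
#' @export
delta_rf <- function(est_aln_tree, true_aln_tree, true_tree) {
  rf_error(est_aln_tree, true_tree) - rf_error(true_aln_tree, true_tree)
}

#' Summary statistics of a (true) alignment
#'
#' p-distances are computed over positions where both sequences are
#' non-gap (ambiguity codes count as mismatches); gap statistics are per
#' maximal gap run.
#'
#' @param true_aln An `msa`.
#' @return List with `p_distance_avg_pct`, `p_distance_max_pct`,
#'   `gaps_per_seq`, `gap_len_avg`, `pct_blank`, `n_sites`.
#' @export
dataset_summary <- function(true_aln) {
  stopifnot(is_msa(true_aln))
  m <- toupper(unclass(true_aln))
  n <- nrow(m); L <- ncol(m)
  gap <- m == GAP
  pd <- c()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        warning("sequences ", rownames(m)[i], " and ", rownames(m)[j],
                " share no ungapped positions; pair skipped")
        next
      }
      pd <- c(pd, mean(m[i, ok] != m[j, ok]))
    }
  }
  runs <- unlist(lapply(seq_len(n), function(i) {
    r <- rle(gap[i, ])
    r$lengths[r$values]
  }))
  list(p_distance_avg_pct = 100 * mean(pd),
       p_distance_max_pct = 100 * max(pd),
       gaps_per_seq = length(runs) / n,
       gap_len_avg = if (length(runs)) mean(runs) else 0,
       pct_blank = 100 * mean(gap),
       n_sites = L)
}

#' Paired one-sided comparison of two methods across replicates
#'
#' One-sided paired Student's t-test on the per-replicate differences
#' `a - b`. With zero-variance differences the p-value degenerates to 0 or
#' 1 by the sign of the common difference (0.5 when all differences are
#' zero), with a warning.
#'
#' @param metric_a,metric_b Equal-length numeric vectors (>= 2 replicates).
#' @param alternative `"greater"` tests whether `a` exceeds `b`.
#' @return List with `p_value`, `t`, `mean_diff`, `n`.
#' @export
paired_comparison <- function(metric_a, metric_b,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(metric_a) != length(metric_b)) stop("vectors must have equal length")
  n <- length(metric_a)
  if (n < 2L) stop("need at least 2 replicates")
  d <- metric_a - metric_b
  if (sd(d) == 0) {
    warning("zero variance of paired differences; degenerate p-value")
    md <- mean(d)
    p <- if (md == 0) 0.5 else {
      hit <- (md > 0) == (alternative == "greater")
      if (hit) 0 else 1
    }
    return(list(p_value = p, t = if (md == 0) 0 else sign(md) * Inf,
                mean_diff = md, n = n))
  }
  tt <- t.test(metric_a, metric_b, paired = TRUE, alternative = alternative)
  list(p_value = unname(tt$p.value), t = unname(tt$statistic),
       mean_diff = mean(d), n = n)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up control of the false discovery rate over the supplied p-value
#' family.
#'
#' @param pvals Numeric p-values.
#' @param q Target FDR (default 0.05).
#' @return Logical rejection flags.
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  p.adjust(pvals, method = "BH") <= q
}
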