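#' Define a sequence evolution model
#'
#' General time-reversible substitutions with optional discrete-gamma rate
#' heterogeneity, plus an insertion/deletion event process: along a branch of
#' length `t`, the number of insertion (deletion) events is Poisson with mean
#' `rate * t * L`, where `L` is the sequence length at the start of the
#' branch; each event has a uniform position and a geometric length.
#'
#' @param exchangeabilities Six GTR exchangeability parameters in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Positive shape of the gamma rate distribution, or
#'   `NULL` for rate homogeneity. Discretized to 4 categories by the median
#'   method.
#' @param insertion_rate,deletion_rate Expected events per site per unit
#'   branch length.
#' @param indel_mean_len Mean indel length (geometric on \{1, 2, ...\}).
#' @param root_length Length of the root sequence (positive integer).
#' @return An object of class `evolution_model`.
#' @export
evolution_model <- function(exchangeabilities = rep(1, 6),
                            base_freqs = rep(0.25, 4),
                            gamma_shape = NULL,
                            insertion_rate = 0,
                            deletion_rate = 0,
                            indel_mean_len = 2,
                            root_length = 1000L) {
  stopifnot(length(exchangeabilities) == 6L, length(base_freqs) == 4L)
  if (any(exchangeabilities < 0) || any(base_freqs < 0)) stop("rates and frequencies must be non-negative")
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base frequencies must sum to 1")
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be positive")
  if (insertion_rate < 0 || deletion_rate < 0) stop("indel rates must be non-negative")
  if (indel_mean_len < 1) stop("mean indel length must be >= 1")
  root_length <- as.integer(root_length)
  if (is.na(root_length) || root_length < 1L) stop("root_length must be a positive integer")
  structure(list(exchangeabilities = exchangeabilities,
                 base_freqs = base_freqs / sum(base_freqs),
                 gamma_shape = gamma_shape,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 indel_mean_len = indel_mean_len,
                 root_length = root_length),
            class = "evolution_model")
}

# scaled GTR rate matrix (expected 1 substitution per site per unit time)
gtr_rate_matrix <- function(model) {
  r <- model$exchangeabilities
  pi <- model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(DNA_CORE, DNA_CORE))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate substitution model")
  Q / mu
}

# P(t) by eigendecomposition of Q (GTR is diagonalizable)
transition_matrix <- function(eig, t) {
  P <- eig$vectors %*% diag(exp(eig$values * t)) %*% eig$inv
  P[P < 0] <- 0
  P / rowSums(P)
}

# median-method discrete gamma category rates, normalized to mean 1
gamma_category_rates <- function(shape, k = 4L) {
  if (is.null(shape)) return(1)
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = shape, rate = shape)
  r / mean(r)
}

#' Generate a model tree for simulation
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param shape `"birth-death"` (Yule), `"caterpillar"`, or `"balanced"`
#'   (requires `n_leaves` a power of two).
#' @param scale Expected root-to-tip path length in substitutions per site;
#'   branch lengths are rescaled so the mean root-to-tip depth equals
#'   `scale`.
#' @param seed Integer RNG seed.
#' @return A rooted `phylo` with leaves `t0001`, `t0002`, ...
#' @export
make_model_tree <- function(n_leaves, shape = c("birth-death", "caterpillar", "balanced"),
                            scale = 0.4, seed = 1L) {
  shape <- match.arg(shape)
  if (n_leaves < 2L) stop("n_leaves must be >= 2")
  if (scale <= 0) stop("scale must be positive")
  set.seed(seed)
  if (n_leaves == 2L) {
    tr <- ape::read.tree(text = "(t0001:1,t0002:1);")
    tr$edge.length <- tr$edge.length * (scale / 1)
    return(tr)
  }
  tr <- switch(shape,
    "birth-death" = ape::rphylo(n_leaves, birth = 1, death = 0),
    "caterpillar" = ape::stree(n_leaves, type = "left"),
    "balanced" = {
      if (abs(log2(n_leaves) - round(log2(n_leaves))) > 1e-9) {
        stop("balanced shape requires n_leaves to be a power of two")
      }
      ape::stree(n_leaves, type = "balanced")
    })
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("t%04d", seq_len(n_leaves))
  tr$node.label <- NULL
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_leaves)]
  tr$edge.length <- tr$edge.length * (scale / mean(depths))
  tr
}

#' Evolve sequences down a tree with substitutions and indels
#'
#' The root sequence is drawn from the equilibrium base frequencies. Along
#' each branch, substitutions are applied by exact transition sampling
#' (matrix exponential of the scaled GTR rate matrix, per gamma category),
#' then insertion and deletion events are drawn (counts Poisson in the
#' branch-start length, positions uniform, lengths geometric) and applied
#' sequentially in random order. Global column bookkeeping produces the true
#' alignment: an inserted site is homologous only within the subtree below
#' the insertion. Inserted residues are drawn from the equilibrium
#' frequencies and receive a fresh gamma category.
#'
#' @param tree A rooted `phylo` with non-negative branch lengths.
#' @param model An [evolution_model()].
#' @param seed Integer RNG seed; the whole simulation is deterministic given
#'   the seed.
#' @return List of class `simulation_result`: `true_alignment` (an [msa]),
#'   `leaf_sequences` (a `dcm_seqs` vector), `model_tree` (the unrooted
#'   version of `tree`), and `seed`.
#' @export
simulate_msa <- function(tree, model, seed = 1L) {
  stopifnot(inherits(model, "evolution_model"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  set.seed(seed)

  Q <- gtr_rate_matrix(model)
  ev <- eigen(Q)
  eig <- list(values = Re(ev$values), vectors = Re(ev$vectors),
              inv = Re(solve(ev$vectors)))
  cat_rates <- gamma_category_rates(model$gamma_shape)
  ncat <- length(cat_rates)
  pi <- model$base_freqs

  L0 <- model$root_length
  next_col <- L0 + 1L
  global_cols <- seq_len(L0)  # total order of all alignment columns ever created

  root_states <- sample.int(4L, L0, replace = TRUE, prob = pi)
  root_cats <- sample.int(ncat, L0, replace = TRUE)

  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  leaf_states <- vector("list", ntip)
  leaf_cols <- vector("list", ntip)

  sample_indel_len <- function() 1L + stats::rgeom(1L, prob = 1 / model$indel_mean_len)

  evolve_branch <- function(states, cats, cols, bl) {
    L <- length(states)
    if (L > 0L && bl > 0) {
      # substitutions: exact transition sampling per category, into a fresh
      # vector so a site is substituted exactly once per branch
      new_states <- states
      for (c in seq_len(ncat)) {
        idx <- which(cats == c)
        if (!length(idx)) next
        P <- transition_matrix(eig, bl * cat_rates[c])
        for (s in 1:4) {
          ii <- idx[states[idx] == s]
          if (length(ii)) new_states[ii] <- sample.int(4L, length(ii), replace = TRUE, prob = P[s, ])
        }
      }
      states <- new_states
      # indel events: counts from branch-start length
      n_ins <- stats::rpois(1L, model$insertion_rate * bl * L)
      n_del <- stats::rpois(1L, model$deletion_rate * bl * L)
      events <- sample(rep(c("I", "D"), c(n_ins, n_del)))
      for (e in events) {
        L <- length(states)
        if (e == "I") {
          pos <- sample.int(L + 1L, 1L) - 1L  # insert after position pos (0 = front)
          len <- sample_indel_len()
          new_states <- sample.int(4L, len, replace = TRUE, prob = pi)
          new_cats <- sample.int(ncat, len, replace = TRUE)
          new_ids <- next_col:(next_col + len - 1L)
          next_col <<- next_col + len
          # global order: new columns go directly after the left flanking column
          gpos <- if (pos == 0L) 0L else match(cols[pos], global_cols)
          global_cols <<- append(global_cols, new_ids, after = gpos)
          states <- append(states, new_states, after = pos)
          cats <- append(cats, new_cats, after = pos)
          cols <- append(cols, new_ids, after = pos)
        } else {
          if (L == 0L) next
          start <- sample.int(L, 1L)
          len <- sample_indel_len()
          drop <- start:min(start + len - 1L, L)
          states <- states[-drop]; cats <- cats[-drop]; cols <- cols[-drop]
        }
      }
    }
    list(states = states, cats = cats, cols = cols)
  }

  recurse <- function(node, states, cats, cols) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {  # leaf
      leaf_states[[node]] <<- states
      leaf_cols[[node]] <<- cols
      return(invisible(NULL))
    }
    for (k in kids) {
      res <- evolve_branch(states, cats, cols, tree$edge.length[k])
      recurse(tree$edge[k, 2L], res$states, res$cats, res$cols)
    }
    invisible(NULL)
  }
  recurse(root_node, root_states, root_cats, seq_len(L0))

  # assemble true alignment over columns present in >= 1 leaf
  used <- global_cols[global_cols %in% unique(unlist(leaf_cols))]
  mat <- matrix(GAP, nrow = ntip, ncol = length(used),
                dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) {
    j <- match(leaf_cols[[i]], used)
    mat[i, j] <- DNA_CORE[leaf_states[[i]]]
  }
  true_aln <- msa_quiet(mat)
  leaves <- new_seqs(ungap(true_aln))
  stopifnot(identical(unname(nchar(leaves)), unname(vapply(leaf_states, length, 1L))))
  structure(list(true_alignment = true_aln,
                 leaf_sequences = leaves,
                 model_tree = if (length(tree$tip.label) > 2L) ape::unroot(tree) else tree,
                 seed = seed),
            class = "simulation_result")
}

#' Replace sequences by contiguous fragments
#'
#' Stresses the HMM-ensemble extension stage with fragmentary data: a chosen
#' fraction of the sequences is replaced by a contiguous substring whose
#' length is a clipped normal around `mean_len`.
#'
#' @param seqs A `dcm_seqs` vector.
#' @param fraction Fraction of sequences to fragment, in \[0, 1\].
#' @param mean_len Mean fragment length (>= 1); the standard deviation is
#'   `mean_len / 4`.
#' @param seed Integer RNG seed.
#' @return A `dcm_seqs` vector of the same ids.
#' @export
fragmentize <- function(seqs, fraction, mean_len, seed = 1L) {
  if (mean_len < 1) stop("mean_len must be >= 1")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  set.seed(seed)
  n <- length(seqs)
  k <- round(fraction * n)
  if (k == 0L) return(seqs)
  pick <- sort(sample.int(n, k))
  out <- unclass(seqs)
  for (i in pick) {
    L <- nchar(out[i])
    len <- max(1L, min(L, as.integer(round(rnorm(1L, mean_len, mean_len / 4)))))
    start <- sample.int(L - len + 1L, 1L)
    out[i] <- substr(out[i], start, start + len - 1L)
  }
  new_seqs(out)
}
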