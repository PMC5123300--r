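#' Specify a subset aligner
#'
#' Either the built-in progressive aligner, or an external command invoked
#' with `{input}` / `{output}` placeholders (e.g. a MAFFT or BAli-Phy
#' wrapper). External output is validated: it must contain exactly the input
#' sequences, with ungapped rows identical to the inputs.
#'
#' @param kind `"builtin"` or `"external"`.
#' @param params An [align_params()] (builtin only).
#' @param command Command template containing `{input}` and `{output}`
#'   (external only).
#' @param timeout Seconds before the external command is killed.
#' @return List of class `subset_aligner`.
#' @export
subset_aligner <- function(kind = c("builtin", "external"),
                           params = align_params(),
                           command = NULL, timeout = 3600) {
  kind <- match.arg(kind)
  if (kind == "external") {
    if (is.null(command) || !grepl("{input}", command, fixed = TRUE) ||
        !grepl("{output}", command, fixed = TRUE)) {
      stop("external aligner command must contain {input} and {output} placeholders")
    }
  }
  structure(list(kind = kind, params = params, command = command,
                 timeout = timeout),
            class = "subset_aligner")
}

#' Align one subset of sequences
#'
#' @param seqs A `dcm_seqs` vector (>= 1 sequence).
#' @param spec A [subset_aligner()].
#' @return An `msa` over exactly the input ids.
#' @export
align_subset <- function(seqs, spec = subset_aligner()) {
  stopifnot(inherits(spec, "subset_aligner"))
  if (length(seqs) == 0L) stop("no sequences to align")
  if (spec$kind == "builtin") {
    return(progressive_align(seqs, spec$params))
  }
  run_external_aligner(seqs, spec)
}

run_external_aligner <- function(seqs, spec) {
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_fasta(unclass(seqs), tmp_in)
  cmd <- gsub("{input}", tmp_in, spec$command, fixed = TRUE)
  cmd <- gsub("{output}", tmp_out, cmd, fixed = TRUE)
  err <- tempfile()
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = err,
                    timeout = spec$timeout)
  if (status != 0L) {
    stop("external aligner failed (exit ", status, "): ",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  }
  if (!file.exists(tmp_out) || file.size(tmp_out) == 0L) {
    stop("external aligner produced no output")
  }
  aln <- read_fasta(tmp_out)
  if (!is_msa(aln)) {
    if (length(unique(nchar(aln))) == 1L) {
      aln <- msa(setNames(unclass(aln), names(aln)))  # gap-free alignment
    } else {
      stop("external aligner output is not an alignment")
    }
  }
  if (!setequal(rownames(aln), names(seqs))) {
    stop("external aligner lost or renamed sequences")
  }
  ung <- ungap(aln)[names(seqs)]
  if (!identical(unname(ung), unname(toupper(unclass(seqs))))) {
    stop("external aligner mutated sequence residues")
  }
  reorder_rows(aln, names(seqs))
}

#' Configuration for the iterative divide-and-conquer alignment
#'
#' Defaults follow standard PASTA practice: three iterations with maximum
#' subset size 200, with an optional final "boost" iteration using a
#' different (typically more expensive) subset aligner at maximum subset
#' size 100.
#'
#' @param iterations Number of decompose-align-merge iterations (>= 1).
#' @param max_subset Maximum subset size for the decomposition (>= 2).
#' @param aligner A [subset_aligner()] for the main iterations.
#' @param boost_aligner Optional [subset_aligner()] for one extra final
#'   iteration (`NULL` to disable boosting).
#' @param boost_max_subset Maximum subset size for the boost iteration.
#' @param merge_params An [align_params()] for the pairwise profile merges.
#' @param tree_correction Distance correction for the per-iteration NJ tree.
#' @return List of class `pasta_config`.
#' @export
pasta_config <- function(iterations = 3L, max_subset = 200L,
                         aligner = subset_aligner(),
                         boost_aligner = NULL, boost_max_subset = 100L,
                         merge_params = align_params(),
                         tree_correction = "jc") {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (max_subset < 2L || boost_max_subset < 2L) stop("subset sizes must be >= 2")
  structure(list(iterations = as.integer(iterations),
                 max_subset = as.integer(max_subset),
                 aligner = aligner,
                 boost_aligner = boost_aligner,
                 boost_max_subset = as.integer(boost_max_subset),
                 merge_params = merge_params,
                 tree_correction = tree_correction),
            class = "pasta_config")
}

# one decompose-align-merge pass given a guide tree
dcm_pass <- function(seqs, tree, max_subset, aligner, merge_params) {
  if (length(seqs) <= max_subset) {
    return(list(alignment = align_subset(seqs, aligner),
                decomposition = list(subsets = list(sort(names(seqs))),
                                     adjacency = matrix(integer(0), ncol = 2L)),
                subalns = NULL))
  }
  dec <- decompose_tree(tree, max_subset)
  subalns <- lapply(dec$subsets, function(ids) {
    tryCatch(align_subset(new_seqs(unclass(seqs)[ids]), aligner),
             error = function(e) {
               stop("subset aligner failed on subset {", paste(ids, collapse = ","),
                    "}: ", conditionMessage(e))
             })
  })
  g <- merge_graph(subalns, dec$adjacency, merge_params)
  list(alignment = transitivity_merge(g), decomposition = dec, subalns = subalns)
}

#' Iterative divide-and-conquer co-estimation of alignment and tree
#'
#' Starts from the built-in progressive alignment of the full set (or a
#' user-supplied initial alignment), then repeats: estimate a guide tree
#' from the current alignment, break the tree into subsets by centroid-edge
#' decomposition, align each subset, merge adjacent subset alignments
#' profile-to-profile, and combine everything into a full alignment by
#' transitivity. Optionally runs one extra "boost" iteration with a
#' different subset aligner and subset size.
#'
#' @param seqs A `dcm_seqs` vector (>= 4 sequences).
#' @param config A [pasta_config()].
#' @param initial_alignment Optional starting `msa` over the input ids.
#' @return List of class `pasta_result`: `alignment`, `tree`, and `history`
#'   (one record per iteration, holding the alignment, the guide tree used
#'   and the decomposition).
#' @export
pasta_iterate <- function(seqs, config = pasta_config(), initial_alignment = NULL) {
  stopifnot(inherits(config, "pasta_config"))
  if (length(seqs) < 4L) stop("pasta_iterate needs at least 4 sequences")
  aln <- if (is.null(initial_alignment)) {
    align_subset(seqs, config$aligner)
  } else {
    stopifnot(is_msa(initial_alignment))
    if (!setequal(rownames(initial_alignment), names(seqs))) {
      stop("initial alignment ids do not match input sequences")
    }
    initial_alignment
  }
  history <- list(list(iteration = 0L, alignment = aln, tree = NULL,
                       decomposition = NULL))

  passes <- rep(list(list(max_subset = config$max_subset, aligner = config$aligner)),
                config$iterations)
  if (!is.null(config$boost_aligner)) {
    passes <- c(passes, list(list(max_subset = config$boost_max_subset,
                                  aligner = config$boost_aligner)))
  }
  tree <- NULL
  for (it in seq_along(passes)) {
    tree <- nj_tree(aln, config$tree_correction)
    pass <- dcm_pass(seqs, tree, passes[[it]]$max_subset, passes[[it]]$aligner,
                     config$merge_params)
    aln <- reorder_rows(pass$alignment, names(seqs))
    history[[length(history) + 1L]] <-
      list(iteration = it, alignment = aln, tree = tree,
           decomposition = pass$decomposition,
           subset_alignments = pass$subalns)
  }
  final_tree <- nj_tree(aln, config$tree_correction)
  structure(list(alignment = aln, tree = final_tree, history = history),
            class = "pasta_result")
}
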