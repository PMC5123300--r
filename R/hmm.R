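#' Build a profile HMM from an alignment
#'
#' Match states are the columns with at least 50 % non-gap cells. Match
#' emissions are `(frequency + pseudocount * background) / normalizer`
#' (frequencies, so the model is invariant to duplicating rows);
#' transition probabilities are estimated from the observed match /
#' insert / delete state paths of the rows, smoothed by adding
#' `pseudocount` to every structurally valid transition. Insert states emit
#' the background distribution; the null model is the background.
#'
#' @param aln An `msa` (>= 1 qualifying column).
#' @param pseudocount Non-negative smoothing weight (default 0.1).
#' @param background Background residue frequencies (A, C, G, T).
#' @return Object of class `profile_hmm` with elements `match_cols`
#'   (1-based column indices of `aln`), `emissions` (L x 4), `tM`, `tI`,
#'   `tD` ((L+1) x 3 transition matrices out of the states at each slot,
#'   destinations M/I/D), and `background`.
#' @export
build_hmm <- function(aln, pseudocount = 0.1, background = rep(0.25, 4)) {
  stopifnot(is_msa(aln))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  m <- toupper(unclass(aln))
  n <- nrow(m)
  nongap <- colSums(m != GAP)
  match_cols <- which(nongap >= n / 2)
  if (length(match_cols) == 0L) stop("no column with >= 50% non-gap cells")
  L <- length(match_cols)

  # frequencies rather than raw counts, so the model is invariant to
  # duplicating backbone rows
  em <- matrix(0, L, 4, dimnames = list(NULL, DNA_CORE))
  for (b in 1:4) em[, b] <- colSums(m[, match_cols, drop = FALSE] == DNA_CORE[b]) / n
  em <- em + pseudocount * matrix(background, L, 4, byrow = TRUE)
  norm <- rowSums(em)
  if (any(norm == 0)) stop("zero emission mass in a match column (pseudocount 0 with only ambiguity codes)")
  em <- em / norm

  # transition counts from observed row state paths
  is_match <- logical(ncol(m)); is_match[match_cols] <- TRUE
  slot_of_col <- cumsum(is_match)  # match index reached at/after each column
  cM <- matrix(0, L + 1L, 3L); cI <- cM; cD <- cM  # dest: M, I, D
  for (i in seq_len(n)) {
    prev_type <- 1L; prev_slot <- 0L  # Begin acts as M_0
    for (j in seq_len(ncol(m))) {
      resid <- m[i, j] != GAP
      if (is_match[j]) {
        type <- if (resid) 1L else 3L
        slot <- slot_of_col[j]
      } else {
        if (!resid) next
        type <- 2L
        slot <- slot_of_col[j]
      }
      if (prev_type == 1L) cM[prev_slot + 1L, type] <- cM[prev_slot + 1L, type] + 1
      if (prev_type == 2L) cI[prev_slot + 1L, type] <- cI[prev_slot + 1L, type] + 1
      if (prev_type == 3L) cD[prev_slot + 1L, type] <- cD[prev_slot + 1L, type] + 1
      prev_type <- type; prev_slot <- slot
    }
    # end transition (to "M" at slot L)
    if (prev_type == 1L) cM[prev_slot + 1L, 1L] <- cM[prev_slot + 1L, 1L] + 1
    if (prev_type == 2L) cI[prev_slot + 1L, 1L] <- cI[prev_slot + 1L, 1L] + 1
    if (prev_type == 3L) cD[prev_slot + 1L, 1L] <- cD[prev_slot + 1L, 1L] + 1
  }
  smooth <- function(cnt) {
    cnt <- cnt / n + pseudocount
    cnt[L + 1L, 3L] <- 0  # D_{L+1} does not exist
    sw <- rowSums(cnt)
    cnt / ifelse(sw == 0, 1, sw)
  }
  structure(list(match_cols = match_cols,
                 emissions = em,
                 tM = smooth(cM), tI = smooth(cI), tD = smooth(cD),
                 background = background,
                 pseudocount = pseudocount),
            class = "profile_hmm")
}

hmm_log_tables <- function(hmm) {
  lg <- function(x) ifelse(x > 0, log2(x), -1e300)
  list(em = lg(hmm$emissions), tM = lg(hmm$tM), tI = lg(hmm$tI), tD = lg(hmm$tD),
       ins = lg(hmm$background), amb = log2(0.25))
}

encode_query <- function(q) {
  ch <- strsplit(toupper(q), "", fixed = TRUE)[[1L]]
  code <- match(ch, DNA_CORE)
  code[is.na(code)] <- 0L  # ambiguity: scored as background
  code
}

#' Bitscore of a query sequence against a profile HMM
#'
#' `log2` of the ratio between the forward probability of the query under
#' the HMM and its probability under the background null model.
#'
#' @param hmm A [build_hmm()] model.
#' @param q A single sequence string (non-empty).
#' @return Finite numeric bitscore.
#' @export
score_query <- function(hmm, q) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (nchar(q) == 0L) stop("query must be non-empty")
  code <- encode_query(q)
  lt <- hmm_log_tables(hmm)
  fwd <- hmm_forward_log2(code, lt$em, lt$tM, lt$tI, lt$tD, lt$ins, lt$amb)
  null <- sum(ifelse(code == 0L, lt$amb, lt$ins[pmax(code, 1L)]))
  fwd - null
}

#' Viterbi alignment of a query to a profile HMM
#'
#' @param hmm A [build_hmm()] model.
#' @param q A single sequence string.
#' @return List with `log2prob` and `path`, a matrix of (state, slot, qpos)
#'   rows where state 0/1/2 = match/insert/delete, slot is the match-state
#'   index, and qpos the 1-based consumed query position (0 for deletes).
#' @export
viterbi_query <- function(hmm, q) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (nchar(q) == 0L) stop("query must be non-empty")
  code <- encode_query(q)
  lt <- hmm_log_tables(hmm)
  hmm_viterbi_path(code, lt$em, lt$tM, lt$tI, lt$tD, lt$ins, lt$amb)
}
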