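#' Alignment scoring scheme
#'
#' Linear gap-penalty scoring used by [global_align()] and [local_align()].
#' Defaults (match 1, mismatch -1, gap -2) are the pipeline-wide defaults.
#'
#' @param match integer match score (> mismatch).
#' @param mismatch integer mismatch score (<= 0).
#' @param gap integer per-base gap penalty (<= 0).
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme(1, -1, -2)
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (is.na(match) || is.na(mismatch) || is.na(gap))
    stop("scores must be integers")
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (mismatch > 0L) stop("mismatch score must be <= 0")
  if (gap > 0L) stop("gap penalty must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: match %+d, mismatch %+d, gap %+d (linear)\n",
              x$match, x$mismatch, x$gap))
  invisible(x)
}

.as_scheme <- function(s) {
  if (inherits(s, "scoring_scheme")) return(s)
  if (is.numeric(s) && length(s) == 3L) return(scoring_scheme(s[1], s[2], s[3]))
  stop("'s' must be a scoring_scheme or a numeric triple (match, mismatch, gap)")
}

.mk_alignment <- function(raw) {
  structure(raw, class = "pairwise_alignment")
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' End-to-end optimal alignment under a linear gap penalty. `N` scores as a
#' mismatch against everything. The traceback tie-break is fixed (diagonal
#' over up over left), so results are bit-reproducible.
#'
#' @param a,b nucleotide sequences over A,C,G,T,N (case-insensitive).
#' @param s a [scoring_scheme()] or numeric triple (match, mismatch, gap).
#' @return a `pairwise_alignment`: `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, and 0-based half-open coordinates `start_a`,
#'   `end_a`, `start_b`, `end_b` into the ungapped inputs.
#' @examples
#' global_align("ACGT", "AGT", scoring_scheme(1, -1, -1))
#' @export
global_align <- function(a, b, s = scoring_scheme()) {
  a <- .norm_seq(a, arg = "a"); b <- .norm_seq(b, arg = "b")
  s <- .as_scheme(s)
  .mk_alignment(.nw_align_cpp(a, b, s$match, s$mismatch, s$gap))
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Maximal-scoring local alignment; score is always >= 0, and an empty
#' alignment with score 0 is returned when no positive-scoring pair exists.
#'
#' @inheritParams global_align
#' @return a `pairwise_alignment` (see [global_align()]); its coordinate
#'   slots delimit the aligned substrings.
#' @examples
#' local_align("AAATTTCCC", "GGTTTGG", scoring_scheme(1, -1, -2))
#' @export
local_align <- function(a, b, s = scoring_scheme()) {
  a <- .norm_seq(a, arg = "a"); b <- .norm_seq(b, arg = "b")
  s <- .as_scheme(s)
  .mk_alignment(.sw_align_cpp(a, b, s$match, s$mismatch, s$gap))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %d, a[%d,%d) x b[%d,%d)\n",
              x$score, x$start_a, x$end_a, x$start_b, x$end_b))
  w <- 60L
  n <- nchar(x$aligned_a)
  for (i in seq(1L, max(n, 1L), by = w)) {
    if (n == 0L) break
    cat(substr(x$aligned_a, i, min(i + w - 1L, n)), "\n")
    cat(substr(x$aligned_b, i, min(i + w - 1L, n)), "\n\n")
  }
  invisible(x)
}

# Fraction of identical columns among columns ungapped on both sides.
.alignment_identity <- function(aln) {
  ca <- .seq_chars(aln$aligned_a); cb <- .seq_chars(aln$aligned_b)
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(NA_real_)
  mean(ca[keep] == cb[keep])
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' Counts transition- and transversion-differing columns over the comparable
#' columns of an alignment (pairwise deletion: columns with a gap or `N` on
#' either side are excluded) and applies the K2P correction
#' `kappa = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, the estimated number of
#' substitutions per site between the two sequences.
#'
#' @param aln a `pairwise_alignment`, or a list with equal-length
#'   `aligned_a` / `aligned_b` gapped strings.
#' @return an object of class `k2p_dist` with fields `P` (transition
#'   proportion), `Q` (transversion proportion), `kappa`, and `n_sites`.
#' @examples
#' k2p_distance(global_align("ACGTACGT", "ACGTACAT"))
#' @export
k2p_distance <- function(aln) {
  ca <- .seq_chars(toupper(aln$aligned_a))
  cb <- .seq_chars(toupper(aln$aligned_b))
  if (length(ca) != length(cb))
    stop("aligned strings must have equal length")
  keep <- ca %in% .BASES & cb %in% .BASES
  n <- sum(keep)
  if (n == 0L)
    stop("no comparable (ungapped, unambiguous) columns")
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  purine <- function(z) z %in% c("A", "G")
  transition <- diff & (purine(ca) == purine(cb))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined: sequences too diverged (saturation)")
  kappa <- -0.5 * log(w1) - 0.25 * log(w2)
  structure(list(P = P, Q = Q, kappa = kappa, n_sites = n),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance: kappa = %.5f (P = %.4f, Q = %.4f, %d sites)\n",
              x$kappa, x$P, x$Q, x$n_sites))
  invisible(x)
}
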