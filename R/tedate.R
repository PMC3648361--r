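# Nested insertion detection (TSD + LTR pair) and molecular dating from
# LTR-pair K2P divergence.

#' Convert an LTR-pair K2P distance to an insertion age
#'
#' The two LTRs of a retroelement are identical at insertion time and
#' diverge neutrally afterwards, so the insertion age is
#' `T = kappa / (2 r)` with `r` the substitution rate per site per year.
#' The default rate reproduces published LTR-pair (kappa, age) calibrations
#' for the nested insertions in maize CRM-derived tandem repeat arrays.
#'
#' @param kappa K2P distance between the 5' and 3' LTR.
#' @param r substitution rate per site per year (default 6.5e-9).
#' @return age in years.
#' @examples
#' kappa_to_age(0.0122) / 1e6   # ~0.94 My
#' @export
kappa_to_age <- function(kappa, r = 6.5e-9) {
  if (any(r <= 0)) stop("substitution rate must be positive")
  if (any(kappa < 0)) stop("kappa must be non-negative")
  kappa / (2 * r)
}

# longest exact duplication (length min_len..max_len) whose left copy ends at
# g0 and whose right copy ends at the anchor a1; returns 0 when none
.tsd_len <- function(gseq, g0, a1, min_len = 3L, max_len = 20L) {
  L <- min(max_len, g0, a1 - g0)
  while (L >= min_len) {
    if (.slice(gseq, g0 - L, g0) == .slice(gseq, a1 - L, a1)) return(L)
    L <- L - 1L
  }
  0L
}

#' Locate nested element insertions between tandem repeat islands
#'
#' Inspects every gap between consecutive islands: refines the gap
#' boundaries by local alignment of a tandem unit dimer against the
#' junction windows, searches for the longest exact target site duplication
#' (3-20 nt) flanking the gap, and looks for an LTR pair as the best local
#' self-match between the gap's first and last thirds with both hits
#' terminal-proximal. Candidates without a detectable LTR pair are reported
#' with `NA` LTR intervals. Strand is called only when a reference element
#' sequence is supplied (an LTR pair alone is strand-symmetric).
#'
#' @param genome named character vector of genomic sequences.
#' @param islands data.frame from [segment_islands()] (>= 2 rows), sorted.
#' @param unit reference repeat unit (for boundary refinement).
#' @param min_element_len minimum gap length to inspect (default 1000).
#' @param ltr_min_len,ltr_min_identity LTR-pair acceptance thresholds
#'   (default 100 nt at 80% identity).
#' @param element_ref optional known element sequence used to call strand.
#' @param target_id genome sequence name (default first).
#' @param s scoring scheme.
#' @return data.frame of class `nested_insertions`: `start0`, `end0`,
#'   `tsd`, `strand`, `ltr5_start0`, `ltr5_end0`, `ltr3_start0`,
#'   `ltr3_end0` (genome coordinates, `NA` when no LTR pair was found).
#' @export
find_insertions <- function(genome, islands, unit, min_element_len = 1000L,
                            ltr_min_len = 100L, ltr_min_identity = 0.8,
                            element_ref = NULL, target_id = names(genome)[1],
                            s = scoring_scheme()) {
  gseq <- .norm_seq(genome[[target_id]], arg = "genome")
  n <- nchar(gseq)
  unit <- .norm_seq(unit, arg = "unit")
  ulen <- nchar(unit)
  empty <- data.frame(start0 = integer(), end0 = integer(), tsd = character(),
                      strand = character(), ltr5_start0 = integer(),
                      ltr5_end0 = integer(), ltr3_start0 = integer(),
                      ltr3_end0 = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("nested_insertions", class(empty))
  if (nrow(islands) < 2L) return(empty)
  islands <- islands[order(islands$start0), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(islands) - 1L)) {
    g0 <- islands$end0[i]; g1 <- islands$start0[i + 1L]
    if (g1 - g0 < min_element_len) next
    # refine boundaries: the element is flanked by a monomer tail on the left
    # and (after the duplicated target site) a monomer head on the right, so
    # anchor both junctions with mismatch-tolerant unit tail/head probes
    w <- min(30L, ulen)
    tailp <- substr(unit, ulen - w + 1L, ulen)
    headp <- substr(unit, 1L, w)
    win0 <- c(max(0L, g0 - 60L - w), min(n, g0 + 60L))
    sc0 <- .probe_scan_cpp(.slice(gseq, win0[1], win0[2]), tailp) / w
    if (length(sc0) && max(sc0) >= 0.7) g0 <- win0[1] + which.max(sc0) - 1L + w
    win1 <- c(max(0L, g1 - 60L), min(n, g1 + 60L + w))
    sc1 <- .probe_scan_cpp(.slice(gseq, win1[1], win1[2]), headp) / w
    a1 <- if (length(sc1) && max(sc1) >= 0.7) win1[1] + which.max(sc1) - 1L else g1
    L <- .tsd_len(gseq, g0, a1)
    tsd_seq <- if (L > 0L) .slice(gseq, g0 - L, g0) else ""
    g1 <- a1 - L
    if (g1 - g0 < min_element_len) next
    elem <- .slice(gseq, g0, g1)
    third <- nchar(elem) %/% 3L
    ltr <- rep(NA_integer_, 4L)
    if (third >= ltr_min_len) {
      first <- .slice(elem, 0L, third)
      last <- .slice(elem, nchar(elem) - third, nchar(elem))
      aln <- local_align(first, last, s)
      idt <- .alignment_identity(aln)
      prox <- aln$start_a <= 0.25 * third &&
        aln$end_b >= 0.75 * third
      if (aln$score > 0 && !is.na(idt) && idt >= ltr_min_identity &&
          (aln$end_a - aln$start_a) >= ltr_min_len && prox) {
        off3 <- nchar(elem) - third
        ltr <- c(g0 + aln$start_a, g0 + aln$end_a,
                 g0 + off3 + aln$start_b, g0 + off3 + aln$end_b)
      }
    }
    strand <- "*"
    if (!is.null(element_ref)) {
      fwd <- local_align(elem, element_ref, s)$score
      rev <- local_align(elem, revcomp(element_ref), s)$score
      strand <- if (fwd >= rev) "+" else "-"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = g0, end0 = g1, tsd = tsd_seq, strand = strand,
      ltr5_start0 = ltr[1], ltr5_end0 = ltr[2],
      ltr3_start0 = ltr[3], ltr3_end0 = ltr[4], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("nested_insertions", class(out))
  out
}

#' Date a nested insertion from its LTR pair
#'
#' Globally aligns the 5' and 3' LTR of an insertion, computes their K2P
#' distance, and converts it to an age `T = kappa / (2 r)`.
#'
#' @param ins one row of a [find_insertions()] result (LTR intervals must
#'   be present).
#' @param genome named character vector holding the sequence.
#' @param r substitution rate per site per year (default 6.5e-9).
#' @param target_id genome sequence name (default first).
#' @param s scoring scheme.
#' @return object of class `insertion_age`: `kappa`, `P`, `Q`, `n_sites`,
#'   `r`, `T_years`, `T_my`.
#' @export
estimate_age <- function(ins, genome, r = 6.5e-9,
                         target_id = names(genome)[1], s = scoring_scheme()) {
  if (any(is.na(c(ins$ltr5_start0, ins$ltr5_end0, ins$ltr3_start0, ins$ltr3_end0))))
    stop("insertion has no detected LTR pair; cannot estimate age")
  gseq <- genome[[target_id]]
  ltr5 <- .slice(gseq, ins$ltr5_start0, ins$ltr5_end0)
  ltr3 <- .slice(gseq, ins$ltr3_start0, ins$ltr3_end0)
  k <- k2p_distance(global_align(ltr5, ltr3, s))
  T_years <- kappa_to_age(k$kappa, r)
  structure(list(kappa = k$kappa, P = k$P, Q = k$Q, n_sites = k$n_sites,
                 r = r, T_years = T_years, T_my = T_years / 1e6),
            class = "insertion_age")
}

#' @export
print.insertion_age <- function(x, ...) {
  cat(sprintf("insertion age: %.2f My (kappa = %.5f over %d sites, r = %.3g)\n",
              x$T_my, x$kappa, x$n_sites, x$r))
  invisible(x)
}
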