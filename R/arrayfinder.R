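# Tandem array detection: k-mer seeded homology search against a reference
# repeat unit, island segmentation, phase-normalised monomer extraction and
# internal periodicity measurement.

.kmer_starts <- function(seq, kmers, k) {
  n <- nchar(seq)
  if (n < k) return(integer())
  starts <- seq_len(n - k + 1L)
  gk <- substring(seq, starts, starts + k - 1L)
  starts[gk %in% kmers] - 1L                  # 0-based
}

# chain 0-based k-mer hit starts into runs separated by < max_gap
.chain_hits <- function(hits, k, max_gap) {
  if (!length(hits)) return(NULL)
  hits <- sort(hits)
  brk <- which(diff(hits) >= max_gap)
  grp_start <- c(1L, brk + 1L)
  grp_end <- c(brk, length(hits))
  data.frame(start0 = hits[grp_start], end0 = hits[grp_end] + k,
             n_hits = grp_end - grp_start + 1L)
}

#' Find tandem arrays homologous to a reference repeat unit
#'
#' Seeds exact k-mer matches of the unit on both strands of each genomic
#' sequence, chains collinear seeds closer than one unit length, and reports
#' chains spanning at least `min_monomers` unit-equivalents whose sampled
#' alignment identity to the unit reaches `min_identity`. Coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param genome named character vector of genomic sequences (see
#'   [read_fasta()]).
#' @param unit reference repeat unit sequence (>= 50 nt).
#' @param min_identity minimum mean percent identity of sampled unit-length
#'   windows (default 80).
#' @param min_monomers minimum span in unit-equivalents (default 2).
#' @param k seed k-mer length (default 13).
#' @param s scoring scheme for the identity windows.
#' @return a data.frame of class `array_hits` with columns `target_id`,
#'   `start0`, `end0`, `strand`, `n_monomer_equivalents`, `mean_identity`;
#'   attribute `match_mask` holds one logical per-base match indicator per
#'   hit (TRUE where a seeded k-mer covers the base).
#' @export
find_arrays <- function(genome, unit, min_identity = 80, min_monomers = 2,
                        k = 13L, s = scoring_scheme()) {
  unit <- .norm_seq(unit, arg = "unit")
  ulen <- nchar(unit)
  if (ulen < 50L) stop("reference unit must be at least 50 nt")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  # circular closure so k-mers spanning the monomer-monomer junction seed too
  ucirc <- paste0(unit, substr(unit, 1L, k - 1L))
  ust <- seq_len(ulen)
  ukmers <- unique(substring(ucirc, ust, ust + k - 1L))
  rows <- list(); masks <- list()
  for (nm in names(genome)) {
    gseq <- .norm_seq(genome[[nm]], arg = nm)
    n <- nchar(gseq)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") gseq else revcomp(gseq)
      hits <- .kmer_starts(sseq, ukmers, k)
      ch <- .chain_hits(hits, k, max_gap = ulen)
      if (is.null(ch)) next
      for (i in seq_len(nrow(ch))) {
        span <- ch$end0[i] - ch$start0[i]
        if (span / ulen < min_monomers) next
        # sampled identity: up to 3 unit-length windows, each aligned locally
        # against a unit dimer so the window's unknown phase does not matter
        uu <- paste0(unit, unit)
        nwin <- min(3L, max(1L, span %/% ulen))
        offs <- floor(seq(0, span - ulen, length.out = nwin))
        ids <- vapply(offs, function(o) {
          w <- .slice(sseq, ch$start0[i] + o, min(ch$start0[i] + o + ulen, ch$end0[i]))
          .alignment_identity(local_align(w, uu, s))
        }, numeric(1))
        mid <- 100 * mean(ids, na.rm = TRUE)
        if (is.na(mid) || mid < min_identity) next
        # mask and coordinates on the forward strand
        local_mask <- rep(FALSE, span)
        rel <- hits[hits >= ch$start0[i] & hits < ch$end0[i]] - ch$start0[i]
        for (d in 0:(k - 1L)) local_mask[rel + d + 1L] <- TRUE
        if (strand == "+") {
          st <- ch$start0[i]; en <- ch$end0[i]
        } else {
          st <- n - ch$end0[i]; en <- n - ch$start0[i]
          local_mask <- rev(local_mask)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = nm, start0 = st, end0 = en, strand = strand,
          n_monomer_equivalents = span / ulen, mean_identity = mid,
          n_hits = ch$n_hits[i], stringsAsFactors = FALSE)
        masks[[length(masks) + 1L]] <- local_mask
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(target_id = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      n_monomer_equivalents = numeric(),
                      mean_identity = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "match_mask") <- list()
    class(out) <- c("array_hits", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  # a chain found on both strands over the same span keeps the strand with
  # more seed hits
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i >= j || !keep[i] || !keep[j]) next
    if (out$target_id[i] != out$target_id[j]) next
    ov <- min(out$end0[i], out$end0[j]) - max(out$start0[i], out$start0[j])
    if (ov > 0.5 * min(out$end0[i] - out$start0[i], out$end0[j] - out$start0[j])) {
      drop <- if (out$n_hits[i] >= out$n_hits[j]) j else i
      keep[drop] <- FALSE
    }
  }
  masks <- masks[keep]
  out <- out[keep, , drop = FALSE]
  o <- order(out$target_id, out$start0)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "match_mask") <- masks[o]
  class(out) <- c("array_hits", class(out))
  out
}

#' Segment an array hit into uninterrupted islands
#'
#' Maximal runs of matching sequence separated by at least `gap_min`
#' non-matching bases become distinct islands, mirroring the separation of
#' tandem arrays by intervening sequences such as nested retroelements.
#'
#' @param hit one row of an [find_arrays()] result (data.frame or list with
#'   `start0`, `end0`).
#' @param match_mask logical per-base match indicator over the hit interval.
#' @param gap_min minimum non-matching gap (nt) that splits islands;
#'   a common choice is one unit length.
#' @return data.frame with columns `start0`, `end0` (genome coordinates) and
#'   `n_full_monomers` (NA until [extract_monomers()] fills it).
#' @export
segment_islands <- function(hit, match_mask, gap_min) {
  span <- hit$end0 - hit$start0
  if (length(match_mask) != span)
    stop("match_mask must cover the hit interval")
  r <- rle(match_mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  iv <- cbind(starts[r$values], ends[r$values])  # 0-based local TRUE runs
  if (!nrow(iv))
    return(data.frame(start0 = integer(), end0 = integer(),
                      n_full_monomers = integer()))
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] - merged[nrow(merged), 2] < gap_min)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  data.frame(start0 = hit$start0 + merged[, 1],
             end0 = hit$start0 + merged[, 2],
             n_full_monomers = NA_integer_)
}

#' Extract phase-normalised monomers from an island
#'
#' Locates recurrences of the canonical phase anchor (the position
#' homologous to the reference unit start) by a mismatch-tolerant scan of
#' the unit's leading bases, and partitions the island at the anchors.
#' Monomers at least `flen_frac` of the unit length are flagged full length;
#' partial edge monomers are retained unflagged.
#'
#' @param genome named character vector holding the island's sequence.
#' @param island one row of a [segment_islands()] result (or a list with
#'   `start0`, `end0`).
#' @param unit reference repeat unit.
#' @param flen_frac full-length threshold as a fraction of unit length
#'   (default 0.9; the notion of "full length" is a calibration choice).
#' @param strand `"+"` or `"-"`; minus-strand islands are reverse
#'   complemented before phasing.
#' @param target_id which genome sequence the island lives on (default the
#'   first).
#' @param anchor_width width of the phase-anchor probe (default 40 nt).
#' @param anchor_min_frac minimum identity of the probe at an anchor
#'   (default 0.7).
#' @return data.frame of class `monomer_set`: `id`, `start0`, `end0`
#'   (forward-strand genome coordinates), `strand`, `length`, `full_length`,
#'   `sequence` (phase-normalised, reverse complemented for minus strand).
#' @export
extract_monomers <- function(genome, island, unit, flen_frac = 0.9,
                             strand = "+", target_id = names(genome)[1],
                             anchor_width = 40L, anchor_min_frac = 0.7) {
  unit <- .norm_seq(unit, arg = "unit")
  ulen <- nchar(unit)
  gseq <- genome[[target_id]]
  glen <- nchar(gseq)
  # seeded island boundaries can be trimmed by a few bases when a mutation
  # falls near the edge; extend the anchor search slightly upstream of the
  # phase-wise start of the island
  slack <- 25L
  if (strand == "+") {
    ext0 <- max(0L, island$start0 - slack)
    lead <- island$start0 - ext0
    iseq <- .slice(gseq, ext0, island$end0)
  } else {
    ext1 <- min(glen, island$end0 + slack)
    lead <- ext1 - island$end0
    iseq <- revcomp(.slice(gseq, island$start0, ext1))
  }
  ilen <- nchar(iseq)
  empty <- data.frame(id = character(), start0 = integer(), end0 = integer(),
                      strand = character(), length = integer(),
                      full_length = logical(), sequence = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("monomer_set", class(empty))
  if (ilen < anchor_width || ilen < flen_frac * ulen) {
    warning("island shorter than one unit; no monomers extracted")
    return(empty)
  }
  probe <- substr(unit, 1L, min(anchor_width, ulen))
  w <- nchar(probe)
  sc <- .probe_scan_cpp(iseq, probe) / w
  cand <- which(sc >= anchor_min_frac) - 1L   # 0-based island-local
  if (!length(cand)) {
    warning("no phase anchor found in island; no monomers extracted")
    return(empty)
  }
  # cluster candidates closer than half a unit; keep the best-scoring one
  anchors <- integer()
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && cand[j + 1L] - cand[i] < 0.5 * ulen) j <- j + 1L
    grp <- cand[i:j]
    anchors <- c(anchors, grp[which.max(sc[grp + 1L])])
    i <- j + 1L
  }
  # the first cut is the first anchor when one sits at or near the island
  # edge, else the original island boundary (the extension is non-array)
  first_cut <- if (length(anchors) && anchors[1] <= lead + slack) anchors[1]
               else lead
  cuts <- sort(unique(c(first_cut, anchors[anchors > first_cut], ilen)))
  st <- head(cuts, -1L); en <- tail(cuts, -1L)
  drop <- (en - st) < max(10L, w %/% 2L)      # ignore slivers at the edges
  st <- st[!drop]; en <- en[!drop]
  if (!length(st)) {
    warning("no monomer-sized segments in island")
    return(empty)
  }
  lens <- en - st
  segs <- vapply(seq_along(st), function(q) .slice(iseq, st[q], en[q]), "")
  if (strand == "+") {
    g_st <- ext0 + st; g_en <- ext0 + en
  } else {
    g_st <- ext1 - en; g_en <- ext1 - st
  }
  out <- data.frame(
    id = sprintf("mono_%d_%d", g_st, g_en),
    start0 = g_st, end0 = g_en, strand = strand, length = lens,
    full_length = lens >= flen_frac * ulen & st %in% anchors,
    sequence = segs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("monomer_set", class(out))
  out
}

#' Measure internal periodicity of a sequence
#'
#' Self-match autocorrelation: for each lag in `[kmin, kmax]` the fraction
#' of positions matching the base `lag` positions downstream. The period is
#' the smallest lag scoring within `fundamental_margin` of the best lag (so
#' the fundamental is preferred over its harmonics); a secondary period of
#' twice the fundamental is reported when doubling the lag improves
#' self-similarity by more than `harmonic_delta`, the signature of a
#' composite higher-order repeat with alternating unit variants.
#'
#' @param seq nucleotide sequence (length >= 2 * kmin).
#' @param kmin,kmax lag range (defaults 2 and half the sequence length).
#' @param threshold minimum autocorrelation to call any period (default 0.6).
#' @param fundamental_margin how far below the maximum the fundamental may
#'   score (default 0.2).
#' @param harmonic_delta required improvement at twice the period for a
#'   secondary period call (default 0.05).
#' @return list of class `periodicity_report`: `period` (or `NA`),
#'   `n_copies`, `secondary_period` (or `NA`), `autocorrelation` (named
#'   vector over lags).
#' @export
find_periodicity <- function(seq, kmin = 2L, kmax = NULL, threshold = 0.6,
                             fundamental_margin = 0.2, harmonic_delta = 0.05) {
  seq <- .norm_seq(seq)
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (kmin < 2L) stop("kmin must be >= 2")
  if (n < 2L * kmin) stop("sequence too short for the requested kmin")
  if (is.null(kmax)) kmax <- n %/% 2L
  kmax <- min(kmax, n - 5L)
  lags <- seq.int(kmin, kmax)
  ac <- vapply(lags, function(l) mean(ch[seq_len(n - l)] == ch[seq_len(n - l) + l]),
               numeric(1))
  names(ac) <- lags
  rep_none <- structure(list(period = NA_integer_, n_copies = NA_real_,
                             secondary_period = NA_integer_,
                             autocorrelation = ac),
                        class = "periodicity_report")
  mx <- max(ac)
  if (mx < threshold) return(rep_none)
  ok <- ac >= max(threshold, mx - fundamental_margin)
  period <- lags[which(ok)[1L]]
  sec <- NA_integer_
  cand <- lags[abs(lags - 2L * period) <= 2L]
  if (length(cand)) {
    best2 <- cand[which.max(ac[as.character(cand)])]
    if (ac[as.character(best2)] >= ac[as.character(period)] + harmonic_delta)
      sec <- best2
  }
  structure(list(period = as.integer(period), n_copies = n / period,
                 secondary_period = as.integer(sec), autocorrelation = ac),
            class = "periodicity_report")
}

#' @export
print.periodicity_report <- function(x, ...) {
  if (is.na(x$period)) cat("no internal periodicity above threshold\n")
  else cat(sprintf("period %d nt (%.1f copies)%s\n", x$period, x$n_copies,
                   if (!is.na(x$secondary_period))
                     sprintf(", secondary period %d nt", x$secondary_period)
                   else ""))
  invisible(x)
}
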