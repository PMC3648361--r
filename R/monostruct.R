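# Monomer architecture, consensus building, diagnostic SNP selection and
# haplotype tabulation.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Build a star-alignment consensus profile
#'
#' Globally aligns every sequence to an anchor (the longest sequence when
#' none is given) and projects each onto the anchor's columns, which is
#' adequate and deterministic for the near-identical monomers of a tandem
#' array. Per column the majority base wins; ties among bases are encoded as
#' IUPAC ambiguity codes. Columns that are gap in more than half of the
#' sequences are dropped from the consensus string but kept in the column
#' map.
#'
#' @param seqs named character vector of sequences (>= 1).
#' @param anchor optional reference sequence defining the column frame.
#' @param s scoring scheme for the star alignments.
#' @return an object of class `consensus_profile`: `sequence` (consensus
#'   over retained columns), `depth` (contributing non-gap sequences per
#'   retained column), `retained` (anchor column indices kept), `matrix`
#'   (full anchor-columns x sequences base matrix, `-` for gaps),
#'   `column_map` (retained columns x sequences matrix of 1-based positions
#'   in each input sequence, `NA` at gaps).
#' @export
build_consensus <- function(seqs, anchor = NULL, s = scoring_scheme()) {
  if (length(seqs) == 0L) stop("at least one sequence is required")
  seqs <- vapply(seqs, .norm_seq, "", USE.NAMES = TRUE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(anchor)) anchor <- seqs[[which.max(nchar(seqs))]]
  anchor <- .norm_seq(anchor, arg = "anchor")
  alen <- nchar(anchor)
  nseq <- length(seqs)
  mat <- matrix("-", nrow = alen, ncol = nseq, dimnames = list(NULL, names(seqs)))
  pos <- matrix(NA_integer_, nrow = alen, ncol = nseq,
                dimnames = list(NULL, names(seqs)))
  for (j in seq_len(nseq)) {
    aln <- global_align(anchor, seqs[[j]], s)
    ca <- .seq_chars(aln$aligned_a); cb <- .seq_chars(aln$aligned_b)
    ai <- cumsum(ca != "-")                   # anchor position per column
    bi <- cumsum(cb != "-")
    keep <- ca != "-"
    mat[ai[keep], j] <- cb[keep]
    pj <- ifelse(cb[keep] == "-", NA_integer_, bi[keep])
    pos[ai[keep], j] <- pj
  }
  gap_frac <- rowMeans(mat == "-")
  retained <- which(gap_frac <= 0.5)
  cons <- vapply(retained, function(r) {
    bases <- mat[r, ]
    bases <- bases[bases %in% .BASES]
    if (!length(bases)) return("-")
    tab <- table(bases)
    winners <- sort(names(tab)[tab == max(tab)])
    .IUPAC[[paste(winners, collapse = "")]]
  }, "")
  structure(list(
    sequence = .chars_seq(cons),
    depth = as.integer(rowSums(mat[retained, , drop = FALSE] != "-")),
    retained = retained,
    matrix = mat,
    column_map = pos[retained, , drop = FALSE],
    anchor = anchor), class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus profile: %d columns (%d retained), %d sequences\n",
              nrow(x$matrix), length(x$retained), ncol(x$matrix)))
  invisible(x)
}

#' Decompose a monomer into its domain architecture
#'
#' Locally aligns each domain reference (start sequence `S`, internal repeat
#' `IR`, end variants `E_A`/`E_B`) against a phase-normalised monomer,
#' greedily keeps non-overlapping hits above an identity threshold (IR is
#' matched iteratively so tandem copies are counted), assigns the end domain
#' to whichever variant scores higher (`E_?` when the scores are within the
#' tie margin), and composes the architecture string left to right, e.g.
#' `"S-IRx3-E_A"`.
#'
#' @param m a monomer sequence, or a row of an [extract_monomers()] result.
#' @param refs named list of reference subsequences with elements `S`, `IR`
#'   and at least one of `E_A`, `E_B` (or `E`).
#' @param s scoring scheme.
#' @param identity_min minimum hit identity (default 0.7).
#' @param min_hit_frac minimum hit length as fraction of the reference
#'   (default 0.5).
#' @param e_tie_margin relative score margin within which the two end
#'   variants are considered tied (default 0.05).
#' @return object of class `domain_annotation`: `architecture`, `domains`
#'   (data.frame `label`, `start0`, `end0`, `score`, `identity`), `ir_k`,
#'   `e_label`, `partial`.
#' @export
decompose_monomer <- function(m, refs, s = scoring_scheme(),
                              identity_min = 0.7, min_hit_frac = 0.5,
                              e_tie_margin = 0.05) {
  seqm <- if (is.list(m) || is.data.frame(m)) m$sequence else m
  seqm <- .norm_seq(seqm, arg = "monomer")
  if (is.null(refs$S) && is.null(refs$IR)) stop("refs must be non-empty")
  hit_row <- function(label, aln) data.frame(
    label = label, start0 = aln$start_a, end0 = aln$end_a,
    score = aln$score, identity = .alignment_identity(aln),
    stringsAsFactors = FALSE)
  hits <- list()
  ok_hit <- function(aln, ref) aln$score > 0 &&
    !is.na(.alignment_identity(aln)) &&
    .alignment_identity(aln) >= identity_min &&
    (aln$end_a - aln$start_a) >= min_hit_frac * nchar(ref)
  if (!is.null(refs$S)) {
    aln <- local_align(seqm, refs$S, s)
    if (ok_hit(aln, refs$S)) hits[[length(hits) + 1L]] <- hit_row("S", aln)
  }
  if (!is.null(refs$IR)) {
    work <- seqm
    for (it in seq_len(8L)) {
      aln <- local_align(work, refs$IR, s)
      if (!ok_hit(aln, refs$IR)) break
      hits[[length(hits) + 1L]] <- hit_row("IR", aln)
      substr(work, aln$start_a + 1L, aln$end_a) <-
        strrep("N", aln$end_a - aln$start_a)
    }
  }
  e_refs <- refs[intersect(c("E_A", "E_B", "E"), names(refs))]
  if (length(e_refs)) {
    e_hits <- lapply(names(e_refs), function(lb) {
      aln <- local_align(seqm, e_refs[[lb]], s)
      if (ok_hit(aln, e_refs[[lb]])) hit_row(lb, aln) else NULL
    })
    e_hits <- do.call(rbind, e_hits)
    if (!is.null(e_hits) && nrow(e_hits)) {
      best <- which.max(e_hits$score)
      lab <- e_hits$label[best]
      if (nrow(e_hits) > 1L) {
        other <- max(e_hits$score[-best])
        if (other >= (1 - e_tie_margin) * e_hits$score[best]) lab <- "E_?"
      }
      row <- e_hits[best, , drop = FALSE]
      row$label <- lab
      hits[[length(hits) + 1L]] <- row
    }
  }
  empty_ann <- function() structure(
    list(architecture = "?", domains = data.frame(
      label = character(), start0 = integer(), end0 = integer(),
      score = integer(), identity = numeric(), stringsAsFactors = FALSE),
      ir_k = 0L, e_label = NA_character_, partial = TRUE),
    class = "domain_annotation")
  if (!length(hits)) return(empty_ann())
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$score), , drop = FALSE]
  # greedy non-overlap selection (10 nt slack for ragged hit ends)
  sel <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    for (j in which(sel)) {
      o <- min(hits$end0[i], hits$end0[j]) - max(hits$start0[i], hits$start0[j])
      if (o > 10L) { ov <- TRUE; break }
    }
    sel[i] <- !ov
  }
  dom <- hits[sel, , drop = FALSE]
  dom <- dom[order(dom$start0), , drop = FALSE]
  rownames(dom) <- NULL
  labels <- dom$label
  ir_k <- sum(labels == "IR")
  e_label <- if (any(grepl("^E", labels))) labels[grepl("^E", labels)][1L]
             else NA_character_
  parts <- character(); i <- 1L
  while (i <= length(labels)) {
    if (labels[i] == "IR") {
      j <- i
      while (j < length(labels) && labels[j + 1L] == "IR") j <- j + 1L
      parts <- c(parts, paste0("IRx", j - i + 1L))
      i <- j + 1L
    } else { parts <- c(parts, labels[i]); i <- i + 1L }
  }
  structure(list(
    architecture = paste(parts, collapse = "-"),
    domains = dom, ir_k = ir_k, e_label = e_label,
    partial = !("S" %in% labels) || is.na(e_label)),
    class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("monomer architecture: %s%s\n", x$architecture,
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Mask low-complexity single-base runs
#'
#' Reports the union of all windows of length `min_len` whose composition is
#' at least `min_frac` of the given base, merged into maximal intervals.
#' Used to mask the highly polymorphic A-rich tail of internal repeats
#' before SNP analysis.
#'
#' @param seq nucleotide sequence.
#' @param base base to mask (default `"A"`).
#' @param min_len minimum window length (default 10, must be >= 4).
#' @param min_frac minimum base fraction in a window (default 0.8).
#' @return data.frame with 0-based half-open `start0`, `end0` intervals.
#' @export
mask_low_complexity <- function(seq, base = "A", min_len = 10L, min_frac = 0.8) {
  if (min_len < 4L) stop("min_len must be >= 4")
  seq <- .norm_seq(seq)
  ch <- .seq_chars(seq)
  n <- length(ch)
  none <- data.frame(start0 = integer(), end0 = integer())
  if (n < min_len) return(none)
  cs <- cumsum(ch == base)
  win <- (cs[min_len:n] - c(0L, cs)[1:(n - min_len + 1L)]) / min_len
  q <- which(win >= min_frac)                 # window start (1-based)
  if (!length(q)) return(none)
  iv <- cbind(q - 1L, q - 1L + min_len)       # 0-based half-open
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, ])
  }
  data.frame(start0 = merged[, 1], end0 = merged[, 2])
}

#' Select diagnostic SNP columns between two monomer groups
#'
#' From a consensus profile and a two-group partition of its sequences,
#' selects the retained columns at which the two groups' majority alleles
#' are distinct bases, each reaching at least `concordance_min` within its
#' group. Columns whose majority in either group is a gap, and masked
#' columns, are excluded.
#'
#' @param profile a [build_consensus()] result over both groups.
#' @param groups factor or character vector (length = number of sequences)
#'   with exactly two levels, in the column order of the profile.
#' @param concordance_min minimum within-group majority fraction
#'   (default 0.7).
#' @param mask_columns optional retained-column indices (anchor frame) to
#'   exclude, e.g. from [mask_low_complexity()] on the anchor.
#' @return data.frame of class `diagnostic_panel`: `column` (anchor column,
#'   1-based), `group1_allele`, `group2_allele`, `concordance1`,
#'   `concordance2`; attribute `groups` holds the level names.
#' @export
select_diagnostic_snps <- function(profile, groups, concordance_min = 0.7,
                                   mask_columns = NULL) {
  stopifnot(inherits(profile, "consensus_profile"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must define exactly two groups")
  if (length(groups) != ncol(profile$matrix))
    stop("groups length must match the number of sequences in the profile")
  if (min(table(groups)) < 2L)
    stop("each group must have at least 2 members")
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  cols <- setdiff(profile$retained, mask_columns)
  major <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    c(allele = names(tab)[1L], frac = unname(tab[1L]) / length(x))
  }
  rows <- lapply(cols, function(cc) {
    m1 <- major(profile$matrix[cc, g1])
    m2 <- major(profile$matrix[cc, g2])
    a1 <- m1[["allele"]]; a2 <- m2[["allele"]]
    f1 <- as.numeric(m1[["frac"]]); f2 <- as.numeric(m2[["frac"]])
    if (a1 == a2) return(NULL)
    if (!(a1 %in% .BASES) || !(a2 %in% .BASES)) return(NULL)
    if (f1 < concordance_min || f2 < concordance_min) return(NULL)
    data.frame(column = cc, group1_allele = a1, group2_allele = a2,
               concordance1 = f1, concordance2 = f2, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(), group1_allele = character(),
               group2_allele = character(), concordance1 = numeric(),
               concordance2 = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- levels(groups)
  class(out) <- c("diagnostic_panel", class(out))
  out
}

#' Call haplotypes at a diagnostic SNP panel
#'
#' Concatenates each sequence's bases at the panel columns into a haplotype
#' string over `{A,C,G,T,-}` and tabulates per-haplotype frequencies among
#' complete calls (calls containing a gap or ambiguous base are flagged
#' incomplete and tabulated separately).
#'
#' @param profile a [build_consensus()] result.
#' @param panel a [select_diagnostic_snps()] result (non-empty).
#' @param region_label label for the region the panel covers (e.g. `"S"`,
#'   `"IR.c1"`).
#' @return list of class `haplotype_calls`: `calls` (data.frame
#'   `monomer_ref`, `region_label`, `haplotype`, `complete`) and `freq`
#'   (data.frame `haplotype`, `count`, `percent` over complete calls).
#' @export
call_haplotypes <- function(profile, panel, region_label = "S") {
  stopifnot(inherits(profile, "consensus_profile"))
  if (nrow(panel) == 0L) stop("panel must be non-empty")
  sub <- profile$matrix[panel$column, , drop = FALSE]
  hap <- apply(sub, 2L, paste, collapse = "")
  complete <- apply(sub, 2L, function(x) all(x %in% .BASES))
  calls <- data.frame(monomer_ref = colnames(profile$matrix),
                      region_label = region_label,
                      haplotype = unname(hap), complete = unname(complete),
                      stringsAsFactors = FALSE)
  tab <- sort(table(hap[complete]), decreasing = TRUE)
  freq <- data.frame(haplotype = names(tab), count = as.integer(tab),
                     percent = 100 * as.integer(tab) / sum(tab),
                     stringsAsFactors = FALSE)
  structure(list(calls = calls, freq = freq), class = "haplotype_calls")
}

#' @export
print.haplotype_calls <- function(x, ...) {
  cat(sprintf("haplotype calls: %d sequences (%d complete), %d haplotypes\n",
              nrow(x$calls), sum(x$calls$complete), nrow(x$freq)))
  print(head(x$freq, 10L))
  invisible(x)
}
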