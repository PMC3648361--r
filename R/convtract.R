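# Parent-allele assignment of diagnostic sites and gene-conversion tract
# inference with minimal/maximal breakpoint bounds.

#' Diagnostic sites distinguishing two parent alleles
#'
#' Enumerates the positions within the monomer frame at which the A and B
#' parent alleles carry different bases; these are the sites that allow a
#' monomer segment to be attributed to one parent.
#'
#' @param parentA,parentB [parent_model()] objects sharing coordinates.
#' @param frame optional 0-based half-open interval in parent coordinates
#'   (default the B parent's monomer frame).
#' @return data.frame of class `parent_diagnostics` with `site0` (0-based
#'   offset within the frame), `alleleA`, `alleleB`.
#' @export
parent_diagnostics <- function(parentA, parentB, frame = NULL) {
  stopifnot(inherits(parentA, "parent_model"), inherits(parentB, "parent_model"))
  if (is.null(frame)) frame <- parentB$monomer_frame
  chA <- .seq_chars(.slice(parentA$sequence, frame[1], frame[2]))
  chB <- .seq_chars(.slice(parentB$sequence, frame[1], frame[2]))
  d <- which(chA != chB)
  out <- data.frame(site0 = d - 1L, alleleA = chA[d], alleleB = chB[d],
                    stringsAsFactors = FALSE)
  class(out) <- c("parent_diagnostics", class(out))
  out
}

#' Assign diagnostic sites of a monomer to parent alleles
#'
#' Reads the monomer's base at every diagnostic site and calls it `A` or `B`
#' when it matches the corresponding parent allele, `other` when it matches
#' neither, and `masked` inside masked intervals (e.g. A-rich tails). When
#' the monomer length differs from the frame (extra internal-repeat copies,
#' indels), the monomer is globally aligned to the B-parent frame sequence
#' and sites are mapped through the alignment; the background frame is the
#' B allele by default because the repeat itself is B-derived.
#'
#' @param monomer monomer sequence (or a row of an [extract_monomers()]
#'   result).
#' @param panel a [parent_diagnostics()] result.
#' @param frame_seq the background-parent sequence over the monomer frame;
#'   required when the monomer needs alignment (lengths differ).
#' @param mask optional data.frame of masked monomer intervals
#'   (`start0`, `end0`).
#' @param s scoring scheme for the frame alignment.
#' @return data.frame of class `site_assignments`: `site0` (frame offset),
#'   `pos0` (monomer offset, `NA` if deleted), `observed`, `call`; attribute
#'   `monomer_len`.
#' @export
assign_parent_sites <- function(monomer, panel, frame_seq = NULL, mask = NULL,
                                s = scoring_scheme()) {
  seqm <- if (is.list(monomer) || is.data.frame(monomer)) monomer$sequence else monomer
  seqm <- .norm_seq(seqm, arg = "monomer")
  ch <- .seq_chars(seqm)
  n <- length(ch)
  if (!is.null(frame_seq) && nchar(frame_seq) != n) {
    aln <- global_align(frame_seq, seqm, s)
    ca <- .seq_chars(aln$aligned_a); cb <- .seq_chars(aln$aligned_b)
    fpos <- cumsum(ca != "-"); mpos <- cumsum(cb != "-")
    map <- rep(NA_integer_, nchar(frame_seq))
    keep <- ca != "-"
    map[fpos[keep]] <- ifelse(cb[keep] == "-", NA_integer_, mpos[keep])
  } else {
    map <- seq_len(n)
  }
  pos1 <- map[panel$site0 + 1L]               # 1-based monomer positions
  obs <- ifelse(is.na(pos1), "-", ch[pos1])
  call <- ifelse(obs == panel$alleleA, "A",
                 ifelse(obs == panel$alleleB, "B", "other"))
  if (!is.null(mask) && nrow(mask)) {
    p0 <- pos1 - 1L
    in_mask <- !is.na(p0) & vapply(p0, function(p)
      any(p >= mask$start0 & p < mask$end0), logical(1))
    call[in_mask] <- "masked"
  }
  out <- data.frame(site0 = panel$site0, pos0 = pos1 - 1L,
                    observed = obs, call = call, stringsAsFactors = FALSE)
  attr(out, "monomer_len") <- n
  class(out) <- c("site_assignments", class(out))
  out
}

#' Infer gene-conversion tracts from site assignments
#'
#' Maximal runs of at least `min_sites` donor (non-background) calls, with
#' at most `max_gap_sites` interior background/other calls, become tracts.
#' The minimal bound spans the first to last supporting site; the maximal
#' bound extends to, but excludes, the nearest flanking background-called
#' sites (the conversion breakpoint cannot include a site still carrying the
#' background allele) or the monomer edge.
#'
#' @param assignments a [assign_parent_sites()] result, ordered by
#'   coordinate.
#' @param background background allele, `"B"` (default) or `"A"`.
#' @param min_sites minimum supporting donor sites per tract (default 2;
#'   single-site tracts are indistinguishable from point mutation).
#' @param max_gap_sites tolerated interior non-donor calls (default 0).
#' @param monomer_len monomer length for edge bounds (default from the
#'   assignments attribute).
#' @return data.frame of class `conversion_tracts`: `donor`,
#'   `minimal_start0`, `minimal_end0`, `maximal_start0`, `maximal_end0`
#'   (0-based half-open monomer intervals), `n_supporting_sites`.
#' @export
infer_tracts <- function(assignments, background = c("B", "A"),
                         min_sites = 2L, max_gap_sites = 0L,
                         monomer_len = attr(assignments, "monomer_len")) {
  background <- match.arg(background)
  donor <- setdiff(c("A", "B"), background)
  empty <- data.frame(donor = character(), minimal_start0 = integer(),
                      minimal_end0 = integer(), maximal_start0 = integer(),
                      maximal_end0 = integer(), n_supporting_sites = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("conversion_tracts", class(empty))
  a <- assignments[assignments$call != "masked" & !is.na(assignments$pos0), ,
                   drop = FALSE]
  a <- a[order(a$pos0), , drop = FALSE]
  if (!nrow(a)) return(empty)
  don_idx <- which(a$call == donor)
  if (length(don_idx) < min_sites) return(empty)
  # split donor sites into runs where interior non-donor calls exceed budget
  runs <- list(); cur <- don_idx[1L]
  for (i in seq_along(don_idx)[-1]) {
    interior <- don_idx[i] - don_idx[i - 1L] - 1L
    if (interior <= max_gap_sites) cur <- c(cur, don_idx[i])
    else { runs[[length(runs) + 1L]] <- cur; cur <- don_idx[i] }
  }
  runs[[length(runs) + 1L]] <- cur
  rows <- lapply(runs, function(r) {
    if (length(r) < min_sites) return(NULL)
    first <- a$pos0[r[1L]]; last <- a$pos0[r[length(r)]]
    bg_pos <- a$pos0[a$call == background]
    prev_bg <- bg_pos[bg_pos < first]
    next_bg <- bg_pos[bg_pos > last]
    max_start <- if (length(prev_bg)) max(prev_bg) + 1L else 0L
    max_end <- if (length(next_bg)) min(next_bg) else monomer_len
    data.frame(donor = donor, minimal_start0 = first, minimal_end0 = last + 1L,
               maximal_start0 = max_start, maximal_end0 = max_end,
               n_supporting_sites = length(r), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("conversion_tracts", class(out))
  out
}

#' Summarise recombinant monomers and tract lengths
#'
#' Monomer-level recombinant fractions (a monomer with any tract counts
#' once, however many tracts it carries) per locus and per donor, plus
#' tract-level length distributions of the minimal and maximal bounds.
#'
#' @param tracts data.frame of tracts carrying a `monomer_ref` column
#'   (rbind of [infer_tracts()] results with the monomer id added).
#' @param monomers data.frame with `id` and optionally `locus` per monomer.
#' @return list of class `recombinant_summary`: `by_locus` (data.frame
#'   `locus`, `n_monomers`, `n_recombinant`, `percent_recombinant`),
#'   `by_donor` (tract counts per donor), `tract_lengths` (data.frame of
#'   `bound`, `min`, `median`, `mean`, `max`).
#' @export
summarize_recombinants <- function(tracts, monomers) {
  loc <- if ("locus" %in% names(monomers)) monomers$locus else "all"
  monomers$.locus <- loc
  rec_ids <- unique(tracts$monomer_ref)
  by_locus <- do.call(rbind, lapply(split(monomers, monomers$.locus), function(g) {
    nr <- sum(g$id %in% rec_ids)
    data.frame(locus = g$.locus[1L], n_monomers = nrow(g), n_recombinant = nr,
               percent_recombinant = 100 * nr / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(by_locus) <- NULL
  by_donor <- if (nrow(tracts))
    as.data.frame(table(donor = tracts$donor), responseName = "n_tracts")
  else data.frame(donor = character(), n_tracts = integer())
  lens <- function(v) if (length(v)) c(min(v), stats::median(v), mean(v), max(v))
                      else rep(NA_real_, 4L)
  tl <- rbind(lens(tracts$minimal_end0 - tracts$minimal_start0),
              lens(tracts$maximal_end0 - tracts$maximal_start0))
  tract_lengths <- data.frame(bound = c("minimal", "maximal"),
                              min = tl[, 1], median = tl[, 2],
                              mean = tl[, 3], max = tl[, 4])
  structure(list(by_locus = by_locus, by_donor = by_donor,
                 tract_lengths = tract_lengths),
            class = "recombinant_summary")
}

#' @export
print.recombinant_summary <- function(x, ...) {
  print(x$by_locus)
  invisible(x)
}
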