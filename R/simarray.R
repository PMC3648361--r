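#' Parent retroelement model
#'
#' Builds a synthetic full-length LTR retrotransposon of the kind that gives
#' rise to LTR-UTR derived tandem repeats: `LTR5 - UTR - internal - LTR3`,
#' with the two LTRs identical at time zero. The model also fixes the monomer
#' frame of the derived tandem repeat: the repeat unit runs from an offset
#' inside the LTR (downstream of the TATA motif, in the U5 region) through
#' the start (`S`, ~402 nt by default, spanning the LTR-UTR boundary), one
#' internal repeat (`IR`, ~100 nt) and the end domain (`E`, ~185 nt) inside
#' the UTR.
#'
#' @param sequence optional full parent sequence; when `NULL` a random
#'   sequence is drawn from the current RNG stream.
#' @param allele allele label, `"A"` or `"B"`.
#' @param ltr_len,utr_len,internal_len domain lengths in nt.
#' @param tata_offset position of the TATA motif within the LTR.
#' @param s_len,ir_len,e_len monomer subdomain lengths (start, internal
#'   repeat, end).
#' @param s_utr_part how much of `S` lies in the UTR (the rest is LTR tail).
#' @return an object of class `parent_model` with the sequence, 0-based
#'   half-open intervals `ltr5`, `utr`, `internal`, `ltr3`, the
#'   `monomer_frame` interval, and `domain_refs` (`S`, `IR`, `E` intervals in
#'   parent coordinates).
#' @export
parent_model <- function(sequence = NULL, allele = c("B", "A"),
                         ltr_len = 1000L, utr_len = 1500L, internal_len = 3000L,
                         tata_offset = 500L, s_len = 402L, ir_len = 100L,
                         e_len = 185L, s_utr_part = 100L) {
  allele <- match.arg(allele)
  ltr_len <- as.integer(ltr_len); utr_len <- as.integer(utr_len)
  internal_len <- as.integer(internal_len)
  s_ltr_part <- as.integer(s_len) - as.integer(s_utr_part)
  if (s_ltr_part <= 0L || s_ltr_part >= ltr_len)
    stop("s_len/s_utr_part inconsistent with ltr_len")
  u_keep <- as.integer(s_utr_part + ir_len + e_len)
  if (u_keep >= utr_len) stop("monomer UTR portion exceeds utr_len")
  total <- 2L * ltr_len + utr_len + internal_len
  if (is.null(sequence)) {
    ltr <- .random_seq(ltr_len)
    sequence <- paste0(ltr, .random_seq(utr_len + internal_len), ltr)
  } else {
    sequence <- .norm_seq(sequence, arg = "sequence")
    if (nchar(sequence) != total)
      stop("sequence length does not match domain lengths")
  }
  m0 <- ltr_len - s_ltr_part
  structure(list(
    allele_label = allele,
    sequence = sequence,
    ltr5 = c(0L, ltr_len),
    utr = c(ltr_len, ltr_len + utr_len),
    internal = c(ltr_len + utr_len, ltr_len + utr_len + internal_len),
    ltr3 = c(total - ltr_len, total),
    tata_offset = as.integer(tata_offset),
    monomer_frame = c(m0, ltr_len + u_keep),
    domain_refs = list(
      S = c(m0, m0 + as.integer(s_len)),
      IR = c(m0 + as.integer(s_len), m0 + as.integer(s_len) + as.integer(ir_len)),
      E = c(m0 + as.integer(s_len) + as.integer(ir_len), ltr_len + u_keep)),
    s_len = as.integer(s_len), ir_len = as.integer(ir_len),
    e_len = as.integer(e_len)),
    class = "parent_model")
}

#' @export
print.parent_model <- function(x, ...) {
  cat(sprintf(
    "parent element (allele %s): %d nt [LTR %d | UTR %d | internal %d | LTR %d]\n",
    x$allele_label, nchar(x$sequence), diff(x$ltr5), diff(x$utr),
    diff(x$internal), diff(x$ltr3)))
  cat(sprintf("monomer frame [%d,%d): S %d nt, IR %d nt, E %d nt\n",
              x$monomer_frame[1], x$monomer_frame[2], x$s_len, x$ir_len, x$e_len))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the forward simulator of tandem-array genesis and growth.
#' Defaults reproduce the study conditions of the maize CRM-derived repeats:
#' substitution rate `mu` back-calculated from the four published LTR-pair
#' (kappa, age) calibrations; internal-repeat copy-number distribution,
#' donor-tract probability and tract lengths as observed at the recombinant
#' locus; monomer subdomain sizes as measured on the repeat consensus.
#'
#' @param seed integer RNG seed; every stochastic choice in a simulation is
#'   drawn from one global stream seeded with this value.
#' @param mu substitution rate per site per year.
#' @param tstv transition/transversion ratio (alpha / 2 beta); may be `Inf`.
#' @param n_monomers_target number of monomers to grow the array to.
#' @param expansion_block_mean mean of the geometric block length (in
#'   monomers) copied per conversion-mediated expansion event.
#' @param n_expansion_events optional alternative stop rule: perform exactly
#'   this many expansion events instead of growing to a target count.
#' @param divergence_years years of independent per-monomer divergence
#'   applied after growth (pairwise divergence approx. `2 * mu * years`).
#' @param parent_divergence_years total divergence separating the A and B
#'   parent alleles.
#' @param ir_copy_distribution named probability vector over IR copy numbers.
#' @param donor_tract_prob per-monomer probability of a gene-conversion tract
#'   from the donor (A) parent.
#' @param tract_len_min,tract_len_mean minimum and mean donor tract length
#'   (nt); lengths are `min + geometric`.
#' @param nested_insertions list of nested-TE insertion requests, each a list
#'   with `age_years`, `element_length`, `tsd_length` and optionally
#'   `ltr_length` (default 1000), `strand`, and `family` (insertions sharing
#'   a family label are copies of one element template, as for repeated
#'   insertions of the same retrotransposon).
#' @param spacer_len length of random intervening sequence between islands
#'   when `island_sizes` splits the array.
#' @param island_sizes optional integer vector partitioning the monomers into
#'   islands separated by spacers.
#' @param flank_len random flanking sequence added on each side.
#' @param s_len,ir_len,e_len,ltr_len,utr_len,internal_len,tata_offset parent
#'   model geometry, passed to [parent_model()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, mu = 6.5e-9, tstv = 2,
                       n_monomers_target = 10L, expansion_block_mean = 2,
                       n_expansion_events = NULL,
                       divergence_years = 2e6, parent_divergence_years = 16e6,
                       ir_copy_distribution = c(`1` = 2, `2` = 22, `3` = 60, `4` = 6) / 90,
                       donor_tract_prob = 0.68,
                       tract_len_min = 71L, tract_len_mean = 135,
                       nested_insertions = list(),
                       spacer_len = 2000L, island_sizes = NULL,
                       flank_len = 1000L,
                       s_len = 402L, ir_len = 100L, e_len = 185L,
                       ltr_len = 1000L, utr_len = 1500L, internal_len = 3000L,
                       tata_offset = 500L) {
  stopifnot(mu >= 0, tstv > 0, n_monomers_target >= 1,
            expansion_block_mean >= 1, divergence_years >= 0,
            donor_tract_prob >= 0, donor_tract_prob <= 1,
            tract_len_min >= 1, tract_len_mean >= tract_len_min)
  p <- ir_copy_distribution
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("ir_copy_distribution must be a named probability vector summing to 1")
  if (!is.null(island_sizes) && sum(island_sizes) != n_monomers_target)
    stop("island_sizes must sum to n_monomers_target")
  for (ins in nested_insertions)
    stopifnot(ins$age_years >= 0, ins$element_length >= 200,
              ins$tsd_length >= 0, ins$tsd_length <= 20)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation config: seed %d, mu %.3g /site/yr, ts/tv %.3g\n",
    "  %d monomers, divergence %.3g yr, donor tract prob %.2f, %d nested TE(s)\n"),
    x$seed, x$mu, x$tstv, x$n_monomers_target, x$divergence_years,
    x$donor_tract_prob, length(x$nested_insertions)))
  invisible(x)
}

#' Splice a parent element into an LTR-UTR~LTR seed
#'
#' Applies a set of internal deletions to a parent element, modelling the
#' sequential illegitimate recombinations that join a truncated UTR to the
#' downstream LTR and create the seed structure from which a tandem array
#' can grow. The characteristic UTR~LTR junction recurs at every monomer
#' boundary of the derived array.
#'
#' @param parent a [parent_model()].
#' @param deletions list of 0-based half-open intervals (integer pairs) to
#'   excise; must be disjoint, strictly internal spans. `NULL` uses the
#'   default two-deletion construction that removes the UTR tail, the
#'   internal region and the 5' part of the downstream LTR, leaving the
#'   monomer frame joined at the UTR~LTR junction.
#' @return a list with `sequence` (the spliced seed), `retained` (parent
#'   intervals kept), `junctions` (seed coordinates of the splice points)
#'   and `unit` (the tandem repeat unit implied by the monomer frame).
#' @export
splice_seed <- function(parent, deletions = NULL) {
  stopifnot(inherits(parent, "parent_model"))
  total <- nchar(parent$sequence)
  if (is.null(deletions)) {
    u_end <- parent$monomer_frame[2]          # end of monomer UTR portion
    ltr3_keep <- parent$ltr3[1] + parent$monomer_frame[1]
    mid <- parent$internal[1] + diff(parent$internal) %/% 2L
    deletions <- list(c(u_end, mid), c(mid, ltr3_keep))
  }
  unit <- .slice(parent$sequence, parent$monomer_frame[1], parent$monomer_frame[2])
  if (length(deletions) == 0L)
    return(list(sequence = parent$sequence,
                retained = matrix(c(0L, total), 1L), junctions = integer(),
                unit = unit))
  dm <- do.call(rbind, lapply(deletions, as.integer))
  if (any(dm[, 1] >= dm[, 2]) || any(dm[, 1] < 0) || any(dm[, 2] > total))
    stop("deletions must be non-empty intervals within the parent")
  dm <- dm[order(dm[, 1]), , drop = FALSE]
  if (nrow(dm) > 1 && any(dm[-1, 1] < dm[-nrow(dm), 2]))
    stop("deletions must be disjoint")
  covers <- function(iv) any(dm[, 1] <= iv[1] & dm[, 2] >= iv[2])
  if (covers(parent$utr)) stop("deletion removes the entire UTR; no repeat unit would remain")
  if (covers(parent$ltr5) || covers(parent$ltr3))
    stop("deletion removes an entire LTR; no repeat unit would remain")
  bounds <- c(0L, as.vector(t(dm)), total)
  keep <- matrix(bounds, ncol = 2, byrow = TRUE)
  keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]
  parts <- apply(keep, 1L, function(iv) .slice(parent$sequence, iv[1], iv[2]))
  junctions <- cumsum(head(keep[, 2] - keep[, 1], -1L))
  list(sequence = paste(parts, collapse = ""),
       retained = keep,
       junctions = as.integer(junctions),
       unit = unit)
}

#' Grow a tandem array by conversion-mediated block duplication
#'
#' Iterated expansion events, each copying a contiguous block of monomers
#' (block length geometric, mean `cfg$expansion_block_mean`) and inserting
#' the copy adjacent to its source, model the growth of an array by
#' non-allelic gene conversion between repeats. Draws come from the current
#' RNG stream; seed it for reproducibility.
#'
#' @param seed the repeat unit (seed monomer) sequence.
#' @param cfg a [sim_config()].
#' @return list with `monomers` (character vector of monomer sequences, all
#'   copies of the seed), `lineage` (integer id of the founder copy each
#'   monomer descends from, by event order) and `events` (data.frame
#'   `src_start`, `block_len`, `insert_after`, 1-based monomer indices).
#' @export
grow_array <- function(seed, cfg) {
  seed <- .norm_seq(seed, arg = "seed")
  if (nchar(seed) == 0L) stop("seed must be non-empty")
  target <- if (is.null(cfg$n_expansion_events)) cfg$n_monomers_target else Inf
  n_events <- if (is.null(cfg$n_expansion_events)) Inf else cfg$n_expansion_events
  ids <- 1L
  ev <- list()
  e <- 0L
  while (length(ids) < target && e < n_events) {
    len <- length(ids)
    src <- sample.int(len, 1L)
    blk <- 1L + rgeom(1L, prob = 1 / cfg$expansion_block_mean)
    blk <- min(blk, len - src + 1L)
    if (is.finite(target)) blk <- min(blk, target - len)
    ins_after <- src + blk - 1L
    ids <- append(ids, ids[src:(src + blk - 1L)], after = ins_after)
    e <- e + 1L
    ev[[e]] <- c(src_start = src, block_len = blk, insert_after = ins_after)
  }
  events <- if (length(ev)) as.data.frame(do.call(rbind, ev)) else
    data.frame(src_start = integer(), block_len = integer(), insert_after = integer())
  list(monomers = rep(seed, length(ids)), lineage = ids, events = events)
}

#' Replay an expansion event log
#'
#' Reconstructs the lineage vector of [grow_array()] from its event log;
#' used as an independent check that the recorded events generate the array.
#'
#' @param events event data.frame from [grow_array()].
#' @return integer lineage vector.
#' @export
replay_events <- function(events) {
  ids <- 1L
  for (i in seq_len(nrow(events))) {
    s <- events$src_start[i]; b <- events$block_len[i]; a <- events$insert_after[i]
    ids <- append(ids, ids[s:(s + b - 1L)], after = a)
  }
  ids
}

#' Neutrally mutate a sequence under the K2P substitution model
#'
#' Each site evolves for `years` years under a Kimura two-parameter process
#' with total rate `cfg$mu` per site per year and transition/transversion
#' ratio `cfg$tstv`; per-site change probabilities use the exact
#' finite-time transition probabilities of the process, so the expected K2P
#' distance between two independently mutated copies of one ancestor is
#' `2 * mu * years`. Draws come from the current RNG stream.
#'
#' @param seq nucleotide sequence.
#' @param years branch length in years.
#' @param cfg a [sim_config()] (fields `mu`, `tstv`).
#' @return mutated sequence.
#' @export
mutate_seq <- function(seq, years, cfg) {
  seq <- .norm_seq(seq)
  n <- nchar(seq)
  if (n == 0L || years == 0 || cfg$mu == 0) return(seq)
  R <- cfg$tstv
  if (is.infinite(R)) { beta <- 0; alpha <- cfg$mu } else {
    beta <- cfg$mu / (2 * (R + 1)); alpha <- cfg$mu * R / (R + 1)
  }
  t <- years
  e4b <- exp(-4 * beta * t)
  e2ab <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv <- 0.5 - 0.5 * e4b                     # total over both transversions
  ch <- .seq_chars(seq)
  u <- runif(n)
  is_base <- ch %in% .BASES
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_map2 <- c(A = "T", G = "T", C = "G", T = "G")
  do_ts <- is_base & u < p_ts
  do_tv <- is_base & !do_ts & u < p_ts + p_tv
  ch[do_ts] <- ts_map[ch[do_ts]]
  if (any(do_tv)) {
    pick <- runif(sum(do_tv)) < 0.5
    ch[do_tv] <- ifelse(pick, tv_map1[ch[do_tv]], tv_map2[ch[do_tv]])
  }
  .chars_seq(ch)
}

# Monomer-frame -> parent-frame position map for a monomer with k IR copies.
# Returns 0-based offsets into the monomer frame of the parent model.
.frame_map <- function(parent, k) {
  s <- parent$s_len; ir <- parent$ir_len; e <- parent$e_len
  c(seq_len(s) - 1L,
    rep(seq.int(s, s + ir - 1L), times = k),
    seq.int(s + ir, s + ir + e - 1L))
}

#' Inject IR copy-number variation and donor gene-conversion tracts
#'
#' Per monomer, draws an internal-repeat copy number from
#' `cfg$ir_copy_distribution` (the extra copies replicate the monomer's own
#' IR segment in tandem) and, with probability `cfg$donor_tract_prob`,
#' overwrites a tract (length `tract_len_min + geometric`) with the
#' homologous donor-parent (allele A) sequence, modelling gene conversion
#' from a second parent allele. Draws come from the current RNG stream.
#'
#' @param monomers character vector of monomer sequences in seed frame
#'   (one IR copy).
#' @param parentA,parentB [parent_model()] objects for the donor (A) and
#'   background (B) alleles, sharing coordinates.
#' @param cfg a [sim_config()].
#' @return list with `monomers` (modified sequences), `info` (data.frame
#'   `ir_k`, `e_label`, `architecture`) and `tracts` (data.frame `monomer`,
#'   `start0`, `end0` in monomer coordinates, `donor`, `n_diff_sites`).
#' @export
inject_variation <- function(monomers, parentA, parentB, cfg) {
  stopifnot(inherits(parentA, "parent_model"), inherits(parentB, "parent_model"))
  fr <- parentB$monomer_frame
  baseA <- .seq_chars(.slice(parentA$sequence, fr[1], fr[2]))
  baseB <- .seq_chars(.slice(parentB$sequence, fr[1], fr[2]))
  diff_sites <- which(baseA != baseB)         # 1-based offsets in frame
  ks <- as.integer(names(cfg$ir_copy_distribution))
  out <- character(length(monomers))
  info <- data.frame(ir_k = integer(length(monomers)),
                     e_label = character(length(monomers)),
                     architecture = character(length(monomers)),
                     stringsAsFactors = FALSE)
  tracts <- list()
  s <- parentB$s_len; ir <- parentB$ir_len; e <- parentB$e_len
  for (i in seq_along(monomers)) {
    ch <- .seq_chars(monomers[i])
    if (length(ch) != s + ir + e)
      stop("monomer ", i, " is not in seed frame")
    k <- ks[sample.int(length(ks), 1L, prob = cfg$ir_copy_distribution)]
    ir_seg <- ch[seq.int(s + 1L, s + ir)]
    ch <- c(ch[seq_len(s)], rep(ir_seg, k), ch[seq.int(s + ir + 1L, s + ir + e)])
    fmap <- .frame_map(parentB, k)            # 0-based frame offsets
    has_tract <- runif(1L) < cfg$donor_tract_prob
    if (has_tract) {
      L <- cfg$tract_len_min +
        rgeom(1L, prob = 1 / (cfg$tract_len_mean - cfg$tract_len_min + 1))
      L <- min(L, length(ch))
      start <- sample.int(length(ch) - L + 1L, 1L) - 1L   # 0-based
      idx <- seq.int(start + 1L, start + L)
      ch[idx] <- baseA[fmap[idx] + 1L]
      nd <- sum((fmap[idx] + 1L) %in% diff_sites)
      tracts[[length(tracts) + 1L]] <-
        data.frame(monomer = i, start0 = start, end0 = start + L,
                   donor = "A", n_diff_sites = nd, stringsAsFactors = FALSE)
    }
    # E label truth: majority allele over the A/B-discriminating sites in E
    e_idx <- seq.int(s + k * ir + 1L, length(ch))
    e_diag <- e_idx[(fmap[e_idx] + 1L) %in% diff_sites]
    if (length(e_diag)) {
      a_frac <- mean(ch[e_diag] == baseA[fmap[e_diag] + 1L])
      e_lab <- if (a_frac > 0.5) "E_A" else "E_B"
    } else e_lab <- "E_?"
    out[i] <- .chars_seq(ch)
    info$ir_k[i] <- k
    info$e_label[i] <- e_lab
    info$architecture[i] <- paste0("S-IRx", k, "-", e_lab)
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(monomer = integer(), start0 = integer(), end0 = integer(),
               donor = character(), n_diff_sites = integer(),
               stringsAsFactors = FALSE)
  list(monomers = out, info = info, tracts = tracts)
}

# Build one nested TE: LTR-internal-LTR with the two LTRs independently
# mutated copies of one template (expected pair kappa = 2 * mu * age).
.make_nested_te <- function(ins, cfg, tmpl = NULL) {
  ltr_len <- if (!is.null(ins$ltr_length)) as.integer(ins$ltr_length) else 1000L
  int_len <- as.integer(ins$element_length) - 2L * ltr_len
  if (int_len < 0L) stop("element_length smaller than its two LTRs")
  if (is.null(tmpl))
    tmpl <- list(ltr = .random_seq(ltr_len), internal = .random_seq(int_len))
  if (nchar(tmpl$ltr) != ltr_len || nchar(tmpl$internal) != int_len)
    stop("insertions of one element family must share ltr/element lengths")
  template <- tmpl$ltr
  ltr5 <- mutate_seq(template, ins$age_years, cfg)
  ltr3 <- mutate_seq(template, ins$age_years, cfg)
  internal <- mutate_seq(tmpl$internal, ins$age_years, cfg)
  strand <- if (!is.null(ins$strand)) ins$strand else sample(c("+", "-"), 1L)
  seqp <- paste0(ltr5, internal, ltr3)
  list(sequence = if (strand == "-") revcomp(seqp) else seqp,
       strand = strand, ltr_len = ltr_len,
       kappa_expected = 2 * cfg$mu * ins$age_years,
       age_years = ins$age_years,
       tsd_length = as.integer(ins$tsd_length))
}

#' Insert nested transposable elements into an assembled array
#'
#' Each requested insertion places a synthetic LTR-internal-LTR element at a
#' random interior monomer boundary of the array piece list; `tsd_length`
#' bases immediately upstream of the insertion site are duplicated after the
#' element, producing the target site duplication that flanks a genuine
#' retroelement insertion. Draws come from the current RNG stream.
#'
#' @param pieces internal piece list (see [simulate_tandem_locus()]).
#' @param cfg a [sim_config()] with `nested_insertions` requests.
#' @return the piece list with `te` and `tsd` pieces added.
#' @keywords internal
.insert_nested_tes <- function(pieces, cfg) {
  used <- integer()
  families <- list()
  for (ins in cfg$nested_insertions) {
    tmpl <- NULL
    if (!is.null(ins$family)) {
      if (is.null(families[[ins$family]])) {
        ltr_len <- if (!is.null(ins$ltr_length)) as.integer(ins$ltr_length) else 1000L
        families[[ins$family]] <- list(
          ltr = .random_seq(ltr_len),
          internal = .random_seq(as.integer(ins$element_length) - 2L * ltr_len))
      }
      tmpl <- families[[ins$family]]
    }
    te <- .make_nested_te(ins, cfg, tmpl)
    mono_idx <- which(vapply(pieces, function(p) p$kind == "monomer", logical(1)))
    # interior boundaries: after any monomer except the last; each boundary
    # hosts at most one insertion
    cand <- mono_idx[-length(mono_idx)]
    cand <- cand[!vapply(pieces[cand], function(p) p$meta$index, integer(1)) %in% used]
    if (!length(cand)) stop("no interior monomer boundary available for insertion")
    if (!is.null(ins$after_monomer)) {
      at <- cand[vapply(pieces[cand], function(p) p$meta$index, integer(1)) ==
                   ins$after_monomer]
      if (length(at) != 1L)
        stop("after_monomer is not an available interior boundary")
    } else {
      at <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    used <- c(used, pieces[[at]]$meta$index)
    prev_seq <- pieces[[at]]$seq
    tl <- te$tsd_length
    if (tl > nchar(prev_seq)) stop("tsd_length exceeds monomer length")
    tsd <- if (tl > 0L) .slice(prev_seq, nchar(prev_seq) - tl, nchar(prev_seq)) else ""
    new <- list(
      list(kind = "te", seq = te$sequence, meta = te),
      list(kind = "tsd", seq = tsd, meta = list()))
    pieces <- append(pieces, new, after = at)
  }
  pieces
}

#' Forward-simulate a tandem repeat locus with ground truth
#'
#' Runs the full genesis/growth model: builds diverged A/B parent alleles
#' from a common ancestor, splices the B parent into an LTR-UTR~LTR seed,
#' grows a tandem array by block duplication, applies per-monomer neutral
#' divergence, injects IR copy-number variation and donor-allele conversion
#' tracts, optionally splits the array into islands and inserts nested TEs
#' with target site duplications, and assembles the final sequence with
#' machine-readable truth for every feature.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `tandem_sim`: list with `genome` (named
#'   character vector of one sequence), `truth` (lists/data.frames:
#'   `monomers`, `tracts`, `insertions`, `islands`, `events`, `unit`,
#'   `diff_sites`), `parents` (A and B [parent_model()]s), `seed_unit`, and
#'   `config`.
#' @examples
#' sim <- simulate_tandem_locus(sim_config(seed = 42, n_monomers_target = 5))
#' sim$truth$monomers
#' @export
simulate_tandem_locus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pm_args <- list(ltr_len = cfg$ltr_len, utr_len = cfg$utr_len,
                  internal_len = cfg$internal_len, tata_offset = cfg$tata_offset,
                  s_len = cfg$s_len, ir_len = cfg$ir_len, e_len = cfg$e_len)
  ancestor <- do.call(parent_model, c(list(allele = "B"), pm_args))
  half <- cfg$parent_divergence_years / 2
  parentB <- do.call(parent_model, c(
    list(sequence = mutate_seq(ancestor$sequence, half, cfg), allele = "B"), pm_args))
  parentA <- do.call(parent_model, c(
    list(sequence = mutate_seq(ancestor$sequence, half, cfg), allele = "A"), pm_args))
  spl <- splice_seed(parentB)
  grown <- grow_array(spl$unit, cfg)
  monomers <- vapply(grown$monomers, mutate_seq, character(1),
                     years = cfg$divergence_years, cfg = cfg, USE.NAMES = FALSE)
  inj <- inject_variation(monomers, parentA, parentB, cfg)

  # assemble pieces: flank | monomers (optionally split into islands) | flank
  pieces <- list(list(kind = "flank", seq = .random_seq(cfg$flank_len), meta = list()))
  sizes <- if (is.null(cfg$island_sizes)) length(inj$monomers) else cfg$island_sizes
  m <- 0L
  for (gi in seq_along(sizes)) {
    if (gi > 1L)
      pieces <- c(pieces, list(list(kind = "spacer",
                                    seq = .random_seq(cfg$spacer_len), meta = list())))
    for (j in seq_len(sizes[gi])) {
      m <- m + 1L
      pieces <- c(pieces, list(list(kind = "monomer", seq = inj$monomers[m],
                                    meta = list(index = m))))
    }
  }
  pieces <- c(pieces, list(list(kind = "flank", seq = .random_seq(cfg$flank_len),
                                meta = list())))
  if (length(cfg$nested_insertions))
    pieces <- .insert_nested_tes(pieces, cfg)

  # lay out coordinates
  lens <- vapply(pieces, function(p) nchar(p$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  kinds <- vapply(pieces, function(p) p$kind, character(1))
  genome <- paste(vapply(pieces, function(p) p$seq, character(1)), collapse = "")

  mono_rows <- which(kinds == "monomer")
  idx <- vapply(pieces[mono_rows], function(p) p$meta$index, integer(1))
  monomers_df <- data.frame(
    id = paste0("m", idx),
    start0 = starts[mono_rows][order(idx)],
    end0 = ends[mono_rows][order(idx)],
    ir_k = inj$info$ir_k, e_label = inj$info$e_label,
    architecture = inj$info$architecture,
    lineage = grown$lineage, stringsAsFactors = FALSE)

  tr <- inj$tracts
  if (nrow(tr)) {
    tr$genome_start0 <- monomers_df$start0[tr$monomer] + tr$start0
    tr$genome_end0 <- monomers_df$start0[tr$monomer] + tr$end0
  } else { tr$genome_start0 <- integer(); tr$genome_end0 <- integer() }

  te_rows <- which(kinds == "te")
  insertions_df <- data.frame(
    start0 = starts[te_rows], end0 = ends[te_rows],
    tsd = vapply(te_rows, function(r) pieces[[r + 1L]]$seq, character(1)),
    strand = vapply(pieces[te_rows], function(p) p$meta$strand, character(1)),
    ltr_len = vapply(pieces[te_rows], function(p) p$meta$ltr_len, integer(1)),
    age_years = vapply(pieces[te_rows], function(p) p$meta$age_years, numeric(1)),
    kappa_expected = vapply(pieces[te_rows], function(p) p$meta$kappa_expected,
                            numeric(1)),
    stringsAsFactors = FALSE)

  # islands: maximal runs of monomer/tsd pieces
  in_island <- kinds %in% c("monomer", "tsd")
  r <- rle(in_island)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  isl <- which(r$values)
  islands_df <- data.frame(
    start0 = starts[run_start[isl]], end0 = ends[run_end[isl]],
    n_monomers = vapply(isl, function(k)
      sum(kinds[run_start[k]:run_end[k]] == "monomer"), integer(1)))

  fr <- parentB$monomer_frame
  baseA <- .seq_chars(.slice(parentA$sequence, fr[1], fr[2]))
  baseB <- .seq_chars(.slice(parentB$sequence, fr[1], fr[2]))
  structure(list(
    genome = setNames(genome, "sim_locus"),
    truth = list(monomers = monomers_df, tracts = tr,
                 insertions = insertions_df, islands = islands_df,
                 events = grown$events, unit = spl$unit,
                 diff_sites = which(baseA != baseB) - 1L),
    parents = list(A = parentA, B = parentB),
    seed_unit = spl$unit,
    config = cfg), class = "tandem_sim")
}

#' @export
print.tandem_sim <- function(x, ...) {
  cat(sprintf(
    "simulated tandem locus: %d nt, %d monomers in %d island(s), %d tract(s), %d nested TE(s)\n",
    nchar(x$genome), nrow(x$truth$monomers), nrow(x$truth$islands),
    nrow(x$truth$tracts), nrow(x$truth$insertions)))
  invisible(x)
}

#' Write a simulated locus to FASTA, truth JSON and GFF3
#'
#' @param sim a `tandem_sim` from [simulate_tandem_locus()].
#' @param fasta,truth_json,gff output paths (`NULL` to skip any of them).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, fasta = NULL, truth_json = NULL, gff = NULL) {
  stopifnot(inherits(sim, "tandem_sim"))
  written <- character()
  if (!is.null(fasta)) {
    write_fasta(sim$genome, fasta); written <- c(written, fasta)
  }
  if (!is.null(truth_json)) {
    tr <- sim$truth
    jsonlite::write_json(
      list(monomers = tr$monomers, tracts = tr$tracts,
           insertions = tr$insertions, islands = tr$islands,
           events = tr$events, unit = tr$unit, diff_sites = tr$diff_sites),
      truth_json, auto_unbox = TRUE, digits = NA)
    written <- c(written, truth_json)
  }
  if (!is.null(gff)) {
    nm <- names(sim$genome)
    tr <- sim$truth
    rows <- rbind(
      if (nrow(tr$islands)) data.frame(
        seqid = nm, source = "retrosat_sim", type = "tandem_repeat_island",
        start0 = tr$islands$start0, end0 = tr$islands$end0, score = NA,
        strand = "+", attributes = paste0("ID=island", seq_len(nrow(tr$islands))),
        stringsAsFactors = FALSE),
      if (nrow(tr$monomers)) data.frame(
        seqid = nm, source = "retrosat_sim", type = "repeat_unit",
        start0 = tr$monomers$start0, end0 = tr$monomers$end0, score = NA,
        strand = "+",
        attributes = paste0("ID=", tr$monomers$id, ";architecture=",
                            tr$monomers$architecture),
        stringsAsFactors = FALSE),
      if (nrow(tr$insertions)) data.frame(
        seqid = nm, source = "retrosat_sim", type = "mobile_element_insertion",
        start0 = tr$insertions$start0, end0 = tr$insertions$end0, score = NA,
        strand = tr$insertions$strand,
        attributes = paste0("ID=te", seq_len(nrow(tr$insertions)),
                            ";tsd=", tr$insertions$tsd),
        stringsAsFactors = FALSE))
    .write_gff3(rows[order(rows$start0), , drop = FALSE], gff)
    written <- c(written, gff)
  }
  invisible(written)
}

#' Simulate two monomer groups with an injected diagnostic-SNP panel
#'
#' Builds two sets of monomer subdomain sequences (e.g. the `S` start
#' domain) from one base sequence, injecting fixed group-discriminating
#' alleles at a chosen number of positions and a within-group haplotype
#' mixture: a major haplotype at frequency `major_freq` and minor haplotypes
#' obtained by substituting one or two panel positions. Low-rate background
#' noise is added off panel. Used for haplotype-recovery studies; defaults
#' mirror the observed locus structure (7 S SNPs, 76% major haplotype).
#'
#' @param n1,n2 group sizes.
#' @param seq_len subdomain length.
#' @param major1,major2 major-haplotype strings (equal length, differing at
#'   every position).
#' @param major_freq frequency of the major haplotype within each group.
#' @param noise per-site background substitution probability off panel.
#' @return list with `group1`, `group2` (named character vectors), `sites`
#'   (1-based panel positions in the subdomain), `major1`, `major2`.
#' @export
simulate_haplotype_groups <- function(n1 = 97L, n2 = 90L, seq_len = 402L,
                                      major1 = "ACGGAGT", major2 = "GTCACTC",
                                      major_freq = 0.76, noise = 0.003) {
  stopifnot(nchar(major1) == nchar(major2))
  h1 <- .seq_chars(major1); h2 <- .seq_chars(major2)
  if (any(h1 == h2)) stop("major haplotypes must differ at every position")
  npanel <- length(h1)
  base <- .seq_chars(.random_seq(seq_len))
  sites <- sort(sample.int(seq_len, npanel))
  make_group <- function(n, major, label) {
    out <- character(n)
    for (i in seq_len(n)) {
      ch <- base
      ch[sites] <- major
      if (runif(1L) >= major_freq) {
        nmut <- sample(1:2, 1L)
        at <- sample.int(npanel, nmut)
        for (a in at)
          ch[sites[a]] <- sample(setdiff(.BASES, major[a]), 1L)
      }
      flip <- runif(seq_len) < noise & !(seq_along(ch) %in% sites)
      if (any(flip))
        ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(.BASES, b), 1L), "")
      out[i] <- .chars_seq(ch)
    }
    names(out) <- paste0(label, seq_len(n))
    out
  }
  list(group1 = make_group(n1, h1, "L1_m"),
       group2 = make_group(n2, h2, "L2_m"),
       sites = sites, major1 = major1, major2 = major2)
}
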