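# Independent oracles used across the suite. These deliberately use a
# different algorithmic route from the package (top-down recursion in R vs
# bottom-up dynamic programming in C++; direct column counting vs the
# packaged K2P path).

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive-enumeration optimum of the global alignment score, top-down
# with memoisation over (i, j) suffix pairs
oracle_global_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i > n && j > m) 0L else {
      best <- -.Machine$integer.max
      if (i <= n && j <= m) {
        s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
        best <- max(best, s + rec(i + 1L, j + 1L))
      }
      if (i <= n) best <- max(best, gap + rec(i + 1L, j))
      if (j <= m) best <- max(best, gap + rec(i, j + 1L))
      best
    }
    memo[i, j] <<- val
    val
  }
  rec(1L, 1L)
}

# brute force over all substring pairs for the local score
oracle_local_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  best <- 0L
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2),
                               match, mismatch, gap)
      if (s > best) best <- s
    }
  best
}

# direct transition/transversion counter over comparable columns
oracle_k2p <- function(aligned_a, aligned_b) {
  x <- strsplit(toupper(aligned_a), "")[[1]]
  y <- strsplit(toupper(aligned_b), "")[[1]]
  ts <- 0L; tv <- 0L; n <- 0L
  pur <- c("A", "G")
  for (i in seq_along(x)) {
    if (!(x[i] %in% c("A", "C", "G", "T")) || !(y[i] %in% c("A", "C", "G", "T")))
      next
    n <- n + 1L
    if (x[i] == y[i]) next
    if ((x[i] %in% pur) == (y[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  list(P = P, Q = Q, n = n,
       kappa = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
}

# mutate a sequence at chosen positions to a different base (for controlled
# divergence in fixtures)
mutate_at <- function(seq, pos1, to = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos1) {
    ch[p] <- if (is.null(to)) sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
             else to
  }
  paste(ch, collapse = "")
}

# run the full detection path on a simulated locus and return the monomers
detect_monomers <- function(sim, gap_min = NULL) {
  unit <- sim$seed_unit
  if (is.null(gap_min)) gap_min <- nchar(unit)
  hits <- find_arrays(sim$genome, unit)
  if (nrow(hits) == 0L) return(NULL)
  masks <- attr(hits, "match_mask")
  isl <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i)
    segment_islands(hits[i, ], masks[[i]], gap_min = gap_min)))
  do.call(rbind, lapply(seq_len(nrow(isl)), function(i)
    extract_monomers(sim$genome, isl[i, ], unit)))
}
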