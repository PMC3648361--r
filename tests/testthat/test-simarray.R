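test_that("splice_seed is exact bookkeeping and rejects degenerate deletions", {
  set.seed(41)
  p <- parent_model()
  spl <- splice_seed(p)
  del_len <- (p$ltr3[1] + p$monomer_frame[1]) - p$monomer_frame[2]
  expect_equal(nchar(spl$sequence), nchar(p$sequence) - del_len)
  # the implied repeat unit is the parent's monomer frame
  expect_equal(spl$unit, substr(p$sequence, p$monomer_frame[1] + 1,
                                p$monomer_frame[2]))
  # with no deletions the seed is the parent
  expect_equal(splice_seed(p, list())$sequence, p$sequence)
  # explicit deletions compose by excision
  spl2 <- splice_seed(p, list(c(1500L, 1600L), c(3000L, 3500L)))
  expect_equal(nchar(spl2$sequence), nchar(p$sequence) - 600L)
  expect_equal(substr(spl2$sequence, 1, 1500), substr(p$sequence, 1, 1500))
  # removing the whole UTR (or LTR) leaves no repeat unit
  expect_error(splice_seed(p, list(c(p$utr[1], p$utr[2]))), "UTR")
  expect_error(splice_seed(p, list(c(p$ltr3[1], p$ltr3[2]))), "LTR")
})

test_that("grow_array duplicates blocks deterministically and replays", {
  cfg <- sim_config(seed = 1, n_monomers_target = 10)
  set.seed(5)
  g1 <- grow_array("ACGTACGTAA", cfg)
  expect_length(g1$monomers, 10L)
  expect_true(all(g1$monomers == "ACGTACGTAA"))
  set.seed(5)
  g2 <- grow_array("ACGTACGTAA", cfg)
  expect_identical(g1, g2)
  # the event log reconstructs the lineage vector
  expect_identical(replay_events(g1$events), g1$lineage)
  set.seed(9)
  g3 <- grow_array("AC", sim_config(seed = 1, n_monomers_target = 57))
  expect_identical(replay_events(g3$events), g3$lineage)
  expect_length(g3$lineage, 57L)
})

test_that("mutate_seq matches its closed-form divergence expectation", {
  cfg <- sim_config(seed = 1)
  expect_equal(mutate_seq("ACGT", 0, cfg), "ACGT")
  set.seed(43)
  anc <- rand_seq(10000)
  ks <- replicate(200, {
    d <- mutate_seq(anc, 1e6, cfg)
    k2p_distance(list(aligned_a = anc, aligned_b = d))$kappa
  })
  target <- cfg$mu * 1e6                      # single branch: mu * t
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - target), 3 * se)
})

test_that("infinite ts/tv ratio produces transitions only", {
  cfg <- sim_config(seed = 1, tstv = Inf, mu = 1e-3)
  set.seed(47)
  anc <- rand_seq(5000)
  mut <- mutate_seq(anc, 100, cfg)
  a <- strsplit(anc, "")[[1]]; b <- strsplit(mut, "")[[1]]
  d <- which(a != b)
  expect_gt(length(d), 0L)
  pur <- c("A", "G")
  expect_true(all((a[d] %in% pur) == (b[d] %in% pur)))
})

test_that("pairwise monomer divergence grows linearly with simulated years", {
  cfg <- sim_config(seed = 1)
  set.seed(53)
  anc <- rand_seq(5000)
  yrs <- c(0.5e6, 1e6, 2e6, 4e6)
  mean_k <- vapply(yrs, function(t) {
    mean(replicate(20, {
      a <- mutate_seq(anc, t, cfg); b <- mutate_seq(anc, t, cfg)
      k2p_distance(list(aligned_a = a, aligned_b = b))$kappa
    }))
  }, numeric(1))
  fit <- lm(mean_k ~ yrs)
  expect_equal(unname(coef(fit)[2]), 2 * cfg$mu, tolerance = 0.1)
})

test_that("simulation is deterministic and its truth slices back exactly", {
  cfg <- sim_config(seed = 77, n_monomers_target = 8,
                    nested_insertions = list(list(age_years = 5e5,
                                                  element_length = 4000,
                                                  tsd_length = 5)))
  sim1 <- simulate_tandem_locus(cfg)
  sim2 <- simulate_tandem_locus(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)

  g <- sim1$genome[[1]]
  tm <- sim1$truth$monomers
  p <- sim1$parents$B
  # monomer lengths follow their IR copy number
  expect_equal(tm$end0 - tm$start0, p$s_len + tm$ir_k * p$ir_len + p$e_len)
  # tract truth: the sliced tract carries donor-parent alleles at every
  # discriminating site it covers
  fr <- p$monomer_frame
  baseA <- strsplit(substr(sim1$parents$A$sequence, fr[1] + 1, fr[2]), "")[[1]]
  tt <- sim1$truth$tracts
  for (j in seq_len(nrow(tt))) {
    i <- tt$monomer[j]
    mono <- substr(g, tm$start0[i] + 1, tm$end0[i])
    k <- tm$ir_k[i]
    fmap <- retrosat:::.frame_map(p, k)
    idx <- seq.int(tt$start0[j] + 1L, tt$end0[j])
    covered <- idx[(fmap[idx] + 1L) %in% (sim1$truth$diff_sites + 1L)]
    if (length(covered))
      expect_equal(strsplit(mono, "")[[1]][covered], baseA[fmap[covered] + 1L])
  }
  # conservation of length
  ins <- sim1$truth$insertions
  expect_equal(nchar(g),
               2L * cfg$flank_len + sum(tm$end0 - tm$start0) +
                 sum(ins$end0 - ins$start0) + sum(nchar(ins$tsd)))
})

test_that("nested TE construction yields exact TSDs and age-0 identical LTRs", {
  cfg0 <- sim_config(seed = 3, n_monomers_target = 6,
                     nested_insertions = list(list(age_years = 0,
                                                   element_length = 3000,
                                                   tsd_length = 7)))
  sim <- simulate_tandem_locus(cfg0)
  ins <- sim$truth$insertions
  expect_equal(nrow(ins), 1L)
  g <- sim$genome[[1]]
  # the TSD is literally duplicated on both sides of the element
  L <- nchar(ins$tsd)
  expect_equal(L, 7L)
  expect_equal(substr(g, ins$start0 - L + 1, ins$start0), ins$tsd)
  expect_equal(substr(g, ins$end0 + 1, ins$end0 + L), ins$tsd)
  # age 0: the two LTRs are identical copies
  elem <- substr(g, ins$start0 + 1, ins$end0)
  ltr5 <- substr(elem, 1, ins$ltr_len)
  ltr3 <- substr(elem, nchar(elem) - ins$ltr_len + 1, nchar(elem))
  if (ins$strand == "-") { tmp <- ltr5; ltr5 <- revcomp(ltr3); ltr3 <- revcomp(tmp) }
  expect_equal(ltr5, ltr3)
  expect_equal(ins$kappa_expected, 0)
})

test_that("variation injection honours its controls", {
  set.seed(61)
  p <- parent_model()
  pa <- parent_model(sequence = mutate_at(p$sequence, sample(nchar(p$sequence), 300)),
                     allele = "A")
  unit <- substr(p$sequence, p$monomer_frame[1] + 1, p$monomer_frame[2])
  mono <- rep(unit, 20)
  cfg_fix <- sim_config(seed = 1, donor_tract_prob = 0,
                        ir_copy_distribution = c(`3` = 1))
  inj <- inject_variation(mono, pa, p, cfg_fix)
  expect_equal(nrow(inj$tracts), 0L)
  expect_true(all(inj$info$ir_k == 3L))
  expect_true(all(startsWith(inj$info$architecture, "S-IRx3-")))
  cfg_all <- sim_config(seed = 1, donor_tract_prob = 1,
                        ir_copy_distribution = c(`1` = 1))
  inj2 <- inject_variation(mono, pa, p, cfg_all)
  expect_equal(nrow(inj2$tracts), 20L)
  expect_true(all(inj2$tracts$end0 - inj2$tracts$start0 >= cfg_all$tract_len_min))
})

test_that("simulation writers emit FASTA, truth JSON and GFF3", {
  sim <- simulate_tandem_locus(sim_config(seed = 13, n_monomers_target = 4))
  td <- withr::local_tempdir()
  fa <- file.path(td, "locus.fa"); js <- file.path(td, "truth.json")
  gff <- file.path(td, "truth.gff3")
  write_sim(sim, fasta = fa, truth_json = js, gff = gff)
  back <- read_fasta(fa)
  expect_identical(unname(back), unname(sim$genome))
  tr <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(tr$monomers$start0, sim$truth$monomers$start0)
  gl <- readLines(gff)
  expect_equal(gl[1], "##gff-version 3")
  body <- read.delim(text = gl[-1], header = FALSE)
  expect_true(all(body$V4 >= 1))              # 1-based closed coordinates
  expect_equal(sum(body$V3 == "repeat_unit"), 4L)
})
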