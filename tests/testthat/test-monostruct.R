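test_that("consensus building is idempotent and majority-ruled", {
  set.seed(91)
  x <- rand_seq(60)
  for (n in c(1L, 2L, 5L)) {
    prof <- build_consensus(rep(x, n))
    expect_equal(prof$sequence, x)
    expect_true(all(prof$depth == n))
  }
  # majority A,A,G -> A; tie A,G -> R (IUPAC)
  base <- rand_seq(40)
  s1 <- base
  s2 <- mutate_at(base, 5, "G")
  stopifnot(substr(base, 5, 5) != "G")
  prof3 <- build_consensus(c(mutate_at(base, 5, "A"), mutate_at(s1, 5, "A"), s2))
  expect_equal(substr(prof3$sequence, 5, 5), "A")
  prof2 <- build_consensus(c(mutate_at(base, 5, "A"), mutate_at(base, 5, "G")))
  expect_equal(substr(prof2$sequence, 5, 5), "R")
  expect_error(build_consensus(character(0)), "sequence")
})

test_that("columns deleted in most sequences drop out of the consensus", {
  set.seed(93)
  anchor <- rand_seq(80)
  del <- paste0(substr(anchor, 1, 39), substr(anchor, 50, 80))  # drop 40..49
  prof <- build_consensus(c(anchor, del, del), anchor = anchor)
  expect_equal(length(prof$retained), 70L)
  expect_equal(nchar(prof$sequence), 70L)
  # the consensus over the retained columns is the deleted variant (the gap
  # block may sit anywhere within an equal-scoring repeat run)
  expect_equal(prof$sequence, del)
})

test_that("monomers decompose into their domain architectures", {
  set.seed(97)
  S <- rand_seq(402); IR <- rand_seq(100)
  EB <- rand_seq(185)
  EA <- mutate_at(EB, sample(185, 28))        # ~15% diverged end variant
  refs <- list(S = S, IR = IR, E_A = EA, E_B = EB)

  a3 <- decompose_monomer(paste0(S, IR, IR, IR, EA), refs)
  expect_equal(a3$architecture, "S-IRx3-E_A")
  expect_equal(a3$ir_k, 3L)
  expect_false(a3$partial)

  a1 <- decompose_monomer(paste0(S, IR, EB), refs)
  expect_equal(a1$architecture, "S-IRx1-E_B")

  am <- decompose_monomer(paste0(IR, IR, EB), refs)
  expect_equal(am$architecture, "IRx2-E_B")
  expect_true(am$partial)

  # a tied end variant is not overcalled
  at <- decompose_monomer(paste0(S, IR, EB), list(S = S, IR = IR,
                                                  E_A = EB, E_B = EB))
  expect_equal(at$e_label, "E_?")

  junk <- decompose_monomer(rand_seq(500), refs)
  expect_equal(junk$architecture, "?")
  expect_true(junk$partial)
})

test_that("architecture recovery holds at low divergence", {
  # simulated monomers with known IR copy number, ~1% divergence to the refs
  sim <- simulate_tandem_locus(sim_config(seed = 29, n_monomers_target = 40,
                                          divergence_years = 1.5e6))
  p <- sim$parents$B
  unit <- sim$seed_unit
  refs <- list(S = substr(unit, 1, p$s_len),
               IR = substr(unit, p$s_len + 1, p$s_len + p$ir_len),
               E_B = substr(unit, p$s_len + p$ir_len + 1, nchar(unit)))
  tm <- sim$truth$monomers
  ok <- 0L
  for (i in seq_len(nrow(tm))) {
    mseq <- substr(sim$genome[[1]], tm$start0[i] + 1, tm$end0[i])
    if (decompose_monomer(mseq, refs)$ir_k == tm$ir_k[i]) ok <- ok + 1L
  }
  expect_gte(ok / nrow(tm), 0.95)
})

test_that("low-complexity masking finds A-rich tails and nothing else", {
  m1 <- mask_low_complexity(strrep("A", 10), "A", 10, 0.8)
  expect_equal(m1, data.frame(start0 = 0L, end0 = 10L))
  expect_equal(nrow(mask_low_complexity("ACGTACGTAC", "A", 10, 0.8)), 0L)
  expect_error(mask_low_complexity("AAAA", "A", min_len = 3), "min_len")

  # 38 nt and 25 nt tails at ~85% A, embedded after unrelated sequence
  set.seed(101)
  tail38 <- mutate_at(strrep("A", 38), sample(38, 5), "C")
  tail25 <- mutate_at(strrep("A", 25), sample(25, 3), "G")
  for (tl in list(tail38, tail25)) {
    ctx <- paste0("CGTCGTGCGTCGTCGGCTCG", tl)
    mm <- mask_low_complexity(ctx, "A", 10, 0.8)
    expect_equal(nrow(mm), 1L)
    # the mask covers most of the tail and none of the GC context
    expect_gte(mm$start0, 20L)
    expect_gte(mm$end0 - mm$start0, 0.6 * nchar(tl))
  }
})

test_that("diagnostic SNP selection recovers injected panels exactly", {
  set.seed(103)
  hg <- simulate_haplotype_groups(n1 = 20, n2 = 20, noise = 0)
  seqs <- c(hg$group1, hg$group2)
  prof <- build_consensus(seqs, anchor = seqs[[1]])
  groups <- rep(c("L1", "L2"), each = 20)
  panel <- select_diagnostic_snps(prof, groups)
  expect_equal(panel$column, hg$sites)
  expect_equal(paste(panel$group1_allele, collapse = ""), hg$major1)
  expect_equal(paste(panel$group2_allele, collapse = ""), hg$major2)

  # symmetry: swapping group labels permutes alleles, keeps columns
  panel_sw <- select_diagnostic_snps(prof, rev(groups))
  expect_equal(panel_sw$column, panel$column)
  expect_equal(panel_sw$group1_allele, panel$group2_allele)

  # identical groups yield an empty panel
  same <- build_consensus(rep(hg$group1[1], 8), anchor = hg$group1[[1]])
  expect_equal(nrow(select_diagnostic_snps(same, rep(c("a", "b"), 4))), 0L)

  expect_error(select_diagnostic_snps(prof, c("L1", rep("L2", 39))), "at least 2")
})

test_that("a gap-majority column is never selected as diagnostic", {
  set.seed(107)
  base <- rand_seq(60)
  # group 2 deletes positions 30..34, so those columns are gap-major there
  g1 <- vapply(1:4, function(i) base, "")
  g2 <- vapply(1:4, function(i)
    paste0(substr(base, 1, 29), substr(base, 35, 60)), "")
  prof <- build_consensus(c(g1, g2), anchor = base)
  panel <- select_diagnostic_snps(prof, rep(c("g1", "g2"), each = 4))
  expect_false(any(30:34 %in% panel$column))
})

test_that("haplotype calls tabulate mixtures and flag incomplete calls", {
  set.seed(109)
  hg <- simulate_haplotype_groups(n1 = 30, n2 = 30, noise = 0)
  seqs <- c(hg$group1, hg$group2)
  prof <- build_consensus(seqs, anchor = seqs[[1]])
  panel <- select_diagnostic_snps(prof, rep(c("L1", "L2"), each = 30))
  hc <- call_haplotypes(prof, panel, region_label = "S")
  expect_equal(nrow(hc$calls), 60L)
  expect_equal(sum(hc$freq$percent), 100)
  expect_true(hg$major1 %in% hc$freq$haplotype)
  expect_true(all(nchar(hc$calls$haplotype) == nrow(panel)))

  # all identical monomers: one haplotype at 100%
  same <- build_consensus(rep(seqs[1], 5), anchor = seqs[[1]])
  hc1 <- call_haplotypes(same, panel, "S")
  expect_equal(nrow(hc1$freq), 1L)
  expect_equal(hc1$freq$percent, 100)
})
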