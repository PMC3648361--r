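test_that("site assignment reads parent alleles, others and masks", {
  set.seed(113)
  p <- parent_model()
  pa <- parent_model(sequence = mutate_at(p$sequence,
                                          sample(nchar(p$sequence), 400)),
                     allele = "A")
  pd <- parent_diagnostics(pa, p)
  expect_gt(nrow(pd), 10L)
  expect_true(all(pd$alleleA != pd$alleleB))
  expect_true(all(diff(pd$site0) > 0))

  fr <- p$monomer_frame
  frameB <- substr(p$sequence, fr[1] + 1, fr[2])
  frameA <- substr(pa$sequence, fr[1] + 1, fr[2])

  asnB <- assign_parent_sites(frameB, pd)
  expect_true(all(asnB$call == "B"))

  # plant parent-A alleles at two sites
  chs <- strsplit(frameB, "")[[1]]
  two <- pd$site0[c(3, 7)] + 1L
  chs[two] <- strsplit(frameA, "")[[1]][two]
  asn2 <- assign_parent_sites(paste(chs, collapse = ""), pd)
  expect_equal(which(asn2$call == "A"), c(3L, 7L))

  # a masked interval silences its sites
  mask <- data.frame(start0 = pd$site0[3], end0 = pd$site0[3] + 1L)
  asnM <- assign_parent_sites(paste(chs, collapse = ""), pd, mask = mask)
  expect_equal(asnM$call[3], "masked")
  expect_equal(which(asnM$call == "A"), 7L)
})

test_that("tract bounds follow the minimal/maximal rule", {
  # background B with donor calls at 30 and 50 among sites 10,30,50,70,90
  asn <- data.frame(site0 = c(10L, 30L, 50L, 70L, 90L),
                    pos0 = c(10L, 30L, 50L, 70L, 90L),
                    observed = c("C", "A", "A", "C", "C"),
                    call = c("B", "A", "A", "B", "B"))
  attr(asn, "monomer_len") <- 100L
  tr <- infer_tracts(asn, min_sites = 2)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$donor, "A")
  expect_equal(tr$minimal_start0, 30L)
  expect_equal(tr$minimal_end0, 51L)
  # maximal bound stops at the nearest background-called sites (11..70):
  # a site still carrying the background allele cannot have been converted
  expect_equal(tr$maximal_start0, 11L)
  expect_equal(tr$maximal_end0, 70L)
  expect_equal(tr$n_supporting_sites, 2L)

  # edges: donor run at the start extends the maximal bound to the edge
  asn2 <- asn
  asn2$call <- c("A", "A", "B", "B", "B")
  attr(asn2, "monomer_len") <- 100L
  tr2 <- infer_tracts(asn2)
  expect_equal(tr2$maximal_start0, 0L)
  expect_equal(tr2$maximal_end0, 50L)

  # all background: nothing
  asn3 <- asn; asn3$call <- rep("B", 5)
  expect_equal(nrow(infer_tracts(asn3)), 0L)
  # a single supporting site is indistinguishable from a point mutation
  asn4 <- asn; asn4$call <- c("B", "A", "B", "B", "B")
  expect_equal(nrow(infer_tracts(asn4)), 0L)
})

test_that("tract inference is monotone in min_sites and label-symmetric", {
  set.seed(127)
  for (rep in 1:20) {
    n <- 30L
    calls <- sample(c("A", "B", "other"), n, replace = TRUE, prob = c(.4, .5, .1))
    asn <- data.frame(site0 = seq(0L, by = 10L, length.out = n),
                      pos0 = seq(0L, by = 10L, length.out = n),
                      observed = "N", call = calls)
    attr(asn, "monomer_len") <- 300L
    counts <- vapply(2:5, function(ms)
      nrow(infer_tracts(asn, min_sites = ms)), integer(1))
    expect_true(all(diff(counts) <= 0))

    # swapping parent labels swaps donors but preserves intervals
    asn_sw <- asn
    asn_sw$call <- ifelse(calls == "A", "B", ifelse(calls == "B", "A", calls))
    tr <- infer_tracts(asn, background = "B")
    tr_sw <- infer_tracts(asn_sw, background = "A")
    expect_equal(tr_sw$minimal_start0, tr$minimal_start0)
    expect_equal(tr_sw$maximal_end0, tr$maximal_end0)
    expect_true(all(tr$donor == "A") && all(tr_sw$donor == "B"))
  }
})

test_that("simulated donor tracts are bracketed by the inferred bounds", {
  sim <- simulate_tandem_locus(sim_config(seed = 131, n_monomers_target = 30,
                                          divergence_years = 0,
                                          ir_copy_distribution = c(`1` = 1)))
  pd <- parent_diagnostics(sim$parents$A, sim$parents$B)
  tm <- sim$truth$monomers; tt <- sim$truth$tracts
  expect_gt(nrow(tt), 5L)
  for (j in seq_len(nrow(tt))) {
    i <- tt$monomer[j]
    mseq <- substr(sim$genome[[1]], tm$start0[i] + 1, tm$end0[i])
    tr <- infer_tracts(assign_parent_sites(mseq, pd))
    if (tt$n_diff_sites[j] < 2L) next       # below the detection floor
    hit <- tr[tr$minimal_start0 < tt$end0[j] & tr$minimal_end0 > tt$start0[j], ]
    expect_equal(nrow(hit), 1L)
    expect_gte(hit$minimal_start0, tt$start0[j])
    expect_lte(hit$minimal_end0, tt$end0[j])
    expect_lte(hit$maximal_start0, tt$start0[j])
    expect_gte(hit$maximal_end0, tt$end0[j])
  }
})

test_that("recombinant summaries count monomers once and tracts each", {
  mons <- data.frame(id = c("m1", "m2", "m3", "m4"),
                     locus = c("I", "I", "II", "II"))
  none <- summarize_recombinants(
    data.frame(monomer_ref = character(), donor = character(),
               minimal_start0 = integer(), minimal_end0 = integer(),
               maximal_start0 = integer(), maximal_end0 = integer()), mons)
  expect_true(all(none$by_locus$percent_recombinant == 0))

  tr <- data.frame(monomer_ref = c("m3", "m3", "m4"), donor = "A",
                   minimal_start0 = c(0L, 100L, 10L),
                   minimal_end0 = c(50L, 150L, 80L),
                   maximal_start0 = c(0L, 90L, 0L),
                   maximal_end0 = c(60L, 160L, 100L))
  sm <- summarize_recombinants(tr, mons)
  l2 <- sm$by_locus[sm$by_locus$locus == "II", ]
  expect_equal(l2$n_recombinant, 2L)          # m3 counted once
  expect_equal(l2$percent_recombinant, 100)
  expect_equal(sm$by_donor$n_tracts, 3L)      # but all three tracts tallied
  expect_equal(sm$by_locus$percent_recombinant[sm$by_locus$locus == "I"], 0)
})
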