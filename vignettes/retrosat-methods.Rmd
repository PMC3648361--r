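---
title: "Methods: models, parameters and design choices in retrosat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in retrosat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosat)
```

## The biological model

`retrosat` analyses tandem repeats that originated from the LTR-UTR region
of an LTR retrotransposon. The genesis model has two steps. First,
sequential intrastrand deletions between short homologies excise the UTR
tail, the coding interior and the 5' part of the downstream LTR, leaving an
`LTR-UTR~LTR` structure whose UTR~LTR junction recurs at every monomer
boundary of the later array (`splice_seed()`). Second, non-allelic gene
conversion between sister chromatids duplicates the cassette repeatedly;
`grow_array()` models this as iterated copy-paste of contiguous monomer
blocks. The repeat unit carries a start domain `S` (~402 nt, spanning the
LTR-UTR boundary), a tandem internal repeat `IR` (~100 nt, 1–4 copies) and
an end domain `E` (~185 nt), the architecture written `S-IRxk-E_X`.

Two further mechanisms shape real arrays and are modelled explicitly:

* **Gene conversion from a second parent allele.** A donor tract replaces
  the homologous span of a monomer with the A-allele sequence
  (`inject_variation()`); downstream, `infer_tracts()` reconstructs such
  tracts from parent-discriminating sites.
* **Nested retrotransposon insertions.** A synthetic `LTR–internal–LTR`
  element with a target site duplication is inserted at a monomer boundary;
  its two LTRs are identical at insertion time and diverge neutrally, which
  is the molecular clock used for dating.

## Dating: K2P distance and the substitution rate

`k2p_distance()` counts transition- and transversion-differing columns over
comparable alignment columns (pairwise deletion: any column with a gap or
`N` on either side is excluded, matching the common "pairwise deletion"
convention of phylogenetic software) and applies

$$\kappa = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

raising an error when either logarithm's argument is non-positive
(saturation) or no comparable column exists. Insertion age is
$T = \kappa / (2r)$.

The substitution rate is not a free parameter here: the published analyses
report four (kappa, age) pairs — 0.00699/0.54 My, 0.05319/4.09 My,
0.0122/0.94 My and 0.0103/0.79 My — and all four imply
$r = \kappa/2T \approx 6.5\times10^{-9}$ substitutions/site/year to the
printed precision. `kappa_to_age()` therefore defaults to `r = 6.5e-9`,
overridable everywhere it is used.

## The forward simulator and its defaults

All stochastic choices are drawn from one global RNG stream seeded by
`sim_config(seed=)`; identical configurations are byte-reproducible.
Neutral mutation uses the exact finite-time transition probabilities of the
K2P process (rates $\alpha + 2\beta = \mu$, ratio
$\alpha/2\beta = $ `tstv`), so the expected K2P distance between two copies
of an ancestor mutated for $t$ years is exactly $2\mu t$ — no
single-hit approximation.

Defaults are the study conditions of the maize CRM-derived repeats:

| parameter | default | unit | rationale |
|---|---|---|---|
| `mu` | 6.5e-9 | subs/site/yr | back-calculated from the four (kappa, age) calibrations |
| `tstv` | 2 | — | typical plant nuclear transition bias |
| `s_len`, `ir_len`, `e_len` | 402, 100, 185 | nt | measured monomer subdomain sizes |
| `ir_copy_distribution` | 2/22/60/6 of 90 over k=1..4 | — | observed copy-number spectrum at the heterogeneous locus |
| `donor_tract_prob` | 0.68 | — | observed recombinant-monomer fraction |
| `tract_len_min`, `tract_len_mean` | 71, 135 | nt | observed tract bounds (at least 71 bp, up to ~200 bp); length is min + geometric |
| `divergence_years` | 2e6 | yr | gives ~2.6% pairwise monomer divergence, matching "up to 97%" monomer similarity |
| `parent_divergence_years` | 16e6 | yr | ~10% A/B allele divergence; the published bitscore contrast between the end-domain and the two parent consensi implies ~10–15% |
| TSD length | 5 | bp | typical for Ty3/gypsy elements |
| spacers | random, 2 kb | nt | stand-ins for intervening sequence between islands |

Expansion events copy a block of geometric length (mean 2 monomers),
reflecting that conversion tracts of one to a few kilobases move whole
monomers rather than fragments. Nested insertions are placed at interior
monomer boundaries — the configuration the island-segmentation and dating
analyses consume; insertions that disrupt a monomer internally are not
generated. Insertions sharing a `family` label are copies of one element
template (as for repeated insertions of the same retrotransposon family),
which is what makes strand calling possible downstream.

### What the simulator does not emulate

No indel mutation within monomers (substitutions only), no rate
heterogeneity along the sequence, no selection, no population sampling, no
assembly gaps, no transcription or splicing. Consequences: detector
components that would have to cope with indel-induced phase drift
(anchor scanning, frame mapping) are exercised only mildly by the
simulations — passing recovery tests demonstrates correctness of the logic
under the stated model, not robustness to heavily indel-laden real
assemblies.

## Detection: numerical choices

* **Seeding and chaining.** `find_arrays()` seeds exact 13-mers of the
  reference unit (including k-mers spanning the head-to-tail junction,
  via circular closure of the unit) on both strands and chains seeds
  closer than one unit length. Array bounds are seed-resolution: exact to
  within about one k-mer. A chain found on both strands over the same span
  keeps the strand with more seed hits. `min_identity` (default 80%) is
  measured by locally aligning up to three unit-length windows against a
  unit dimer, so window phase does not matter.
* **Islands.** Runs of seed-covered bases separated by at least `gap_min`
  (default one unit length) uncovered bases; the published criterion
  ("intervening sequences") is qualitative, so the gap is configurable.
* **Monomer extraction.** The canonical phase anchor is the homolog of the
  unit start, located by a mismatch-tolerant 40 nt probe scan (minimum 70%
  identity, candidates closer than half a unit merged to the best-scoring
  one). The anchor search extends 25 nt upstream of the seeded island edge
  because an edge mutation can trim seed coverage into the first monomer.
  Monomers at least `flen_frac` (default 0.9) of the unit length are
  flagged full length — "full length" is never quantified in the source
  analyses, so the fraction is an explicit, configurable calibration.
* **Periodicity.** The self-match autocorrelation is maximised over a lag
  range; the reported period is the *smallest* lag scoring within a margin
  (default 0.2) of the maximum, because a composite repeat with alternating
  unit variants scores strictly higher at twice the fundamental — taking
  the argmax would report the harmonic instead of the 18 nt fundamental. A
  secondary period of twice the fundamental is reported when doubling the
  lag improves self-similarity by more than 0.05, the signature of a
  two-unit higher-order structure. Below an autocorrelation of 0.6 no
  period is called.

## Consensus, SNP panels and haplotypes

Monomers within an array are typically ≥95% identical, so
`build_consensus()` uses deterministic star alignment to an anchor rather
than progressive MSA; columns are anchor-projected (insertions relative to
the anchor are not represented), majority bases win, ties become IUPAC
codes, and columns gapped in more than half of the sequences are dropped
from the consensus but kept in the column map. Diagnostic columns require
distinct within-group majority *bases* (gap-major columns are excluded) at
a within-group concordance of at least 0.7 — permissive enough to keep
columns where minor haplotypes segregate, strict enough to stay
discriminative. The A-rich IR tail is masked
(`mask_low_complexity()`, windows of ≥10 nt at ≥80% A) before SNP work, as
its length polymorphism makes columns there unalignable.

`decompose_monomer()` assigns the end domain to whichever variant scores
higher, with a 5% relative tie margin yielding `E_?` so that recombinant or
ambiguous ends are not overcalled.

## Conversion tracts

Sites where the two parent alleles differ are the only observable record of
a conversion tract. A tract is called from at least `min_sites = 2`
consecutive donor calls (a single donor site is indistinguishable from a
point mutation) with no interior background call by default. The minimal
bound spans the supporting sites; the maximal bound extends to, but
excludes, the nearest flanking background-called sites — a site still
carrying the background allele cannot have been inside the conversion
tract — or the monomer edge. On noise-free simulations the truth interval
is provably bracketed: `minimal ⊆ truth ⊆ maximal`.

The tract recovery studies run with a fixed `S-IR-E` architecture
(`ir_copy_distribution = c("1" = 1)`): the published tract analysis is done
in a common alignment frame, and a tract inside an extra IR copy has no
image in the single-IR parent frame. Monomers with extra IR copies are
still handled in the general pipeline by global alignment to the parent
frame, with the caveat that donor segments inside surplus IR copies are
invisible to the site map.

## Problem sizes

The recovery studies use desk-scale problem sizes chosen to give stable
statistics: 50 replicate LTR pairs of 1000 nt per age point for dating
recovery; 20 replicate ten-monomer loci for monomer-count recovery; 200
monomers for IR copy-number recovery; two groups of 97 and 90 subdomain
sequences (the real locus sample sizes) for SNP-panel and haplotype
recovery, averaged over five replicate draws; 100 donor-tract monomers for
bracketing; and five replicate 90-monomer loci for the recombinant
fraction. Genome-scale quantities of the original study (monomer and
island censuses of a real assembly) are outside the scope of these
simulations.

## Known limitations

* Linear gap penalties only (affine gaps would better model real indels);
  alignment is exact DP, so sequences beyond a few tens of kilobases per
  pair are rejected rather than approximated.
* Strand of a nested insertion is not identifiable from an LTR pair alone
  (direct repeats read the same on both strands); a reference element
  sequence must be supplied to call orientation.
* The TSD detector requires an exact duplication of 3–20 bp; degenerate
  TSDs are reported as absent rather than guessed.
* Island segmentation treats any seed-coverage gap the same way; it cannot
  distinguish a nested element from an assembly gap or unrelated sequence
  without the downstream insertion analysis.
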