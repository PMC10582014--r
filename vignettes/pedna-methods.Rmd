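---
title: "Partitioning protected extracellular DNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning protected extracellular DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Marine "viromes" are sequenced from size-filtered (<0.22 µm), DNase-treated
water samples. Those preparations retain everything that protects DNA from
nucleases, not only virus particles: gene transfer agents (GTAs,
defective-prophage-derived particles that package random short host genome
segments) and extracellular vesicles (EVs, membrane vesicles that can
enclose host DNA) co-purify with virions. We call the recovered sequence
space *protected extracellular DNA* (peDNA). There is no sequence signature
that distinguishes DNA packaged in an EV from DNA packaged in a GTA or a
transducing phage particle, so the attribution has to come from indirect
evidence: which contigs look viral, which genomes the non-viral reads
recruit to, what those genomes encode (GTA clusters, proviruses), and how
peDNA coverage is distributed along them.

pednar implements that analysis chain — SSU screen, viral/non-viral split,
per-genome mechanism attribution, COG profiling — together with a seeded
synthetic community generator that provides per-read ground truth, so every
stage can be validated end to end without external data.

## The synthetic community generator

`build_community()` plants coordinate-anchored features into random genome
backbones:

* every host gets one SSU rRNA gene (a copy of the bundled reference with
  2% substitutions, emulating within-clade divergence), COG-labelled genes
  back-translated from the bundled COG-style protein set, and transposase
  genes (Mobilome-category entries whose cluster names match the transposase
  regular expression);
* *GTA producers* get an RcGTA-like cluster: all ten core genes (TG, TAP,
  TTP, MTP, HTJ, GP6, MCP, Prot, PPP, MBP) plus a draw of accessory genes,
  11–15 genes in reference order with 20–200 bp spacers, optionally split
  into three dispersed subclusters;
* *transducers* get one integrated provirus: a virus-like segment carrying
  several hallmark-gene copies (major capsid protein, terminase large
  subunit, portal protein) with bounded intergenic spacing, as in gene-dense
  virus genomes;
* free viruses are built the same way as proviruses.

All planted proteins are back-translated with uniformly drawn synonymous
codons, so homology searches against the bundled references recover the
planted truth at the protein level while the DNA differs between plantings.
The bundled reference sets themselves are synthetic constructs (random
sequences with realistic residue frequencies, generated once with a fixed
seed by `data-raw/synthetic_references.R`); they are internally consistent
with the generator, which is all the pipeline logic exercises. Results on
these references say nothing about the sensitivity of real homology
searches against real viral or GTA proteins.

Cell abundance and peDNA output are drawn independently (log-normal,
sdlog 1) per genome. This encodes the central assumption that a genome's
contribution to peDNA reflects its particle production, not its cell count,
and makes the expected squared correlation between the two abundances
1/(n−1) — which the mechanism stage's abundance check should (and does)
reproduce.

### Carrier models

`sample_pedna_reads()` draws, per read pair: a carrier from the
`carrier_mix()`, an eligible source genome proportional to `abundance_pedna`,
a packaged fragment per the carrier model, and a sequencing insert
(normal, mean 350 bp, sd 40) inside the fragment, emitting 2×150 bp mates
with independent substitution errors (default 0.005/base).

| carrier | eligible sources | packaged fragment |
|---|---|---|
| `virion` | free viruses; transducer proviruses at `induction`-fold weight | whole virus genome / provirus interval |
| `transduction_general` | transducer hosts | uniform host fragment |
| `transduction_specialized` | transducer hosts | fragment within 8 kb of a provirus boundary |
| `gta_particle` | GTA hosts | 4.5 ± 1 kb fragment (RcGTA-like headful) |
| `ev` | any host | log-normal cargo, median 2 kb, sdlog 0.6 |
| `free_dna`, `cell` | any genome / hosts by cell abundance | contamination carriers, weight 0 by default |

Three modelling decisions deserve justification:

* **EV eligibility is any host, not only EV-labelled hosts.** EV production
  has no genetic signature, and the truth label marks a genome's
  *predominant* export mechanism, not an exclusive one. This is what allows
  the two-population scenario below (a transducer-labelled genome exporting
  DNA EV-style at a second station).
* **Provirus induction.** Published evidence for active transduction is
  "elevated coverage over the proviral region"; how elevated is never
  quantified. We model induction as the provirus competing within the
  virion carrier at `induction` (default 10) times the host's peDNA weight,
  reflecting the elevated intracellular copy number of a replicating
  prophage. The realized region/flank depth ratio then follows from the
  carrier weights and genome geometry; tests derive the expected ratio from
  those weights independently and require agreement within 20%.
* **GTA particle size.** The GTA literature gives head diameters in tens of
  nanometres and packaged cargo of roughly 4–5 kb; the packaging length is
  modelled as 4.5 ± 1 kb and is not derived from particle dimensions.
* `provirus_free` models a provirus-free subpopulation: host-derived
  fragments avoid the provirus interval and the genome stops feeding the
  virion carrier, so the provirus region recruits exactly nothing.

`default_pedna_mix()` (virion 0.35, EV 0.30, GTA 0.20, generalized
transduction 0.10, specialized 0.05) is the fixed study condition for
mixed-community scenarios: EV cargo dominating the non-viral fraction with
a substantial virion background. The field provides no measured carrier
mixture for any real sample; these are scenario parameters, not estimates.

## Core primitives

* **ORF calling** (`find_orfs()`): maximal start-to-stop frames on both
  strands, starts {ATG, GTG, TTG}, minimum 50 codons for genomic ORFs
  (20 for read fragments via `read_orf()`), coordinates 0-based half-open on
  the forward strand. This is a deliberate simplification of a real gene
  caller: no RBS model, no overlapping-gene resolution — sufficient because
  every downstream consumer only needs the planted proteins back.
* **Protein search** (`sw_align()`, `sw_search()`): optimal local alignment
  under BLOSUM62 with affine gaps (open 11, extend 1), E-value
  `K·m·n·exp(−λS)` with the gapped defaults λ = 0.267, K = 0.041, and hit
  thresholds E ≤ 1e−5, identity > 50%. Batch searches run the full
  alignment only for pairs sharing ≥ 2 peptide 4-mers — the seeding
  shortcut every fast protein search tool uses; at these identity
  thresholds the filter is conservative.
* **Read mapping** (`kmer_map_reads()`): 21-mer seeds at stride 12 in both
  orientations, diagonal voting, ungapped verification by direct base
  comparison, N as mismatch. A pair maps only if both mates place on one
  target and pooled identity ≥ 0.9 (0.95 for the functional-profiling
  stage, mirroring strict recruitment). Indels are not modelled — the
  generator is substitution-only, and the downstream statistics consume
  only (target, position, identity). Ties go to the lexicographically
  smaller target id, making all outputs deterministic.

## The analysis stages

**SSU screen** (`ssu_rate()`): a pair counts as SSU if either mate places on
any 16S/18S reference at ≥ 0.8 identity over ≥ 50 bp (declared defaults; the
published screen does not restate its internal thresholds). The report
carries the 0.078% mean metagenome alignment rate as context only and
issues no verdict: EVs and GTAs package SSU genes, so the rate neither
proves nor disproves contamination.

**Split** (`split_pedna()`): contigs < 2000 bp are removed (inclusive
boundary); classifier A calls a contig viral when ≥ 1 translated ORF hits
the hallmark set; classifier B (tetranucleotide similarity to the
hallmark-bearing contigs) is recorded but off by default — the merge rule
defaults to `a_only` so results stay interpretable, with `union`,
`intersection`, `b_only` and an external label table available (the
external path is the recommended way to plug in real classifier output).
`nv_ratio` counts read *pairs*; unmapped and label-ambiguous pairs are
excluded from the denominator.

**Mechanism attribution** (`call_mechanisms()`): MAGs < 100 kb are removed;
all peDNA pairs are mapped to the survivors; the 20 most-recruiting MAGs
proceed. Candidate proviral regions are chains of ≥ 2 hallmark-hit ORFs
within 15 kb, padded 5 kb per side. Coverage profiles use 1 kb windows;
the background is the 10%-trimmed mean over windows outside candidate
regions. A region is *active* when its full-resolution mean depth is at
least α = 3 times the background, *absent* when it is at most ε = 0.05
times a background of at least 1×, *inactive* otherwise; α, ε and the
background floor are declared stand-ins for a judgement the original
analysis made by eye, and are exposed as arguments. A GTA call is
*functional* with > 10 distinct reference genes hit and all core genes
present, *dispersed* when hits fall into > 2 loci ≥ 20 kb apart. The
decision rule is then exact: active ∧ ¬functional → transducer;
functional ∧ ¬active → GTA producer; neither → EV producer; contradictory
evidence (active ∧ functional), or an uninformative coverage profile on a
MAG that still recruits ≥ 100 pairs, → unclear.

**COG profiling**: reads inherit their best MAG's mechanism label at ≥ 95%
identity; per mate, the longest stop-free frame ≥ 20 codons is searched
against the COG set (best hit per read, query cover ≥ 80%, subject cover
≥ 10%). A gene is *high-coverage* when its peDNA recruitment (pairs per kb)
reaches the mean plus two population standard deviations across the gene
set — the threshold is inclusive and degenerate zero-variance inputs flag
nothing, which is the only reading consistent with both boundary cases of
the rule. Per (label, category): `freq = n_hc / n_tot` with `n_tot` the
reads assigned to that category; the raw category share is emitted
alongside so either frequency reading can be audited (the published
formula's prose is ambiguous about the denominator). Fold changes are
signed: `freq_label/freq_microbial` when ≥ 1, otherwise the negated
reciprocal, so no value lies in (−1, 1); a zero frequency is replaced by
half the smallest nonzero frequency of the profile pair (avoids infinities
without dominating the signal), and a category empty on both sides is
reported missing.

## What passing tests do and do not show

The generator produces substitution-only reads from clonal genomes with
clean, non-overlapping features, known boundaries, and references that
match the planted genes near-perfectly. Passing the validation suite
therefore shows the *logic* of the pipeline is correct — counting,
thresholds, decision rules, determinism — under the stated study
conditions. It does not show robustness to assembly fragmentation, strain
microdiversity, indel/quality error profiles, diverged homologs, chimeric
contigs, or classifier error on real data; those enter real analyses
through the external-label pathway and the configurable thresholds, and are
out of scope here.

## Problem sizes

The validation experiments use sizes chosen to keep the full suite
comfortably reproducible on a laptop-class single core: purified-particle
controls with 5 genomes and 20,000 pairs; mixture-recovery runs at 50,000
pairs; the mechanism-recovery experiment with 30 hosts (10 per mechanism),
5 free viruses, 100,000 pairs and 10× induction; profiling checks at a few
thousand pairs. Statistical tolerances are derived from the corresponding
binomial or multinomial errors at those sizes.

## Reproducing the headline checks

```r
library(pednar)

com <- build_community(30, 5, c(EV_producer = 10, GTA_producer = 10,
                                transducer = 10), seed = 42)
sm  <- sample_pedna_reads(com, default_pedna_mix(), n_pairs = 1e5, seed = 43)
mags <- community_contigs(com)[com$role == "host", ]
mech <- call_mechanisms(mags, sm$reads, top_k = 20)
glance(mech)
autoplot(mech)
```

`scripts/acceptance.R` re-runs the two purified-particle controls from
scratch and writes their percentages as JSON.
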