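# Community generator and carrier-model read sampling: determinism, planted
# truth, and distributional checks against direct probabilistic oracles.

test_that("community generation is deterministic and honours counts", {
  com1 <- build_community(4, 2, c(EV_producer = 2, GTA_producer = 1,
                                  transducer = 1),
                          genome_len_range = c(70e3, 90e3),
                          cog_genes_per_host = 10, seed = 99)
  com2 <- build_community(4, 2, c(EV_producer = 2, GTA_producer = 1,
                                  transducer = 1),
                          genome_len_range = c(70e3, 90e3),
                          cog_genes_per_host = 10, seed = 99)
  expect_identical(com1$seq, com2$seq)
  expect_identical(com1$features, com2$features)
  expect_equal(sum(com1$truth_mechanism == "EV_producer"), 2)
  expect_equal(sum(com1$truth_mechanism == "GTA_producer"), 1)
  expect_equal(sum(com1$truth_mechanism == "transducer"), 1)
  expect_equal(sum(com1$role == "virus"), 2)
  com3 <- build_community(4, 2, c(EV_producer = 2, GTA_producer = 1,
                                  transducer = 1),
                          genome_len_range = c(70e3, 90e3),
                          cog_genes_per_host = 10, seed = 100)
  expect_false(identical(com1$seq, com3$seq))
  expect_error(build_community(4, 1, c(EV_producer = 4, transducer = 1)),
               "sum to n_hosts")
})

test_that("features lie within genomes and carry their required attributes", {
  com <- small_community()
  f <- community_features(com)
  len <- setNames(com$length, com$genome_id)
  expect_true(all(f$start >= 0 & f$end <= len[f$genome]))
  expect_true(all(f$start < f$end))
  expect_true(all(!is.na(f$category[f$kind == "cog_gene"])))
  expect_true(all(!is.na(f$gene[f$kind == "gta_gene"])))
  # planted feature sequences match: a cog gene translates to a db protein
  cg <- f[f$kind == "cog_gene", ][1, ]
  g <- substr(com$seq[com$genome_id == cg$genome], cg$start + 1, cg$end)
  cog <- load_cog_db()
  prot <- translate_dna(g)
  expect_equal(unname(prot), unname(cog$protein[cog$name == cg$name][1]))
})

test_that("GTA hosts carry a functional planted cluster", {
  com <- small_community()
  f <- community_features(com)
  gta_host <- com$genome_id[com$truth_mechanism == "GTA_producer"]
  genes <- f[f$genome == gta_host & f$kind == "gta_gene", ]
  expect_gte(nrow(genes), 11)
  core <- load_gta_db()$gene[load_gta_db()$core]
  expect_true(all(core %in% genes$gene))
})

test_that("transducer proviruses contain detectable hallmark genes", {
  com <- small_community()
  f <- community_features(com)
  tr <- com$genome_id[com$truth_mechanism == "transducer"]
  pro <- f[f$genome == tr & f$kind == "provirus", ]
  expect_equal(nrow(pro), 1)
  # translated ORFs of the provirus interval hit the hallmark set >= 2 times
  sub <- substr(com$seq[com$genome_id == tr], pro$start + 1, pro$end)
  orfs <- find_orfs(tibble::tibble(id = "pro", seq = sub))
  hits <- sw_search(tibble::tibble(id = paste0("o", seq_len(nrow(orfs))),
                                   protein = orfs$protein),
                    load_hallmark_db())
  expect_gte(length(unique(hits$query_id)), 2)
})

test_that("pure-virion sampling emits only virion truth from viruses", {
  com <- build_community(0, 3, c(), genome_len_range = c(30e3, 40e3),
                         seed = 12)
  sm <- sample_pedna_reads(com, carrier_mix(virion = 1), n_pairs = 500,
                           seed = 13)
  expect_true(all(sm$truth$carrier == "virion"))
  expect_true(all(sm$truth$source_genome %in% com$genome_id))
  expect_equal(nrow(sm$reads), 500)
  # one truth row per emitted pair
  expect_identical(sort(sm$reads$read_id), sort(sm$truth$read_id))
})

test_that("a carrier without eligible genomes raises a validation error", {
  com <- build_community(2, 0, c(EV_producer = 2),
                         genome_len_range = c(30e3, 40e3), seed = 14)
  expect_error(sample_pedna_reads(com, carrier_mix(virion = 1), 10, seed = 1),
               "no eligible genome")
  expect_error(sample_pedna_reads(com, carrier_mix(gta_particle = 1), 10,
                                  seed = 1),
               "no eligible genome")
})

test_that("EV sampling follows peDNA abundance weights (multinomial 3-sigma)", {
  com <- build_community(6, 0, c(EV_producer = 6),
                         genome_len_range = c(30e3, 40e3), seed = 15)
  n <- 6000
  sm <- sample_pedna_reads(com, carrier_mix(ev = 1), n_pairs = n, seed = 16)
  p <- com$abundance_pedna / sum(com$abundance_pedna)
  cnt <- table(factor(sm$truth$source_genome, levels = com$genome_id))
  for (i in seq_along(p)) {
    sigma <- sqrt(n * p[i] * (1 - p[i]))
    expect_lt(abs(cnt[i] - n * p[i]), 3 * sigma + 1)
  }
})

test_that("reads match their recorded source interval up to the error rate", {
  com <- small_community()
  sm <- sample_pedna_reads(com, default_pedna_mix(), n_pairs = 200,
                           err_rate = 0, seed = 17)
  gseq <- setNames(com$seq, com$genome_id)
  tr <- sm$truth
  r1_true <- substring(gseq[tr$source_genome], tr$start + 1, tr$start + 150)
  r2_true <- vapply(substring(gseq[tr$source_genome], tr$end - 149, tr$end),
                    oracle_revcomp, "", USE.NAMES = FALSE)
  expect_equal(sm$reads$seq1, unname(r1_true))
  expect_equal(sm$reads$seq2, r2_true)
})

test_that("provirus depth exceeds flank depth per the sampling-weight oracle", {
  com <- build_community(1, 0, c(transducer = 1),
                         genome_len_range = c(140e3, 150e3), seed = 18)
  f <- community_features(com)
  pro <- f[f$kind == "provirus", ]
  n <- 30000
  sm <- sample_pedna_reads(com, carrier_mix(virion = 0.5,
                                            transduction_general = 0.5),
                           n_pairs = n, seed = 19)
  # oracle: virion inserts all land in the provirus, transduction uniform;
  # expected per-base rates give ratio 1 + (w_v/w_t) * Lg/Lp
  Lg <- com$length[1]
  Lp <- pro$end - pro$start
  expected <- 1 + (0.5 / 0.5) * Lg / Lp
  tr <- sm$truth
  mid <- (tr$start + tr$end) / 2
  inside <- mid >= pro$start & mid < pro$end
  depth_in <- sum(inside) / Lp
  depth_out <- sum(!inside) / (Lg - Lp)
  expect_lt(abs(depth_in / depth_out - expected) / expected, 0.2)
})

test_that("metagenome sampling follows cell abundance (binomial 3-sigma)", {
  com <- build_community(2, 0, c(EV_producer = 2),
                         genome_len_range = c(30e3, 40e3), seed = 20)
  com$abundance_cell <- c(3, 1)
  n <- 4000
  sm <- sample_metagenome_reads(com, n_pairs = n, seed = 21)
  n1 <- sum(sm$truth$source_genome == com$genome_id[1])
  sigma <- sqrt(n * 0.75 * 0.25)
  expect_lt(abs(n1 - n * 0.75), 3 * sigma)
  # single-genome community: everything comes from it
  sm1 <- sample_metagenome_reads(com[1, ], n_pairs = 50, seed = 22)
  expect_true(all(sm1$truth$source_genome == com$genome_id[1]))
  # determinism in seeds
  a <- sample_metagenome_reads(com, 100, seed = 5)
  b <- sample_metagenome_reads(com, 100, seed = 5)
  d <- sample_metagenome_reads(com, 100, seed = 6)
  expect_identical(a$reads, b$reads)
  expect_false(identical(a$reads, d$reads))
})

test_that("cell and peDNA abundances are uncorrelated across hosts", {
  r2 <- vapply(1:12, function(s) {
    com <- build_community(80, 0, c(EV_producer = 80),
                           genome_len_range = c(6e3, 8e3),
                           cog_genes_per_host = 2, seed = 1000 + s)
    # log scale: the draws are log-normal, so independence gives the clean
    # E[R^2] = 1/(n-1) behaviour without heavy-tail spikes
    cor(log(com$abundance_cell), log(com$abundance_pedna))^2
  }, 0)
  expect_lt(mean(r2), 0.04)
  expect_gt(mean(r2), 0.002)
  expect_true(all(r2 < 0.15))
})
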