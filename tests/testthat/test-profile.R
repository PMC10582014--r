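# Functional profiling: read partitioning by mechanism, COG assignment,
# high-coverage flagging, fold changes, and the transposase views.

make_cog_fragments <- function(n_per, picks, jitter = 0) {
  cog <- load_cog_db()
  rows <- list()
  k <- 0
  for (p in picks) {
    prot <- cog$protein[cog$cluster == p]
    for (i in seq_len(n_per)) {
      k <- k + 1
      rows[[k]] <- tibble::tibble(read_id = sprintf("%s_%d", p, i), mate = 1L,
                                  protein = substr(prot, 10, 59))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("reads inherit the mechanism label of their best MAG", {
  com <- small_community()
  sm <- small_pedna()
  mags <- small_mags()
  labels <- tibble::tibble(mag_id = com$genome_id[com$role == "host"],
                           label = com$truth_mechanism[com$role == "host"])
  parts <- assign_mechanism_reads(sm$reads, mags, labels)
  expect_true(all(parts$mechanism_label %in%
                    c("EV_producer", "GTA_producer", "transducer")))
  # cross-check against the truth table: reads from a GTA host end up GTA
  tr <- sm$truth
  m <- dplyr::inner_join(parts, tr, by = "read_id")
  host_rows <- m[m$source_genome %in% labels$mag_id, ]
  expect_gt(nrow(host_rows), 100)
  expect_true(all(host_rows$mag_id == host_rows$source_genome))
  # strict identity threshold excludes diverged reads
  set.seed(61)
  noisy <- sm$reads[1:50, ]
  noisy$seq1 <- add_noise <- vapply(noisy$seq1, function(s) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), 15)  # 10% per mate
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1), "")
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
  parts_noisy <- assign_mechanism_reads(noisy, mags, labels,
                                        min_identity = 0.97)
  expect_equal(nrow(parts_noisy), 0)
})

test_that("COG assignment honours the coverage thresholds", {
  cog <- load_cog_db()
  frags <- tibble::tibble(
    read_id = c("exact", "short"), mate = 1L,
    protein = c(cog$protein[1],
                substr(cog$protein[5], 1, round(nchar(cog$protein[5]) *
                                                  0.05))))
  hits <- cog_assign(frags)
  expect_equal(hits$read_id, "exact")
  expect_equal(hits$cog_cluster, cog$cluster[1])
  expect_equal(hits$cog_category, cog$category[1])
  # scov 5% is below the 10% floor -> rejected
  expect_false("short" %in% hits$read_id)
})

test_that("category counts recover the planted composition", {
  cog <- load_cog_db()
  picks <- c(cog$cluster[cog$category == "C"][1],
             cog$cluster[cog$category == "X"][1])
  frags <- make_cog_fragments(20, picks)
  hits <- cog_assign(frags)
  tab <- table(hits$cog_category)
  expect_equal(unname(tab[["C"]]), 20)
  expect_equal(unname(tab[["X"]]), 20)
  # per-read uniqueness: no read is assigned twice
  expect_equal(anyDuplicated(hits$read_id), 0)
})

test_that("high-coverage flagging uses mean + 2 population SD, inclusively", {
  asn <- tibble::tibble(read_id = paste0("r", 1:5),
                        cog_cluster = paste0("c", 1:5),
                        cog_category = "C",
                        cog_name = paste0("gene", 1:5))
  rec <- tibble::tibble(gene_id = paste0("gene", 1:5),
                        recruitment = c(1, 1, 1, 1, 10))
  # mean 2.8, population SD 3.6 -> threshold 10.0; only the 10 reaches it
  out <- flag_high_coverage(asn, rec)
  expect_equal(out$high_coverage, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # equal recruitment: zero SD, nothing flagged
  rec2 <- dplyr::mutate(rec, recruitment = 4)
  expect_true(all(!flag_high_coverage(asn, rec2)$high_coverage))
  # fewer than 3 genes: warning, nothing flagged
  expect_warning(out3 <- flag_high_coverage(asn, rec[1, ]), "fewer than 3")
  expect_true(all(!out3$high_coverage))
})

test_that("fold changes follow the signed formula and exclude (-1, 1)", {
  mk <- function(freqs) tibble::tibble(label = "L",
                                       category = names(freqs),
                                       n_tot = 100L, n_hc = 10L,
                                       freq = unname(freqs))
  a <- mk(c(A = 0.2, B = 0.1, C = 0.15, D = 0))
  b <- dplyr::mutate(mk(c(A = 0.1, B = 0.2, C = 0.15, D = 0)), label = "M")
  fc <- fold_changes(a, b)
  expect_equal(fc$fold_change[fc$category == "A"], 2)
  expect_equal(fc$fold_change[fc$category == "B"], -2)
  expect_equal(fc$fold_change[fc$category == "C"], 1)
  expect_true(is.na(fc$fold_change[fc$category == "D"]))
  ok <- !is.na(fc$fold_change)
  expect_true(all(abs(fc$fold_change[ok]) >= 1))
  # sign antisymmetry away from +/-1
  fc_rev <- fold_changes(b, a)
  for (cat in c("A", "B")) {
    expect_equal(fc$fold_change[fc$category == cat],
                 -fc_rev$fold_change[fc_rev$category == cat])
  }
  # self-comparison gives +1 wherever the frequency is nonzero
  fc_self <- fold_changes(a, dplyr::mutate(a, label = "self"))
  expect_true(all(fc_self$fold_change[a$freq > 0] == 1))
  # a zero frequency against a nonzero one uses the pseudocount
  z <- mk(c(A = 0, B = 0.2))
  nz <- dplyr::mutate(mk(c(A = 0.1, B = 0.2)), label = "M")
  fcz <- fold_changes(z, nz)
  expect_equal(fcz$fold_change[fcz$category == "A"], -(0.1 / 0.05))
})

test_that("profiles conserve read totals per label", {
  cog <- load_cog_db()
  picks <- cog$cluster[c(1, 6, 11)]
  frags <- make_cog_fragments(10, picks)
  hits <- cog_assign(frags)
  hits$high_coverage <- rep(c(TRUE, FALSE), length.out = nrow(hits))
  prof <- cog_profile(hits, label = "EV")
  expect_equal(sum(prof$n_tot), nrow(hits))
  expect_true(all(prof$freq >= 0 & prof$freq <= 1))
  expect_equal(sum(prof$freq_raw), 1)
})

test_that("the transposase regex matches both engines on random annotations", {
  expect_equal(transposase_scan(c("IS5 family element", "hypothetical")), 1)
  expect_equal(transposase_scan(c("Transposase", "transposase")), 2)
  set.seed(62)
  vocab <- c("IS", "Tn", "attTn", "transposase", "Transposase", "kinase",
             "ISOmerase", "protein", "3", "91", " ")
  anns <- vapply(1:50, function(i) {
    paste(sample(vocab, sample(1:4, 1), replace = TRUE), collapse = "")
  }, "")
  rx <- "IS\\d+|Tn\\d+|attTn\\d+|transposase|Transposase"
  want <- sum(grepl(rx, anns))          # TRE engine
  expect_equal(transposase_scan(anns), want)  # implementation uses PCRE
  tab <- transposase_scan(tibble::tibble(mag_id = rep(c("a", "b"), 25),
                                         annotation = anns))
  expect_equal(sum(tab$n_transposase), want)
})

test_that("the Mobilome transposase share is the planted share", {
  asn <- tibble::tibble(
    read_id = paste0("r", 1:6),
    cog_category = c("X", "X", "X", "X", "C", "C"),
    cog_name = c("IS3 family transposase", "Tn3 family transposase",
                 "prophage antirepressor", "IS200-like transposase",
                 "citrate synthase", "aconitase"))
  expect_equal(mobilome_transposase_fraction(asn), 0.75)
  asn_none <- dplyr::mutate(asn, cog_name = "prophage antirepressor")
  expect_equal(mobilome_transposase_fraction(asn_none), 0)
  expect_warning(
    out <- mobilome_transposase_fraction(asn[asn$cog_category == "C", ]),
    "Mobilome")
  expect_true(is.na(out))
})

test_that("EV cargo shows the planted Mobilome enrichment end to end", {
  # EV hosts carry 3x the community-average Mobilome gene density; the EV
  # read set must show a positive Mobilome fold change vs the metagenome,
  # larger than any other category's
  com <- fixture("enrich_com", build_community(
    6, 0, c(EV_producer = 6), genome_len_range = c(60e3, 80e3),
    ev_mobilome_factor = 3, seed = 63))
  sm <- sample_pedna_reads(com, carrier_mix(ev = 1), n_pairs = 2500,
                           seed = 64)
  mg <- sample_metagenome_reads(com, n_pairs = 2500, seed = 65)
  # metagenome of an EV-only community still has the X enrichment in its
  # genomes; build the microbial comparator from hosts without the boost
  com0 <- fixture("enrich_com0", build_community(
    6, 0, c(EV_producer = 6), genome_len_range = c(60e3, 80e3),
    ev_mobilome_factor = 1, seed = 63))
  mg0 <- sample_metagenome_reads(com0, n_pairs = 2500, seed = 65)
  prof_of <- function(reads, label) {
    frags <- read_orf(reads)
    hits <- cog_assign(frags)
    hits$high_coverage <- TRUE   # compare raw composition
    cog_profile(hits, label = label, categories = sort(unique(
      load_cog_db()$category)))
  }
  p_ev <- prof_of(sm$reads, "EV")
  p_mic <- prof_of(mg0$reads, "microbial")
  fc <- fold_changes(p_ev, p_mic, freq_col = "freq_raw")
  x_fc <- fc$fold_change[fc$category == "X"]
  expect_gt(x_fc, 1)
  expect_true(all(x_fc >= fc$fold_change[fc$category != "X"], na.rm = TRUE))
})
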