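# Mechanism attribution: recruitment ranking, coverage arithmetic, provirus
# detection and activity, GTA calls, and the decision rule.

test_that("the MAG length filter keeps exactly length >= 100 kb", {
  set.seed(51)
  mags <- tibble::tibble(id = c("m1", "m2"),
                         seq = vapply(c(99999, 100000), random_dna_str, ""))
  expect_equal(filter_mags(mags)$id, "m2")
  expect_equal(nrow(filter_mags(mags[0, ])), 0)
  rnd <- tibble::tibble(id = paste0("m", 1:8),
                        seq = vapply(sample(5e4:2e5, 8), random_dna_str, ""))
  expect_equal(filter_mags(rnd)$id, rnd$id[nchar(rnd$seq) >= 1e5])
})

test_that("recruitment ranking counts pairs and breaks ties by id", {
  aln <- tibble::tibble(
    read_id = paste0("r", 1:16),
    target_id = c(rep("mB", 10), rep("mA", 5), "mC"),
    start1 = 0L, end1 = 100L, start2 = 200L, end2 = 300L,
    matches = 200L, bases = 200L, identity = 1, mapped = TRUE)
  mags <- tibble::tibble(id = c("mA", "mB", "mC", "mD"),
                         seq = strrep("A", 10))
  rk <- recruit_and_rank(NULL, mags, top_k = 2, alignments = aln)
  expect_equal(rk$mag_id, c("mB", "mA"))
  expect_equal(rk$recruitment_pairs, c(10L, 5L))
  # tie at rank k: lexicographically smaller id kept
  aln2 <- dplyr::mutate(aln, target_id = c(rep("mB", 8), rep("mA", 8)))
  rk2 <- recruit_and_rank(NULL, mags, top_k = 1, alignments = aln2)
  expect_equal(rk2$mag_id, "mA")
})

test_that("coverage windows hold the exact per-window mean depth", {
  # 10 pairs of 2x100 bp inside the first 1 kb window
  aln <- tibble::tibble(
    read_id = paste0("r", 1:10), target_id = "m",
    start1 = 0L, end1 = 100L, start2 = 500L, end2 = 600L,
    matches = 200L, bases = 200L, identity = 1, mapped = TRUE)
  prof <- coverage_profile(aln, "m", 5000, window_bp = 1000)
  expect_equal(prof$depth, c(2, 0, 0, 0, 0))
  # no alignments: all-zero profile, background 0
  prof0 <- coverage_profile(aln[0, ], "m", 5000)
  expect_true(all(prof0$depth == 0))
  expect_equal(attr(prof0, "background"), 0)
})

test_that("total windowed coverage conserves mapped bases", {
  set.seed(52)
  n <- 300
  L <- 57000
  s1 <- sample(0:(L - 150), n)
  s2 <- pmin(s1 + sample(100:300, n, replace = TRUE), L - 150)
  aln <- tibble::tibble(read_id = paste0("r", 1:n), target_id = "m",
                        start1 = s1, end1 = s1 + 150L,
                        start2 = s2, end2 = s2 + 150L,
                        matches = 300L, bases = 300L, identity = 1,
                        mapped = TRUE)
  prof <- coverage_profile(aln, "m", L, window_bp = 1000)
  win_len <- prof$end - prof$start
  expect_equal(sum(prof$depth * win_len),
               sum(aln$end1 - aln$start1) + sum(aln$end2 - aln$start2))
})

test_that("provirus detection recovers the planted region and only it", {
  com <- small_community()
  mags <- community_contigs(com)
  tr_id <- com$genome_id[com$truth_mechanism == "transducer"]
  ev_id <- com$genome_id[com$truth_mechanism == "EV_producer"][1]
  reg <- detect_provirus(mags[mags$id == tr_id, ])
  expect_equal(nrow(reg), 1)
  f <- community_features(com)
  pro <- f[f$genome == tr_id & f$kind == "provirus", ]
  overlap <- min(reg$end, pro$end) - max(reg$start, pro$start)
  expect_gte(overlap / (pro$end - pro$start), 0.8)
  expect_equal(nrow(detect_provirus(mags[mags$id == ev_id, ])), 0)
})

test_that("two distant proviruses yield two disjoint regions", {
  set.seed(53)
  hm <- load_hallmark_db()
  mkgene <- function(p) back_translate(p)
  v <- paste0(mkgene(hm$protein[1]), random_dna_str(2000),
              mkgene(hm$protein[2]))
  g <- paste0(random_dna_str(10000), v, random_dna_str(100000), v,
              random_dna_str(10000))
  reg <- detect_provirus(tibble::tibble(id = "m", seq = g))
  expect_equal(nrow(reg), 2)
  expect_true(reg$end[1] < reg$start[2])
})

test_that("provirus activity statuses follow the depth-ratio arithmetic", {
  mk_prof <- function(region_depth, bg_depth, L = 50000,
                      region = c(20000, 30000)) {
    # constant synthetic coverage: bg outside the region, region_depth inside
    cov <- S4Vectors::Rle(c(rep(bg_depth, region[1]),
                            rep(region_depth, region[2] - region[1]),
                            rep(bg_depth, L - region[2])))
    prof <- tibble::tibble(mag_id = "m", window = 1, start = 0L,
                           end = L, depth = mean(as.numeric(cov)))
    class(prof) <- c("pedna_coverage", class(prof))
    attr(prof, "coverage") <- cov
    attr(prof, "background") <- bg_depth
    prof
  }
  region <- tibble::tibble(start = 20000L, end = 30000L)
  a <- provirus_status(mk_prof(30, 3), region)
  expect_equal(a$status, "active")
  expect_equal(a$depth_ratio, 10)
  b <- provirus_status(mk_prof(0, 5), region)
  expect_equal(b$status, "absent")
  c_ <- provirus_status(mk_prof(4, 3), region)
  expect_equal(c_$status, "inactive")
  d <- provirus_status(mk_prof(0, 0), region)
  expect_equal(d$status, "inactive")
  expect_equal(d$flag, "no_signal")
  # absent requires a real background
  e <- provirus_status(mk_prof(0.01, 0.5), region, min_bg = 1)
  expect_equal(e$status, "inactive")
})

test_that("GTA calls follow the core-gene and count rules", {
  com <- small_community()
  mags <- community_contigs(com)
  gta_id <- com$genome_id[com$truth_mechanism == "GTA_producer"]
  ev_id <- com$genome_id[com$truth_mechanism == "EV_producer"][1]
  call <- detect_gta(mags[mags$id == gta_id, ])
  expect_true(call$functional)
  expect_gte(call$n_gta_genes, 11)
  expect_equal(call$core_missing, "")
  expect_false(detect_gta(mags[mags$id == ev_id, ])$functional)
})

test_that("a cluster missing one core gene or too few genes is not functional", {
  db <- load_gta_db()
  set.seed(54)
  plant <- function(genes) {
    sub <- db[db$gene %in% genes, ]
    dna <- vapply(sub$protein, back_translate, "", USE.NAMES = FALSE)
    paste0(random_dna_str(3000),
           paste(vapply(dna, function(d) paste0(d, random_dna_str(100)), ""),
                 collapse = ""),
           random_dna_str(3000))
  }
  core <- db$gene[db$core]
  noncore <- db$gene[!db$core]
  # 11 genes but missing core MCP
  g1 <- plant(c(setdiff(core, "MCP"), noncore[1:2]))
  c1 <- detect_gta(tibble::tibble(id = "m1", seq = g1))
  expect_equal(c1$n_gta_genes, 11)
  expect_false(c1$functional)
  expect_true(grepl("MCP", c1$core_missing))
  # 9 genes, all core: n <= 10 fails the count rule
  g2 <- plant(core[1:9])
  c2 <- detect_gta(tibble::tibble(id = "m2", seq = g2))
  expect_equal(c2$n_gta_genes, 9)
  expect_false(c2$functional)
})

test_that("dispersed clusters are recognised as such", {
  com <- build_community(1, 0, c(GTA_producer = 1), gta_dispersed = TRUE,
                         genome_len_range = c(150e3, 180e3), seed = 55)
  call <- detect_gta(community_contigs(com))
  expect_true(call$functional)
  expect_true(call$dispersed)
  # the compact cluster of the shared fixture is not dispersed
  com2 <- small_community()
  gta_id <- com2$genome_id[com2$truth_mechanism == "GTA_producer"]
  expect_false(detect_gta(
    community_contigs(com2)[community_contigs(com2)$id == gta_id, ])$dispersed)
})

test_that("the decision rule is the fixed truth table, exhaustively", {
  gta_call <- function(fn) tibble::tibble(mag_id = "m", n_gta_genes = 12L,
                                          core_present = "", core_missing = "",
                                          functional = fn, dispersed = FALSE)
  pro_call <- function(status, flag = NA_character_) {
    tibble::tibble(mag_id = "m", start = 0L, end = 10L, status = status,
                   depth_ratio = 5, background = 2, flag = flag)
  }
  want <- list(
    c("active", "TRUE", "unclear"),
    c("active", "FALSE", "transducer"),
    c("inactive", "TRUE", "GTA_producer"),
    c("inactive", "FALSE", "EV_producer"),
    c("absent", "TRUE", "GTA_producer"),
    c("absent", "FALSE", "EV_producer"),
    c("none_found", "TRUE", "GTA_producer"),
    c("none_found", "FALSE", "EV_producer"))
  for (w in want) {
    pro <- if (w[1] == "none_found") NULL else pro_call(w[1])
    got <- decide_mechanism(pro, gta_call(as.logical(w[2])))
    expect_equal(got$label, w[3])
  }
  # an uninformative profile on a recruiting MAG is unclear
  got <- decide_mechanism(pro_call("inactive", flag = "no_signal"),
                          gta_call(FALSE), recruitment_pairs = 500)
  expect_equal(got$label, "unclear")
  got2 <- decide_mechanism(pro_call("inactive", flag = "no_signal"),
                           gta_call(FALSE), recruitment_pairs = 3)
  expect_equal(got2$label, "EV_producer")
})

test_that("abundance correlation matches a closed-form Pearson computation", {
  x <- c(2, 4, 6, 8, 10, 12)
  y <- c(1, 3, 2, 6, 4, 9)
  r2 <- abundance_correlation(x, y)
  mx <- x / sum(x)
  my <- y / sum(y)
  hand <- (sum((mx - mean(mx)) * (my - mean(my))) /
             sqrt(sum((mx - mean(mx))^2) * sum((my - mean(my))^2)))^2
  expect_equal(r2, hand)
  expect_equal(abundance_correlation(x, x), 1)
  expect_warning(r0 <- abundance_correlation(x, rep(2, 6)), "zero variance")
  expect_true(is.na(r0))
})

test_that("the Haliea scenario splits into transducer and EV calls", {
  com <- build_community(1, 0, c(transducer = 1),
                         genome_len_range = c(140e3, 160e3), seed = 56)
  mag <- community_contigs(com)
  mix_with <- carrier_mix(virion = 0.4, ev = 0.6)
  s1 <- sample_pedna_reads(com, mix_with, n_pairs = 12000, seed = 57)
  m1 <- call_mechanisms(mag, s1$reads, top_k = 1)
  expect_equal(m1$label, "transducer")
  expect_equal(m1$provirus_status, "active")
  # station 2: the sampled population lacks the provirus
  s2 <- sample_pedna_reads(com, carrier_mix(ev = 1), n_pairs = 12000,
                           provirus_free = com$genome_id, seed = 58)
  m2 <- call_mechanisms(mag, s2$reads, top_k = 1)
  expect_equal(m2$label, "EV_producer")
  expect_equal(m2$provirus_status, "absent")
})

test_that("mechanism labels are recovered on the shared mixed community", {
  com <- small_community()
  sm <- small_pedna()
  mech <- call_mechanisms(small_mags(), sm$reads, top_k = 4)
  truth <- setNames(com$truth_mechanism, com$genome_id)
  expect_equal(unname(truth[mech$mag_id]), mech$label)
})
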