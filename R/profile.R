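# Per-mechanism functional profiling: COG category assignment of reads,
# high-coverage flagging, category frequencies and signed fold changes
# against the microbial metagenome, and the transposase view of the
# Mobilome category.

TRANSPOSASE_REGEX <- "IS\\d+|Tn\\d+|attTn\\d+|transposase|Transposase"

#' Partition peDNA reads by the mechanism label of their best MAG
#'
#' Pairs are mapped against the labelled MAGs at a strict identity threshold
#' (bbmap `minid=95` analogue); a mapped pair inherits the mechanism label
#' of its best MAG. Pairs mapping below the threshold are dropped.
#'
#' @param reads Read-set tibble.
#' @param mags Sequence tibble of the labelled MAGs.
#' @param mag_labels Tibble (`mag_id`, `label`), e.g. from
#'   [call_mechanisms()]; MAGs labelled `unclear` are excluded.
#' @param min_identity Mapping identity threshold.
#' @return Tibble: `read_id`, `seq1`, `seq2`, `mag_id`, `mechanism_label`;
#'   the alignment table is attached as attribute `alignments`.
#' @export
assign_mechanism_reads <- function(reads, mags, mag_labels,
                                   min_identity = 0.95) {
  use <- mag_labels[mag_labels$label != "unclear", ]
  if (nrow(use) == 0) abort("no labelled MAG")
  mm <- mags[mags$id %in% use$mag_id, ]
  aln <- kmer_map_reads(reads, mm[, c("id", "seq")],
                        min_identity = min_identity)
  hit <- aln[aln$mapped, c("read_id", "target_id")]
  out <- hit %>%
    left_join(use, by = c(target_id = "mag_id")) %>%
    rename(mag_id = "target_id", mechanism_label = "label") %>%
    left_join(reads[, c("read_id", "seq1", "seq2")], by = "read_id") %>%
    select("read_id", "seq1", "seq2", "mag_id", "mechanism_label")
  attr(out, "alignments") <- aln
  out
}

#' Assign protein fragments to COG clusters
#'
#' Each fragment is searched against the COG-style reference; the best hit
#' per read (both mates pooled, highest score) is kept if it meets the
#' E-value, query-coverage and subject-coverage thresholds. The read
#' inherits cluster, category and cluster name from the hit.
#'
#' @param fragments Tibble from [read_orf()] (`read_id`, `mate`, `protein`).
#' @param cog_db COG reference tibble (`id`, `cluster`, `category`, `name`,
#'   `protein`).
#' @param evalue_max,qcov_min,scov_min Acceptance thresholds (percent
#'   coverages).
#' @return Tibble: `read_id`, `cog_cluster`, `cog_category`, `cog_name`,
#'   `gene_id` (reference entry hit), `score`, `pident`, `qcov`, `scov`,
#'   `evalue`.
#' @export
cog_assign <- function(fragments, cog_db = load_cog_db(), evalue_max = 1e-5,
                       qcov_min = 80, scov_min = 10) {
  empty <- tibble(read_id = character(), cog_cluster = character(),
                  cog_category = character(), cog_name = character(),
                  gene_id = character(), score = numeric(),
                  pident = numeric(), qcov = numeric(), scov = numeric(),
                  evalue = numeric())
  if (nrow(fragments) == 0) return(empty)
  q <- tibble(id = paste0("f", seq_len(nrow(fragments))),
              protein = fragments$protein)
  hits <- sw_search(q, cog_db[, c("id", "protein")], evalue_max = evalue_max,
                    pident_min = 0)
  hits <- filter(hits, .data$qcov >= qcov_min, .data$scov >= scov_min)
  if (nrow(hits) == 0) return(empty)
  hits$read_id <- fragments$read_id[match(hits$query_id, q$id)]
  hits %>%
    arrange(desc(.data$score), .data$subject_id) %>%
    distinct(.data$read_id, .keep_all = TRUE) %>%
    left_join(cog_db[, c("id", "cluster", "category", "name")],
              by = c(subject_id = "id")) %>%
    select(read_id = "read_id", cog_cluster = "cluster",
           cog_category = "category", cog_name = "name",
           gene_id = "subject_id", "score", "pident", "qcov", "scov",
           "evalue")
}

#' Per-gene peDNA recruitment (pairs per gene per kb)
#'
#' Counts mapped pairs whose insert overlaps each planted gene feature and
#' normalises by the summed feature length per reference gene. Used to feed
#' [flag_high_coverage()].
#'
#' @param alignments Alignment table against the MAGs (mapped pairs).
#' @param community A `pedna_community` providing the planted features.
#' @param kinds Feature kinds treated as genes.
#' @return Tibble: `gene_id` (reference entry name of the feature),
#'   `recruitment` (pairs per kb).
#' @export
gene_recruitment <- function(alignments, community,
                             kinds = c("cog_gene", "transposase")) {
  feats <- purrr::map2_dfr(community$genome_id, community$features,
                           ~ bind_cols(tibble(genome = .x), .y)) %>%
    filter(.data$kind %in% kinds)
  a <- alignments[alignments$mapped, ]
  if (nrow(feats) == 0) return(tibble(gene_id = character(),
                                      recruitment = numeric()))
  # pair interval on the target: min mate start to max mate end
  ps <- pmin(a$start1, a$start2, na.rm = TRUE)
  pe <- pmax(a$end1, a$end2, na.rm = TRUE)
  dt_a <- data.table::data.table(genome = a$target_id, s = ps, e = pe)
  dt_f <- data.table::data.table(genome = feats$genome, fs = feats$start,
                                 fe = feats$end, gene_id = feats$name)
  m <- merge(dt_a, dt_f, by = "genome", allow.cartesian = TRUE)
  m <- m[m$s < m$fe & m$e > m$fs, ]
  cnt <- m[, list(pairs = .N), by = "gene_id"]
  lens <- dt_f[, list(kb = sum(fe - fs) / 1000), by = "gene_id"]
  out <- merge(lens, cnt, by = "gene_id", all.x = TRUE)
  out$pairs[is.na(out$pairs)] <- 0L
  tibble(gene_id = out$gene_id, recruitment = out$pairs / out$kb)
}

#' Flag reads assigned to highly recruiting genes
#'
#' A gene is "high coverage" when its peDNA recruitment reaches the mean
#' plus two standard deviations (population SD) across all genes of the MAG
#' set, provided the recruitment values are not all equal; a read is flagged
#' iff its assigned gene is high. With fewer than 3 genes no flag is set and
#' a warning is raised.
#'
#' @param assignments Tibble from [cog_assign()].
#' @param per_gene_recruitment Tibble (`gene_id`, `recruitment`) from
#'   [gene_recruitment()].
#' @return `assignments` with a logical `high_coverage` column.
#' @export
flag_high_coverage <- function(assignments, per_gene_recruitment) {
  r <- per_gene_recruitment$recruitment
  if (length(r) < 3) {
    warn("fewer than 3 genes: no high-coverage flag set")
    assignments$high_coverage <- FALSE
    return(assignments)
  }
  sd_pop <- sqrt(mean((r - mean(r))^2))
  high <- if (sd_pop > 0) r >= mean(r) + 2 * sd_pop else rep(FALSE, length(r))
  high_genes <- per_gene_recruitment$gene_id[high]
  assignments$high_coverage <-
    !is.na(assignments$cog_name) & assignments$cog_name %in% high_genes
  assignments
}

#' Build a per-category COG profile
#'
#' Per category: `n_tot` (reads assigned to the category), `n_hc`
#' (high-coverage reads among them), `freq = n_hc / n_tot`, plus the raw
#' category share `freq_raw = n_tot / sum(n_tot)` so either frequency
#' reading can be audited.
#'
#' @param assignments Tibble from [flag_high_coverage()] (must carry
#'   `high_coverage`).
#' @param label Mechanism label recorded in the profile.
#' @param categories Category universe (rows are emitted for every category,
#'   zero counts included).
#' @return Tibble: `label`, `category`, `n_tot`, `n_hc`, `freq`, `freq_raw`.
#' @export
cog_profile <- function(assignments, label = "sample",
                        categories = sort(unique(assignments$cog_category))) {
  if (!"high_coverage" %in% names(assignments)) {
    abort("assignments must carry `high_coverage` (see flag_high_coverage)")
  }
  base <- tibble(category = categories)
  agg <- assignments %>%
    group_by(category = .data$cog_category) %>%
    summarise(n_tot = n(), n_hc = sum(.data$high_coverage),
              .groups = "drop")
  out <- base %>%
    left_join(agg, by = "category") %>%
    mutate(n_tot = dplyr::coalesce(.data$n_tot, 0L),
           n_hc = dplyr::coalesce(.data$n_hc, 0L),
           freq = ifelse(.data$n_tot > 0, .data$n_hc / .data$n_tot, 0),
           label = label)
  total <- sum(out$n_tot)
  out$freq_raw <- if (total > 0) out$n_tot / total else 0
  select(out, "label", "category", "n_tot", "n_hc", "freq", "freq_raw")
}

#' Signed fold changes of a mechanism profile against the microbial profile
#'
#' Per category: `fc = freq_label / freq_microbial` when the quotient is at
#' least 1, else the reversed quotient with a negative sign, so no output
#' lies in the open interval (-1, 1). When exactly one of the two
#' frequencies is zero it is replaced by a pseudocount (half the smallest
#' nonzero frequency of the pair of profiles); when both are zero the fold
#' change is missing.
#'
#' @param profile_label Profile tibble from [cog_profile()] for a mechanism
#'   label.
#' @param profile_microbial Profile tibble for the metagenome reads,
#'   processed identically.
#' @param freq_col Which frequency to compare (`"freq"`, the high-coverage
#'   share, or `"freq_raw"`).
#' @return A `pedna_cog_profile` tibble: `label`, `category`, `n_tot`,
#'   `n_hc`, `freq`, `freq_microbial`, `fold_change`.
#' @export
fold_changes <- function(profile_label, profile_microbial,
                         freq_col = "freq") {
  if (!setequal(profile_label$category, profile_microbial$category)) {
    abort("profiles must cover the same category set")
  }
  m <- match(profile_label$category, profile_microbial$category)
  fl <- profile_label[[freq_col]]
  fm <- profile_microbial[[freq_col]][m]
  nz <- c(fl[fl > 0], fm[fm > 0])
  pseudo <- if (length(nz)) min(nz) / 2 else NA_real_
  both_zero <- fl == 0 & fm == 0
  fl2 <- ifelse(fl == 0, pseudo, fl)
  fm2 <- ifelse(fm == 0, pseudo, fm)
  fc <- ifelse(both_zero, NA_real_,
               ifelse(fl2 >= fm2, fl2 / fm2, -(fm2 / fl2)))
  out <- tibble(label = profile_label$label,
                category = profile_label$category,
                n_tot = profile_label$n_tot,
                n_hc = profile_label$n_hc,
                freq = fl, freq_microbial = fm, fold_change = fc)
  class(out) <- c("pedna_cog_profile", class(out))
  out
}

#' Count transposase genes from free-text annotations
#'
#' Applies the transposase regular expression
#' `IS\\d+|Tn\\d+|attTn\\d+|transposase|Transposase` to each annotation
#' string.
#'
#' @param annotations Tibble (`mag_id`, `annotation`) or a character vector.
#' @return Per-MAG counts (`mag_id`, `n_transposase`), or a single count for
#'   a character vector.
#' @export
transposase_scan <- function(annotations) {
  if (is.character(annotations)) {
    return(sum(grepl(TRANSPOSASE_REGEX, annotations, perl = TRUE)))
  }
  annotations %>%
    group_by(.data$mag_id) %>%
    summarise(n_transposase = sum(grepl(TRANSPOSASE_REGEX, .data$annotation,
                                        perl = TRUE)),
              .groups = "drop")
}

#' Share of Mobilome reads on transposase clusters
#'
#' Among reads assigned to COG category X ("Mobilome"), the fraction whose
#' cluster name contains "transposase" (case-insensitive).
#'
#' @param assignments Tibble from [cog_assign()].
#' @return A fraction in `[0, 1]`, or `NA` (with a warning) when no read is
#'   assigned to the Mobilome category.
#' @export
mobilome_transposase_fraction <- function(assignments) {
  mob <- assignments[assignments$cog_category == "X", ]
  if (nrow(mob) == 0) {
    warn("no Mobilome-assigned read")
    return(NA_real_)
  }
  mean(grepl("transposase", mob$cog_name, ignore.case = TRUE))
}
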