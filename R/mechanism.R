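# Attribution of nvpeDNA to source MAGs: read recruitment, windowed coverage
# profiles, provirus activity from depth ratios, GTA cluster detection, and
# the deterministic mechanism decision rule.

#' Remove short MAGs
#'
#' @param mags Sequence tibble (`id`, `seq`).
#' @param min_len Minimum length in bp (inclusive).
#' @return The surviving MAGs, order preserved.
#' @export
filter_mags <- function(mags, min_len = 100000) {
  mags[nchar(mags$seq) >= min_len, ]
}

#' Rank MAGs by peDNA read-pair recruitment
#'
#' Maps pairs against the MAGs (unless a precomputed alignment table is
#' supplied) and returns the `top_k` most recruiting MAGs, ties broken
#' towards the lexicographically smaller id. MAGs recruiting zero pairs are
#' ranked too (count 0) so `top_k` is always honoured when possible.
#'
#' @param reads Read-set tibble.
#' @param mags Sequence tibble (`id`, `seq`).
#' @param top_k Number of MAGs to keep.
#' @param alignments Optional precomputed result of [kmer_map_reads()]
#'   against `mags`.
#' @param min_identity,k Mapping parameters.
#' @return Tibble: `mag_id`, `recruitment_pairs`, `rank`; the alignment
#'   table is attached as attribute `alignments`.
#' @export
recruit_and_rank <- function(reads, mags, top_k = 20, alignments = NULL,
                             min_identity = 0.9, k = 21) {
  if (nrow(mags) == 0) abort("mags must be non-empty")
  aln <- alignments %||% kmer_map_reads(reads, mags[, c("id", "seq")], k = k,
                                        min_identity = min_identity)
  cnt <- count(filter(aln, .data$mapped), .data$target_id,
               name = "recruitment_pairs")
  res <- tibble(mag_id = mags$id) %>%
    left_join(cnt, by = c(mag_id = "target_id")) %>%
    mutate(recruitment_pairs = dplyr::coalesce(.data$recruitment_pairs, 0L)) %>%
    arrange(desc(.data$recruitment_pairs), .data$mag_id) %>%
    mutate(rank = row_number()) %>%
    head(top_k)
  attr(res, "alignments") <- aln
  res
}

#' Windowed coverage profile of a MAG
#'
#' Mean per-window depth computed from the mate intervals of mapped pairs.
#' The background is the 10%-trimmed mean depth over windows that do not
#' intersect a candidate (proviral) region. The full-resolution per-base
#' coverage is kept as attribute `coverage` for region-level statistics.
#'
#' @param alignments Alignment table from [kmer_map_reads()].
#' @param mag_id MAG id to profile.
#' @param mag_len MAG length in bp.
#' @param window_bp Window size (>= 100).
#' @param candidate_regions Optional tibble (`start`, `end`, 0-based
#'   half-open) of regions excluded from the background.
#' @return A `pedna_coverage` tibble: `mag_id`, `window`, `start`, `end`,
#'   `depth`, with attributes `background` and `coverage` (an Rle).
#' @export
coverage_profile <- function(alignments, mag_id, mag_len, window_bp = 1000,
                             candidate_regions = NULL) {
  if (window_bp < 100) abort("window_bp must be >= 100")
  a <- alignments[alignments$mapped & alignments$target_id == mag_id, ]
  ir <- IRanges::IRanges(
    start = c(a$start1[!is.na(a$start1)] + 1L, a$start2[!is.na(a$start2)] + 1L),
    end = c(a$end1[!is.na(a$end1)], a$end2[!is.na(a$end2)]))
  cov <- IRanges::coverage(ir, width = mag_len)
  starts <- seq(1L, mag_len, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, mag_len)
  depth <- IRanges::viewMeans(IRanges::Views(cov, start = starts, end = ends))
  prof <- tibble(mag_id = mag_id, window = seq_along(starts),
                 start = starts - 1L, end = ends, depth = as.numeric(depth))
  in_candidate <- rep(FALSE, nrow(prof))
  if (!is.null(candidate_regions) && nrow(candidate_regions) > 0) {
    for (i in seq_len(nrow(candidate_regions))) {
      in_candidate <- in_candidate |
        (prof$start < candidate_regions$end[i] &
           prof$end > candidate_regions$start[i])
    }
  }
  bg_depths <- prof$depth[!in_candidate]
  background <- if (length(bg_depths) == 0) 0 else mean(bg_depths, trim = 0.1)
  class(prof) <- c("pedna_coverage", class(prof))
  attr(prof, "background") <- background
  attr(prof, "coverage") <- cov
  prof
}

#' Detect candidate proviral regions on a MAG
#'
#' Translated ORFs are searched against the virus hallmark reference;
#' maximal chains of hit ORFs lying within `link_bp` of each other with at
#' least `min_hits` members define candidate regions, padded by `pad_bp` on
#' each side and clipped to the MAG.
#'
#' @param mag One-row sequence tibble (`id`, `seq`).
#' @param hallmark_db Hallmark protein tibble.
#' @param min_hits Minimum hallmark-hit ORFs per region.
#' @param link_bp Maximum gap between hit ORFs within one region.
#' @param pad_bp Padding added to each region side.
#' @param evalue_max,pident_min Hit thresholds.
#' @return Tibble: `mag_id`, `start`, `end` (0-based half-open), `n_hits`.
#' @export
detect_provirus <- function(mag, hallmark_db = load_hallmark_db(),
                            min_hits = 2, link_bp = 15000, pad_bp = 5000,
                            evalue_max = 1e-5, pident_min = 50) {
  if (nrow(hallmark_db) == 0) abort("hallmark_db must be non-empty")
  empty <- tibble(mag_id = character(), start = integer(), end = integer(),
                  n_hits = integer())
  orfs <- find_orfs(mag)
  if (nrow(orfs) == 0) return(empty)
  q <- tibble(id = paste0("orf", seq_len(nrow(orfs))), protein = orfs$protein)
  hits <- sw_search(q, hallmark_db, evalue_max = evalue_max,
                    pident_min = pident_min)
  if (nrow(hits) == 0) return(empty)
  oi <- match(unique(hits$query_id), q$id)
  iv <- orfs[oi, c("start", "end")]
  iv <- arrange(iv, .data$start)
  gap_new <- c(TRUE, iv$start[-1] - head(iv$end, -1) > link_bp)
  grp <- cumsum(gap_new)
  L <- nchar(mag$seq[1])
  out <- iv %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end), n_hits = n(),
              .groups = "drop") %>%
    filter(.data$n_hits >= min_hits) %>%
    mutate(mag_id = mag$id[1],
           start = pmax(.data$start - pad_bp, 0L),
           end = pmin(.data$end + pad_bp, L)) %>%
    select("mag_id", "start", "end", "n_hits")
  out
}

#' Provirus activity from a coverage profile
#'
#' The depth ratio `r` is the full-resolution mean depth over the region
#' divided by the profile background. Status: `active` if `r >= alpha` and
#' the region depth is positive; `absent` if the region depth is at most
#' `epsilon * background` with background at least `min_bg` (a region that
#' recruits no peDNA reads while the rest of the genome does); `inactive`
#' otherwise. A zero background with a zero-depth region yields `inactive`
#' with flag `no_signal`.
#'
#' @param profile A `pedna_coverage` from [coverage_profile()].
#' @param region One-row tibble (`start`, `end`, 0-based half-open) within
#'   the profile extent.
#' @param alpha Minimum depth ratio for `active`.
#' @param epsilon Maximum region/background depth fraction for `absent`.
#' @param min_bg Minimum background depth for an `absent` call.
#' @return One-row tibble: `mag_id`, `start`, `end`, `status`,
#'   `depth_ratio`, `background`, `flag`.
#' @export
provirus_status <- function(profile, region, alpha = 3.0, epsilon = 0.05,
                            min_bg = 1.0) {
  cov <- attr(profile, "coverage")
  bg <- attr(profile, "background")
  L <- length(cov)
  if (region$start[1] < 0 || region$end[1] > L) {
    abort("region outside profile extent")
  }
  v <- IRanges::Views(cov, start = region$start[1] + 1L, end = region$end[1])
  depth <- as.numeric(IRanges::viewMeans(v))
  flag <- NA_character_
  if (bg <= 0 && depth <= 0) {
    status <- "inactive"
    flag <- "no_signal"
    r <- NA_real_
  } else {
    r <- if (bg > 0) depth / bg else Inf
    status <- if (r >= alpha && depth > 0) "active"
    else if (depth <= epsilon * bg && bg >= min_bg) "absent"
    else "inactive"
  }
  tibble(mag_id = profile$mag_id[1], start = region$start[1],
         end = region$end[1], status = status, depth_ratio = r,
         background = bg, flag = flag)
}

#' Detect an RcGTA-like gene cluster on a MAG
#'
#' Translated ORFs are searched against the GTA reference set; the best hit
#' per reference gene is kept (E-value <= `evalue_max`, identity >
#' `pident_min`). The cluster is `functional` when more than `n_min - 1`
#' distinct reference genes are hit and every core gene is present, and
#' `dispersed` when the hit ORFs fall into more than two loci separated by
#' at least `dispersed_gap` bp.
#'
#' @param mag One-row sequence tibble (`id`, `seq`).
#' @param gta_db GTA reference tibble (`id`, `gene`, `core`, `protein`).
#' @param evalue_max,pident_min Hit thresholds.
#' @param n_min Minimum number of distinct GTA genes (functional requires
#'   `n_gta_genes >= n_min`, i.e. more than `n_min - 1`).
#' @param dispersed_gap Minimum gap defining separate loci.
#' @return One-row `pedna_gta` tibble: `mag_id`, `n_gta_genes`,
#'   `core_present`, `core_missing` (comma-separated gene names),
#'   `functional`, `dispersed`; per-gene hits as attribute `hits`.
#' @export
detect_gta <- function(mag, gta_db = load_gta_db(), evalue_max = 1e-5,
                       pident_min = 50, n_min = 11, dispersed_gap = 20000) {
  if (!all(c("gene", "core") %in% names(gta_db))) {
    abort("gta_db must carry `gene` and `core` columns")
  }
  orfs <- find_orfs(mag)
  hits <- if (nrow(orfs) == 0) tibble() else {
    q <- tibble(id = paste0("orf", seq_len(nrow(orfs))), protein = orfs$protein)
    h <- sw_search(q, gta_db, evalue_max = evalue_max, pident_min = pident_min)
    if (nrow(h)) {
      h <- left_join(h, gta_db[, c("id", "gene", "core")],
                     by = c(subject_id = "id"))
      h$orf_start <- orfs$start[match(h$query_id, q$id)]
      h$orf_end <- orfs$end[match(h$query_id, q$id)]
      # best hit per reference gene
      h %>% arrange(desc(.data$score)) %>%
        distinct(.data$gene, .keep_all = TRUE)
    } else tibble()
  }
  core_genes <- gta_db$gene[gta_db$core]
  if (nrow(hits) == 0) {
    out <- tibble(mag_id = mag$id[1], n_gta_genes = 0L,
                  core_present = "", core_missing = paste(core_genes,
                                                          collapse = ","),
                  functional = FALSE, dispersed = FALSE)
  } else {
    present_core <- intersect(core_genes, hits$gene)
    missing_core <- setdiff(core_genes, hits$gene)
    n_loci <- {
      iv <- arrange(hits, .data$orf_start)
      sum(c(TRUE, iv$orf_start[-1] - head(iv$orf_end, -1) >= dispersed_gap))
    }
    out <- tibble(
      mag_id = mag$id[1],
      n_gta_genes = nrow(hits),
      core_present = paste(sort(present_core), collapse = ","),
      core_missing = paste(sort(missing_core), collapse = ","),
      functional = nrow(hits) >= n_min && length(missing_core) == 0,
      dispersed = n_loci > 2)
  }
  attr(out, "hits") <- hits
  class(out) <- c("pedna_gta", class(out))
  out
}

#' Decide the predominant DNA-export mechanism of a MAG
#'
#' Pure decision rule over the provirus and GTA calls: an active provirus
#' without a functional GTA cluster means `transducer`; a functional GTA
#' cluster without an active provirus means `GTA_producer`; neither means
#' `EV_producer`; an active provirus together with a functional GTA cluster
#' is contradictory and yields `unclear`, as does a `no_signal` coverage
#' profile on a MAG that still recruits at least `min_recruit` pairs.
#'
#' @param provirus One-row tibble from [provirus_status()], or `NULL` /
#'   zero rows when no candidate region exists (`none_found`).
#' @param gta One-row tibble from [detect_gta()].
#' @param recruitment_pairs Recruited pair count (used with `no_signal`).
#' @param min_recruit Recruitment above which an uninformative coverage
#'   profile makes the call `unclear` rather than `EV_producer`.
#' @return One-row `pedna_mechanism_call` tibble: `mag_id`, `label`,
#'   `provirus_status`, `depth_ratio`, `n_gta_genes`, `core_missing`,
#'   `gta_functional`, `recruitment_pairs`.
#' @export
decide_mechanism <- function(provirus, gta, recruitment_pairs = NA_integer_,
                             min_recruit = 100) {
  status <- if (is.null(provirus) || nrow(provirus) == 0) "none_found"
  else provirus$status[1]
  flag <- if (is.null(provirus) || nrow(provirus) == 0) NA_character_
  else provirus$flag[1]
  functional <- gta$functional[1]
  label <- if (status == "active" && functional) "unclear"
  else if (status == "active") "transducer"
  else if (functional) "GTA_producer"
  else if (identical(flag, "no_signal") && !is.na(recruitment_pairs) &&
           recruitment_pairs >= min_recruit) "unclear"
  else "EV_producer"
  tibble(mag_id = gta$mag_id[1], label = label,
         provirus_status = status,
         depth_ratio = if (status %in% c("none_found")) NA_real_
         else provirus$depth_ratio[1],
         n_gta_genes = gta$n_gta_genes[1],
         core_missing = gta$core_missing[1],
         gta_functional = functional,
         recruitment_pairs = recruitment_pairs)
}

#' Squared Pearson correlation of peDNA vs metagenome abundance
#'
#' @param pedna_counts,metagenome_counts Paired per-MAG read-pair counts
#'   (same order, length >= 3). Relative abundances are used, so scaling is
#'   irrelevant.
#' @return R-squared, or `NA` (with a warning) when either vector has zero
#'   variance.
#' @export
abundance_correlation <- function(pedna_counts, metagenome_counts) {
  if (length(pedna_counts) != length(metagenome_counts)) {
    abort("count vectors must have equal length")
  }
  if (length(pedna_counts) < 3) abort("need at least 3 paired counts")
  x <- pedna_counts / sum(pedna_counts)
  y <- metagenome_counts / sum(metagenome_counts)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)^2
}

#' End-to-end mechanism attribution
#'
#' Filters MAGs by length, recruits peDNA read pairs, selects the `top_k`
#' most recruiting MAGs and, for each: detects candidate proviral regions,
#' computes the coverage profile, scores provirus activity (the region with
#' the highest depth ratio decides; an `absent` region takes precedence over
#' `inactive` ones), detects a GTA cluster and applies the decision rule.
#'
#' @param mags Sequence tibble (`id`, `seq`).
#' @param reads peDNA read-set tibble.
#' @param hallmark_db,gta_db Reference sets.
#' @param top_k MAGs taken forward after recruitment ranking.
#' @param min_len MAG length floor.
#' @param min_identity Mapping identity threshold.
#' @param window_bp Coverage window.
#' @param alpha,epsilon,min_bg Provirus activity thresholds
#'   (see [provirus_status()]).
#' @param min_recruit See [decide_mechanism()].
#' @return A `pedna_mechanism` tibble with one row per analysed MAG
#'   (columns as in [decide_mechanism()], plus `rank`); the alignment table
#'   is attached as attribute `alignments`, the called regions as attribute
#'   `regions`.
#' @export
call_mechanisms <- function(mags, reads, hallmark_db = load_hallmark_db(),
                            gta_db = load_gta_db(), top_k = 20,
                            min_len = 100000, min_identity = 0.9,
                            window_bp = 1000, alpha = 3.0, epsilon = 0.05,
                            min_bg = 1.0, min_recruit = 100) {
  kept <- filter_mags(mags, min_len)
  if (nrow(kept) == 0) abort("no MAG passes the length filter")
  ranked <- recruit_and_rank(reads, kept, top_k = top_k,
                             min_identity = min_identity)
  aln <- attr(ranked, "alignments")
  rows <- vector("list", nrow(ranked))
  regions_out <- vector("list", nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    id <- ranked$mag_id[i]
    mag <- kept[kept$id == id, ]
    regions <- detect_provirus(mag, hallmark_db)
    prof <- coverage_profile(aln, id, nchar(mag$seq[1]), window_bp,
                             candidate_regions = regions)
    pstat <- NULL
    if (nrow(regions) > 0) {
      calls <- bind_rows(lapply(seq_len(nrow(regions)), function(j) {
        provirus_status(prof, regions[j, ], alpha, epsilon, min_bg)
      }))
      pstat <- if (any(calls$status == "active")) {
        act <- calls[calls$status == "active", ]
        act[which.max(act$depth_ratio), ]
      } else if (any(calls$status == "absent")) {
        calls[calls$status == "absent", ][1, ]
      } else calls[1, ]
    }
    gta <- detect_gta(mag, gta_db)
    rows[[i]] <- decide_mechanism(pstat, gta, ranked$recruitment_pairs[i],
                                  min_recruit) %>%
      mutate(rank = ranked$rank[i])
    regions_out[[i]] <- regions
  }
  out <- bind_rows(rows)
  class(out) <- c("pedna_mechanism", class(out))
  attr(out, "alignments") <- aln
  attr(out, "regions") <- bind_rows(regions_out)
  out
}
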