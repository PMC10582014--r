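# The nvpeDNA/vpeDNA partition: contig length filter, dual viral
# classification, label merging and the non-viral-to-viral read-pair ratio.

#' Remove short contigs
#'
#' @param contigs Sequence tibble (`id`, `seq`).
#' @param min_len Minimum contig length in bp (inclusive).
#' @return The surviving contigs, order preserved.
#' @export
filter_contigs <- function(contigs, min_len = 2000) {
  if (min_len < 0) abort("min_len must be >= 0")
  contigs[nchar(contigs$seq) >= min_len, ]
}

# 4-mer composition profiles (relative frequencies), one row per sequence
tetra_freqs <- function(seqs) {
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                 collapse = "")
  out <- matrix(0, nrow = length(seqs), ncol = length(kmers),
                dimnames = list(NULL, sort(kmers)))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    if (n < 4) next
    km <- substring(s, 1:(n - 3), 4:n)
    tt <- table(km[!grepl("N", km, fixed = TRUE)])
    tt <- tt[names(tt) %in% colnames(out)]
    out[i, names(tt)] <- as.numeric(tt) / sum(tt)
  }
  out
}

#' Classify contigs as viral or non-viral
#'
#' Two builtin classifiers are run and their evidence recorded per contig:
#'
#' * Classifier A (homology): a contig is viral if at least `min_hallmarks`
#'   of its translated ORFs hit the virus hallmark reference
#'   (E-value <= `evalue_max`, identity > `pident_min`).
#' * Classifier B (composition): a declared stand-in for composition-based
#'   prediction — cosine similarity of the contig's tetranucleotide profile
#'   to the hallmark-bearing contigs; viral if the best similarity reaches
#'   `b_threshold`. It is reported but, by default, not used by
#'   [merge_labels()].
#'
#' @param contigs Sequence tibble (`id`, `seq`).
#' @param hallmark_db Hallmark protein tibble (`id`, `protein`).
#' @param min_hallmarks Minimum distinct hallmark-hit ORFs for classifier A.
#' @param evalue_max,pident_min Hit thresholds.
#' @param min_codons ORF length floor passed to [find_orfs()].
#' @param b_threshold Cosine-similarity threshold for classifier B.
#' @return Tibble: `contig_id`, `label_a`, `label_b`, `evidence_a`
#'   (hallmark-hit ORF count), `evidence_b` (composition score in `[0, 1]`).
#' @export
classify_contigs <- function(contigs, hallmark_db = load_hallmark_db(),
                             min_hallmarks = 1, evalue_max = 1e-5,
                             pident_min = 50, min_codons = 50,
                             b_threshold = 0.95) {
  check_seq_tbl(contigs, "contigs")
  if (nrow(hallmark_db) == 0) abort("hallmark_db must be non-empty")
  orfs <- find_orfs(contigs, min_codons = min_codons)
  ev_a <- setNames(integer(nrow(contigs)), contigs$id)
  if (nrow(orfs) > 0) {
    q <- tibble(id = paste0("orf", seq_len(nrow(orfs))),
                protein = orfs$protein, parent = orfs$parent_id)
    hits <- sw_search(q[, c("id", "protein")], hallmark_db,
                      evalue_max = evalue_max, pident_min = pident_min)
    if (nrow(hits) > 0) {
      hit_orfs <- distinct(hits, .data$query_id)
      cnt <- count(left_join(hit_orfs, q, by = c(query_id = "id")),
                   .data$parent)
      ev_a[cnt$parent] <- cnt$n
    }
  }
  label_a <- ifelse(ev_a >= min_hallmarks, "viral", "nonviral")

  # classifier B: tetranucleotide similarity to the hallmark-bearing contigs
  ev_b <- numeric(nrow(contigs))
  train <- which(label_a == "viral")
  if (length(train) > 0) {
    tf <- tetra_freqs(contigs$seq)
    nrm <- sqrt(rowSums(tf^2))
    nrm[nrm == 0] <- 1
    tfn <- tf / nrm
    sims <- tfn %*% t(tfn[train, , drop = FALSE])
    ev_b <- apply(sims, 1, max)
  }
  tibble(contig_id = contigs$id,
         label_a = unname(label_a),
         label_b = unname(ifelse(ev_b >= b_threshold, "viral", "nonviral")),
         evidence_a = unname(as.integer(ev_a)),
         evidence_b = unname(as.numeric(ev_b)))
}

#' Merge the two classifier calls into final contig labels
#'
#' Rules: `a_only` (default — classifier B is a declared stand-in and stays
#' advisory), `b_only`, `union` (viral if either says viral), `intersection`
#' (viral only if both do). An external label table, when supplied, bypasses
#' both classifiers; this is the recommended way to plug in real
#' VirSorter2/DeepVirFinder output.
#'
#' @param labels Output of [classify_contigs()].
#' @param rule Merge rule.
#' @param external Optional tibble (`contig_id`, `label`) covering exactly
#'   the same contigs.
#' @return Tibble: `contig_id`, `label`, `evidence_a`, `evidence_b`,
#'   `source` (`builtin` or `external`).
#' @export
merge_labels <- function(labels,
                         rule = c("a_only", "union", "intersection", "b_only"),
                         external = NULL) {
  rule <- match.arg(rule)
  if (!is.null(external)) {
    if (!setequal(external$contig_id, labels$contig_id)) {
      abort("external labels do not cover the same contigs")
    }
    if (!all(external$label %in% c("viral", "nonviral"))) {
      abort("external labels must be 'viral' or 'nonviral'")
    }
    m <- match(labels$contig_id, external$contig_id)
    return(tibble(contig_id = labels$contig_id,
                  label = external$label[m],
                  evidence_a = labels$evidence_a,
                  evidence_b = labels$evidence_b,
                  source = "external"))
  }
  a <- labels$label_a == "viral"
  b <- labels$label_b == "viral"
  v <- switch(rule,
              a_only = a, b_only = b,
              union = a | b, intersection = a & b)
  tibble(contig_id = labels$contig_id,
         label = ifelse(v, "viral", "nonviral"),
         evidence_a = labels$evidence_a,
         evidence_b = labels$evidence_b,
         source = "builtin")
}

#' Non-viral to viral read-pair ratio
#'
#' Maps read pairs against the labelled contigs and tallies pairs by contig
#' label. `nv_ratio = n_pairs_nonviral / (n_pairs_viral + n_pairs_nonviral)`;
#' unmapped pairs are excluded from the denominator. Pairs whose mates do
#' not agree on a single contig are counted as unmapped.
#'
#' @param reads Read-set tibble.
#' @param contigs Sequence tibble of the labelled contigs.
#' @param labels Tibble (`contig_id`, `label`) from [merge_labels()] or an
#'   external source.
#' @param min_identity,k Mapping parameters (see [kmer_map_reads()]).
#' @param sample_id Label carried into the report.
#' @return A one-row `pedna_split` tibble: `sample_id`, `n_pairs_viral`,
#'   `n_pairs_nonviral`, `n_pairs_unmapped`, `nv_ratio`.
#' @export
nv_ratio <- function(reads, contigs, labels, min_identity = 0.9, k = 21,
                     sample_id = "sample") {
  if (nrow(labels) < 1) abort("need at least one labelled contig")
  missing <- setdiff(contigs$id, labels$contig_id)
  if (length(missing)) {
    abort(paste0("contigs without label: ", paste(head(missing, 3),
                                                  collapse = ", ")))
  }
  aln <- kmer_map_reads(reads, contigs[, c("id", "seq")], k = k,
                        min_identity = min_identity)
  lab <- setNames(labels$label, labels$contig_id)
  hit <- lab[aln$target_id[aln$mapped]]
  n_v <- sum(hit == "viral")
  n_nv <- sum(hit == "nonviral")
  ratio <- if (n_v + n_nv == 0) {
    warn("no mapped pairs: nv_ratio undefined")
    NA_real_
  } else n_nv / (n_v + n_nv)
  out <- tibble(sample_id = sample_id,
                n_pairs_viral = n_v,
                n_pairs_nonviral = n_nv,
                n_pairs_unmapped = nrow(reads) - n_v - n_nv,
                nv_ratio = ratio)
  class(out) <- c("pedna_split", class(out))
  out
}

#' Run the full split stage
#'
#' Length filter, classification, label merging and the read-pair ratio in
#' one call.
#'
#' @inheritParams nv_ratio
#' @inheritParams classify_contigs
#' @inheritParams merge_labels
#' @param min_contig_len Contig length floor.
#' @return A `pedna_split` report with the merged labels attached as
#'   attribute `labels`.
#' @export
split_pedna <- function(reads, contigs, hallmark_db = load_hallmark_db(),
                        min_contig_len = 2000, rule = "a_only",
                        external = NULL, min_identity = 0.9,
                        min_hallmarks = 1, sample_id = "sample") {
  kept <- filter_contigs(contigs, min_contig_len)
  cls <- classify_contigs(kept, hallmark_db, min_hallmarks = min_hallmarks)
  lab <- merge_labels(cls, rule = rule, external = external)
  rep <- nv_ratio(reads, kept, lab, min_identity = min_identity,
                  sample_id = sample_id)
  attr(rep, "labels") <- lab
  rep
}
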