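# SSU rRNA contamination screen (ViromeQC-style stand-in): the percentage of
# read pairs with at least one mate aligning to a 16S/18S reference.

#' SSU rRNA alignment rate of a read set
#'
#' A pair counts as SSU-derived if either mate places on any SSU reference at
#' `min_identity` or better over at least `min_len` aligned bases
#' (clipped placements at reference boundaries are allowed). The report
#' carries the published mean alignment rate of microbial metagenomes
#' (0.078%) as context only: following the source analysis, a high or low
#' rate neither proves nor disproves contamination of a peDNA sample, since
#' EVs and GTAs package SSU genes too, so no pass/fail verdict is issued.
#'
#' @param reads Read-set tibble (`read_id`, `seq1`, `seq2`).
#' @param ssu_refs Sequence tibble of SSU references; defaults to the bundled
#'   synthetic reference.
#' @param min_identity Minimum aligned identity.
#' @param min_len Minimum aligned bases for a mate to count.
#' @param sample_id Label carried into the report.
#' @return A one-row `pedna_ssu` tibble: `sample_id`, `n_pairs_total`,
#'   `n_pairs_ssu`, `rate_percent`, `ref_metagenome_mean_percent`.
#' @export
ssu_rate <- function(reads, ssu_refs = load_ssu_refs(), min_identity = 0.8,
                     min_len = 50, sample_id = "sample") {
  if (nrow(reads) == 0) abort("empty read set")
  if (nrow(ssu_refs) == 0) abort("ssu_refs must be non-empty")
  refs <- distinct(ssu_refs, .data$seq, .keep_all = TRUE)
  aln <- kmer_map_reads(reads, refs[, c("id", "seq")],
                        min_identity = min_identity, min_overlap = min_len,
                        require_both = FALSE)
  n_ssu <- sum(aln$mapped)
  out <- tibble(
    sample_id = sample_id,
    n_pairs_total = nrow(reads),
    n_pairs_ssu = n_ssu,
    rate_percent = 100 * n_ssu / nrow(reads),
    ref_metagenome_mean_percent = 0.078)
  class(out) <- c("pedna_ssu", class(out))
  out
}
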