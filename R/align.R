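# Protein local alignment with E-values: a diamond-blastp-style stand-in.
# The optimal local alignment itself (Smith-Waterman, BLOSUM62, affine gaps)
# is delegated to Biostrings::pairwiseAlignment; the Karlin-Altschul E-value
# layer and the seeded batch search live here.

# BLOSUM62 with ambiguity codes neutralised: any residue outside the 20
# standard amino acids scores 0 against everything (wildcard).
blosum62_wild <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b <- e$BLOSUM62
      wild <- setdiff(rownames(b), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
      b[wild, ] <- 0L
      b[, wild] <- 0L
      m <<- b
    }
    m
  }
})

AA_STANDARD <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

sanitize_protein <- function(x) {
  bad <- grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), x)
  if (any(bad)) {
    inform("non-standard residue(s) treated as score-0 wildcard 'X'")
    x[bad] <- gsub(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), "X", x[bad])
  }
  x
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the gapped BLOSUM62 defaults
#' `lambda = 0.267`, `K = 0.041`.
#'
#' @param score Raw alignment score(s).
#' @param m,n Search-space sizes (query and subject lengths).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Numeric vector of expectation values.
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Optimal local protein alignment with E-value
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gap penalties
#' (open 11, extend 1, BLAST convention: a gap of length L costs
#' `open + L * extend`). Residues outside the 20 standard amino acids are
#' treated as score-0 wildcards. Identity and coverage are computed from the
#' optimal traceback; the E-value uses the Karlin-Altschul closed form.
#'
#' @param query,subject Protein sequences (single strings).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @param m,n Search-space sizes; default to the sequence lengths.
#' @param query_id,subject_id Optional ids carried into the result.
#' @return One-row tibble: `query_id`, `subject_id`, `score`, `pident`
#'   (percent identity over aligned columns), `qcov`, `scov` (percent of
#'   query/subject covered by the aligned region), `evalue`.
#' @export
sw_align <- function(query, subject, gap_open = 11, gap_extend = 1,
                     lambda = 0.267, K = 0.041, m = NULL, n = NULL,
                     query_id = "query", subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject)) abort("empty sequence")
  m <- m %||% nchar(query)
  n <- n %||% nchar(subject)
  q <- sanitize_protein(query)
  s <- sanitize_protein(subject)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = blosum62_wild(),
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- BiocGenerics::score(aln)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  tibble(
    query_id = query_id, subject_id = subject_id, score = score,
    pident = Biostrings::pid(aln, type = "PID1"),
    qcov = 100 * (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1) / nchar(q),
    scov = 100 * (BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1) / nchar(s),
    evalue = karlin_evalue(score, m, n, lambda, K))
}

# shared-kmer prefilter: candidate (query, subject) pairs sharing at least
# `min_shared` distinct peptide k-mers. Mimics the seeding step of fast
# protein search tools so that full DP runs only on plausible homologs.
kmer_prefilter <- function(queries, subjects, k = 4, min_shared = 2) {
  pep_kmers <- function(x) {
    n <- nchar(x)
    if (n < k) return(character())
    unique(substring(x, 1:(n - k + 1), k:n))
  }
  subj_tab <- data.table::rbindlist(lapply(seq_along(subjects), function(j) {
    data.table::data.table(kmer = pep_kmers(subjects[j]), sj = j)
  }))
  if (nrow(subj_tab) == 0) return(tibble(qi = integer(), sj = integer()))
  qry_tab <- data.table::rbindlist(lapply(seq_along(queries), function(i) {
    data.table::data.table(kmer = pep_kmers(queries[i]), qi = i)
  }))
  if (nrow(qry_tab) == 0) return(tibble(qi = integer(), sj = integer()))
  hits <- merge(qry_tab, subj_tab, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0) return(tibble(qi = integer(), sj = integer()))
  cnt <- hits[, list(nshared = .N), by = c("qi", "sj")]
  as_tibble(cnt[cnt$nshared >= min_shared, c("qi", "sj")])
}

#' Batch protein search with seed prefilter
#'
#' Searches every query against every database entry, running the full local
#' alignment only for pairs passing a shared-peptide-k-mer seed filter, and
#' keeps hits meeting the E-value/identity thresholds.
#'
#' @param queries Tibble with `id` and `protein` columns (e.g. ORFs from
#'   [find_orfs()] renamed, or fragments from [read_orf()]).
#' @param db Tibble with `id` and `protein` columns (a reference set).
#' @param evalue_max,pident_min Hit acceptance thresholds.
#' @param seed_k,seed_min_shared Seed filter: peptide k-mer size and minimum
#'   number of shared distinct k-mers to trigger a full alignment.
#' @inheritParams sw_align
#' @return Tibble of hits: `query_id`, `subject_id`, `score`, `pident`,
#'   `qcov`, `scov`, `evalue`.
#' @export
sw_search <- function(queries, db, evalue_max = 1e-5, pident_min = 50,
                      gap_open = 11, gap_extend = 1,
                      lambda = 0.267, K = 0.041,
                      seed_k = 4, seed_min_shared = 2) {
  empty <- tibble(query_id = character(), subject_id = character(),
                  score = numeric(), pident = numeric(), qcov = numeric(),
                  scov = numeric(), evalue = numeric())
  if (nrow(queries) == 0 || nrow(db) == 0) return(empty)
  qs <- sanitize_protein(queries$protein)
  ss <- sanitize_protein(db$protein)
  cand <- kmer_prefilter(qs, ss, k = seed_k, min_shared = seed_min_shared)
  if (nrow(cand) == 0) return(empty)
  out <- vector("list", length(unique(cand$sj)))
  ii <- 0L
  for (j in unique(cand$sj)) {
    qi <- cand$qi[cand$sj == j]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(qs[qi]), Biostrings::AAString(ss[j]),
      type = "local", substitutionMatrix = blosum62_wild(),
      gapOpening = gap_open, gapExtension = gap_extend)
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    score <- BiocGenerics::score(aln)
    ii <- ii + 1L
    out[[ii]] <- tibble(
      query_id = queries$id[qi], subject_id = db$id[j], score = score,
      pident = Biostrings::pid(aln, type = "PID1"),
      qcov = 100 * (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1) /
        nchar(qs[qi]),
      scov = 100 * (BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1) /
        nchar(ss[j]),
      evalue = karlin_evalue(score, nchar(qs[qi]), nchar(ss[j]), lambda, K))
  }
  hits <- bind_rows(out)
  filter(hits, .data$evalue <= evalue_max, .data$pident > pident_min)
}
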