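# ORF finding and translation. Stand-in for prodigal-style gene calling at
# the level the downstream homology searches need: maximal start-to-stop
# frames on both strands, 0-based half-open forward-strand coordinates.

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate DNA to protein (standard genetic code)
#'
#' Length must be a multiple of 3. A trailing stop codon is dropped; internal
#' stops are reported as `*`. Codons containing `N` translate to `X`.
#'
#' @param dna Character vector of DNA sequences.
#' @return Character vector of protein sequences.
#' @export
#' @examples
#' translate_dna("ATGTTTAAA")  # "MFK"
translate_dna <- function(dna) {
  if (length(dna) == 0) return(character())
  if (any(nchar(dna) %% 3 != 0)) abort("sequence length not a multiple of 3")
  gc <- genetic_code()
  vapply(toupper(dna), function(s) {
    if (nchar(s) == 0) return("")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    n <- length(aa)
    if (aa[n] == "*") aa <- aa[-n]
    paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# ORFs in a single oriented sequence, one strand's three frames.
# Returns 1-based inclusive [a, b] on the oriented sequence, including the
# stop codon, plus the first-start position per stop-delimited segment.
orfs_one_strand <- function(s, min_codons, starts) {
  L <- nchar(s)
  res <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3
    if (n_cod < min_codons + 1) next
    p <- f + seq(0, (n_cod - 1) * 3, by = 3) + 1L
    codons <- substring(s, p, p + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% starts
    if (!any(is_stop) || !any(is_start)) next
    seg <- cumsum(c(0L, head(is_stop, -1L)))  # segment index per codon
    stop_idx <- which(is_stop)
    # first start codon within each segment
    start_idx <- which(is_start)
    if (length(start_idx) == 0) next
    first_start <- tapply(start_idx, seg[start_idx], min)
    seg_of_stop <- seg[stop_idx]
    m <- match(as.character(seg_of_stop), names(first_start))
    ok <- !is.na(m)
    if (!any(ok)) next
    a_cod <- unname(first_start[m[ok]])
    b_cod <- stop_idx[ok]
    n_codons <- b_cod - a_cod          # codons excluding the stop
    keep <- n_codons >= min_codons
    if (!any(keep)) next
    res[[length(res) + 1L]] <- tibble(
      a = p[a_cod[keep]], b = p[b_cod[keep]] + 2L)
  }
  if (length(res) == 0) tibble(a = integer(), b = integer()) else bind_rows(res)
}

#' Find open reading frames
#'
#' Scans all six frames of each sequence for maximal start-to-stop ORFs: the
#' first start codon after the preceding stop, through the next in-frame stop
#' (included in the interval). Coordinates are 0-based, half-open, anchored on
#' the forward strand regardless of ORF strand.
#'
#' @param seqs A sequence tibble (`id`, `seq`), e.g. from [read_fasta()].
#' @param min_codons Minimum ORF length in codons, stop excluded (>= 10).
#' @param starts Permitted start codons.
#' @return Tibble: `parent_id`, `start`, `end`, `strand`, `protein`. The
#'   protein always begins with `M` (alternative starts are translated as
#'   initiator methionine) and excludes the stop.
#' @export
find_orfs <- function(seqs, min_codons = 50,
                      starts = c("ATG", "GTG", "TTG")) {
  check_seq_tbl(seqs, "seqs")
  if (min_codons < 10) abort("min_codons must be >= 10")
  out <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$seq[i]
    L <- nchar(s)
    fwd <- orfs_one_strand(s, min_codons, starts)
    rc <- revcomp(s)
    rev <- orfs_one_strand(rc, min_codons, starts)
    pieces <- list()
    if (nrow(fwd)) {
      pieces$f <- tibble(parent_id = seqs$id[i],
                         start = fwd$a - 1L, end = fwd$b, strand = "+",
                         ori_seq = substring(s, fwd$a, fwd$b))
    }
    if (nrow(rev)) {
      pieces$r <- tibble(parent_id = seqs$id[i],
                         start = L - rev$b, end = L - rev$a + 1L, strand = "-",
                         ori_seq = substring(rc, rev$a, rev$b))
    }
    if (length(pieces) == 0) next
    o <- bind_rows(pieces)
    prot <- translate_dna(o$ori_seq)
    # initiator codon reads as M whatever the start codon was
    substr(prot, 1L, 1L) <- "M"
    o$protein <- prot
    o$ori_seq <- NULL
    out[[i]] <- o
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(parent_id = character(), start = integer(), end = integer(),
                  strand = character(), protein = character()))
  }
  arrange(res, .data$parent_id, .data$start, .data$strand)
}

#' Predict partial protein fragments on short reads
#'
#' FragGeneScan-style stand-in for read-level gene calling: for each mate the
#' longest stop-free codon run over all six frames is reported, provided it
#' reaches `min_codons`. Reads shorter than 60 nt or with no qualifying frame
#' are skipped.
#'
#' @param reads Read-set tibble (`read_id`, `seq1`, `seq2`) or a tibble with
#'   `read_id`, `seq` for single-end input.
#' @param min_codons Minimum fragment length in codons.
#' @return Tibble: `read_id`, `mate`, `protein`.
#' @export
read_orf <- function(reads, min_codons = 20) {
  if (all(c("seq1", "seq2") %in% names(reads))) {
    long <- bind_rows(
      tibble(read_id = reads$read_id, mate = 1L, seq = reads$seq1),
      tibble(read_id = reads$read_id, mate = 2L, seq = reads$seq2))
  } else {
    long <- tibble(read_id = reads$read_id, mate = 1L, seq = reads$seq)
  }
  long <- filter(long, nchar(.data$seq) >= 60)
  if (nrow(long) == 0) {
    return(tibble(read_id = character(), mate = integer(), protein = character()))
  }
  frag <- vapply(long$seq, best_stop_free_fragment, "", min_codons = min_codons,
                 USE.NAMES = FALSE)
  out <- long[frag != "", c("read_id", "mate")]
  out$protein <- frag[frag != ""]
  out
}

# longest stop-free codon run across six frames of a read; "" if < min_codons
best_stop_free_fragment <- function(s, min_codons) {
  best <- ""
  for (ori in c(s, revcomp(s))) {
    L <- nchar(ori)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < min_codons) next
      p <- f + seq(0, (n_cod - 1) * 3, by = 3) + 1L
      codons <- substring(ori, p, p + 2L)
      is_stop <- codons %in% STOP_CODONS
      r <- rle(!is_stop)
      if (!any(r$values)) next
      lens <- r$lengths[r$values]
      if (max(lens) < max(min_codons, nchar(best) + 1)) next
      ends <- cumsum(r$lengths)
      starts_i <- ends - r$lengths + 1L
      k <- which(r$values)[which.max(lens)]
      run <- paste(codons[starts_i[k]:ends[k]], collapse = "")
      prot <- translate_dna(run)
      if (nchar(prot) > nchar(best)) best <- prot
    }
  }
  if (nchar(best) >= min_codons) best else ""
}
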