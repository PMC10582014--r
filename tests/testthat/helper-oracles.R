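# Independent oracles used by the tests. These deliberately re-derive each
# quantity with a different algorithm (full-matrix DP, positional scans,
# direct counting) and never call the implementation paths they check.

# --- full-matrix affine-gap local alignment (quadratic space DP) -----------
blosum62_ref <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

oracle_sw_score <- function(q, s, open = 11, ext = 1) {
  B <- blosum62_ref()
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa)
  m <- length(sa)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + B[qa[i - 1], sa[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- independent codon table (typed out, not derived from Biostrings) ------
oracle_codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  aa <- unname(oracle_codon_table[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# --- positional 6-frame ORF scan -------------------------------------------
oracle_orfs <- function(s, min_codons = 50, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    o <- if (strand == "+") s else oracle_revcomp(s)
    L <- nchar(o)
    for (f in 0:2) {
      i <- f + 1L
      open_start <- NA_integer_
      while (i + 2L <= L) {
        cod <- substr(o, i, i + 2L)
        if (is.na(open_start) && cod %in% starts) open_start <- i
        if (cod %in% stops) {
          if (!is.na(open_start) && (i - open_start) / 3 >= min_codons) {
            a <- open_start
            b <- i + 2L
            rows[[length(rows) + 1L]] <- if (strand == "+") {
              data.frame(start = a - 1L, end = b, strand = "+")
            } else {
              data.frame(start = L - b, end = L - a + 1L, strand = "-")
            }
          }
          open_start <- NA_integer_
        }
        i <- i + 3L
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# longest stop-free codon run over six frames, via translated-* scan
oracle_read_fragment <- function(s, min_codons = 20) {
  best <- ""
  for (o in c(s, oracle_revcomp(s))) {
    for (f in 0:2) {
      n_cod <- (nchar(o) - f) %/% 3
      if (n_cod < 1) next
      prot <- oracle_translate(substr(o, f + 1, f + n_cod * 3))
      runs <- regmatches(prot, gregexpr("[^*]+", prot))[[1]]
      for (r in runs) if (nchar(r) > nchar(best)) best <- r
    }
  }
  if (nchar(best) >= min_codons) best else ""
}

# --- misc ------------------------------------------------------------------
random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# per-genome feature table of a community, flattened
community_features <- function(com) {
  purrr::map2_dfr(com$genome_id, com$features,
                  ~ dplyr::bind_cols(tibble::tibble(genome = .x), .y))
}
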