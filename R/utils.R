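# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Mismatch counts between equal-length string pairs. N on either side counts
# as a mismatch. Vectorised by grouping pairs of equal width and comparing
# raw bytes in bulk.
hamming_mismatches <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) return(integer())
  nx <- nchar(x)
  if (any(nx != nchar(y))) abort("hamming_mismatches: length mismatch within a pair")
  out <- integer(length(x))
  n_raw <- charToRaw("N")
  for (L in unique(nx)) {
    i <- which(nx == L)
    if (L == 0) { out[i] <- 0L; next }
    rx <- charToRaw(paste(x[i], collapse = ""))
    ry <- charToRaw(paste(y[i], collapse = ""))
    bad <- (rx != ry) | rx == n_raw | ry == n_raw
    out[i] <- as.integer(colSums(matrix(bad, nrow = L)))
  }
  out
}

# Substitution errors at a fixed per-base rate, seeded by the caller's RNG.
add_substitutions <- function(seqs, err_rate) {
  if (err_rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), err_rate)
  hit <- which(n_err > 0)
  if (length(hit) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs[hit], "", fixed = TRUE)
  for (j in seq_along(hit)) {
    v <- chars[[j]]
    pos <- sample.int(length(v), n_err[hit[j]])
    # draw a base different from the current one
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1), "")
    chars[[j]] <- v
  }
  seqs[hit] <- vapply(chars, paste, "", collapse = "")
  seqs
}

# Validate a sequence table (id, seq) minimally.
check_seq_tbl <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (anyDuplicated(x$id)) {
    abort(sprintf("duplicate sequence id(s) in `%s`: %s", arg,
                  paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  invisible(x)
}
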