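# Seed-and-vote read-pair mapper: a desk-scale stand-in for bbmap whose
# contract (single best target per pair, identity threshold, both mates on
# the same target) is all the downstream statistics need.
#
# Design: 2-bit k-mer codes (exact in doubles for k <= 26), a data.table join
# between read seeds and the target index, diagonal voting (reads are
# substitution-only, so a true placement concentrates its seed hits on one
# diagonal), then ungapped verification by vectorised byte comparison.
# Ambiguous bases (N) never seed and count as mismatches.

# numeric 2-bit codes of all k-mers of `s`; NA where the window contains a
# non-ACGT character
kmer_codes <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(numeric())
  v <- utf8ToInt(s)
  b <- rep(NA_real_, length(v))
  b[v == 65L] <- 0; b[v == 67L] <- 1; b[v == 71L] <- 2; b[v == 84L] <- 3
  n <- L - k + 1L
  code <- numeric(n)
  for (j in 0:(k - 1L)) code <- code * 4 + b[(1L + j):(n + j)]
  code  # NA propagates from any N in the window
}

#' Map read pairs to targets by k-mer seeding and voting
#'
#' Each mate is seeded with k-mers at a fixed stride in both orientations;
#' seed matches against the target index vote on (target, strand, diagonal),
#' the best diagonal defines an ungapped placement, and the placement is
#' verified by direct base comparison. A pair is reported mapped only if both
#' mates place on the same target (`require_both = TRUE`, the default) and
#' the pooled identity over both mates reaches `min_identity`. With
#' `require_both = FALSE` a single mate placing at `min_identity` over at
#' least `min_overlap` bases suffices (used by the SSU screen, where targets
#' are shorter than an insert).
#'
#' Ties between equally supported targets are broken towards the
#' lexicographically smaller target id; the output is deterministic in row
#' order for identical inputs.
#'
#' @param reads Read-set tibble: `read_id`, `seq1`, `seq2`.
#' @param targets Sequence tibble: `id`, `seq`.
#' @param k Seed length (odd, 15-31).
#' @param min_identity Minimum fraction of matching bases.
#' @param stride Distance between seed start positions within a mate.
#' @param min_overlap Minimum aligned bases per mate; defaults to the full
#'   mate length (placements running off a target end are discarded).
#'   Set lower to allow clipped placements at target boundaries.
#' @param require_both Must both mates place on the same target?
#' @param max_seed_occ Seeds occurring more often than this in the index are
#'   skipped as repeats.
#' @return A tibble with one row per pair: `read_id`, `target_id`, `start1`,
#'   `end1`, `start2`, `end2` (0-based half-open mate intervals on the
#'   target; NA when the mate did not place), `matches`, `bases`, `identity`,
#'   `mapped`.
#' @export
kmer_map_reads <- function(reads, targets, k = 21, min_identity = 0.9,
                           stride = 12, min_overlap = NULL,
                           require_both = TRUE, max_seed_occ = 64) {
  if (k %% 2 == 0 || k < 15 || k > 31) abort("k must be odd and in [15, 31]")
  unmapped_tbl <- function() tibble(
    read_id = reads$read_id, target_id = NA_character_,
    start1 = NA_integer_, end1 = NA_integer_,
    start2 = NA_integer_, end2 = NA_integer_,
    matches = 0L, bases = 0L, identity = NA_real_, mapped = FALSE)
  if (nrow(reads) == 0) return(unmapped_tbl())
  check_seq_tbl(targets, "targets")
  if (nrow(targets) == 0) {
    warn("empty target set: all pairs unmapped")
    return(unmapped_tbl())
  }
  targets <- arrange(targets, .data$id)  # tid order = lexicographic id order
  tseq <- targets$seq
  tlen <- nchar(tseq)

  idx <- data.table::rbindlist(lapply(seq_along(tseq), function(j) {
    code <- kmer_codes(tseq[j], k)
    keep <- which(!is.na(code))
    data.table::data.table(code = code[keep], tid = j, tpos = keep)
  }))
  if (nrow(idx) == 0) {
    warn("no indexable k-mers in targets: all pairs unmapped")
    return(unmapped_tbl())
  }
  occ <- idx[, list(nocc = .N), by = "code"]
  idx <- idx[!idx$code %in% occ$code[occ$nocc > max_seed_occ], ]
  data.table::setkeyv(idx, "code")

  # mate table: one row per (pair, mate, orientation) with oriented sequence
  mates <- data.table::data.table(
    rid = rep(seq_len(nrow(reads)), 2L),
    mate = rep(1:2, each = nrow(reads)),
    seq = c(reads$seq1, reads$seq2))
  oriented <- data.table::rbindlist(list(
    data.table::data.table(mates, ori = "f"),
    data.table::data.table(mates[, c("rid", "mate")], seq = revcomp(mates$seq),
                           ori = "r")))
  oriented$mlen <- nchar(oriented$seq)

  # seed extraction, vectorised: all oriented mates joined by 'N' (windows
  # crossing a separator encode as NA and drop out)
  ok_len <- oriented$mlen >= k
  seeds <- if (!any(ok_len)) NULL else {
    om <- oriented[ok_len, ]
    big <- paste(om$seq, collapse = "N")
    codes <- kmer_codes(big, k)
    off <- cumsum(c(0L, head(om$mlen + 1L, -1L)))  # 0-based mate offsets
    n_main <- (om$mlen - k) %/% stride + 1L
    local_pos <- sequence(n_main, from = 1L, by = stride)
    mi_rep <- rep(which(ok_len), n_main)
    off_rep <- rep(off, n_main)
    # add the final window where the stride did not land on it
    tail_needed <- (om$mlen - k) %% stride != 0L
    if (any(tail_needed)) {
      local_pos <- c(local_pos, om$mlen[tail_needed] - k + 1L)
      mi_rep <- c(mi_rep, which(ok_len)[tail_needed])
      off_rep <- c(off_rep, off[tail_needed])
    }
    code <- codes[off_rep + local_pos]
    keep <- !is.na(code)
    if (!any(keep)) NULL else data.table::data.table(
      code = code[keep], mi = mi_rep[keep], roff = local_pos[keep])
  }
  if (is.null(seeds)) return(unmapped_tbl())

  hits <- idx[seeds, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(unmapped_tbl())
  hits$diag <- hits$tpos - hits$roff + 1L   # 1-based placement of mate start
  votes <- hits[, list(n_votes = .N), by = c("mi", "tid", "diag")]
  data.table::setorderv(votes, c("mi", "n_votes", "tid", "diag"),
                        order = c(1L, -1L, 1L, 1L))
  keep_first <- !duplicated(votes$mi)
  best <- votes[keep_first, ]

  # verification: clip placement to the target, compare bytes
  mi <- best$mi
  place <- data.table::data.table(
    rid = oriented$rid[mi], mate = oriented$mate[mi], ori = oriented$ori[mi],
    tid = best$tid, diag = best$diag, mlen = oriented$mlen[mi],
    oseq = oriented$seq[mi])
  place$tstart <- pmax(place$diag, 1L)
  place$tend <- pmin(place$diag + place$mlen - 1L, tlen[place$tid])
  place$overlap <- place$tend - place$tstart + 1L
  place <- place[place$overlap > 0L, ]
  qs <- place$tstart - place$diag + 1L
  window <- substring(tseq[place$tid], place$tstart, place$tend)
  rpart <- substring(place$oseq, qs, qs + place$overlap - 1L)
  place$mm <- hamming_mismatches(rpart, window)
  place$matches <- place$overlap - place$mm

  # best orientation per (pair, mate): more matches wins, then f before r
  data.table::setorderv(place, c("rid", "mate", "matches", "ori"),
                        order = c(1L, 1L, -1L, 1L))
  place <- place[!duplicated(place[, c("rid", "mate")]), ]

  min_ov <- min_overlap  # NULL means: full mate length required
  full_required <- is.null(min_ov)
  if (full_required) {
    place <- place[place$overlap == place$mlen, ]
  } else {
    place <- place[place$overlap >= min_ov, ]
  }

  m1 <- place[place$mate == 1L, ]
  m2 <- place[place$mate == 2L, ]
  res <- merge(data.table::data.table(rid = seq_len(nrow(reads))),
               m1[, c("rid", "tid", "tstart", "tend", "matches", "overlap")],
               by = "rid", all.x = TRUE)
  data.table::setnames(res, c("tid", "tstart", "tend", "matches", "overlap"),
                       c("tid1", "s1", "e1", "match1", "ov1"))
  res <- merge(res, m2[, c("rid", "tid", "tstart", "tend", "matches", "overlap")],
               by = "rid", all.x = TRUE)
  data.table::setnames(res, c("tid", "tstart", "tend", "matches", "overlap"),
                       c("tid2", "s2", "e2", "match2", "ov2"))

  same <- !is.na(res$tid1) & !is.na(res$tid2) & res$tid1 == res$tid2
  if (require_both) {
    ok <- same
    matches <- ifelse(ok, res$match1 + res$match2, 0L)
    bases <- ifelse(ok, res$ov1 + res$ov2, 0L)
    tid <- ifelse(ok, res$tid1, NA_integer_)
  } else {
    id1 <- res$match1 / res$ov1
    id2 <- res$match2 / res$ov2
    use1 <- !is.na(res$tid1) & (is.na(res$tid2) | same |
                                  (!same & !is.na(id1) &
                                     (is.na(id2) | id1 >= id2)))
    use2 <- !is.na(res$tid2) & !use1
    both <- same
    tid <- ifelse(use1, res$tid1, ifelse(use2, res$tid2, NA_integer_))
    matches <- ifelse(both, res$match1 + res$match2,
                      ifelse(use1, res$match1, ifelse(use2, res$match2, 0L)))
    bases <- ifelse(both, res$ov1 + res$ov2,
                    ifelse(use1, res$ov1, ifelse(use2, res$ov2, 0L)))
    ok <- use1 | use2
  }
  identity <- ifelse(bases > 0L, matches / bases, NA_real_)
  ok <- ok & !is.na(identity) & identity >= min_identity

  keep1 <- ok & !is.na(res$tid1) & (!require_both | TRUE) & res$tid1 == tid
  keep2 <- ok & !is.na(res$tid2) & res$tid2 == tid
  out <- tibble(
    read_id = reads$read_id[res$rid],
    target_id = ifelse(ok, targets$id[tid], NA_character_),
    start1 = ifelse(keep1 & !is.na(res$s1), res$s1 - 1L, NA_integer_),
    end1 = ifelse(keep1 & !is.na(res$e1), res$e1, NA_integer_),
    start2 = ifelse(keep2 & !is.na(res$s2), res$s2 - 1L, NA_integer_),
    end2 = ifelse(keep2 & !is.na(res$e2), res$e2, NA_integer_),
    matches = ifelse(ok, as.integer(matches), 0L),
    bases = ifelse(ok, as.integer(bases), 0L),
    identity = ifelse(ok, identity, NA_real_),
    mapped = ok)
  out[order(match(out$read_id, reads$read_id)), ]
}
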