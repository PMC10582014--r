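# Synthetic marine community generator: genomes with planted,
# coordinate-anchored features (SSU rRNA, COG-labelled genes, transposases,
# RcGTA-like clusters, integrated proviruses with virus hallmark genes),
# peDNA read sets drawn under explicit carrier models, and per-read truth
# tables. Everything is deterministic under a fixed seed.

CARRIERS <- c("virion", "transduction_general", "transduction_specialized",
              "gta_particle", "ev", "free_dna", "cell")

#' Carrier mixture for peDNA sampling
#'
#' Non-negative weights over the seven carrier models, normalised to sum 1.
#' `free_dna` and `cell` default to 0: after in-silico size filtration and
#' DNase treatment those carriers are removed unless contamination is
#' explicitly requested.
#'
#' @param virion,transduction_general,transduction_specialized,gta_particle,ev,free_dna,cell
#'   Carrier weights.
#' @return Named numeric vector of class `pedna_mix`, summing to 1.
#' @export
#' @examples
#' carrier_mix(virion = 0.6, ev = 0.4)
carrier_mix <- function(virion = 0, transduction_general = 0,
                        transduction_specialized = 0, gta_particle = 0,
                        ev = 0, free_dna = 0, cell = 0) {
  w <- c(virion = virion, transduction_general = transduction_general,
         transduction_specialized = transduction_specialized,
         gta_particle = gta_particle, ev = ev, free_dna = free_dna,
         cell = cell)
  if (any(w < 0)) abort("carrier weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) abort("at least one carrier weight must be positive")
  w <- w / tot
  structure(w, class = c("pedna_mix", "numeric"))
}

#' @rdname carrier_mix
#' @details `default_pedna_mix()` is the default study condition for
#'   mixed-community scenarios: EV cargo dominating the non-viral fraction,
#'   a substantial virion fraction, GTA particles, and a minor transduction
#'   component split between generalized and specialized packaging.
#' @export
default_pedna_mix <- function() {
  carrier_mix(virion = 0.35, ev = 0.30, gta_particle = 0.20,
              transduction_general = 0.10, transduction_specialized = 0.05)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# reverse codon table (amino acid -> codons), stops excluded
synonymous_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- genetic_code()
      tab <<- split(names(gc), gc)
      tab[["*"]] <- NULL
    }
    tab
  }
})

#' Back-translate a protein with uniform synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' set (seeded by the caller's RNG state); a `TAA` stop is appended. Used by
#' the community generator to plant reference proteins as genes.
#'
#' @param protein Protein sequence (single string, standard residues).
#' @return DNA string of length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein) {
  syn <- synonymous_codons()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    cc <- syn[[a]]
    if (is.null(cc)) abort(paste0("cannot back-translate residue: ", a))
    if (length(cc) == 1) cc else sample(cc, 1)
  }, "", USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

empty_features <- function() {
  tibble(kind = character(), start = integer(), end = integer(),
         strand = character(), gene = character(), core = logical(),
         cluster = character(), category = character(), name = character())
}

feature_row <- function(kind, start, end, strand = "+", gene = NA_character_,
                        core = NA, cluster = NA_character_,
                        category = NA_character_, name = NA_character_) {
  tibble(kind = kind, start = as.integer(start), end = as.integer(end),
         strand = strand, gene = gene, core = core, cluster = cluster,
         category = category, name = name)
}

# assemble blocks (list of list(seq, features)) with spacers into one genome;
# features inside blocks carry block-local 0-based half-open coordinates
assemble_genome <- function(blocks, target_len, min_spacer = 100) {
  flen <- vapply(blocks, function(b) nchar(b$seq), 0)
  nb <- length(blocks)
  spacer_total <- target_len - sum(flen)
  if (spacer_total < (nb + 1) * min_spacer) {
    abort("infeasible genome layout: features exceed target length")
  }
  # random composition of the spacer budget
  cuts <- sort(runif(nb))
  prop <- diff(c(0, cuts, 1))
  extra <- spacer_total - (nb + 1) * min_spacer
  sp <- min_spacer + floor(prop * extra)
  sp[1] <- sp[1] + (spacer_total - sum(sp))  # fix rounding remainder
  seqs <- character(2 * nb + 1)
  feats <- vector("list", nb)
  pos <- 0L
  for (i in seq_len(nb)) {
    seqs[2 * i - 1] <- random_dna(sp[i])
    pos <- pos + sp[i]
    seqs[2 * i] <- blocks[[i]]$seq
    f <- blocks[[i]]$features
    if (nrow(f)) {
      f$start <- f$start + pos
      f$end <- f$end + pos
      feats[[i]] <- f
    }
    pos <- pos + flen[i]
  }
  seqs[2 * nb + 1] <- random_dna(sp[nb + 1])
  ft <- bind_rows(feats)
  if (nrow(ft) == 0) ft <- empty_features()
  list(seq = paste(seqs, collapse = ""), features = ft)
}

gene_block <- function(protein, kind, ...) {
  dna <- back_translate(protein)
  list(seq = dna, features = feature_row(kind, 0L, nchar(dna), ...))
}

# a virus-like sequence: hallmark genes (several copies, as in gene-dense
# virus genomes) over a backbone with bounded intergenic spacing, so the
# hallmark chain downstream tracks the provirus extent
build_virus_seq <- function(len, hallmark_db, n_genes = 6,
                            max_internal_gap = 9000, edge_total = 11000) {
  ord <- sample(rep(seq_len(nrow(hallmark_db)),
                    length.out = max(n_genes, 2)))
  dna <- vapply(hallmark_db$protein[ord], back_translate, "",
                USE.NAMES = FALSE)
  glen <- sum(nchar(dna))
  n_int <- length(dna) - 1L
  avail <- len - glen
  if (avail < n_int * 200 + edge_total) {
    abort("virus length too short for hallmarks")
  }
  int_sp <- rep(min(max_internal_gap, (avail - edge_total) / n_int), n_int)
  edge_sum <- avail - sum(int_sp)
  p <- runif(1, 0.45, 0.55)
  edges <- c(floor(edge_sum * p), ceiling(edge_sum * (1 - p)))
  seqs <- character(0)
  feats <- list()
  pos <- 0L
  push <- function(s) {
    seqs <<- c(seqs, s)
    pos <<- pos + nchar(s)
  }
  push(random_dna(edges[1]))
  for (i in seq_along(dna)) {
    feats[[i]] <- feature_row("hallmark_gene", pos, pos + nchar(dna[i]),
                              gene = hallmark_db$gene[ord[i]],
                              name = hallmark_db$id[ord[i]])
    push(dna[i])
    if (i <= n_int) push(random_dna(round(int_sp[i])))
  }
  push(random_dna(edges[2]))
  list(seq = paste(seqs, collapse = ""), features = bind_rows(feats))
}

# RcGTA-like cluster: genes in reference order with short spacers
build_gta_cluster <- function(gta_db, n_genes) {
  noncore <- which(!gta_db$core)
  keep <- sort(c(which(gta_db$core),
                 sample(noncore, n_genes - sum(gta_db$core))))
  seqs <- list()
  feats <- list()
  pos <- 0L
  for (i in keep) {
    sp <- sample(20:200, 1)
    seqs[[length(seqs) + 1]] <- random_dna(sp)
    pos <- pos + sp
    dna <- back_translate(gta_db$protein[i])
    seqs[[length(seqs) + 1]] <- dna
    feats[[length(feats) + 1]] <- feature_row(
      "gta_gene", pos, pos + nchar(dna), gene = gta_db$gene[i],
      core = gta_db$core[i], name = gta_db$id[i])
    pos <- pos + nchar(dna)
  }
  list(seq = paste(unlist(seqs), collapse = ""), features = bind_rows(feats))
}

#' Build a synthetic community of host and virus genomes
#'
#' Generates `n_hosts` host genomes and `n_viruses` free virus genomes with
#' planted, coordinate-anchored features. Every host carries one SSU rRNA
#' gene (a mutated copy of the bundled reference), COG-labelled genes drawn
#' from the bundled COG set (including transposase genes of the Mobilome
#' category), and per its assigned mechanism either an RcGTA-like gene
#' cluster (all core genes plus a draw of accessory genes, 11-15 in total)
#' or an integrated provirus carrying virus hallmark genes. Viruses carry
#' the full hallmark set. Cell abundance and peDNA output are drawn
#' independently (log-normal), so they are uncorrelated by construction.
#'
#' @param n_hosts,n_viruses Number of host / free virus genomes.
#' @param mechanism_counts Named integer vector over
#'   `EV_producer`, `GTA_producer`, `transducer` (and optionally `none`),
#'   summing to `n_hosts`. Defaults to the 129:30:11 field proportions.
#' @param genome_len_range,virus_len_range Length ranges (bp).
#' @param cog_genes_per_host COG-labelled genes planted per host.
#' @param ev_mobilome_factor Up-weighting of Mobilome (X) genes when drawing
#'   COG genes for EV-producer hosts (emulates the transposon link of EV
#'   cargo).
#' @param gta_dispersed Split each GTA cluster into three well-separated
#'   subclusters instead of one contiguous locus?
#' @param ssu_divergence Per-base substitution rate applied to the planted
#'   SSU gene copy.
#' @param abundance_sdlog Log-sd of the log-normal abundance draws.
#' @param seed Integer seed; the result is byte-identical under the same
#'   seed and parameters.
#' @return A `pedna_community` tibble: `genome_id`, `seq`, `role`,
#'   `truth_mechanism`, `length`, `abundance_cell`, `abundance_pedna`, and a
#'   `features` list-column of per-genome feature tibbles (0-based half-open
#'   intervals).
#' @export
build_community <- function(n_hosts, n_viruses,
                            mechanism_counts = NULL,
                            genome_len_range = c(120e3, 180e3),
                            virus_len_range = c(35e3, 45e3),
                            cog_genes_per_host = 30,
                            ev_mobilome_factor = 3,
                            gta_dispersed = FALSE,
                            ssu_divergence = 0.02,
                            abundance_sdlog = 1,
                            seed = 1) {
  if (is.null(mechanism_counts)) {
    ev <- round(n_hosts * 129 / 170)
    gta <- round(n_hosts * 30 / 170)
    tr <- n_hosts - ev - gta
    mechanism_counts <- c(EV_producer = ev, GTA_producer = gta, transducer = tr)
  }
  mc <- c(EV_producer = 0L, GTA_producer = 0L, transducer = 0L, none = 0L)
  bad <- setdiff(names(mechanism_counts), names(mc))
  if (length(bad)) abort(paste0("unknown mechanism: ", paste(bad, collapse = ", ")))
  mc[names(mechanism_counts)] <- as.integer(mechanism_counts)
  if (any(mc < 0) || sum(mc) != n_hosts) {
    abort("mechanism_counts must be non-negative and sum to n_hosts")
  }
  hallmark_db <- load_hallmark_db()
  gta_db <- load_gta_db()
  cog_db <- load_cog_db()
  ssu_refs <- load_ssu_refs()

  with_seed(seed, {
    mech <- sample(rep(names(mc), mc))
    rows <- vector("list", n_hosts + n_viruses)
    for (i in seq_len(n_hosts)) {
      L <- round(runif(1, genome_len_range[1], genome_len_range[2]))
      blocks <- list()
      # SSU rRNA gene
      ssu <- ssu_refs$seq[sample.int(nrow(ssu_refs), 1)]
      ssu <- add_substitutions(ssu, ssu_divergence)
      blocks[[1]] <- list(seq = ssu,
                          features = feature_row("ssu_rrna", 0L, nchar(ssu)))
      # COG-labelled genes (Mobilome up-weighted for EV producers)
      wcog <- rep(1, nrow(cog_db))
      if (mech[i] == "EV_producer") {
        wcog[cog_db$category == "X"] <- ev_mobilome_factor
      }
      gi <- sample.int(nrow(cog_db), cog_genes_per_host, replace = TRUE,
                       prob = wcog)
      for (g in gi) {
        is_tnp <- grepl("transposase", cog_db$name[g], ignore.case = TRUE)
        blocks[[length(blocks) + 1]] <- gene_block(
          cog_db$protein[g], if (is_tnp) "transposase" else "cog_gene",
          cluster = cog_db$cluster[g], category = cog_db$category[g],
          name = cog_db$name[g])
      }
      gta_blocks <- integer()
      if (mech[i] == "GTA_producer") {
        n_genes <- sample(11:15, 1)
        if (gta_dispersed) {
          # three subclusters: partition the reference set into thirds
          idx <- seq_len(nrow(gta_db))
          parts <- split(idx, cut(idx, 3, labels = FALSE))
          for (p in parts) {
            sub <- gta_db[p, ]
            cl <- build_gta_cluster(sub, nrow(sub))
            blocks[[length(blocks) + 1]] <- cl
            gta_blocks <- c(gta_blocks, length(blocks))
          }
        } else {
          blocks[[length(blocks) + 1]] <- build_gta_cluster(gta_db, n_genes)
        }
      }
      pro_block <- NA_integer_
      if (mech[i] == "transducer") {
        vlen <- round(runif(1, virus_len_range[1], virus_len_range[2]))
        v <- build_virus_seq(vlen, hallmark_db)
        pro <- list(seq = v$seq,
                    features = bind_rows(
                      feature_row("provirus", 0L, nchar(v$seq),
                                  name = sprintf("provirus_of_host_%03d", i)),
                      v$features))
        blocks[[length(blocks) + 1]] <- pro
        pro_block <- length(blocks)
      }
      # shuffle blocks; keep dispersed GTA subclusters spread out
      ord <- sample.int(length(blocks))
      if (mech[i] == "GTA_producer" && gta_dispersed) {
        others <- setdiff(ord, gta_blocks)
        third <- ceiling(length(others) / 3)
        ord <- c(gta_blocks[1], others[seq_len(third)],
                 gta_blocks[2], others[(third + 1):(2 * third)],
                 gta_blocks[3], others[-seq_len(2 * third)])
        ord <- ord[!is.na(ord)]
      }
      g <- assemble_genome(blocks[ord], L)
      rows[[i]] <- tibble(
        genome_id = sprintf("host_%03d", i), seq = g$seq, role = "host",
        truth_mechanism = mech[i], length = nchar(g$seq),
        abundance_cell = rlnorm(1, 0, abundance_sdlog),
        abundance_pedna = rlnorm(1, 0, abundance_sdlog),
        features = list(arrange(g$features, .data$start)))
    }
    for (j in seq_len(n_viruses)) {
      vlen <- round(runif(1, virus_len_range[1], virus_len_range[2]))
      v <- build_virus_seq(vlen, hallmark_db)
      rows[[n_hosts + j]] <- tibble(
        genome_id = sprintf("virus_%03d", j), seq = v$seq, role = "virus",
        truth_mechanism = "none", length = nchar(v$seq),
        abundance_cell = 0,
        abundance_pedna = rlnorm(1, 0, abundance_sdlog),
        features = list(arrange(v$features, .data$start)))
    }
    out <- bind_rows(rows)
    class(out) <- c("pedna_community", class(out))
    out
  })
}

#' Extract the contig set of a community
#'
#' The split stage consumes contigs; at desk scale the simulator emits each
#' genome as one contig (assembly is out of scope and orthogonal to every
#' statistic computed downstream).
#'
#' @param community A `pedna_community` tibble.
#' @return Sequence tibble (`id`, `seq`).
#' @export
community_contigs <- function(community) {
  tibble(id = community$genome_id, seq = community$seq)
}

# provirus interval per genome (1-based inclusive), NA if none
provirus_intervals <- function(community) {
  purrr::map2_dfr(community$genome_id, community$features, function(id, f) {
    p <- f[f$kind == "provirus", ]
    if (nrow(p) == 0) {
      tibble(genome_id = id, pro_start = NA_integer_, pro_end = NA_integer_)
    } else {
      tibble(genome_id = id, pro_start = p$start[1] + 1L, pro_end = p$end[1])
    }
  })
}

# sample insert start positions avoiding a 1-based inclusive interval [a, b]
sample_pos_avoiding <- function(n, L, il, a, b) {
  L <- as.integer(L); il <- as.integer(il)
  a <- as.integer(a); b <- as.integer(b)
  lo_max <- a - il          # inserts ending before the interval
  hi_min <- b + 1L          # inserts starting after it
  w1 <- pmax(lo_max, 0L)
  w2 <- pmax(L - il + 1L - hi_min + 1L, 0L)
  if (all(w1 + w2 <= 0)) abort("no room outside the excluded interval")
  left <- runif(n) < w1 / (w1 + w2)
  s <- integer(n)
  if (any(left)) s[left] <- sample.int(w1, sum(left), replace = TRUE)
  if (any(!left)) {
    s[!left] <- hi_min + sample.int(w2, sum(!left), replace = TRUE) - 1L
  }
  as.integer(s)
}

#' Sample a peDNA read set under a carrier mixture
#'
#' Draws `n_pairs` read pairs. Per pair a carrier is drawn from `mix`, an
#' eligible source genome is drawn proportional to `abundance_pedna`
#' (`abundance_cell` for the `cell` contamination carrier), a packaged
#' fragment is placed per the carrier model, and a sequencing insert inside
#' the fragment yields two `read_len` mates with independent substitution
#' errors. Carrier models:
#'
#' * `virion`: whole virus genomes; transducer hosts participate through
#'   their provirus interval at `induction`-fold elevated copy weight.
#' * `transduction_general`: uniform host fragments from transducer hosts.
#' * `transduction_specialized`: fragments adjacent to the provirus
#'   (within `adj_window` bp of either boundary).
#' * `gta_particle`: ~4.5 kb fragments (normal, sd 1 kb) from GTA hosts.
#' * `ev`: log-normal cargo fragments (median 2 kb) from any host genome —
#'   EV production carries no genetic signature, so eligibility is not
#'   restricted to hosts whose predominant mechanism is EV production.
#' * `free_dna`, `cell`: contamination carriers (off in a purified sample).
#'
#' @param community A `pedna_community`.
#' @param mix A [carrier_mix()].
#' @param n_pairs Number of read pairs.
#' @param read_len Mate length (bp).
#' @param err_rate Per-base substitution error rate, in `[0, 0.05]`.
#' @param induction Copy-number elevation of transducer proviruses within the
#'   virion carrier.
#' @param provirus_free Genome ids whose sampled population lacks the
#'   integrated provirus: host-derived fragments avoid the provirus interval
#'   and the genome does not feed the virion carrier (models a provirus-free
#'   subpopulation).
#' @param insert_mean,insert_sd Sequencing insert length model (bp).
#' @param gta_frag_mean,gta_frag_sd,ev_frag_meanlog,ev_frag_sdlog,adj_window
#'   Carrier fragment-length parameters.
#' @param seed Integer seed.
#' @return A list with `reads` (read-set tibble: `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`) and `truth` (tibble: `read_id`, `carrier`,
#'   `source_genome`, `start`, `end` — the 0-based half-open insert
#'   interval).
#' @export
sample_pedna_reads <- function(community, mix, n_pairs, read_len = 150,
                               err_rate = 0.005, induction = 10,
                               provirus_free = character(),
                               insert_mean = 350, insert_sd = 40,
                               gta_frag_mean = 4500, gta_frag_sd = 1000,
                               ev_frag_meanlog = log(2000),
                               ev_frag_sdlog = 0.6,
                               adj_window = 8000, seed = 1) {
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  if (err_rate < 0 || err_rate > 0.05) abort("err_rate must be in [0, 0.05]")
  if (!inherits(mix, "pedna_mix")) abort("mix must be a carrier_mix()")
  com <- community
  pro <- provirus_intervals(com)
  com <- left_join(as_tibble(com)[, c("genome_id", "seq", "role",
                                      "truth_mechanism", "length",
                                      "abundance_cell", "abundance_pedna")],
                   pro, by = "genome_id")
  glen <- setNames(com$length, com$genome_id)
  gseq <- setNames(com$seq, com$genome_id)

  eligible <- function(carrier) {
    switch(carrier,
      virion = {
        v <- com[com$role == "virus", ]
        t <- com[com$role == "host" & com$truth_mechanism == "transducer" &
                   !(com$genome_id %in% provirus_free), ]
        tibble(genome_id = c(v$genome_id, t$genome_id),
               w = c(v$abundance_pedna, t$abundance_pedna * induction),
               from_provirus = c(rep(FALSE, nrow(v)), rep(TRUE, nrow(t))))
      },
      transduction_general = ,
      transduction_specialized = {
        t <- com[com$role == "host" & com$truth_mechanism == "transducer", ]
        tibble(genome_id = t$genome_id, w = t$abundance_pedna,
               from_provirus = FALSE)
      },
      gta_particle = {
        t <- com[com$role == "host" & com$truth_mechanism == "GTA_producer", ]
        tibble(genome_id = t$genome_id, w = t$abundance_pedna,
               from_provirus = FALSE)
      },
      ev = {
        t <- com[com$role == "host", ]
        tibble(genome_id = t$genome_id, w = t$abundance_pedna,
               from_provirus = FALSE)
      },
      free_dna = tibble(genome_id = com$genome_id, w = com$abundance_pedna,
                        from_provirus = FALSE),
      cell = {
        t <- com[com$role == "host", ]
        tibble(genome_id = t$genome_id, w = t$abundance_cell,
               from_provirus = FALSE)
      })
  }

  with_seed(seed, {
    w <- as.numeric(mix)
    names(w) <- names(mix)
    active <- names(w)[w > 0]
    carriers <- if (length(active) == 1) rep(active, n_pairs) else {
      sample(active, n_pairs, replace = TRUE, prob = w[active])
    }
    src <- character(n_pairs)
    s <- integer(n_pairs)
    il <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                    read_len), 600L)

    for (carrier in unique(carriers)) {
      i <- which(carriers == carrier)
      el <- eligible(carrier)
      if (nrow(el) == 0 || sum(el$w) <= 0) {
        abort(paste0("carrier '", carrier, "' has positive weight but no ",
                     "eligible genome"))
      }
      pick <- sample.int(nrow(el), length(i), replace = TRUE, prob = el$w)
      gid <- el$genome_id[pick]
      src[i] <- gid
      L <- glen[gid]
      pi <- match(gid, pro$genome_id)
      ps <- pro$pro_start[pi]
      pe <- pro$pro_end[pi]
      ili <- il[i]
      si <- integer(length(i))
      if (carrier == "virion") {
        fp <- el$from_provirus[pick]
        # free virus: uniform in genome; provirus: uniform in the interval
        lo <- ifelse(fp, ps, 1L)
        hi <- ifelse(fp, pe, L)
        ili <- pmin(ili, hi - lo + 1L)
        si <- lo + floor(runif(length(i)) * (hi - lo + 1L - ili + 1L))
      } else if (carrier == "transduction_specialized") {
        left <- runif(length(i)) < 0.5
        lo <- ifelse(left, pmax(ps - adj_window, 1L), pe + 1L)
        hi <- ifelse(left, ps - 1L, pmin(pe + adj_window, L))
        # fall back to the other side where the flank is too short
        short <- hi - lo + 1L < ili
        lo[short] <- pmax(pe[short] + 1L, 1L)
        hi[short] <- pmin(pe[short] + adj_window, L[short])
        ili <- pmin(ili, hi - lo + 1L)
        si <- lo + floor(runif(length(i)) * (hi - lo + 1L - ili + 1L))
      } else if (carrier == "gta_particle") {
        fl <- pmax(round(rnorm(length(i), gta_frag_mean, gta_frag_sd)),
                   pmax(ili, 1000L))
        fl <- pmin(fl, L)
        fs <- 1L + floor(runif(length(i)) * (L - fl + 1L))
        si <- fs + floor(runif(length(i)) * (fl - ili + 1L))
      } else if (carrier == "ev") {
        fl <- pmin(pmax(round(rlnorm(length(i), ev_frag_meanlog,
                                     ev_frag_sdlog)), ili), L)
        avoid <- gid %in% provirus_free & !is.na(ps)
        fs <- integer(length(i))
        if (any(avoid)) {
          fs[avoid] <- vapply(which(avoid), function(jj) {
            sample_pos_avoiding(1L, L[jj], fl[jj], ps[jj], pe[jj])
          }, 0L)
        }
        fs[!avoid] <- 1L + floor(runif(sum(!avoid)) *
                                   (L[!avoid] - fl[!avoid] + 1L))
        si <- fs + floor(runif(length(i)) * (fl - ili + 1L))
      } else if (carrier == "free_dna") {
        fl <- pmax(round(rnorm(length(i), 500, 150)), ili)
        fl <- pmin(fl, L)
        fs <- 1L + floor(runif(length(i)) * (L - fl + 1L))
        si <- fs + floor(runif(length(i)) * (fl - ili + 1L))
      } else {  # transduction_general, cell: uniform over the genome
        avoid <- gid %in% provirus_free & !is.na(ps)
        si <- integer(length(i))
        if (any(avoid)) {
          si[avoid] <- vapply(which(avoid), function(jj) {
            sample_pos_avoiding(1L, L[jj], ili[jj], ps[jj], pe[jj])
          }, 0L)
        }
        si[!avoid] <- 1L + floor(runif(sum(!avoid)) *
                                   (L[!avoid] - ili[!avoid] + 1L))
      }
      s[i] <- as.integer(si)
      il[i] <- as.integer(ili)
    }

    e <- s + il - 1L
    r1 <- substring(gseq[src], s, s + read_len - 1L)
    r2 <- revcomp(substring(gseq[src], e - read_len + 1L, e))
    r1 <- add_substitutions(r1, err_rate)
    r2 <- add_substitutions(r2, err_rate)
    ids <- sprintf("pedna_%07d", seq_len(n_pairs))
    q <- strrep("I", read_len)
    list(
      reads = tibble(read_id = ids, seq1 = unname(r1), qual1 = q,
                     seq2 = unname(r2), qual2 = q),
      truth = tibble(read_id = ids, carrier = carriers,
                     source_genome = unname(src),
                     start = s - 1L, end = e))
  })
}

#' Sample a microbial metagenome read set
#'
#' Uniform fragments from host genomes weighted by `abundance_cell`
#' (independent of `abundance_pedna`), with the same insert and error model
#' as [sample_pedna_reads()].
#'
#' @inheritParams sample_pedna_reads
#' @return A list with `reads` and `truth` (carrier `cell`).
#' @export
sample_metagenome_reads <- function(community, n_pairs, read_len = 150,
                                    err_rate = 0.005, insert_mean = 350,
                                    insert_sd = 40, seed = 1) {
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  hosts <- community[community$abundance_cell > 0, ]
  if (nrow(hosts) == 0) abort("no genome with positive cell abundance")
  with_seed(seed, {
    il <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                    read_len), 600L)
    pick <- sample.int(nrow(hosts), n_pairs, replace = TRUE,
                       prob = hosts$abundance_cell)
    gid <- hosts$genome_id[pick]
    L <- hosts$length[pick]
    s <- 1L + floor(runif(n_pairs) * (L - il + 1L))
    e <- s + il - 1L
    gseq <- setNames(hosts$seq, hosts$genome_id)
    r1 <- add_substitutions(substring(gseq[gid], s, s + read_len - 1L),
                            err_rate)
    r2 <- add_substitutions(revcomp(substring(gseq[gid], e - read_len + 1L, e)),
                            err_rate)
    ids <- sprintf("meta_%07d", seq_len(n_pairs))
    q <- strrep("I", read_len)
    list(
      reads = tibble(read_id = ids, seq1 = unname(r1), qual1 = q,
                     seq2 = unname(r2), qual2 = q),
      truth = tibble(read_id = ids, carrier = "cell",
                     source_genome = unname(gid),
                     start = as.integer(s - 1L), end = as.integer(e)))
  })
}

#' Write a community and a sampled read set to disk
#'
#' `write_community()` writes the genomes as FASTA and the planted features
#' as a BED-like TSV. `write_pedna_sample()` writes `_R1`/`_R2` FASTQ files,
#' the truth TSV and a plain key-value run-config capturing the sampling
#' parameters.
#'
#' @param community A `pedna_community`.
#' @param dir Output directory (created if missing).
#' @param sample Result of [sample_pedna_reads()] or
#'   [sample_metagenome_reads()].
#' @param prefix File name prefix for the read set.
#' @param config Named list of parameters to record.
#' @return The output directory, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tibble(id = community$genome_id, seq = community$seq,
                     desc = paste0("role=", community$role,
                                   " mechanism=", community$truth_mechanism)),
              file.path(dir, "genomes.fasta"))
  feats <- purrr::map2_dfr(community$genome_id, community$features,
                           ~ bind_cols(tibble(genome = .x), .y))
  readr::write_tsv(feats, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_community
#' @export
write_pedna_sample <- function(sample, dir, prefix = "sample",
                               config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs_fastq(sample$reads,
                    file.path(dir, paste0(prefix, "_R1.fastq")),
                    file.path(dir, paste0(prefix, "_R2.fastq")))
  readr::write_tsv(sample$truth, file.path(dir, paste0(prefix, "_truth.tsv")))
  if (length(config)) {
    writeLines(paste0(names(config), "=",
                      vapply(config, function(x) paste(x, collapse = ","), "")),
               file.path(dir, paste0(prefix, "_config.txt")))
  }
  invisible(dir)
}
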