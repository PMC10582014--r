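# Generates the bundled synthetic reference sets under inst/extdata/.
# All sequences are random constructs (fixed seed) standing in for real
# reference proteins/rRNA genes; they only need to be internally consistent
# with the community generator, which back-translates them into planted genes.
# Run from the package root: Rscript data-raw/synthetic_references.R

set.seed(48151623)

AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
# loosely realistic residue frequencies (small proteome average)
AA_P <- c(8.3,5.7,4.4,5.3,1.4,3.9,6.1,7.2,2.2,5.9,9.7,5.8,2.4,3.9,4.7,6.6,5.4,1.1,2.9,6.9)
AA_P <- AA_P / sum(AA_P)

rprotein <- function(len) {
  paste0("M", paste(sample(AA, len - 1, replace = TRUE, prob = AA_P), collapse = ""))
}

write_faa <- function(path, ids, descs, seqs) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i], " ", descs[i]), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[i]), con)
  }
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## viral hallmark proteins ---------------------------------------------------
hm <- data.frame(
  id   = c("hallmark_MCP_synthetic", "hallmark_TerL_synthetic", "hallmark_portal_synthetic"),
  gene = c("major_capsid_protein", "terminase_large_subunit", "portal_protein"),
  len  = c(350L, 420L, 400L)
)
write_faa("inst/extdata/hallmark_proteins_synthetic.faa",
          hm$id, paste0("synthetic stand-in gene=", hm$gene),
          vapply(hm$len, rprotein, ""))

## RcGTA-like gene set -------------------------------------------------------
gta <- data.frame(
  gene = c("TG","TAP","TTP","MTP","HTJ","GP6","MCP","Prot","PPP","MBP",
           "AT","Pept","TMP","HypA","HypB"),
  core = c(rep(TRUE, 10), rep(FALSE, 5)),
  len  = c(210L, 190L, 160L, 240L, 130L, 180L, 330L, 220L, 340L, 150L,
           140L, 170L, 300L, 90L, 110L)
)
write_faa("inst/extdata/gta_proteins_synthetic.faa",
          paste0("gta_", gta$gene, "_synthetic"),
          paste0("synthetic stand-in gene=", gta$gene, " core=", tolower(gta$core)),
          vapply(gta$len, rprotein, ""))

## COG-labelled protein set --------------------------------------------------
cats <- c("C","E","J","K","L","M","N","T","W","X")
x_names <- c("IS3 family transposase", "Tn3 family transposase",
             "IS200-like transposase", "prophage antirepressor")
rows <- list()
cogid <- 5000L
for (cat in cats) {
  for (j in 1:4) {
    cogid <- cogid + 1L
    nm <- if (cat == "X") x_names[j] else sprintf("category %s protein %d", cat, j)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("COG%04d", cogid), cat = cat, name = nm,
      len = sample(120:250, 1))
  }
}
cog <- do.call(rbind, rows)
write_faa("inst/extdata/cog_proteins_synthetic.faa",
          paste0(cog$id, "_synthetic"),
          paste0("cluster=", cog$id, " cat=", cog$cat, " name=", cog$name),
          vapply(cog$len, rprotein, ""))

## SSU rRNA reference --------------------------------------------------------
rdna <- function(len) paste(sample(c("A","C","G","T"), len, replace = TRUE,
                                   prob = c(0.24, 0.26, 0.30, 0.20)), collapse = "")
write_faa("inst/extdata/ssu_rrna_synthetic.fasta",
          c("ssu_16S_synthetic_1", "ssu_16S_synthetic_2"),
          rep("synthetic SSU rRNA reference", 2),
          c(rdna(1500), rdna(1500)))

cat("synthetic references written to inst/extdata/\n")
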