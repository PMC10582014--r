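# FASTA/FASTQ input/output and bundled reference loaders.
#
# Sequence tables are plain tibbles: `id`, `seq`, `desc` (FASTA) or
# `id`, `seq`, `qual` (FASTQ). Parsing is delegated to Biostrings; this layer
# adds the validation the downstream contracts rely on (unique ids, restricted
# alphabet in strict mode) and tidy return types.

DNA_STRICT <- "^[ACGTN]*$"

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @param strict Restrict the alphabet to `{A,C,G,T,N}` (after upper-casing)?
#'   Records violating it raise an error.
#' @return A tibble with columns `id`, `seq`, `desc`, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && !startsWith(first, ">")) {
    abort(paste0("malformed FASTA (line 1 does not start with '>'): ", path))
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0) {
    return(tibble(id = character(), seq = character(), desc = character()))
  }
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seq <- toupper(as.character(x))
  if (any(id == "")) abort("FASTA record with empty id")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (strict) {
    bad <- which(!grepl(DNA_STRICT, seq))
    if (length(bad)) {
      abort(sprintf("record '%s' contains characters outside {A,C,G,T,N}", id[bad[1]]))
    }
  }
  if (any(nchar(seq) == 0)) abort("FASTA record with empty sequence")
  tibble(id = id, seq = unname(seq), desc = unname(desc))
}

#' Write a sequence tibble to FASTA
#'
#' Round-trips with [read_fasta()]: write-then-read is the identity on
#' `(id, seq)`.
#'
#' @param x Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  check_seq_tbl(x)
  hdr <- if ("desc" %in% names(x)) {
    ifelse(is.na(x$desc) | x$desc == "", x$id, paste(x$id, x$desc))
  } else x$id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", hdr[i]), con)
    writeLines(gsub(sprintf("(.{%d})", width), "\\1\n", x$seq[i]), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `seq`, `qual`, in file order.
#' @export
read_fastq <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  id <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(id)) {
    abort(paste0("duplicate FASTQ id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  seq <- toupper(as.character(x))
  if (strict) {
    bad <- which(!grepl(DNA_STRICT, seq))
    if (length(bad)) {
      abort(sprintf("record '%s' contains characters outside {A,C,G,T,N}", id[bad[1]]))
    }
  }
  tibble(id = unname(id), seq = unname(seq),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write a FASTQ tibble (Sanger +33 qualities)
#'
#' @param x Tibble with columns `id`, `seq` and optionally `qual` (defaults to
#'   constant quality `I`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  check_seq_tbl(x)
  qual <- if ("qual" %in% names(x)) x$qual else strrep("I", nchar(x$seq))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read / write a paired read set
#'
#' A read set is a tibble with one row per pair: `read_id`, `seq1`, `qual1`,
#' `seq2`, `qual2`. On disk it is a pair of `_R1`/`_R2` FASTQ files whose
#' record ids carry a `/1` / `/2` suffix.
#'
#' @param r1,r2 Paths to the two mate FASTQ files.
#' @return A read-set tibble.
#' @export
read_pairs_fastq <- function(r1, r2) {
  a <- read_fastq(r1)
  b <- read_fastq(r2)
  if (nrow(a) != nrow(b)) abort("R1/R2 files differ in record count")
  ida <- sub("/[12]$", "", a$id)
  idb <- sub("/[12]$", "", b$id)
  if (!identical(ida, idb)) abort("R1/R2 read ids do not pair up")
  tibble(read_id = ida, seq1 = a$seq, qual1 = a$qual, seq2 = b$seq, qual2 = b$qual)
}

#' @rdname read_pairs_fastq
#' @param reads Read-set tibble.
#' @export
write_pairs_fastq <- function(reads, r1, r2) {
  write_fastq(tibble(id = paste0(reads$read_id, "/1"),
                     seq = reads$seq1, qual = reads$qual1), r1)
  write_fastq(tibble(id = paste0(reads$read_id, "/2"),
                     seq = reads$seq2, qual = reads$qual2), r2)
  invisible(c(r1, r2))
}

# ---- bundled references ----------------------------------------------------

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "pednar")
  if (p == "") abort(paste0("bundled reference not found: ", file))
  p
}

parse_desc_tags <- function(desc) {
  # "gene=TG core=true name=IS3 family transposase" -> named list; the last
  # tag may contain spaces (name=...)
  out <- list()
  g <- gregexpr("\\b(\\w+)=", desc)
  m <- g[[1]]
  if (m[1] == -1) return(out)
  keys <- regmatches(desc, g)[[1]]
  starts <- as.integer(m)
  ends <- c(starts[-1] - 1L, nchar(desc))
  for (i in seq_along(starts)) {
    key <- sub("=$", "", keys[i])
    val <- substr(desc, starts[i] + attr(m, "match.length")[i], ends[i])
    out[[key]] <- trimws(val)
  }
  out
}

read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  tibble(id = sub("\\s.*$", "", full),
         desc = ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), ""),
         protein = unname(as.character(x)))
}

#' Bundled synthetic reference sets
#'
#' The package ships small synthetic stand-ins for the reference sets the
#' pipeline searches against: virus hallmark proteins (major capsid protein,
#' terminase large subunit, portal protein), an RcGTA-like gene set with
#' per-gene core flags, a COG-style protein set with cluster/category/name
#' tags, and an SSU rRNA reference. All are random constructs generated with
#' a fixed seed (`data-raw/synthetic_references.R`); the community generator
#' back-translates the same proteins into planted genes, so searches against
#' these references recover the planted truth.
#'
#' @return Tibbles. `load_hallmark_db()`: `id`, `gene`, `protein`.
#'   `load_gta_db()`: `id`, `gene`, `core`, `protein`. `load_cog_db()`: `id`,
#'   `cluster`, `category`, `name`, `protein`. `load_ssu_refs()`: `id`, `seq`,
#'   `desc`.
#' @name references
NULL

#' @rdname references
#' @export
load_hallmark_db <- function() {
  x <- read_protein_fasta(ref_path("hallmark_proteins_synthetic.faa"))
  x$gene <- vapply(x$desc, function(d) parse_desc_tags(d)$gene %||% NA_character_, "")
  select(x, "id", "gene", "protein")
}

#' @rdname references
#' @export
load_gta_db <- function() {
  x <- read_protein_fasta(ref_path("gta_proteins_synthetic.faa"))
  tags <- lapply(x$desc, parse_desc_tags)
  x$gene <- vapply(tags, function(t) t$gene %||% NA_character_, "")
  x$core <- vapply(tags, function(t) identical(t$core, "true"), TRUE)
  select(x, "id", "gene", "core", "protein")
}

#' @rdname references
#' @export
load_cog_db <- function() {
  x <- read_protein_fasta(ref_path("cog_proteins_synthetic.faa"))
  tags <- lapply(x$desc, parse_desc_tags)
  x$cluster <- vapply(tags, function(t) t$cluster %||% NA_character_, "")
  x$category <- vapply(tags, function(t) t$cat %||% NA_character_, "")
  x$name <- vapply(tags, function(t) t$name %||% NA_character_, "")
  select(x, "id", "cluster", "category", "name", "protein")
}

#' @rdname references
#' @export
load_ssu_refs <- function() {
  read_fasta(ref_path("ssu_rrna_synthetic.fasta"))
}
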