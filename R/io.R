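# File interfaces: FASTA/FASTQ sequences, GTF annotation, TSV tables.

#' Read sequences from FASTA or FASTQ
#'
#' @param path FASTA (or FASTQ, detected by extension) file.
#' @return tibble (`id`, `seq`) with ids truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readBStringSet(path, format = fmt)
  tibble(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss))
}

#' Write sequences to FASTA
#'
#' Sequences are held internally in the RNA alphabet; on disk they are
#' written with `T` (the common reference-file convention) unless
#' `alphabet = "rna"`.
#'
#' @param seqs `tibble(id, seq)` or named character vector.
#' @param path output path.
#' @param alphabet `"dna"` (write T) or `"rna"` (write U).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  seqs <- as_seq_tbl(seqs, allow_n = TRUE)
  x <- if (alphabet == "dna")
    Biostrings::DNAStringSet(setNames(chartr("U", "T", seqs$seq), seqs$id))
  else Biostrings::RNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write an annotation as GTF
#'
#' Emits one `gene` row per gene span and one `exon` row per transcript
#' exon, converting the package's 0-based half-open coordinates to GTF's
#' 1-based inclusive convention.
#'
#' @param annotation list with `genes` and `transcripts` as produced by
#'   [simulate_annotation()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  tx <- annotation$transcripts
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1, end = g$end),
    strand = g$strand, type = "gene", gene_id = g$gene_id,
    transcript_id = NA_character_, transcript_type = NA_character_)
  gr_ex <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1, end = tx$end),
    strand = tx$strand, type = "exon",
    gene_id = ifelse(is.na(tx$gene_id), tx$transcript_id, tx$gene_id),
    transcript_id = tx$transcript_id, transcript_type = tx$type)
  rtracklayer::export(c(gr_genes, gr_ex), path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation
#'
#' Inverse of [write_gtf()]: returns gene spans and the exon-level
#' transcript table in 0-based half-open coordinates.
#'
#' @param path GTF file.
#' @return list with `genes` and `transcripts` tibbles.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  genes <- df |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$gene_id, chrom = as.character(.data$seqnames),
              strand = as.character(.data$strand),
              start = .data$start - 1, end = .data$end)
  tx <- df |>
    filter(.data$type == "exon") |>
    transmute(transcript_id = .data$transcript_id,
              gene_id = ifelse(.data$transcript_type == "mRNA",
                               .data$gene_id, NA_character_),
              type = .data$transcript_type,
              chrom = as.character(.data$seqnames),
              strand = as.character(.data$strand),
              start = .data$start - 1, end = .data$end)
  list(genes = genes, transcripts = tx)
}

write_stage_tsv <- function(x, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  readr::write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
  invisible(NULL)
}
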