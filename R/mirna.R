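# Small-RNA read collapsing and identity-based mature miRNA assignment.

#' Collapse small-RNA reads to unique sequences
#'
#' Deduplicates a stream of small-RNA reads into one record per distinct
#' sequence with its multiplicity, keeping only reads in the mature-miRNA
#' length range (16-24 nt by default). Reads containing non-nucleotide
#' characters are skipped with a warning; `T`/`U` encodings are equivalent.
#'
#' @param reads character vector of reads, a `tibble` with a `seq` column,
#'   or a FASTA/FASTQ path.
#' @param min_len,max_len inclusive length range retained.
#' @return tibble (`sequence` in RNA alphabet, `count`, `length`), ordered
#'   by decreasing count then sequence.
#' @export
collapse_reads <- function(reads, min_len = 16, max_len = 24) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fasta(reads)$seq
  if (is.data.frame(reads)) reads <- reads$seq
  empty <- tibble(sequence = character(), count = integer(),
                  length = integer())
  if (length(reads) == 0) return(empty)
  reads <- chartr("t", "T", toupper(reads))
  reads <- chartr("T", "U", reads)
  bad <- grepl("[^ACGU]", reads)
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad),
                " read(s) with non-nucleotide characters"))
    reads <- reads[!bad]
  }
  len <- nchar(reads)
  reads <- reads[len >= min_len & len <= max_len]
  if (length(reads) == 0) return(empty)
  tab <- table(reads)
  tibble(sequence = names(tab), count = as.integer(tab)) |>
    mutate(length = nchar(.data$sequence)) |>
    arrange(desc(.data$count), .data$sequence)
}

# Best ungapped identity of `read` against `ref` over all sliding offsets
# (overhangs allowed); identity = matches / read length * 100.
best_identity <- function(read, ref) {
  rl <- nchar(read)
  fl <- nchar(ref)
  rch <- strsplit(read, "")[[1]]
  fch <- strsplit(ref, "")[[1]]
  best <- 0
  for (off in (-rl + 1):(fl - 1)) {
    i1 <- max(1, 1 - off)          # read positions overlapping the ref
    i2 <- min(rl, fl - off)
    if (i2 < i1) next
    m <- sum(rch[i1:i2] == fch[(i1:i2) + off])
    best <- max(best, 100 * m / rl)
  }
  best
}

#' Assign collapsed reads to a mature miRNA reference
#'
#' For each collapsed read, finds the reference miRNA with the highest
#' ungapped percent identity over all sliding offsets (identity = matching
#' bases / read length x 100, an exhaustive and deterministic replacement
#' for a short-read BLASTn search) and retains assignments at or above
#' `min_identity`. Ties go to the lexicographically smallest mature id, so
#' multi-mapping reads are counted exactly once.
#'
#' @param collapsed tibble from [collapse_reads()].
#' @param reference mature miRNA reference: named character vector,
#'   `tibble(id, seq)`, `XStringSet` or FASTA path (miRBase-style ids).
#' @param min_identity retention cutoff in percent (inclusive).
#' @return list with `assignments` (tibble `sequence`, `count`,
#'   `mature_id`, `identity_pct`) and `counts` (tibble `mature_id`,
#'   `count`, one row per reference entry, zero for unmatched miRNAs).
#' @export
match_mature <- function(collapsed, reference, min_identity = 95) {
  reference <- as_seq_tbl(reference)
  if (nrow(reference) == 0) abort("mature reference must be non-empty")
  reference <- reference |> arrange(.data$id)
  asn <- purrr::map_dfr(seq_len(nrow(collapsed)), function(i) {
    rd <- collapsed$sequence[i]
    ids <- vapply(reference$seq, best_identity, double(1), read = rd,
                  USE.NAMES = FALSE)
    j <- which(ids == max(ids))[1]  # reference sorted by id: tie -> smallest
    tibble(sequence = rd, count = collapsed$count[i],
           mature_id = reference$id[j], identity_pct = ids[j])
  })
  if (nrow(asn) == 0)
    asn <- tibble(sequence = character(), count = integer(),
                  mature_id = character(), identity_pct = double())
  asn <- asn |> filter(.data$identity_pct >= min_identity)
  counts <- asn |>
    group_by(.data$mature_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  counts <- tibble(mature_id = reference$id) |>
    left_join(counts, by = "mature_id") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  list(assignments = asn, counts = counts)
}

#' Quantify miRNAs across samples from small-RNA reads
#'
#' Collapses reads per sample, assigns them to the mature reference with
#' [match_mature()], and joins the per-sample counts into one matrix on the
#' mature id (zeros for miRNAs absent from a sample).
#'
#' @param reads tibble (`sample_id`, `seq`) of reads across samples.
#' @param reference mature miRNA reference (see [match_mature()]).
#' @param min_identity percent-identity cutoff.
#' @param min_len,max_len read length range retained by collapsing.
#' @return wide count tibble: `feature_id` plus one column per sample.
#' @export
quantify_mirnas <- function(reads, reference, min_identity = 95,
                            min_len = 16, max_len = 24) {
  samples <- unique(reads$sample_id)
  ref <- as_seq_tbl(reference)
  out <- tibble(feature_id = sort(ref$id))
  for (s in samples) {
    col <- collapse_reads(reads$seq[reads$sample_id == s], min_len, max_len)
    cnt <- match_mature(col, ref, min_identity)$counts
    out[[s]] <- cnt$count[match(out$feature_id, cnt$mature_id)]
  }
  out
}
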