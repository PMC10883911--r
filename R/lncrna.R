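# lncRNA candidate filtering, coding-potential assessment and positional
# classification against an mRNA annotation.

# Transcript tables are tidy exon tables: one row per exon with columns
# transcript_id, gene_id, type, chrom, strand, start, end. Coordinates are
# 0-based half-open internally; GTF import/export converts to 1-based
# inclusive.

#' Summarize an exon table per transcript
#'
#' @param transcripts exon-level tibble (`transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, one row per exon).
#' @return tibble with one row per transcript: genomic span, spliced length
#'   (sum of exon lengths) and exon count, in first-appearance order.
#' @export
transcript_summary <- function(transcripts) {
  transcripts |>
    mutate(.ord = dplyr::row_number()) |>
    group_by(.data$transcript_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              span_start = min(.data$start),
              span_end = max(.data$end),
              spliced_length = sum(.data$end - .data$start),
              n_exons = dplyr::n(),
              .ord = min(.data$.ord), .groups = "drop") |>
    arrange(.data$.ord) |>
    select(-".ord")
}

#' Filter candidate transcripts by spliced length and exon count
#'
#' Drops transcripts shorter than `min_len` nt of spliced sequence and
#' single-exon transcripts (more generally, transcripts with fewer than
#' `min_exons` exons). Both boundaries are inclusive on the keep side:
#' exactly 200 nt with 2 exons is retained under the defaults.
#'
#' @param transcripts exon-level transcript tibble.
#' @param min_len minimum spliced length (nt) retained.
#' @param min_exons minimum exon count retained.
#' @return the exon rows of retained transcripts, input order preserved.
#' @export
filter_candidates <- function(transcripts, min_len = 200, min_exons = 2) {
  if (nrow(transcripts) == 0) return(transcripts)
  keep <- transcript_summary(transcripts) |>
    filter(.data$spliced_length >= min_len, .data$n_exons >= min_exons)
  transcripts |> filter(.data$transcript_id %in% keep$transcript_id)
}

# Classic Fickett TESTCODE lookup tables: probability that a window with a
# given positional asymmetry / composition value is coding, per base, with
# the published weights.
fickett_tables <- function() {
  list(
    position_breaks = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0),
    content_breaks = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                       0.17, 0),
    position_prob = rbind(
      A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
      C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
      G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
      U = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
    position_weight = c(A = 0.26, C = 0.18, G = 0.31, U = 0.33),
    content_prob = rbind(
      A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
      C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
      G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
      U = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
    content_weight = c(A = 0.11, C = 0.12, G = 0.15, U = 0.14))
}

fickett_score_one <- function(seq) {
  tb <- fickett_tables()
  chars <- strsplit(seq, "")[[1]]
  chars <- chars[chars != "N"]
  n <- length(chars)
  if (n == 0) return(0)
  score <- 0
  for (b in c("A", "C", "G", "U")) {
    at <- which(chars == b)
    cnt <- tabulate(((at - 1) %% 3) + 1, nbins = 3)
    posval <- max(cnt) / (min(cnt) + 1)
    pi <- which(posval >= tb$position_breaks)[1]
    content <- length(at) / n
    ci <- which(content >= tb$content_breaks)[1]
    score <- score + tb$position_prob[b, pi] * tb$position_weight[b] +
      tb$content_prob[b, ci] * tb$content_weight[b]
  }
  score
}

longest_orf_one <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  best <- 0L
  stops <- c("UAA", "UAG", "UGA")
  for (frame in 0:2) {
    starts <- seq(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- vapply(starts, function(s)
      paste(chars[s:(s + 2)], collapse = ""), character(1))
    open <- NA_integer_  # index of the earliest unmatched AUG
    for (k in seq_along(codons)) {
      cd <- codons[k]
      if (grepl("N", cd, fixed = TRUE)) { open <- NA_integer_; next }
      if (cd %in% stops) {
        if (!is.na(open)) best <- max(best, 3L * (k - open))
        open <- NA_integer_
      } else if (is.na(open) && cd == "AUG") {
        open <- k
      }
    }
  }
  best
}

#' Assess the coding potential of a transcript sequence
#'
#' A documented heuristic combining the two classic sequence-intrinsic
#' signals of protein-coding capacity: the length of the longest open
#' reading frame (AUG to stop, scanned over the three forward frames of the
#' stranded transcript; the stop codon is excluded from the length and no
#' ORF may span an `N`) and the Fickett TESTCODE statistic computed from
#' the published position-asymmetry and composition lookup tables. A
#' transcript is called `noncoding` only when both signals are weak:
#' longest ORF `< orf_min` nt and Fickett score `< fickett_min`.
#'
#' @param sequences sequences to assess: named character vector,
#'   `tibble(id, seq)`, `XStringSet` or FASTA path. `T` and `U` encodings
#'   are equivalent; `N` is tolerated.
#' @param orf_min ORF length (nt) at or above which a transcript is called
#'   coding.
#' @param fickett_min Fickett score at or above which a transcript is
#'   called coding.
#' @return tibble with one row per sequence: `id`, `longest_orf_nt`,
#'   `orf_coverage` (ORF length over transcript length), `fickett_score`
#'   and `verdict` (`"coding"` or `"noncoding"`).
#' @export
#' @examples
#' assess_coding_potential(c(t1 = "ACGUACGUACGUACGUACGU"))
assess_coding_potential <- function(sequences, orf_min = 300,
                                    fickett_min = 0.95) {
  tbl <- as_seq_tbl(sequences, allow_n = TRUE)
  if (any(nchar(tbl$seq) < 1)) abort("sequences must be non-empty")
  orf <- vapply(tbl$seq, longest_orf_one, integer(1), USE.NAMES = FALSE)
  fick <- vapply(tbl$seq, fickett_score_one, double(1), USE.NAMES = FALSE)
  tibble(id = tbl$id,
         longest_orf_nt = orf,
         orf_coverage = orf / nchar(tbl$seq),
         fickett_score = fick,
         verdict = ifelse(orf < orf_min & fick < fickett_min,
                          "noncoding", "coding"))
}

#' Classify lncRNA candidates by position relative to mRNA genes
#'
#' Implements the standard positional taxonomy of lncRNAs against a gene
#' annotation. A candidate whose genomic span overlaps a gene span by at
#' least one base (either strand) is `genic`, subdivided into `containing`
#' (candidate span contains the gene span), `nested` (gene contains the
#' candidate) or `overlapping` (partial overlap; equal spans also fall
#' here). Otherwise it is `intergenic`, attached to the nearest gene by
#' span distance, and subdivided by orientation: `same_strand`, or for
#' opposite strands `divergent` when the 5' ends face each other
#' (head-to-head) and `convergent` when the 3' ends do (tail-to-tail).
#'
#' Ties: when several genes overlap a genic candidate the one with the
#' largest overlap wins (then the lexicographically smallest `gene_id`);
#' when the nearest left and right genes are equidistant the gene upstream
#' of the candidate (relative to the candidate's strand) wins.
#'
#' @param candidates exon-level tibble of candidate transcripts, or a
#'   [transcript_summary()] table.
#' @param genes gene annotation tibble (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`; 0-based half-open spans).
#' @param max_window search window (nt) for the nearest gene; if no gene
#'   lies within it the nearest gene overall is still reported.
#' @return tibble (`transcript_id`, `top_level`, `subtype`, `partner_gene`,
#'   `distance`), one row per candidate; `distance` is 0 for genic calls.
#' @export
classify_position <- function(candidates, genes, max_window = 1e5) {
  if (!"span_start" %in% names(candidates))
    candidates <- transcript_summary(candidates)
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    lnc <- candidates[i, ]
    g <- genes |> filter(.data$chrom == lnc$chrom)
    if (nrow(g) == 0)
      abort(paste0("no genes on chromosome `", lnc$chrom,
                   "` in the annotation"))
    ov <- pmin(g$end, lnc$span_end) - pmax(g$start, lnc$span_start)
    if (any(ov > 0)) {
      g <- g[ov > 0, ]
      ov <- ov[ov > 0]
      pick <- order(-ov, g$gene_id)[1]
      gp <- g[pick, ]
      equal <- gp$start == lnc$span_start && gp$end == lnc$span_end
      subtype <- if (!equal && lnc$span_start <= gp$start &&
                     lnc$span_end >= gp$end) "containing"
      else if (!equal && gp$start <= lnc$span_start &&
               gp$end >= lnc$span_end) "nested"
      else "overlapping"
      return(tibble(transcript_id = lnc$transcript_id,
                    top_level = "genic", subtype = subtype,
                    partner_gene = gp$gene_id, distance = 0))
    }
    # intergenic: nearest gene by span distance (half-open spans)
    d <- ifelse(g$start >= lnc$span_end, g$start - lnc$span_end,
                lnc$span_start - g$end)
    within <- d <= max_window
    gg <- if (any(within)) g[within, ] else g
    dd <- if (any(within)) d[within] else d
    near <- which(dd == min(dd))
    if (length(near) > 1) {
      # equidistant left/right: prefer the gene upstream of the candidate
      is_left <- gg$end[near] <= lnc$span_start
      want_left <- lnc$strand == "+"
      pref <- near[is_left == want_left]
      near <- if (length(pref) > 0) pref[order(gg$gene_id[pref])][1]
      else near[order(gg$gene_id[near])][1]
    }
    gp <- gg[near[1], ]
    dist <- dd[near[1]]
    if (gp$strand == lnc$strand) {
      subtype <- "same_strand"
    } else {
      gene_left <- gp$end <= lnc$span_start
      left_strand <- if (gene_left) gp$strand else lnc$strand
      # tail-to-tail (3' ends facing) iff the left feature runs rightwards
      subtype <- if (left_strand == "+") "convergent" else "divergent"
    }
    tibble(transcript_id = lnc$transcript_id, top_level = "intergenic",
           subtype = subtype, partner_gene = gp$gene_id, distance = dist)
  })
}

#' Count lncRNA positional classes at both hierarchy levels
#'
#' @param classes output of [classify_position()].
#' @return tibble (`level`, `class`, `n`): the two top-level labels plus the
#'   six subtypes, so subtype counts sum to the candidate count.
#' @export
summarize_lnc_classes <- function(classes) {
  bind_rows(
    classes |> count(class = .data$top_level) |>
      mutate(level = "top_level"),
    classes |> count(class = .data$subtype) |>
      mutate(level = "subtype")) |>
    select("level", "class", "n")
}
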