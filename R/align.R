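# Seed-weighted duplex alignment and whole-transcript target scanning.

#' Align a miRNA against a target window
#'
#' Computes the best local alignment of the reversed miRNA against the
#' target under complementarity scoring (A:U and G:C score `match`, G:U
#' scores `gu_wobble`, anything else `mismatch`), with affine gap penalties
#' and every column that consumes a miRNA seed position (positions
#' `seed_start`..`seed_end` from the 5' end) scaled by `seed_scale`. This is
#' the alignment stage of miRanda-style target prediction: the miRNA pairs
#' antiparallel to its site, so reversing the miRNA lets a standard local
#' DP find the duplex.
#'
#' @param mirna miRNA sequence, 5' to 3' (16-24 nt).
#' @param target target sequence window, 5' to 3'.
#' @param params a [scoring_params()] object.
#' @return one-row tibble with `score`, `trace` (columns `|` pair, `:`
#'   wobble, `.` mismatch, `-` miRNA base unpaired, `^` target base
#'   unpaired), `energy` (from [duplex_energy()]), the 0-based half-open
#'   `target_start`/`target_end` interval and `q_start` (offset of the
#'   alignment on the reversed miRNA). A score of 0 means no positive-
#'   scoring local alignment exists; the trace is then empty.
#' @seealso [scan_targets()] for scanning full-length transcripts.
#' @export
#' @examples
#' align_duplex("UGAGGUAGUAGGUUGUAUAGU",
#'              reverse_complement_rna("UGAGGUAGUAGGUUGUAUAGU"))
align_duplex <- function(mirna, target, params = scoring_params()) {
  mirna <- normalize_rna(mirna)
  target <- normalize_rna(target)
  if (nchar(mirna) < 1 || nchar(target) < 1)
    abort("both sequences must be non-empty")
  qr <- paste(rev(strsplit(mirna, "")[[1]]), collapse = "")
  res <- duplex_align_cpp(qr, target, params$match, params$gu_wobble,
                          params$mismatch, params$gap_open,
                          params$gap_extend, params$seed_scale,
                          params$seed_start, params$seed_end)
  energy <- duplex_energy(res$trace, mirna, target,
                          q_start = res$q_start, t_start = res$t_start,
                          params = params)
  tibble(score = res$score, trace = res$trace, energy = energy,
         target_start = res$t_start, target_end = res$t_end,
         q_start = res$q_start, q_end = res$q_end)
}

#' Scan miRNAs against target transcripts for binding sites
#'
#' Slides a window of `2 * nchar(mirna) + 10` nt (step: half a window) over
#' every target, aligns the miRNA into each window with [align_duplex()],
#' and keeps sites passing both filters: alignment score `>= score_min` and
#' duplex energy `<= energy_max`. Hits found in overlapping windows at the
#' same target interval are deduplicated keeping the best score.
#'
#' @param mirnas,targets sequences: a named character vector, a
#'   `tibble(id, seq)`, a `Biostrings::XStringSet`, or a FASTA path.
#' @param params a [scoring_params()] object.
#' @return tibble of hits (`mirna_id`, `target_id`, `target_start`,
#'   `target_end` 0-based half-open on the target, `score`, `energy`,
#'   `trace`), ordered by (`target_id`, `target_start`, `mirna_id`).
#' @export
scan_targets <- function(mirnas, targets, params = scoring_params()) {
  mirnas <- as_seq_tbl(mirnas)
  targets <- as_seq_tbl(targets)
  if (nrow(mirnas) == 0 || nrow(targets) == 0)
    abort("`mirnas` and `targets` must be non-empty")

  out <- vector("list", nrow(mirnas) * nrow(targets))
  k <- 0L
  for (mi in seq_len(nrow(mirnas))) {
    m_seq <- mirnas$seq[mi]
    q_rev <- paste(rev(strsplit(m_seq, "")[[1]]), collapse = "")
    win <- 2L * nchar(m_seq) + 10L
    step <- max(1L, win %/% 2L)
    for (ti in seq_len(nrow(targets))) {
      t_seq <- targets$seq[ti]
      cand <- scan_windows_cpp(q_rev, t_seq, win, step, params$match,
                               params$gu_wobble, params$mismatch,
                               params$gap_open, params$gap_extend,
                               params$seed_scale, params$seed_start,
                               params$seed_end, params$score_min)
      if (nrow(cand) == 0) next
      cand <- as_tibble(cand)
      cand$energy <- vapply(seq_len(nrow(cand)), function(r)
        duplex_energy(cand$trace[r], m_seq, t_seq,
                      q_start = cand$q_start[r],
                      t_start = cand$target_start[r], params = params),
        double(1))
      cand <- cand |> filter(.data$energy <= params$energy_max)
      if (nrow(cand) > 0) {
        k <- k + 1L
        cand$mirna_id <- mirnas$id[mi]
        cand$target_id <- targets$id[ti]
        out[[k]] <- cand
      }
    }
  }
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0) {
    return(tibble(mirna_id = character(), target_id = character(),
                  target_start = integer(), target_end = integer(),
                  score = double(), energy = double(), trace = character()))
  }
  hits |>
    group_by(.data$mirna_id, .data$target_id, .data$target_start,
             .data$target_end) |>
    arrange(desc(.data$score), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("mirna_id", "target_id", "target_start", "target_end",
           "score", "energy", "trace") |>
    arrange(.data$target_id, .data$target_start, .data$mirna_id)
}
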