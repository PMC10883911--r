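# Scoring parameters and the nearest-neighbor duplex energy model.

# Simplified Turner-like nearest-neighbor stacking table (kcal/mol) over the
# six RNA base pairs (Watson-Crick plus G:U wobble). A pair is coded by the
# miRNA base followed by the target base; entry [p1, p2] is the free-energy
# contribution of pair p2 stacking on pair p1 along consecutive paired
# columns of a duplex. All entries are <= 0 so extending a helix never
# raises the energy; wobble-containing stacks are the weakest. This is a
# deliberately reduced model (no dangles, no sequence-dependent loops): its
# job is to rank duplexes by stacking content under the conventional
# "energy <= -10 kcal/mol" site filter, not to reproduce full folding
# thermodynamics.
duplex_stack_table <- function() {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  m <- matrix(c(
    # AU     UA     GC     CG     GU     UG
    -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # AU
    -1.33, -0.93, -2.35, -2.11, -1.27, -1.00,  # UA
    -2.08, -2.11, -3.26, -2.36, -1.41, -2.11,  # GC
    -2.24, -2.35, -3.42, -3.26, -1.53, -2.51,  # CG
    -1.36, -1.00, -2.51, -2.11, -0.50, -1.22,  # GU
    -0.55, -1.27, -1.53, -1.41, -0.30, -0.50   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  m
}

#' Scoring parameters for miRNA target-site scanning
#'
#' Bundles the constants of the seed-weighted local complementarity
#' alignment and the duplex energy filter. The per-column scores follow the
#' miRanda defaults (match +5, G:U wobble +2, mismatch -3, affine gaps
#' -9/-4, with every column consuming a miRNA seed position -- positions
#' 2-8 from the 5' end -- scaled by 4). The two retention cutoffs,
#' `score_min = 145` and `energy_max = -10` kcal/mol, are the conventional
#' site filters.
#'
#' @param match,gu_wobble,mismatch per-column substitution scores.
#' @param gap_open,gap_extend affine gap penalties (first / subsequent gap
#'   column of a run).
#' @param seed_scale multiplier applied to columns consuming miRNA seed
#'   positions.
#' @param seed_start,seed_end 1-based seed interval on the miRNA, 5' to 3'.
#' @param score_min minimum alignment score for a reported hit.
#' @param energy_max maximum duplex free energy (kcal/mol) for a reported
#'   hit; must be negative.
#' @param loop_penalty energy added per maximal run of unpaired or gapped
#'   columns inside an alignment.
#' @return an object of class `cerna_scoring` (a named list).
#' @export
#' @examples
#' scoring_params(score_min = 120)
scoring_params <- function(match = 5, gu_wobble = 2, mismatch = -3,
                           gap_open = -9, gap_extend = -4, seed_scale = 4,
                           seed_start = 2, seed_end = 8, score_min = 145,
                           energy_max = -10, loop_penalty = 3) {
  if (score_min <= 0) abort("`score_min` must be positive")
  if (energy_max >= 0) abort("`energy_max` must be negative")
  if (seed_start < 1 || seed_end < seed_start)
    abort("seed interval must satisfy 1 <= seed_start <= seed_end")
  structure(
    list(match = match, gu_wobble = gu_wobble, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend,
         seed_scale = seed_scale, seed_start = seed_start,
         seed_end = seed_end, score_min = score_min,
         energy_max = energy_max, loop_penalty = loop_penalty,
         stack_table = duplex_stack_table()),
    class = "cerna_scoring")
}

#' Nearest-neighbor duplex free energy of an alignment trace
#'
#' Walks an alignment trace from [align_duplex()] and sums nearest-neighbor
#' stacking energies over consecutive paired columns (`|` Watson-Crick, `:`
#' G:U wobble), adding `loop_penalty` for each maximal run of mismatch or
#' gap columns (`.`, `-`, `^`). More stacked pairs therefore always means a
#' lower (more favourable) energy.
#'
#' @param trace alignment trace string.
#' @param mirna miRNA sequence, 5' to 3' (full sequence; the aligned
#'   segment is located with `q_start`).
#' @param target target window the alignment was computed against.
#' @param q_start,t_start 0-based offsets of the alignment start on the
#'   reversed miRNA and on the target window, as returned by
#'   [align_duplex()].
#' @param params a [scoring_params()] object.
#' @return duplex free energy in kcal/mol (0 for an empty trace).
#' @export
duplex_energy <- function(trace, mirna, target, q_start = 0, t_start = 0,
                          params = scoring_params()) {
  if (is.na(trace) || nchar(trace) == 0) return(0)
  mirna <- normalize_rna(mirna)
  target <- normalize_rna(target)
  qr <- strsplit(paste(rev(strsplit(mirna, "")[[1]]), collapse = ""), "")[[1]]
  tg <- strsplit(target, "")[[1]]
  cols <- strsplit(trace, "")[[1]]
  qi <- q_start
  ti <- t_start
  pair_of <- character(length(cols))
  paired <- logical(length(cols))
  for (k in seq_along(cols)) {
    c_k <- cols[k]
    if (c_k %in% c("|", ":", ".")) {
      qi <- qi + 1
      ti <- ti + 1
      if (qi > length(qr) || ti > length(tg))
        abort("trace is longer than the sequences it annotates")
      if (c_k != ".") {
        paired[k] <- TRUE
        pair_of[k] <- paste0(qr[qi], tg[ti])
      }
    } else if (c_k == "-") {
      qi <- qi + 1
    } else if (c_k == "^") {
      ti <- ti + 1
    } else {
      abort(paste0("unknown trace character `", c_k, "`"))
    }
  }
  st <- params$stack_table
  dg <- 0
  for (k in seq_len(length(cols) - 1)) {
    if (paired[k] && paired[k + 1])
      dg <- dg + st[pair_of[k], pair_of[k + 1]]
  }
  runs <- rle(paired)
  dg + params$loop_penalty * sum(!runs$values)
}
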