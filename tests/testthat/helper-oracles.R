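# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementations in R/ or src/.

# Plain-R Gotoh local alignment score with the same stated semantics as the
# compiled DP: reversed miRNA vs target, complementarity scoring, affine
# gaps, seed columns (original miRNA positions seed_start..seed_end) scaled,
# gap-in-target columns weighted by the consumed miRNA position's weight,
# gap-in-miRNA columns unweighted, X from {M,X}, Y from {M,Y}.
naive_align_score <- function(mirna, target, p = scoring_params()) {
  qr <- rev(strsplit(mirna, "")[[1]])
  tg <- strsplit(target, "")[[1]]
  m <- length(qr)
  n <- length(tg)
  orig <- m - seq_len(m) + 1
  w <- ifelse(orig >= p$seed_start & orig <= p$seed_end, p$seed_scale, 1)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  sub <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    sub[i, j] <- if (comp[[qr[i]]] == tg[j]) p$match
    else if ((qr[i] == "G" && tg[j] == "U") ||
             (qr[i] == "U" && tg[j] == "G")) p$gu_wobble
    else p$mismatch
  }
  M <- X <- Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + w[i] * sub[i, j]
    X[i + 1, j + 1] <- max(M[i, j + 1] + w[i] * p$gap_open,
                           X[i, j + 1] + w[i] * p$gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + p$gap_open,
                           Y[i + 1, j] + p$gap_extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Brute-force 3-frame ORF scanner: every AUG, walk codon by codon to the
# first in-frame stop; length excludes the stop codon.
brute_orf <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  n <- nchar(s)
  best <- 0L
  aug <- gregexpr("AUG", s, fixed = TRUE)[[1]]
  aug <- aug[aug > 0]
  for (a in aug) {
    k <- a + 3L
    while (k + 2L <= n) {
      cod <- substr(s, k, k + 2L)
      if (cod %in% c("UAA", "UAG", "UGA")) {
        best <- max(best, k - a)
        break
      }
      k <- k + 3L
    }
  }
  best
}

# Second, independently coded table walk over the published TESTCODE
# position/composition tables.
fickett_oracle <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  s <- s[s %in% c("A", "C", "G", "U")]
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  cont_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    U = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, U = 0.33)
  cont_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    U = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  cont_w <- c(A = 0.11, C = 0.12, G = 0.15, U = 0.14)
  total <- 0
  for (b in c("A", "C", "G", "U")) {
    c1 <- sum(s[seq(1, length(s), 3)] == b)
    c2 <- sum(s[seq(2, length(s), 3)] == b)
    c3 <- sum(s[seq(3, length(s), 3)] == b)
    pv <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    cv <- sum(s == b) / length(s)
    total <- total +
      pos_prob[[b]][which(pv >= pos_para)[1]] * pos_w[[b]] +
      cont_prob[[b]][which(cv >= cont_para)[1]] * cont_w[[b]]
  }
  total
}

# Brute-force best ungapped percent identity of a read against a set of
# reference sequences, scanning every offset explicitly.
brute_best_identity <- function(read, refs) {
  best <- 0
  for (rf in refs) {
    for (off in seq(-nchar(read) + 1, nchar(rf) - 1)) {
      matches <- 0
      for (i in seq_len(nchar(read))) {
        j <- i + off
        if (j >= 1 && j <= nchar(rf) &&
            substr(read, i, i) == substr(rf, j, j))
          matches <- matches + 1
      }
      best <- max(best, 100 * matches / nchar(read))
    }
  }
  best
}

# Independent set-union node count for a triplet table.
node_union_oracle <- function(triplets) {
  length(unique(c(triplets$lnc_id, triplets$mir_id, triplets$mrna_id)))
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Small random triplet tables for network property tests.
random_triplets <- function(n, n_ids = 6) {
  tibble::tibble(
    lnc_id = sample(sprintf("L%d", seq_len(n_ids)), n, replace = TRUE),
    mir_id = sample(sprintf("M%d", seq_len(n_ids)), n, replace = TRUE),
    mrna_id = sample(sprintf("G%d", seq_len(n_ids)), n, replace = TRUE),
    mode = sample(c("A*", "B*"), n, replace = TRUE)) |>
    dplyr::distinct(lnc_id, mir_id, mrna_id, .keep_all = TRUE)
}
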