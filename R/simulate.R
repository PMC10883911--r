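# Synthetic-data generator with planted ground truth: annotation, sequences,
# small-RNA reads and NB count matrices carrying planted binding sites,
# planted differential expression and sponge-consistent correlation
# structure, so the whole inference chain is testable without external data.

#' Configuration for the synthetic ceRNA study
#'
#' Captures the simulated study design: feature counts per RNA class, a
#' two-group contrast with `n_samples_per_group` biological replicates
#' (default 3, a typical per-group tank size in fish stress experiments),
#' planted A*/B* sponge triplets, the planted log2 fold-change magnitude,
#' the NB dispersion, and sequence/genome sizing.
#'
#' @param seed integer seed; every generator derives its randomness from
#'   it, so identical configs give byte-identical outputs.
#' @param n_mrna,n_lncrna,n_mirna features per RNA class.
#' @param n_samples_per_group replicates per group.
#' @param groups ordered group labels; the first is the control/reference.
#' @param n_planted_A,n_planted_B planted triplets per mode (A*: lnc and
#'   mRNA up, miRNA down; B*: mirrored).
#' @param lfc_planted log2 fold-change magnitude planted into DE features.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param base_mean_range range of baseline mean counts; base means are
#'   drawn log-uniformly within it.
#' @param site_len planted binding-site length (nt); planted miRNAs get
#'   this length, background miRNAs draw 16-24 nt.
#' @param genome_len synthetic chromosome length (nt).
#' @param latent_sd standard deviation (log2 units) of the shared
#'   per-sample latent factor coupling each planted triplet (added to the
#'   lncRNA and mRNA log-means, subtracted from the miRNA log-mean).
#' @param size_factor_range per-sample library-size factor range.
#' @return a validated `cerna_sim_config` list.
#' @export
simulation_config <- function(seed = 1, n_mrna = 40, n_lncrna = 40,
                              n_mirna = 40, n_samples_per_group = 3,
                              groups = c("control", "treatment"),
                              n_planted_A = 20, n_planted_B = 20,
                              lfc_planted = 2, dispersion = 0.1,
                              base_mean_range = c(100, 1000),
                              site_len = 21, genome_len = 2e6,
                              latent_sd = 1,
                              size_factor_range = c(0.8, 1.25)) {
  cfg <- list(seed = as.integer(seed), n_mrna = n_mrna,
              n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_samples_per_group = n_samples_per_group, groups = groups,
              n_planted_A = n_planted_A, n_planted_B = n_planted_B,
              lfc_planted = lfc_planted, dispersion = dispersion,
              base_mean_range = base_mean_range, site_len = site_len,
              genome_len = genome_len, latent_sd = latent_sd,
              size_factor_range = size_factor_range)
  counts <- c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna, cfg$n_planted_A,
              cfg$n_planted_B, cfg$n_samples_per_group)
  if (any(counts < 0)) abort("all feature/sample counts must be >= 0")
  if (cfg$n_planted_A + cfg$n_planted_B >
      min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna))
    abort("planted triplets exceed the smallest feature class")
  if (cfg$lfc_planted <= 0) abort("`lfc_planted` must be positive")
  if (cfg$dispersion <= 0) abort("`dispersion` must be positive")
  if (length(cfg$groups) < 2) abort("need a control and >= 1 treatment group")
  structure(cfg, class = "cerna_sim_config")
}

#' Plant the ground truth of a synthetic ceRNA study
#'
#' Fixes feature ids and lengths, assigns the planted A*/B* triplets with
#' their mode-consistent DE signs (A*: lnc +1, mRNA +1, miRNA -1; B*
#' mirrored; unplanted features 0), and records exactly one binding-site
#' interval per planted (miRNA, target) pair, on both the lncRNA and the
#' mRNA of the triplet.
#'
#' @param config a [simulation_config()].
#' @return list with `triplets`, `features` (id, class, length, de_sign),
#'   `sites` (`mirna_id`, `target_id`, `start`, `end`, 0-based half-open)
#'   and the config; deterministic given the config seed.
#' @export
plant_truth <- function(config = simulation_config()) {
  with_seed(config$seed, {
    n_pl <- config$n_planted_A + config$n_planted_B
    feats <- bind_rows(
      tibble(feature_id = sprintf("mrna_%03d", seq_len(config$n_mrna)),
             class = "mrna",
             length = sample(900:1800, config$n_mrna, replace = TRUE)),
      tibble(feature_id = sprintf("lnc_%03d", seq_len(config$n_lncrna)),
             class = "lncrna",
             length = sample(600:1400, config$n_lncrna, replace = TRUE)),
      tibble(feature_id = sprintf("mir_%03d", seq_len(config$n_mirna)),
             class = "mirna",
             length = sample(16:24, config$n_mirna, replace = TRUE)))
    feats$length[feats$class == "mirna"][seq_len(n_pl)] <- config$site_len

    triplets <- tibble(
      lnc_id = sprintf("lnc_%03d", seq_len(n_pl)),
      mir_id = sprintf("mir_%03d", seq_len(n_pl)),
      mrna_id = sprintf("mrna_%03d", seq_len(n_pl)),
      mode = rep(c("A*", "B*"),
                 c(config$n_planted_A, config$n_planted_B)))

    sign_of <- function(ids, up_ids, down_ids)
      ifelse(ids %in% up_ids, 1L, ifelse(ids %in% down_ids, -1L, 0L))
    a <- triplets |> filter(.data$mode == "A*")
    b <- triplets |> filter(.data$mode == "B*")
    feats$de_sign <- sign_of(
      feats$feature_id,
      up_ids = c(a$lnc_id, a$mrna_id, b$mir_id),
      down_ids = c(b$lnc_id, b$mrna_id, a$mir_id))

    len_of <- setNames(feats$length, feats$feature_id)
    site_at <- function(target_id, lo) {
      hi <- len_of[[target_id]] - config$site_len - 50
      if (hi < lo)
        abort(paste0("target `", target_id,
                     "` too short for a planted site"))
      s <- sample(lo:hi, 1)
      tibble(target_id = target_id, start = s, end = s + config$site_len)
    }
    sites <- purrr::map_dfr(seq_len(nrow(triplets)), function(i) {
      bind_rows(
        site_at(triplets$lnc_id[i], lo = 50) |>
          mutate(mirna_id = triplets$mir_id[i], target_class = "lncrna"),
        site_at(triplets$mrna_id[i], lo = 520) |>  # downstream of the ORF
          mutate(mirna_id = triplets$mir_id[i], target_class = "mrna"))
    })
    if (nrow(sites) == 0) {
      sites <- tibble(mirna_id = character(), target_id = character(),
                      target_class = character(), start = integer(),
                      end = integer())
    }
    sites <- select(sites, "mirna_id", "target_id", "target_class",
                    "start", "end")

    list(triplets = triplets, features = feats, sites = sites,
         config = config)
  })
}

# Split a spliced length into n_exons exon intervals evenly spread over
# [span_start, span_end); returns a tibble of 0-based half-open exons.
place_exons <- function(span_start, span_end, spliced_len, n_exons) {
  span <- span_end - span_start
  stopifnot(span >= spliced_len + n_exons - 1)
  ex_len <- rep(spliced_len %/% n_exons, n_exons)
  ex_len[n_exons] <- ex_len[n_exons] + spliced_len %% n_exons
  gap_total <- span - spliced_len
  gaps <- if (n_exons > 1)
    rep(gap_total %/% (n_exons - 1), n_exons - 1) else integer(0)
  if (n_exons > 1)
    gaps[n_exons - 1] <- gaps[n_exons - 1] + gap_total %% (n_exons - 1)
  starts <- span_start + cumsum(c(0, head(ex_len, -1) + gaps))
  tibble(start = starts, end = starts + ex_len)
}

#' Simulate a gene annotation with candidates in every positional class
#'
#' Lays out the mRNA genes of the configured study along one synthetic
#' chromosome (three exons each, alternating strands, wide intergenic
#' gaps) and places one candidate transcript per configured lncRNA,
#' cycling through the six positional classes (`containing`, `nested`,
#' `overlapping`, `same_strand`, `convergent`, `divergent`) so that, with
#' at least six candidates, both top-level labels and all six subtypes are
#' represented. Three filter fixtures are always appended: a 150 nt
#' candidate, a 500 nt single-exon candidate and an 800 nt
#' protein-coding decoy.
#'
#' @param config a [simulation_config()].
#' @param truth optional [plant_truth()] result (recomputed from the
#'   config when missing).
#' @return list with `genes` (gene spans), `transcripts` (exon-level
#'   table covering mRNAs and candidates) and `candidates` (intended
#'   class per candidate); deterministic given the config seed.
#' @export
simulate_annotation <- function(config = simulation_config(),
                                truth = NULL) {
  if (is.null(truth)) truth <- plant_truth(config)
  with_seed(config$seed + 1L, {
    feats <- truth$features
    mrna <- feats |> filter(.data$class == "mrna")
    lnc <- feats |> filter(.data$class == "lncrna")
    gap <- 12000L
    intron <- 500L

    pos <- 5000L
    genes <- purrr::map_dfr(seq_len(nrow(mrna)), function(i) {
      span <- mrna$length[i] + 2L * intron
      g <- tibble(gene_id = mrna$feature_id[i], chrom = "chr1",
                  strand = if (i %% 2 == 1) "+" else "-",
                  start = pos, end = pos + span)
      pos <<- pos + span + gap
      g
    })
    if (pos > config$genome_len)
      abort(paste0("genome_len = ", config$genome_len, " cannot fit ",
                   nrow(mrna), " genes; need >= ", pos))

    tx_mrna <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      place_exons(genes$start[i], genes$end[i], mrna$length[i], 3L) |>
        mutate(transcript_id = mrna$feature_id[i],
               gene_id = genes$gene_id[i], type = "mRNA",
               chrom = "chr1", strand = genes$strand[i])
    })

    classes <- c("containing", "nested", "overlapping", "same_strand",
                 "convergent", "divergent")
    tx_cand <- list()
    cand_info <- list()
    for (i in seq_len(nrow(lnc))) {
      cls <- classes[(i - 1) %% 6 + 1]
      gi <- (i - 1) %% nrow(genes) + 1
      wrap <- (i - 1) %/% nrow(genes)  # spread out repeat visits to a gene
      off <- 400L + 700L * wrap
      g <- genes[gi, ]
      len <- lnc$length[i]
      n_ex <- 2L + i %% 2L
      flank <- 150L * (n_ex - 1L)
      strand <- g$strand
      if (cls == "containing") {
        ls <- g$start - 400L - flank
        le <- g$end + 400L
      } else if (cls == "nested") {
        ls <- g$start + 100L
        le <- ls + len + flank + 50L
      } else if (cls == "overlapping") {
        span <- len + flank + 50L
        ls <- g$start - span %/% 2L
        le <- ls + span
      } else {
        span <- len + flank + 50L
        side_right <- switch(cls,
          same_strand = TRUE,
          convergent = g$strand == "+",
          divergent = g$strand == "-")
        strand <- switch(cls,
          same_strand = g$strand,
          convergent = if (g$strand == "+") "-" else "+",
          divergent = if (g$strand == "+") "-" else "+")
        if (side_right) {
          ls <- g$end + off
          le <- ls + span
        } else {
          le <- g$start - off
          ls <- le - span
        }
      }
      tx_cand[[i]] <- place_exons(ls, le, len, n_ex) |>
        mutate(transcript_id = lnc$feature_id[i], gene_id = NA_character_,
               type = "candidate", chrom = "chr1", strand = strand)
      cand_info[[i]] <- tibble(transcript_id = lnc$feature_id[i],
                               intended_class = cls,
                               partner_gene = g$gene_id,
                               length = len, n_exons = n_ex)
    }

    # filter fixtures: short, single-exon, and coding decoys
    base <- genes$end[1]
    fixtures <- list(
      list(id = "cand_short", len = 150L, n_ex = 2L, at = base + 5000L),
      list(id = "cand_monoexon", len = 500L, n_ex = 1L, at = base + 7000L),
      list(id = "cand_coding", len = 800L, n_ex = 2L, at = base + 9000L))
    for (f in fixtures) {
      span <- f$len + 150L * (f$n_ex - 1L) + 50L
      tx_cand[[length(tx_cand) + 1]] <-
        place_exons(f$at, f$at + span, f$len, f$n_ex) |>
        mutate(transcript_id = f$id, gene_id = NA_character_,
               type = "candidate", chrom = "chr1", strand = "+")
      cand_info[[length(cand_info) + 1]] <-
        tibble(transcript_id = f$id, intended_class = NA_character_,
               partner_gene = NA_character_, length = f$len,
               n_exons = f$n_ex)
    }

    transcripts <- bind_rows(tx_mrna, bind_rows(tx_cand)) |>
      select("transcript_id", "gene_id", "type", "chrom", "strand",
             "start", "end")
    list(genes = genes, transcripts = transcripts,
         candidates = bind_rows(cand_info))
  })
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random open reading frame of n_codons sense codons flanked by AUG / UAA.
random_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "U")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, c("UAA", "UAG", "UGA"))
  paste0("AUG", paste(sample(sense, n_codons, replace = TRUE),
                      collapse = ""), "UAA")
}

insert_at <- function(seq, sub, start) {  # 0-based start
  paste0(substr(seq, 1, start), sub,
         substr(seq, start + nchar(sub) + 1, nchar(seq)))
}

#' Simulate transcript and miRNA sequences with planted binding sites
#'
#' Background sequence is uniform-random RNA. Every planted (miRNA,
#' target) pair's target carries the exact reverse complement of the miRNA
#' at its recorded site interval. mRNA sequences additionally carry a long
#' planted open reading frame (so they assess as coding), while lncRNA
#' candidates are redrawn until they assess as noncoding under the default
#' coding-potential heuristic, mimicking real lncRNA sequence properties.
#' The `cand_coding` fixture gets an ORF, the other fixtures stay random.
#'
#' @param truth a [plant_truth()] result.
#' @param config the matching [simulation_config()].
#' @return list of `tibble(id, seq)` tables: `mirna`, `lncrna`, `mrna`,
#'   `fixtures`, and `candidates` (lncRNA candidates plus fixtures, the
#'   discovery input); RNA alphabet throughout.
#' @export
simulate_sequences <- function(truth, config = truth$config) {
  with_seed(config$seed + 2L, {
    feats <- truth$features
    len_of <- setNames(feats$length, feats$feature_id)

    mirna <- feats |> filter(.data$class == "mirna")
    mir_tbl <- tibble(id = mirna$feature_id,
                      seq = vapply(mirna$length, random_rna, character(1)))
    mir_seq <- setNames(mir_tbl$seq, mir_tbl$id)

    plant_sites <- function(id, seq) {
      s <- truth$sites |> filter(.data$target_id == id)
      for (k in seq_len(nrow(s))) {
        if (s$end[k] > nchar(seq))
          abort(paste0("site interval exceeds length of `", id, "`"))
        seq <- insert_at(seq, reverse_complement_rna(mir_seq[[s$mirna_id[k]]]),
                         s$start[k])
      }
      seq
    }

    noncoding_draw <- function(id, len, max_tries = 200) {
      for (try in seq_len(max_tries)) {
        seq <- plant_sites(id, random_rna(len))
        if (longest_orf_one(seq) < 300 && fickett_score_one(seq) < 0.95)
          return(seq)
      }
      abort(paste0("could not draw a noncoding background for `", id, "`"))
    }

    lnc <- feats |> filter(.data$class == "lncrna")
    lnc_tbl <- tibble(
      id = lnc$feature_id,
      seq = vapply(seq_len(nrow(lnc)), function(i)
        noncoding_draw(lnc$feature_id[i], lnc$length[i]), character(1)))

    mrna <- feats |> filter(.data$class == "mrna")
    mrna_tbl <- tibble(
      id = mrna$feature_id,
      seq = vapply(seq_len(nrow(mrna)), function(i) {
        seq <- insert_at(random_rna(mrna$length[i]), random_orf(150), 30)
        plant_sites(mrna$feature_id[i], seq)
      }, character(1)))

    fixtures <- tibble(
      id = c("cand_short", "cand_monoexon", "cand_coding"),
      seq = c(random_rna(150), random_rna(500),
              insert_at(random_rna(800), random_orf(150), 30)))

    list(mirna = mir_tbl, lncrna = lnc_tbl, mrna = mrna_tbl,
         fixtures = fixtures,
         candidates = bind_rows(lnc_tbl, fixtures))
  })
}

#' Simulate NB count matrices with planted DE and sponge correlation
#'
#' Counts are negative binomial with dispersion `config$dispersion`.
#' Baseline means are log-uniform over `base_mean_range`; planted-DE
#' features have their log2 mean shifted by `+/- lfc_planted` in every
#' treatment group; within each planted triplet a shared per-sample latent
#' factor (sd `latent_sd`, log2 units) is added to the lncRNA and mRNA
#' log-means and subtracted from the miRNA log-mean, so lnc-mRNA
#' correlation is positive and lnc-miRNA / miRNA-mRNA correlations are
#' negative in expectation. Unplanted features are independent nulls.
#'
#' @param truth a [plant_truth()] result.
#' @param config the matching [simulation_config()].
#' @return list with wide count tibbles `mrna`, `lncrna`, `mirna`;
#'   `samples` (`sample_id`, `group`); the true per-sample
#'   `size_factors`; and the latent factor matrix (triplet x sample).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  with_seed(config$seed + 3L, {
    feats <- truth$features
    groups <- config$groups
    n_s <- config$n_samples_per_group
    samples <- tibble(
      sample_id = paste0(rep(groups, each = n_s), "_",
                         rep(seq_len(n_s), length(groups))),
      group = rep(groups, each = n_s))
    is_trt <- samples$group != groups[1]
    sf <- runif(nrow(samples), config$size_factor_range[1],
                config$size_factor_range[2])
    names(sf) <- samples$sample_id

    base <- 2^runif(nrow(feats), log2(config$base_mean_range[1]),
                    log2(config$base_mean_range[2]))
    names(base) <- feats$feature_id

    latent <- matrix(rnorm(nrow(truth$triplets) * nrow(samples), 0,
                           config$latent_sd),
                     nrow = nrow(truth$triplets), ncol = nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    coupling <- matrix(0, nrow(feats), nrow(samples),
                       dimnames = list(feats$feature_id,
                                       samples$sample_id))
    for (t in seq_len(nrow(truth$triplets))) {
      tr <- truth$triplets[t, ]
      coupling[tr$lnc_id, ] <- coupling[tr$lnc_id, ] + latent[t, ]
      coupling[tr$mrna_id, ] <- coupling[tr$mrna_id, ] + latent[t, ]
      coupling[tr$mir_id, ] <- coupling[tr$mir_id, ] - latent[t, ]
    }

    log2mu <- matrix(log2(base), nrow(feats), nrow(samples)) +
      outer(feats$de_sign * config$lfc_planted, as.numeric(is_trt)) +
      coupling
    mu <- sweep(2^log2mu, 2, sf, "*")
    if (any(!is.finite(mu))) abort("non-finite NB mean generated")
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$dispersion),
                     nrow(feats), nrow(samples),
                     dimnames = dimnames(coupling))

    split_class <- function(cl) {
      ids <- feats$feature_id[feats$class == cl]
      as_count_tbl(counts[ids, , drop = FALSE])
    }
    list(mrna = split_class("mrna"), lncrna = split_class("lncrna"),
         mirna = split_class("mirna"), samples = samples,
         size_factors = sf, latent = latent)
  })
}

#' Simulate small-RNA reads from the miRNA count matrix
#'
#' Emits each mature miRNA sequence once per count in each sample, plus a
#' handful of length-outlier junk reads (15 and 26 nt) per sample that
#' read collapsing must discard.
#'
#' @param counts_mirna wide miRNA count tibble from [simulate_counts()].
#' @param mirna_seqs `tibble(id, seq)` of mature miRNA sequences.
#' @param config the matching [simulation_config()].
#' @return tibble (`sample_id`, `seq`).
#' @export
simulate_reads <- function(counts_mirna, mirna_seqs,
                           config = simulation_config()) {
  with_seed(config$seed + 4L, {
    m <- as_count_matrix(counts_mirna)
    seq_of <- setNames(mirna_seqs$seq, mirna_seqs$id)
    purrr::map_dfr(colnames(m), function(s) {
      reads <- c(rep(seq_of[rownames(m)], times = m[, s]),
                 vapply(rep(15L, 10), random_rna, character(1)),
                 vapply(rep(26L, 10), random_rna, character(1)))
      tibble(sample_id = s, seq = unname(reads))
    })
  })
}

#' Run the full synthetic-data generator
#'
#' @param config a [simulation_config()].
#' @param reads also simulate small-RNA reads (set `FALSE` to skip the
#'   read-level stage and use the miRNA count matrix directly).
#' @return a `cerna_sim` list: `config`, `truth`, `annotation`,
#'   `sequences`, `counts` and (optionally) `reads`.
#' @export
simulate_cerna <- function(config = simulation_config(), reads = TRUE) {
  truth <- plant_truth(config)
  ann <- simulate_annotation(config, truth)
  seqs <- simulate_sequences(truth, config)
  cnts <- simulate_counts(truth, config)
  rds <- if (reads) simulate_reads(cnts$mirna, seqs$mirna, config)
  structure(list(config = config, truth = truth, annotation = ann,
                 sequences = seqs, counts = cnts, reads = rds),
            class = "cerna_sim")
}
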