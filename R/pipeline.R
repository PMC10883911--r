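# End-to-end orchestration: simulate -> discover lncRNAs -> quantify
# miRNAs -> scan targets -> differential expression -> co-expression ->
# triplet assembly -> export, with per-stage artifacts and a manifest.

pipeline_stages <- c("simulate", "discover", "quantify", "scan", "de",
                     "correlate", "assemble", "export")

#' Pipeline configuration
#'
#' Bundles every stage threshold (all at the conventional defaults: keep
#' transcripts >= 200 nt with >= 2 exons, coding-potential cutoffs 300 nt /
#' 0.95, mature-miRNA identity >= 95 %, site filters score >= 145 and
#' energy <= -10 kcal/mol, DE filters p <= 0.05 and |log2FC| >= 0.5,
#' co-expression filters |r| >= 0.94 and p <= 0.05) together with the
#' synthetic-study design and the stage list.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param sim a [simulation_config()]; its seed is overridden by `seed`.
#' @param stages subset of
#'   `c("simulate","discover","quantify","scan","de","correlate",
#'   "assemble","export")` to run, in dependency order.
#' @param min_len,min_exons candidate filter thresholds.
#' @param orf_min,fickett_min coding-potential cutoffs.
#' @param min_identity mature miRNA assignment cutoff (percent).
#' @param scoring a [scoring_params()] object.
#' @param p_max,lfc_min DE call thresholds.
#' @param r_min,corr_p_max co-expression pass thresholds.
#' @param use_reads quantify miRNAs from simulated reads (otherwise the
#'   simulated miRNA count matrix is used directly).
#' @param require_correlation demand sign-consistent correlation edges
#'   during triplet assembly.
#' @return a `cerna_pipeline_config` list.
#' @export
cerna_pipeline_config <- function(seed = 1, sim = simulation_config(),
                                  stages = pipeline_stages,
                                  min_len = 200, min_exons = 2,
                                  orf_min = 300, fickett_min = 0.95,
                                  min_identity = 95,
                                  scoring = scoring_params(),
                                  p_max = 0.05, lfc_min = 0.5,
                                  r_min = 0.94, corr_p_max = 0.05,
                                  use_reads = TRUE,
                                  require_correlation = TRUE) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, stages = stages,
                 min_len = min_len, min_exons = min_exons,
                 orf_min = orf_min, fickett_min = fickett_min,
                 min_identity = min_identity, scoring = scoring,
                 p_max = p_max, lfc_min = lfc_min, r_min = r_min,
                 corr_p_max = corr_p_max, use_reads = use_reads,
                 require_correlation = require_correlation),
            class = "cerna_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [cerna_pipeline_config()] arguments; the `sim`
#' and `scoring` keys hold nested maps forwarded to [simulation_config()]
#' and [scoring_params()].
#'
#' @param path YAML file.
#' @return a `cerna_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "scoring"))]
  if (!is.null(y$sim))
    args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$scoring))
    args$scoring <- do.call(scoring_params, y$scoring)
  do.call(cerna_pipeline_config, args)
}

#' Run the ceRNA inference pipeline end to end
#'
#' Executes the configured stages in dependency order on synthetic data
#' with planted ground truth, writing each stage's tables under `outdir`
#' (TSV; annotation as GTF, sequences as FASTA, networks as SIF/GraphML)
#' before the next stage starts, plus a machine-readable JSON manifest of
#' seed, thresholds and per-stage counts. Reruns with an identical config
#' reproduce identical outputs.
#'
#' @param config a [cerna_pipeline_config()].
#' @param outdir output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @return list with the per-stage results (`sim`, `discovery`,
#'   `mirna_counts`, `hits_lnc`, `hits_mrna`, `de`, `edges`, `triplets`,
#'   `summary`, `recovery`, `manifest`).
#' @export
run_cerna_pipeline <- function(config = cerna_pipeline_config(),
                               outdir = NULL) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  st <- config$stages
  res <- list()
  manifest <- list(tool = "cernakit",
                   version = as.character(utils::packageVersion("cernakit")),
                   seed = config$seed,
                   stages = st,
                   thresholds = list(
                     min_len = config$min_len, min_exons = config$min_exons,
                     orf_min = config$orf_min,
                     fickett_min = config$fickett_min,
                     min_identity = config$min_identity,
                     score_min = config$scoring$score_min,
                     energy_max = config$scoring$energy_max,
                     p_max = config$p_max, lfc_min = config$lfc_min,
                     r_min = config$r_min, corr_p_max = config$corr_p_max),
                   counts = list())
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      abort(paste0("stage `", stage, "` needs output of an earlier stage (`",
                   what, "`) that was not run"))
    res[[what]]
  }

  if ("simulate" %in% st) {
    sim <- simulate_cerna(config$sim, reads = config$use_reads)
    res$sim <- sim
    manifest$counts$simulate <- list(
      n_mrna = config$sim$n_mrna, n_lncrna = config$sim$n_lncrna,
      n_mirna = config$sim$n_mirna,
      n_planted_triplets = nrow(sim$truth$triplets),
      n_reads = if (is.null(sim$reads)) 0L else nrow(sim$reads))
    if (!is.null(outdir)) {
      write_gtf(sim$annotation, file.path(outdir, "annotation.gtf"))
      write_fasta(sim$sequences$mirna, file.path(outdir, "mirna.fasta"))
      write_fasta(sim$sequences$candidates,
                  file.path(outdir, "candidates.fasta"))
      write_fasta(sim$sequences$mrna, file.path(outdir, "mrna.fasta"))
      write_stage_tsv(sim$counts$mrna, outdir, "counts_mrna")
      write_stage_tsv(sim$counts$lncrna, outdir, "counts_lncrna")
      write_stage_tsv(sim$counts$mirna, outdir, "counts_mirna")
      write_stage_tsv(sim$truth$triplets, outdir, "truth_triplets")
      write_stage_tsv(sim$truth$features, outdir, "truth_features")
      write_stage_tsv(sim$truth$sites, outdir, "truth_sites")
    }
    inform(paste0("[simulate] ", nrow(sim$truth$features), " features, ",
                  nrow(sim$truth$triplets), " planted triplets"))
  }

  if ("discover" %in% st) {
    sim <- need("sim", "discover")
    cand_tx <- sim$annotation$transcripts |> filter(.data$type == "candidate")
    kept_tx <- filter_candidates(cand_tx, config$min_len, config$min_exons)
    kept_ids <- unique(kept_tx$transcript_id)
    seqs <- sim$sequences$candidates |> filter(.data$id %in% kept_ids)
    cp <- assess_coding_potential(seqs, config$orf_min, config$fickett_min)
    lnc_ids <- cp$id[cp$verdict == "noncoding"]
    classes <- classify_position(kept_tx |>
                                   filter(.data$transcript_id %in% lnc_ids),
                                 sim$annotation$genes)
    res$discovery <- list(candidates = unique(cand_tx$transcript_id),
                          kept = kept_ids, coding_potential = cp,
                          lnc_ids = lnc_ids, classes = classes,
                          class_summary = summarize_lnc_classes(classes))
    manifest$counts$discover <- list(
      candidates_in = length(res$discovery$candidates),
      after_length_exon_filter = length(kept_ids),
      noncoding = length(lnc_ids))
    write_stage_tsv(classes, outdir, "lnc_classes")
    write_stage_tsv(res$discovery$class_summary, outdir,
                    "lnc_class_summary")
    inform(paste0("[discover] ", length(res$discovery$candidates),
                  " candidates -> ", length(kept_ids),
                  " past length/exon filter -> ", length(lnc_ids),
                  " noncoding lncRNAs"))
  }

  if ("quantify" %in% st) {
    sim <- need("sim", "quantify")
    mirna_counts <- if (config$use_reads && !is.null(sim$reads)) {
      quantify_mirnas(sim$reads, sim$sequences$mirna, config$min_identity)
    } else {
      sim$counts$mirna
    }
    res$mirna_counts <- mirna_counts
    manifest$counts$quantify <- list(
      n_mirna = nrow(mirna_counts),
      total_counts = sum(as_count_matrix(mirna_counts)))
    write_stage_tsv(mirna_counts, outdir, "mirna_quantified")
    inform(paste0("[quantify] ", nrow(mirna_counts), " mature miRNAs"))
  }

  if ("scan" %in% st) {
    sim <- need("sim", "scan")
    disc <- need("discovery", "scan")
    lnc_seqs <- sim$sequences$candidates |>
      filter(.data$id %in% disc$lnc_ids)
    res$hits_lnc <- scan_targets(sim$sequences$mirna, lnc_seqs,
                                 config$scoring)
    res$hits_mrna <- scan_targets(sim$sequences$mirna, sim$sequences$mrna,
                                  config$scoring)
    manifest$counts$scan <- list(lnc_mir_hits = nrow(res$hits_lnc),
                                 mir_mrna_hits = nrow(res$hits_mrna))
    write_stage_tsv(res$hits_lnc, outdir, "hits_lnc_mir")
    write_stage_tsv(res$hits_mrna, outdir, "hits_mir_mrna")
    inform(paste0("[scan] ", nrow(res$hits_lnc), " lncRNA-miRNA and ",
                  nrow(res$hits_mrna), " miRNA-mRNA sites pass score >= ",
                  config$scoring$score_min, ", energy <= ",
                  config$scoring$energy_max))
  }

  if ("de" %in% st) {
    sim <- need("sim", "de")
    mir_counts <- need("mirna_counts", "de")
    samples <- sim$counts$samples
    contrast <- c(config$sim$groups[2], config$sim$groups[1])
    run_de <- function(cm) {
      m <- as_count_matrix(cm)[, samples$sample_id, drop = FALSE]
      sf <- size_factors_median_ratio(m)
      disp <- estimate_dispersion_mom(m, sf, samples$group)
      wald_test(m, sf, disp, samples$group, contrast,
                p_max = config$p_max, lfc_min = config$lfc_min)
    }
    res$de <- list(mrna = run_de(sim$counts$mrna),
                   lncrna = run_de(sim$counts$lncrna),
                   mirna = run_de(mir_counts))
    manifest$counts$de <- purrr::map(res$de, function(d)
      list(up = sum(d$call == "up"), down = sum(d$call == "down")))
    for (cl in names(res$de))
      write_stage_tsv(tidy(res$de[[cl]]), outdir, paste0("de_", cl))
    inform(paste0("[de] up/down: mRNA ",
                  manifest$counts$de$mrna$up, "/",
                  manifest$counts$de$mrna$down, ", lncRNA ",
                  manifest$counts$de$lncrna$up, "/",
                  manifest$counts$de$lncrna$down, ", miRNA ",
                  manifest$counts$de$mirna$up, "/",
                  manifest$counts$de$mirna$down))
  }

  if ("correlate" %in% st) {
    sim <- need("sim", "correlate")
    mir_counts <- need("mirna_counts", "correlate")
    hits_lnc <- need("hits_lnc", "correlate")
    hits_mrna <- need("hits_mrna", "correlate")
    lnc_m <- as_count_matrix(sim$counts$lncrna)
    mrna_m <- as_count_matrix(sim$counts$mrna)
    mir_m <- as_count_matrix(mir_counts)[, colnames(lnc_m), drop = FALSE]
    sf <- list(lnc = size_factors_median_ratio(lnc_m),
               mrna = size_factors_median_ratio(mrna_m),
               mir = size_factors_median_ratio(mir_m))
    pairs_lm <- hits_lnc |> distinct(id_a = .data$target_id,
                                     id_b = .data$mirna_id)
    pairs_mg <- hits_mrna |> distinct(id_a = .data$mirna_id,
                                      id_b = .data$target_id)
    pairs_lg <- hits_lnc |>
      select(lnc = "target_id", mir = "mirna_id") |>
      inner_join(hits_mrna |> select(mir = "mirna_id", mrna = "target_id"),
                 by = "mir", relationship = "many-to-many") |>
      distinct(id_a = .data$lnc, id_b = .data$mrna)
    corr_args <- list(log2_transform = TRUE, r_min = config$r_min,
                      p_max = config$corr_p_max)
    res$edges <- bind_rows(
      do.call(correlate_pairs,
              c(list(lnc_m, mir_m, pairs_lm, sf$lnc, sf$mir), corr_args)),
      do.call(correlate_pairs,
              c(list(mir_m, mrna_m, pairs_mg, sf$mir, sf$mrna), corr_args)),
      do.call(correlate_pairs,
              c(list(lnc_m, mrna_m, pairs_lg, sf$lnc, sf$mrna), corr_args)))
    manifest$counts$correlate <- list(edges = nrow(res$edges),
                                      passing = sum(res$edges$passes))
    write_stage_tsv(res$edges, outdir, "correlation_edges")
    inform(paste0("[correlate] ", sum(res$edges$passes), "/",
                  nrow(res$edges), " edges pass |r| >= ", config$r_min,
                  ", p <= ", config$corr_p_max))
  }

  if ("assemble" %in% st) {
    de <- need("de", "assemble")
    hits_lnc <- need("hits_lnc", "assemble")
    hits_mrna <- need("hits_mrna", "assemble")
    edges <- if (config$require_correlation) need("edges", "assemble")
    else res$edges
    tri <- bind_rows(
      assemble_triplets(hits_lnc, hits_mrna, de$lncrna, de$mirna, de$mrna,
                        edges, mode = "A*",
                        require_correlation = config$require_correlation),
      assemble_triplets(hits_lnc, hits_mrna, de$lncrna, de$mirna, de$mrna,
                        edges, mode = "B*",
                        require_correlation = config$require_correlation))
    res$triplets <- structure(tri,
                              class = c("cerna_network", class(tri)))
    res$summary <- summarize_network(res$triplets)
    if (!is.null(res$sim)) {
      res$recovery <- triplet_recovery(res$triplets,
                                       res$sim$truth$triplets)
      write_stage_tsv(res$recovery, outdir, "recovery")
    }
    manifest$counts$assemble <- list(
      triplets_A = sum(tri$mode == "A*"),
      triplets_B = sum(tri$mode == "B*"))
    write_stage_tsv(res$triplets, outdir, "triplets")
    write_stage_tsv(res$summary, outdir, "network_summary")
    inform(paste0("[assemble] ", sum(tri$mode == "A*"), " A* and ",
                  sum(tri$mode == "B*"), " B* triplets"))
  }

  if ("export" %in% st && !is.null(outdir)) {
    tri <- need("triplets", "export")
    for (md in c("A*", "B*")) {
      sub <- tri |> filter(.data$mode == md)
      tag <- if (md == "A*") "A" else "B"
      export_network(sub, file.path(outdir, paste0("network_", tag, ".sif")),
                     "sif")
      export_network(sub,
                     file.path(outdir, paste0("network_", tag, ".graphml")),
                     "graphml")
    }
  }

  res$manifest <- manifest
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
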