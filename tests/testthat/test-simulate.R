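# Synthetic-data generator: determinism, planted structure, fixtures.

small_cfg <- function(seed = 3)
  simulation_config(seed = seed, n_mrna = 8, n_lncrna = 8, n_mirna = 8,
                    n_planted_A = 2, n_planted_B = 2)

test_that("identical configs give byte-identical annotation output", {
  cfg <- small_cfg()
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(simulate_annotation(cfg), f1)
  write_gtf(simulate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and GTF round-trips through the reader
  back <- read_gtf(f1)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(back$genes), nrow(ann$genes))
  expect_equal(sort(unique(back$transcripts$transcript_id)),
               sort(unique(ann$transcripts$transcript_id)))
  expect_equal(back$transcripts$start[1], ann$transcripts$start[1])
})

test_that("sequence and count generators are seed-deterministic", {
  cfg <- small_cfg()
  tr <- plant_truth(cfg)
  expect_identical(simulate_sequences(tr, cfg), simulate_sequences(tr, cfg))
  expect_identical(simulate_counts(tr, cfg), simulate_counts(tr, cfg))
  # a different seed changes the draw
  cfg2 <- small_cfg(seed = 4)
  expect_false(identical(simulate_counts(plant_truth(cfg2), cfg2)$mrna,
                         simulate_counts(tr, cfg)$mrna))
})

test_that("planted truth respects mode sign semantics and one site per pair", {
  tr <- plant_truth(small_cfg())
  signs <- setNames(tr$features$de_sign, tr$features$feature_id)
  for (i in seq_len(nrow(tr$triplets))) {
    t <- tr$triplets[i, ]
    expected <- if (t$mode == "A*") c(1, -1, 1) else c(-1, 1, -1)
    expect_equal(unname(signs[c(t$lnc_id, t$mir_id, t$mrna_id)]), expected)
    # exactly one site on each of the two targets
    expect_equal(sum(tr$sites$mirna_id == t$mir_id &
                       tr$sites$target_id == t$lnc_id), 1)
    expect_equal(sum(tr$sites$mirna_id == t$mir_id &
                       tr$sites$target_id == t$mrna_id), 1)
  }
})

test_that("planted sites are exact reverse complements at their coordinates", {
  cfg <- small_cfg()
  tr <- plant_truth(cfg)
  seqs <- simulate_sequences(tr, cfg)
  all_seqs <- dplyr::bind_rows(seqs$lncrna, seqs$mrna)
  mir <- setNames(seqs$mirna$seq, seqs$mirna$id)
  for (k in seq_len(nrow(tr$sites))) {
    s <- tr$sites[k, ]
    target <- all_seqs$seq[all_seqs$id == s$target_id]
    expect_equal(substr(target, s$start + 1, s$end),
                 reverse_complement_rna(mir[[s$mirna_id]]))
  }
})

test_that("miRNA lengths stay within the mature range", {
  cfg <- simulation_config(seed = 9, n_mrna = 2, n_lncrna = 2,
                           n_mirna = 500, n_planted_A = 1, n_planted_B = 1)
  tr <- plant_truth(cfg)
  lens <- tr$features$length[tr$features$class == "mirna"]
  expect_true(all(lens >= 16 & lens <= 24))
})

test_that("lncRNA candidates assess noncoding, mRNAs coding", {
  cfg <- small_cfg()
  seqs <- simulate_sequences(plant_truth(cfg), cfg)
  cp_lnc <- assess_coding_potential(seqs$lncrna)
  expect_true(all(cp_lnc$verdict == "noncoding"))
  cp_mrna <- assess_coding_potential(seqs$mrna)
  expect_true(all(cp_mrna$verdict == "coding"))
  expect_equal(
    assess_coding_potential(seqs$fixtures |>
                              dplyr::filter(id == "cand_coding"))$verdict,
    "coding")
})

test_that("filter fixtures behave as designed", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  cand <- ann$transcripts |> dplyr::filter(type == "candidate")
  kept <- unique(filter_candidates(cand)$transcript_id)
  expect_false("cand_short" %in% kept)     # 150 nt
  expect_false("cand_monoexon" %in% kept)  # one exon
  expect_true("cand_coding" %in% kept)     # removed later, by coding potential
  expect_true(all(sprintf("lnc_%03d", 1:8) %in% kept))
})

test_that("one candidate per positional class is recovered as intended", {
  cfg <- simulation_config(seed = 6, n_mrna = 6, n_lncrna = 6, n_mirna = 6,
                           n_planted_A = 1, n_planted_B = 1)
  ann <- simulate_annotation(cfg)
  lnc_tx <- ann$transcripts |>
    dplyr::filter(type == "candidate", !grepl("^cand_", transcript_id))
  cls <- classify_position(lnc_tx, ann$genes)
  merged <- dplyr::inner_join(cls, ann$candidates, by = "transcript_id")
  expect_equal(merged$subtype, merged$intended_class)
  # all eight labels of the taxonomy are represented
  labels <- unique(c(merged$top_level, merged$subtype))
  expect_setequal(labels, c("genic", "intergenic", "containing", "nested",
                            "overlapping", "same_strand", "convergent",
                            "divergent"))
})

test_that("count matrices have the right shape, type and null structure", {
  cfg <- small_cfg()
  tr <- plant_truth(cfg)
  cn <- simulate_counts(tr, cfg)
  m <- as.matrix(cn$mrna[-1])
  expect_equal(dim(m), c(8, 6))
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(cn$samples$group, rep(c("control", "treatment"), each = 3))
  # all-zero planting -> pure nulls, no latent coupling
  cfg0 <- simulation_config(seed = 3, n_mrna = 8, n_lncrna = 8, n_mirna = 8,
                            n_planted_A = 0, n_planted_B = 0)
  tr0 <- plant_truth(cfg0)
  expect_true(all(tr0$features$de_sign == 0))
  cn0 <- simulate_counts(tr0, cfg0)
  expect_equal(nrow(cn0$latent), 0)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_planted_A = 30, n_planted_B = 30,
                                 n_mirna = 50),
               "exceed")
  expect_error(simulation_config(lfc_planted = 0), "positive")
  expect_error(simulation_config(dispersion = -1), "positive")
  expect_error(simulate_annotation(simulation_config(genome_len = 1e4)),
               "genome_len")
})
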