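# Candidate filtering, coding potential, positional classification.

mk_tx <- function(id, chrom = "chr1", strand = "+", exons) {
  tibble::tibble(transcript_id = id, gene_id = NA_character_,
                 type = "candidate", chrom = chrom, strand = strand,
                 start = vapply(exons, `[`, 0, 1),
                 end = vapply(exons, `[`, 0, 2))
}

test_that("length/exon filter boundaries are inclusive on the keep side", {
  tx <- dplyr::bind_rows(
    mk_tx("len199", exons = list(c(0, 100), c(200, 299))),
    mk_tx("monoexon500", exons = list(c(0, 500))),
    mk_tx("len200", exons = list(c(0, 100), c(200, 300))),
    mk_tx("big", exons = list(c(0, 300), c(400, 700))))
  kept <- unique(filter_candidates(tx)$transcript_id)
  expect_setequal(kept, c("len200", "big"))
  # idempotence and order preservation
  once <- filter_candidates(tx)
  expect_identical(filter_candidates(once), once)
  expect_identical(unique(once$transcript_id), c("len200", "big"))
  expect_equal(nrow(filter_candidates(tx[0, ])), 0)
})

test_that("ORF detection matches a brute-force scanner", {
  set.seed(21)
  # constructed: AUG + 120 sense codons + UAA inside ~1 kb of background
  sense <- apply(expand.grid(c("A","C","G","U"), c("A","C","G","U"),
                             c("A","C","G","U")), 1, paste, collapse = "")
  sense <- setdiff(sense, c("UAA", "UAG", "UGA"))
  orf <- paste0("AUG", paste(sample(sense, 120, TRUE), collapse = ""), "UAA")
  seq <- paste0(random_rna_str(300), orf, random_rna_str(337))
  rep <- assess_coding_potential(c(x = seq))
  expect_gte(rep$longest_orf_nt, 363)
  expect_equal(rep$longest_orf_nt, brute_orf(seq))
  expect_equal(rep$verdict, "coding")

  # no AUG anywhere -> no ORF
  rep0 <- assess_coding_potential(c(x = strrep("CUC", 100)))
  expect_equal(rep0$longest_orf_nt, 0)
  expect_equal(rep0$verdict, "noncoding")

  # random sequences agree with the oracle
  for (i in 1:20) {
    s <- random_rna_str(sample(200:800, 1))
    expect_equal(assess_coding_potential(c(a = s))$longest_orf_nt,
                 brute_orf(s), info = paste("random", i))
  }
})

test_that("Fickett scores match an independent table walk", {
  expect_equal(assess_coding_potential(c(a = strrep("A", 400)))$fickett_score,
               fickett_oracle(strrep("A", 400)))
  set.seed(22)
  for (i in 1:25) {
    s <- random_rna_str(sample(150:600, 1))
    expect_equal(assess_coding_potential(c(a = s))$fickett_score,
                 fickett_oracle(s), info = paste("random", i))
  }
  # T- and U-encoded inputs give identical reports
  s <- "ATGGCTAAGCTTGCATCA"
  expect_equal(assess_coding_potential(c(a = s)),
               assess_coding_potential(c(a = chartr("T", "U", s))))
})

test_that("positional classification follows the span-based definitions", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 0, end = 10000)
  nested <- mk_tx("l_nested", exons = list(c(100, 500), c(700, 900)))
  expect_equal(classify_position(nested, genes)$subtype, "nested")

  # tail-to-tail across a gap: gene(+) left, candidate(-) right
  genes2 <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = 1000, end = 2000)
  conv <- mk_tx("l_conv", strand = "-", exons = list(c(5000, 6000)))
  got <- classify_position(conv, genes2)
  expect_equal(got$top_level, "intergenic")
  expect_equal(got$subtype, "convergent")
  expect_equal(got$distance, 3000)

  # head-to-head: gene(-) left, candidate(+) right
  genes3 <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-",
                           start = 1000, end = 2000)
  div <- mk_tx("l_div", strand = "+", exons = list(c(5000, 6000)))
  expect_equal(classify_position(div, genes3)$subtype, "divergent")

  # equal spans: neither strict containment -> overlapping
  eq <- mk_tx("l_eq", exons = list(c(0, 10000)))
  expect_equal(classify_position(eq, genes)$subtype, "overlapping")

  expect_error(classify_position(mk_tx("x", chrom = "chrZ",
                                       exons = list(c(0, 100))), genes),
               "chrZ")
})

test_that("classification ignores exon structure within a fixed span", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          strand = c("+", "-"),
                          start = c(0, 50000), end = c(10000, 60000))
  variants <- list(
    mk_tx("v", exons = list(c(2000, 2500), c(7500, 8000))),
    mk_tx("v", exons = list(c(2000, 2100), c(4000, 4400), c(7900, 8000))),
    mk_tx("v", exons = list(c(2000, 8000))))
  calls <- lapply(variants, function(tx)
    classify_position(tx, genes)[c("top_level", "subtype", "partner_gene")])
  expect_identical(calls[[1]], calls[[2]])
  expect_identical(calls[[1]], calls[[3]])
})

test_that("every candidate gets exactly one class and counts add up", {
  cfg <- simulation_config(seed = 5, n_mrna = 12, n_lncrna = 12,
                           n_mirna = 12, n_planted_A = 3, n_planted_B = 3)
  ann <- simulate_annotation(cfg)
  lnc <- ann$transcripts |>
    dplyr::filter(.data$type == "candidate",
                  !grepl("^cand_", .data$transcript_id))
  cls <- classify_position(lnc, ann$genes)
  expect_equal(nrow(cls), dplyr::n_distinct(lnc$transcript_id))
  expect_true(all(cls$subtype %in% c("containing", "nested", "overlapping",
                                     "same_strand", "convergent",
                                     "divergent")))
  expect_true(all(cls$top_level[cls$subtype %in%
    c("containing", "nested", "overlapping")] == "genic"))
  smry <- summarize_lnc_classes(cls)
  expect_equal(sum(smry$n[smry$level == "subtype"]), nrow(cls))
  expect_equal(sum(smry$n[smry$level == "top_level"]), nrow(cls))
})
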