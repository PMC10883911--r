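# Triplet assembly, network summaries, export round-trips.

toy_de <- function(ids, calls) {
  tibble::tibble(feature_id = ids, base_mean = 100,
                 log2fc = ifelse(calls == "up", 1, ifelse(calls == "down",
                                                          -1, 0)),
                 se = 0.1, wald_z = 0, p_value = 0.01, padj = 0.01,
                 testable = TRUE, call = calls)
}
toy_hit <- function(mir, target, score = 180) {
  tibble::tibble(mirna_id = mir, target_id = target, target_start = 10L,
                 target_end = 31L, score = score, energy = -20,
                 trace = strrep("|", 21))
}
toy_edge <- function(a, b, r) {
  tibble::tibble(id_a = a, id_b = b, r = r, n = 6,
                 p_value = 0.001, passes = TRUE)
}

test_that("a minimal sign-consistent A* case yields exactly one triplet", {
  hits_lm <- toy_hit("m1", "l1")
  hits_mg <- toy_hit("m1", "g1")
  de_l <- toy_de("l1", "up")
  de_m <- toy_de("m1", "down")
  de_g <- toy_de("g1", "up")
  edges <- dplyr::bind_rows(toy_edge("l1", "m1", -0.99),
                            toy_edge("m1", "g1", -0.98),
                            toy_edge("l1", "g1", 0.97))
  tri <- assemble_triplets(hits_lm, hits_mg, de_l, de_m, de_g, edges, "A*")
  expect_equal(nrow(tri), 1)
  expect_equal(tri$lnc_id, "l1")
  expect_equal(tri$r_lnc_mrna, 0.97)
  # and zero triplets in the mirrored mode
  triB <- assemble_triplets(hits_lm, hits_mg, de_l, de_m, de_g, edges, "B*")
  expect_equal(nrow(triB), 0)
})

test_that("mixed DE signs fit neither mode", {
  hits_lm <- toy_hit("m1", "l1")
  hits_mg <- toy_hit("m1", "g1")
  de_l <- toy_de("l1", "up")
  de_m <- toy_de("m1", "down")
  de_g <- toy_de("g1", "down")  # mRNA down while lnc up
  edges <- dplyr::bind_rows(toy_edge("l1", "m1", -0.99),
                            toy_edge("m1", "g1", -0.98),
                            toy_edge("l1", "g1", 0.97))
  for (mode in c("A*", "B*"))
    expect_equal(nrow(assemble_triplets(hits_lm, hits_mg, de_l, de_m, de_g,
                                        edges, mode)), 0)
})

test_that("correlation gating demands the sponge sign pattern", {
  hits_lm <- toy_hit("m1", "l1")
  hits_mg <- toy_hit("m1", "g1")
  de_l <- toy_de("l1", "up")
  de_m <- toy_de("m1", "down")
  de_g <- toy_de("g1", "up")
  # lnc-mrna edge passes but with the WRONG (negative) sign
  bad <- dplyr::bind_rows(toy_edge("l1", "m1", -0.99),
                          toy_edge("m1", "g1", -0.98),
                          toy_edge("l1", "g1", -0.97))
  expect_equal(nrow(assemble_triplets(hits_lm, hits_mg, de_l, de_m, de_g,
                                      bad, "A*")), 0)
  # relaxed mode ignores correlations entirely
  expect_equal(nrow(assemble_triplets(hits_lm, hits_mg, de_l, de_m, de_g,
                                      bad, "A*",
                                      require_correlation = FALSE)), 1)
  # the best-scoring site supports the triplet when a pair has several
  hits2 <- dplyr::bind_rows(toy_hit("m1", "l1", score = 150),
                            toy_hit("m1", "l1", score = 190) |>
                              dplyr::mutate(target_start = 50L,
                                            target_end = 71L))
  tri <- assemble_triplets(hits2, hits_mg, de_l, de_m, de_g, bad, "A*",
                           require_correlation = FALSE)
  expect_equal(tri$score_lnc_mir, 190)
})

test_that("summaries count sets exactly", {
  t1 <- tibble::tibble(lnc_id = "L1", mir_id = "M1", mrna_id = "G1",
                       mode = "A*")
  s1 <- summarize_network(t1)
  expect_equal(s1$n_nodes, 3)
  expect_equal(s1$n_edges, 2)
  expect_equal(s1$n_triplets, 1)
  # two triplets sharing lnc and mir, differing in mRNA
  t2 <- dplyr::bind_rows(t1, t1 |> dplyr::mutate(mrna_id = "G2"))
  s2 <- summarize_network(t2)
  expect_equal(s2$n_nodes, 4)
  expect_equal(s2$n_edges, 3)
  expect_equal(s2$n_triplets, 2)
  s0 <- summarize_network(t1[0, ])
  expect_equal(s0$n_nodes, 0)
})

test_that("node counts match the set-union oracle on random networks", {
  set.seed(61)
  for (i in 1:25) {
    tr <- random_triplets(sample(1:40, 1))
    s <- summarize_network(tr) |> dplyr::summarise(
      n_triplets = sum(n_triplets), n_nodes = sum(n_nodes),
      n_edges = sum(n_edges))
    # union over modes can share nodes; compare per mode instead
    per_mode <- summarize_network(tr)
    for (md in per_mode$mode) {
      sub <- tr |> dplyr::filter(mode == md)
      expect_equal(per_mode$n_nodes[per_mode$mode == md],
                   node_union_oracle(sub))
      expect_lte(per_mode$n_edges[per_mode$mode == md], 2 * nrow(sub))
    }
  }
})

test_that("exports round-trip exactly in all three formats", {
  set.seed(62)
  tr <- random_triplets(30)
  expected <- network_edges(tr)
  for (fmt in c("sif", "graphml", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(tr, path, fmt)
    got <- read_network(path, fmt)
    expect_equal(as.data.frame(got), as.data.frame(expected),
                 info = fmt)
  }
  # GraphML is well-formed XML with node/edge structure
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(tr, path, "graphml")
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               node_union_oracle(tr))
  expect_error(export_network(
    tibble::tibble(lnc_id = "a\tb", mir_id = "m", mrna_id = "g",
                   mode = "A*"),
    withr::local_tempfile(), "sif"), "tabs")
})

test_that("triplet recovery scores precision, recall and F1", {
  truth <- tibble::tibble(lnc_id = c("L1", "L2"), mir_id = c("M1", "M2"),
                          mrna_id = c("G1", "G2"), mode = c("A*", "B*"))
  found <- dplyr::bind_rows(truth[1, ],
                            tibble::tibble(lnc_id = "L9", mir_id = "M9",
                                           mrna_id = "G9", mode = "A*"))
  r <- triplet_recovery(found, truth)
  expect_equal(r$tp, 1)
  expect_equal(r$fp, 1)
  expect_equal(r$fn, 1)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 0.5)
})
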