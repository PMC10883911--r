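# Sign-partitioned ceRNA triplet assembly, summary and Cytoscape export.
#
# Mode "A*" collects up-regulated lncRNAs and mRNAs sponging a
# down-regulated miRNA; mode "B*" is the mirror pattern. The two modes are
# mutually exclusive by construction (a triplet's DE sign pattern fits at
# most one).

#' Assemble sign-consistent lncRNA-miRNA-mRNA triplets
#'
#' Emits a triplet (lnc, mir, mrna) when (i) a retained lncRNA-miRNA
#' binding site and a retained miRNA-mRNA binding site share the miRNA,
#' (ii) the three differential-expression calls match the requested mode
#' (`A*`: lnc up, mir down, mrna up; `B*`: mirrored), and (iii) when
#' `require_correlation` is `TRUE`, the three co-expression edges pass
#' their filter with the sponge-consistent signs: lnc-mir negative,
#' mir-mrna negative, lnc-mrna positive (the two ceRNAs compete for the
#' same miRNA, so their expression moves together). When several binding
#' sites exist for a pair, the max-score site supports the triplet.
#' Features present in the hit tables but absent from the DE calls are
#' skipped with a message.
#'
#' @param lnc_mir_hits,mir_mrna_hits hit tibbles from [scan_targets()]
#'   (`mirna_id`, `target_id`, `score`, `energy`).
#' @param de_lnc,de_mir,de_mrna called DE tables (see [call_de()]) for the
#'   three RNA classes.
#' @param corr_edges co-expression edge tibble from [correlate_pairs()]
#'   covering lnc-mir, mir-mrna and lnc-mrna pairs (`id_a`, `id_b`, `r`,
#'   `passes`); may be `NULL` when `require_correlation = FALSE`.
#' @param mode `"A*"` or `"B*"`.
#' @param require_correlation demand the three sign-constrained
#'   correlation edges.
#' @return tibble of triplets, deduplicated and sorted by (`lnc_id`,
#'   `mir_id`, `mrna_id`), carrying the supporting scores, energies and
#'   correlations, with class `cerna_network`.
#' @export
assemble_triplets <- function(lnc_mir_hits, mir_mrna_hits, de_lnc, de_mir,
                              de_mrna, corr_edges = NULL, mode = "A*",
                              require_correlation = TRUE) {
  if (!mode %in% c("A*", "B*")) abort('`mode` must be "A*" or "B*"')
  if (require_correlation && is.null(corr_edges))
    abort("`corr_edges` needed when `require_correlation = TRUE`")

  best_hit <- function(hits) {
    if (nrow(hits) == 0) return(hits)
    hits |>
      group_by(.data$mirna_id, .data$target_id) |>
      arrange(desc(.data$score), .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  lm <- best_hit(lnc_mir_hits)
  mm <- best_hit(mir_mrna_hits)

  empty <- tibble(lnc_id = character(), mir_id = character(),
                  mrna_id = character(), mode = character(),
                  score_lnc_mir = double(), energy_lnc_mir = double(),
                  score_mir_mrna = double(), energy_mir_mrna = double(),
                  r_lnc_mir = double(), r_mir_mrna = double(),
                  r_lnc_mrna = double())
  if (nrow(lm) == 0 || nrow(mm) == 0)
    return(structure(empty, class = c("cerna_network", class(empty))))

  sets_l <- de_sets(de_lnc)
  sets_m <- de_sets(de_mir)
  sets_g <- de_sets(de_mrna)
  if (mode == "A*") {
    ok_l <- sets_l$up; ok_m <- sets_m$down; ok_g <- sets_g$up
  } else {
    ok_l <- sets_l$down; ok_m <- sets_m$up; ok_g <- sets_g$down
  }

  known <- c(de_lnc$feature_id, de_mir$feature_id, de_mrna$feature_id)
  miss <- setdiff(c(lm$target_id, mm$target_id, lm$mirna_id, mm$mirna_id),
                  known)
  if (length(miss) > 0)
    inform(paste0(length(miss),
                  " feature(s) in hits have no DE call and are skipped"))

  cand <- lm |>
    select(mir_id = "mirna_id", lnc_id = "target_id",
           score_lnc_mir = "score", energy_lnc_mir = "energy") |>
    inner_join(mm |>
                 select(mir_id = "mirna_id", mrna_id = "target_id",
                        score_mir_mrna = "score",
                        energy_mir_mrna = "energy"),
               by = "mir_id", relationship = "many-to-many") |>
    filter(.data$lnc_id %in% ok_l, .data$mir_id %in% ok_m,
           .data$mrna_id %in% ok_g)

  lookup_edge <- function(ia, ib) {
    if (is.null(corr_edges)) {
      return(tibble(r = NA_real_, passes = NA))
    }
    e <- corr_edges |>
      filter((.data$id_a == ia & .data$id_b == ib) |
               (.data$id_a == ib & .data$id_b == ia))
    if (nrow(e) == 0) tibble(r = NA_real_, passes = FALSE)
    else tibble(r = e$r[1], passes = e$passes[1])
  }

  if (nrow(cand) == 0)
    return(structure(empty, class = c("cerna_network", class(empty))))

  edges <- purrr::pmap_dfr(
    list(cand$lnc_id, cand$mir_id, cand$mrna_id),
    function(l, m, g) {
      e1 <- lookup_edge(l, m)
      e2 <- lookup_edge(m, g)
      e3 <- lookup_edge(l, g)
      tibble(r_lnc_mir = e1$r, r_mir_mrna = e2$r, r_lnc_mrna = e3$r,
             corr_ok = isTRUE(e1$passes) && isTRUE(e1$r < 0) &&
               isTRUE(e2$passes) && isTRUE(e2$r < 0) &&
               isTRUE(e3$passes) && isTRUE(e3$r > 0))
    })
  cand <- bind_cols(cand, edges)
  if (require_correlation) cand <- filter(cand, .data$corr_ok)

  out <- cand |>
    mutate(mode = mode) |>
    select("lnc_id", "mir_id", "mrna_id", "mode", "score_lnc_mir",
           "energy_lnc_mir", "score_mir_mrna", "energy_mir_mrna",
           "r_lnc_mir", "r_mir_mrna", "r_lnc_mrna") |>
    distinct(.data$lnc_id, .data$mir_id, .data$mrna_id,
             .keep_all = TRUE) |>
    arrange(.data$lnc_id, .data$mir_id, .data$mrna_id)
  structure(out, class = c("cerna_network", class(out)))
}

#' Unique edges of a triplet network
#'
#' @param triplets triplet tibble from [assemble_triplets()].
#' @return tibble (`source`, `interaction`, `target`) with interaction
#'   `lnc_mir` or `mir_mrna`, deduplicated across triplets.
#' @export
network_edges <- function(triplets) {
  bind_rows(
    triplets |> transmute(source = .data$lnc_id, interaction = "lnc_mir",
                          target = .data$mir_id),
    triplets |> transmute(source = .data$mir_id, interaction = "mir_mrna",
                          target = .data$mrna_id)) |>
    distinct() |>
    arrange(.data$interaction, .data$source, .data$target)
}

#' Summarize a ceRNA network
#'
#' Counts triplets, distinct nodes per RNA class, and unique pair-level
#' edges (deduplicated across triplets, so `n_edges <= 2 * n_triplets`).
#' The arithmetic identity `n_nodes = n_lnc + n_mir + n_mrna` holds by
#' construction.
#'
#' @param triplets triplet tibble from [assemble_triplets()].
#' @return one-row tibble per mode present (all-zero single row for an
#'   empty network).
#' @export
summarize_network <- function(triplets) {
  if (nrow(triplets) == 0) {
    return(tibble(mode = NA_character_, n_triplets = 0L, n_lnc = 0L,
                  n_mir = 0L, n_mrna = 0L, n_nodes = 0L, n_edges = 0L))
  }
  triplets |>
    group_by(.data$mode) |>
    group_modify(function(tr, key) {
      tibble(n_triplets = nrow(tr),
             n_lnc = dplyr::n_distinct(tr$lnc_id),
             n_mir = dplyr::n_distinct(tr$mir_id),
             n_mrna = dplyr::n_distinct(tr$mrna_id),
             n_edges = nrow(network_edges(tr)))
    }) |>
    ungroup() |>
    mutate(n_nodes = .data$n_lnc + .data$n_mir + .data$n_mrna) |>
    select("mode", "n_triplets", "n_lnc", "n_mir", "n_mrna", "n_nodes",
           "n_edges")
}

#' @export
glance.cerna_network <- function(x, ...) summarize_network(x)

#' Export a ceRNA network for Cytoscape
#'
#' Writes the pair-level edge set as SIF (`source<TAB>interaction<TAB>
#' target`), GraphML (with node `rna_type` attributes and edge
#' `interaction` attributes), or a plain edge-list TSV. Parsing the export
#' back with [read_network()] reproduces the edge set exactly.
#'
#' @param triplets triplet tibble from [assemble_triplets()].
#' @param path output file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(triplets, path,
                           format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  edges <- network_edges(triplets)
  ids <- c(edges$source, edges$target)
  if (any(grepl("[\t\n]", ids)))
    abort("node ids must not contain tabs or newlines")
  if (format == "sif") {
    readr::write_lines(
      sprintf("%s\t%s\t%s", edges$source, edges$interaction, edges$target),
      path)
  } else if (format == "tsv") {
    readr::write_tsv(edges, path)
  } else {
    nodes <- bind_rows(
      triplets |> transmute(id = .data$lnc_id, rna_type = "lncRNA"),
      triplets |> transmute(id = .data$mir_id, rna_type = "miRNA"),
      triplets |> transmute(id = .data$mrna_id, rna_type = "mRNA")) |>
      distinct() |>
      arrange(.data$id)
    doc <- xml2::xml_new_root(
      "graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    k1 <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                              attr.name = "rna_type", attr.type = "string")
    k2 <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "edge",
                              attr.name = "interaction",
                              attr.type = "string")
    g <- xml2::xml_add_child(doc, "graph", id = "ceRNA",
                             edgedefault = "directed")
    for (i in seq_len(nrow(nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = nodes$id[i])
      dt <- xml2::xml_add_child(nd, "data", key = "d0")
      xml2::xml_text(dt) <- nodes$rna_type[i]
    }
    for (i in seq_len(nrow(edges))) {
      ed <- xml2::xml_add_child(g, "edge", source = edges$source[i],
                                target = edges$target[i])
      dt <- xml2::xml_add_child(ed, "data", key = "d1")
      xml2::xml_text(dt) <- edges$interaction[i]
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read a network export back as an edge table
#'
#' @param path file written by [export_network()].
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return tibble (`source`, `interaction`, `target`).
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readr::read_lines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- tibble(source = vapply(parts, `[`, "", 1),
                    interaction = vapply(parts, `[`, "", 2),
                    target = vapply(parts, `[`, "", 3))
  } else if (format == "tsv") {
    edges <- readr::read_tsv(path, show_col_types = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    es <- xml2::xml_find_all(doc, ".//g:edge", ns)
    edges <- tibble(
      source = xml2::xml_attr(es, "source"),
      interaction = xml2::xml_text(
        xml2::xml_find_first(es, "./g:data[@key='d1']", ns)),
      target = xml2::xml_attr(es, "target"))
  }
  edges |> arrange(.data$interaction, .data$source, .data$target)
}

#' Planted-truth recovery of an assembled network
#'
#' Compares a recovered triplet set against a planted truth set on the
#' (lnc, mir, mrna, mode) key and reports precision, recall and F1.
#'
#' @param found triplet tibble from [assemble_triplets()] (possibly both
#'   modes bound together).
#' @param truth tibble with `lnc_id`, `mir_id`, `mrna_id`, `mode`.
#' @return one-row tibble (`tp`, `fp`, `fn`, `precision`, `recall`, `f1`).
#' @export
triplet_recovery <- function(found, truth) {
  key <- function(d) paste(d$lnc_id, d$mir_id, d$mrna_id, d$mode)
  fk <- unique(key(found))
  tk <- unique(key(truth))
  tp <- length(intersect(fk, tk))
  fp <- length(setdiff(fk, tk))
  fn <- length(setdiff(tk, fk))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
  else 2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn, precision = precision,
         recall = recall, f1 = f1)
}
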