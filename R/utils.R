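# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts `T` to `U`. With `allow_n = FALSE` any character
#' outside `ACGU` is an error; otherwise `N` is also tolerated.
#'
#' @param x character vector of sequences.
#' @param allow_n allow ambiguous `N` bases.
#' @return character vector over the RNA alphabet.
#' @export
normalize_rna <- function(x, allow_n = FALSE) {
  x <- chartr("t", "T", toupper(x))
  x <- chartr("T", "U", x)
  pat <- if (allow_n) "[^ACGUN]" else "[^ACGU]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    abort(paste0("sequence contains characters outside the ",
                 if (allow_n) "ACGUN" else "ACGU",
                 " alphabet (first offender at index ", which(bad)[1], ")"))
  }
  x
}

#' Reverse complement in RNA space
#'
#' @param x character vector over `ACGU`.
#' @return reverse complement (`A<->U`, `G<->C`).
#' @export
reverse_complement_rna <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Coerce FASTA path / named character vector / Biostrings set / tibble into a
# tibble(id, seq) on the RNA alphabet.
as_seq_tbl <- function(x, allow_n = FALSE) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_fasta(x)
  }
  if (methods::is(x, "XStringSet")) {
    x <- tibble(id = names(x), seq = as.character(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) abort("sequence vectors must be named by id")
    x <- tibble(id = names(x), seq = unname(x))
  }
  if (!is_tibble(x)) x <- as_tibble(x)
  if (!all(c("id", "seq") %in% names(x)))
    abort("sequence tables need `id` and `seq` columns")
  x$seq <- normalize_rna(x$seq, allow_n = allow_n)
  x
}

# Wide count tibble (feature_id + one column per sample) or matrix -> integer
# matrix with feature rownames.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else {
    counts <- as_tibble(counts)
    if (!"feature_id" %in% names(counts))
      abort("count tables need a `feature_id` column")
    m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
    rownames(m) <- counts$feature_id
  }
  if (any(m < 0)) abort("count matrices must be non-negative")
  storage.mode(m) <- "double"
  m
}

as_count_tbl <- function(m) {
  tibble(feature_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(m))
}
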