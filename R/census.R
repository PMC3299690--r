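#' Read a proteome-by-domain abundance census TSV
#'
#' One row per proteome; header `proteome<TAB><ccs>...` where each remaining
#' column is a SCOP-style concise classification string (e.g. `c.37.1`) and
#' cells are non-negative integer genomic abundances g (occurrences of the
#' domain superfamily in that proteome).
#'
#' @param path TSV path.
#' @return Tibble with a `proteome` column and one integer column per domain.
#' @export
read_abundance_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "proteome") {
    stop("abundance TSV must start with a 'proteome' column", call. = FALSE)
  }
  vals <- as.matrix(tbl[, -1])
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("abundances must be non-negative integers", call. = FALSE)
  }
  tbl
}

#' @rdname read_abundance_table
#' @param tbl Abundance tibble.
#' @export
write_abundance_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Gap-code an abundance census into a 21-state character matrix
#'
#' Each domain superfamily becomes one linearly ordered character; abundances
#' are compressed with [gap_code()] against the per-proteome maximum (each
#' proteome scales independently) and polarized with 'K' (state 20) ancestral:
#' popular, widespread superfamilies are taken as ancient. Proteomes with no
#' nonzero abundance are dropped with a warning.
#'
#' @param tbl Abundance tibble from [read_abundance_table()].
#' @param orientation `"proteome_rows"` (proteomes x domains) or
#'   `"domain_rows"` (the transpose used to build trees of domains; ancestral
#'   'K' states are attached in this orientation).
#' @param per_proteome Scale g_max per proteome (default) or over the whole
#'   table.
#' @param method Passed to [gap_code()].
#' @return A [character_matrix()] on the 21-symbol census alphabet.
#' @export
build_census_matrix <- function(tbl, orientation = c("domain_rows",
                                                     "proteome_rows"),
                                per_proteome = TRUE,
                                method = c("log", "linear")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  vals <- as.matrix(tbl[, -1, drop = FALSE]) # proteomes x domains
  rownames(vals) <- tbl$proteome
  zero <- rowSums(vals) == 0
  if (any(zero)) {
    warning("dropping all-zero proteomes: ",
            paste(tbl$proteome[zero], collapse = ", "), call. = FALSE)
    vals <- vals[!zero, , drop = FALSE]
  }
  if (!nrow(vals)) stop("no usable proteomes", call. = FALSE)
  ab <- census_alphabet()
  gmax_tbl <- max(vals)
  states <- t(apply(vals, 1, function(g) {
    gm <- if (per_proteome) max(g) else gmax_tbl
    gap_code(g, gm, method = method)
  }))
  sym <- matrix(ab[states + 1L], nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  m <- character_matrix(sym, ordered = TRUE, alphabet = ab)
  if (orientation == "domain_rows") {
    m <- transpose_matrix(m)
    m <- polarize(m, rule = "fixed", symbol = "K")
  }
  m
}

#' Date protein domains from an abundance census (nd_P)
#'
#' Full census pipeline: gap coding ([build_census_matrix()], domains as
#' rows), heuristic maximum-parsimony search, rooting with the hypothetical
#' all-'K' ancestor ([root_with_ancestor()]), and node-distance chronology.
#' The resulting nd_P assigns the oldest domain 0 and the newest 1.
#'
#' @param tbl Abundance tibble.
#' @param seed Seed passed to the search.
#' @param addition,n_starts,max_trees Search options, see
#'   [heuristic_search()].
#' @param per_proteome,method Census coding options.
#' @return Tibble of class `chronology` with `id` (domain) and `nd` columns
#'   (nd_P); attributes `tree` and `search_length`.
#' @export
domain_ages <- function(tbl, seed = NULL, addition = "input_order",
                        n_starts = 5, max_trees = 100,
                        per_proteome = TRUE, method = "log") {
  if (ncol(tbl) - 1 < 4) stop("need >= 4 domains", call. = FALSE)
  m <- build_census_matrix(tbl, orientation = "domain_rows",
                           per_proteome = per_proteome, method = method)
  if (length(unique(as.vector(m$states))) == 1) {
    warning("constant census matrix: chronology is degenerate",
            call. = FALSE)
  }
  trees <- heuristic_search(m, addition = addition, n_starts = n_starts,
                            seed = seed, max_trees = max_trees)
  rooted <- root_with_ancestor(trees[[1]], m)
  chron <- node_distance(rooted)
  attr(chron, "search_length") <- attr(trees, "best_length")
  chron
}
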