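#' Date rRNA helices from a structural alignment (nd)
#'
#' End-to-end substructure chronology: codes stem lengths as ordered
#' characters (substructure rows — the transpose in which helices are the
#' operational taxa and molecules the characters), polarizes them, infers
#' most-parsimonious trees, roots with the hypothetical ancestor and returns
#' the node-distance ages. Only stem (S) slots are used: stems define the 3D
#' pattern of molecular accretion.
#'
#' @param lengths Helix-map tibble (`taxon` + slot columns), e.g. from
#'   [load_structural_alignment()] or [simulate_accretion()].
#' @param rule Polarization rule; default `"max_ancestral"` (longer, more
#'   ordered stems ancestral).
#' @param kinds Slot kinds to use as rows (default `"S"`).
#' @param seed,addition,n_starts,max_trees Search options.
#' @return A `chronology` tibble (`id` = helix region, `nd`), with the rooted
#'   tree attached and `search_length`.
#' @export
helix_ages <- function(lengths, rule = "max_ancestral", kinds = "S",
                       seed = NULL, addition = "input_order", n_starts = 5,
                       max_trees = 100) {
  slots <- setdiff(names(lengths), "taxon")
  kind_of <- substr(vapply(strsplit(slots, ".", fixed = TRUE),
                           function(p) p[length(p)], character(1)), 1, 1)
  keep <- slots[kind_of %in% kinds & !grepl("'$", slots)]
  if (length(keep) < 4) {
    stop("need >= 4 usable slots (have ", length(keep), ")", call. = FALSE)
  }
  sub <- lengths[, c("taxon", keep)]
  m <- build_matrix(sub, orientation = "substructure_rows")
  if (length(unique(as.vector(m$states))) == 1) {
    warning("constant character matrix: chronology is degenerate",
            call. = FALSE)
  }
  m <- polarize(m, rule = rule)
  trees <- heuristic_search(m, addition = addition, n_starts = n_starts,
                            seed = seed, max_trees = max_trees)
  rooted <- root_with_ancestor(trees[[1]], m)
  chron <- node_distance(rooted)
  # report by helix region, not slot id
  chron$id <- vapply(strsplit(chron$id, ".", fixed = TRUE),
                     function(p) paste(p[-length(p)], collapse = "."),
                     character(1))
  attr(chron, "search_length") <- attr(trees, "best_length")
  chron
}
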