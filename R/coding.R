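#' Construct an ordered multistate character matrix
#'
#' @param states Character matrix of state symbols with taxon rownames and
#'   character colnames.
#' @param ordered Treat characters as linearly ordered (Wagner) — the default;
#'   unordered (Fitch) mode exists for testing only.
#' @param alphabet Ordered symbol vector (default 64-state RNA alphabet).
#' @param ancestral Optional per-character ancestral symbol vector.
#' @return Object of class `character_matrix`.
#' @export
character_matrix <- function(states, ordered = TRUE,
                             alphabet = rna_state_alphabet(),
                             ancestral = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) {
    rownames(states) <- paste0("t", seq_len(nrow(states)))
  }
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("c", seq_len(ncol(states)))
  }
  bad <- setdiff(unique(as.vector(states)), c(alphabet, "?"))
  if (length(bad)) {
    stop("states outside alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(ancestral)) {
    if (length(ancestral) != ncol(states)) {
      stop("ancestral_states length must equal character count",
           call. = FALSE)
    }
    if (!all(ancestral %in% alphabet)) {
      stop("ancestral states outside alphabet", call. = FALSE)
    }
  }
  structure(
    list(taxa = rownames(states), characters = colnames(states),
         states = states, ordered = ordered, alphabet = alphabet,
         ancestral = ancestral),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix> ", length(x$taxa), " taxa x ",
      length(x$characters), " characters (",
      if (x$ordered) "ordered" else "unordered", ", ",
      length(x$alphabet), "-state alphabet",
      if (!is.null(x$ancestral)) ", polarized", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.character_matrix <- function(x, ...) {
  tibble::as_tibble(x$states, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "character",
                        values_to = "symbol") |>
    dplyr::mutate(state = symbol_index(.data$symbol, x$alphabet))
}

#' Code substructure lengths into a character matrix
#'
#' Each homologous substructure slot becomes one ordered multistate character;
#' lengths are encoded with [encode_length()] (absent substructures code to
#' the minimum state `0`). With `molecule_rows` the organisms are rows and
#' slots columns; `substructure_rows` is the exact transpose, the orientation
#' used to build trees of substructures.
#'
#' @param x A lengths tibble (`taxon` column plus one integer column per
#'   slot, as returned in `$lengths` by [load_structural_alignment()]) or a
#'   `homology_template` (then `structures` must be supplied).
#' @param structures Named list of aligned `rna_structure` objects, required
#'   when `x` is a template.
#' @param orientation `"molecule_rows"` or `"substructure_rows"`.
#' @param cap_at Saturation index passed to [encode_length()].
#' @param drop_primed Drop primed S-slot columns (the redundant partner strand
#'   of each stem) so every stem is coded once; default TRUE.
#' @return A [character_matrix()].
#' @export
build_matrix <- function(x, structures = NULL,
                         orientation = c("molecule_rows", "substructure_rows"),
                         cap_at = 63L, drop_primed = TRUE) {
  orientation <- match.arg(orientation)
  if (inherits(x, "homology_template")) {
    if (is.null(structures) || !length(structures)) {
      stop("structures required when building from a template", call. = FALSE)
    }
    lens <- lapply(structures, function(s) {
      d <- decompose_structure(s, regions = x)
      stats::setNames(d$length, d$id)
    })
    vals <- do.call(rbind, lens)
    x <- dplyr::bind_cols(
      tibble::tibble(taxon = names(structures)),
      tibble::as_tibble(vals)
    )
  }
  if (!is.data.frame(x) || !"taxon" %in% names(x) || ncol(x) < 2) {
    stop("need a lengths tibble with a 'taxon' column and >= 1 slot column",
         call. = FALSE)
  }
  slots <- setdiff(names(x), "taxon")
  if (drop_primed) slots <- slots[!grepl("'$", slots)]
  if (!length(slots)) stop("empty template: no slots to code", call. = FALSE)
  vals <- as.matrix(x[, slots, drop = FALSE])
  sym <- matrix(encode_length(vals, cap_at = cap_at), nrow = nrow(vals),
                dimnames = list(x$taxon, slots))
  m <- character_matrix(sym)
  if (orientation == "substructure_rows") transpose_matrix(m) else m
}

#' Transpose a character matrix
#'
#' Rows and columns swap; double transposition is the identity. Ancestral
#' states do not survive transposition (they are per-character) and are
#' dropped with a warning if present.
#'
#' @param m A `character_matrix`.
#' @export
transpose_matrix <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  if (!is.null(m$ancestral)) {
    warning("ancestral states dropped on transpose", call. = FALSE)
  }
  character_matrix(t(m$states), ordered = m$ordered, alphabet = m$alphabet)
}

#' Polarize a character matrix
#'
#' Declares the ancestral state of every character, which fixes the direction
#' of character transformation and lets [root_with_ancestor()] root the tree.
#' The default `max_ancestral` treats the maximum observed state as ancestral
#' (the rooting premise for both substructure lengths and census abundances);
#' `min_ancestral` inverts the direction, and `fixed` pins a single symbol,
#' e.g. `"K"` for the 21-state census coding.
#'
#' @param m A `character_matrix`.
#' @param rule `"max_ancestral"`, `"min_ancestral"` or `"fixed"`.
#' @param symbol Ancestral symbol when `rule = "fixed"`.
#' @return The matrix with `ancestral` filled in.
#' @export
polarize <- function(m, rule = c("max_ancestral", "min_ancestral", "fixed"),
                     symbol = NULL) {
  stopifnot(inherits(m, "character_matrix"))
  rule <- match.arg(rule)
  idx <- apply(m$states, 2, function(col) {
    v <- symbol_index(col[col != "?"], m$alphabet)
    if (!length(v)) 0L else v
  }, simplify = FALSE)
  anc <- switch(rule,
    max_ancestral = vapply(idx, max, integer(1)),
    min_ancestral = vapply(idx, min, integer(1)),
    fixed = {
      if (is.null(symbol) || !symbol %in% m$alphabet) {
        stop("fixed rule needs a symbol inside the alphabet", call. = FALSE)
      }
      rep(symbol_index(symbol, m$alphabet), length(m$characters))
    }
  )
  character_matrix(m$states, ordered = m$ordered, alphabet = m$alphabet,
                   ancestral = m$alphabet[anc + 1L])
}
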