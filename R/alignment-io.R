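#' Build a homology template from slot identifiers
#'
#' A homology template names the universal helix regions and the ordered
#' S/B/H/U segment slots they contain, e.g. `h44.S1`, `h44.S1'` (the primed
#' partner strand of the same stem), `h44.H1`. Optional alignment column
#' ranges tie slots to a master alignment.
#'
#' @param slot_ids Character vector of `<region>.<slot>` identifiers, 5'->3'.
#' @param col_start,col_end Optional 1-based closed column ranges per slot.
#' @param aliases Optional named character vector mapping alternative names
#'   (e.g. Brimacombe numbering) onto region ids.
#' @return A tibble of class `homology_template` with columns `slot_id`,
#'   `region`, `slot`, `kind`, `primed`, `partner`, `col_start`, `col_end`.
#' @export
homology_template <- function(slot_ids, col_start = NULL, col_end = NULL,
                              aliases = NULL) {
  if (!length(slot_ids)) stop("empty template", call. = FALSE)
  parts <- strsplit(slot_ids, ".", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    bad <- slot_ids[lengths(parts) < 2]
    stop("slot ids must look like <region>.<slot>: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  region <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
                   character(1))
  slot <- vapply(parts, function(p) p[length(p)], character(1))
  kind <- substr(slot, 1, 1)
  if (!all(kind %in% c("S", "B", "H", "U"))) {
    stop("slot kinds must be one of S, B, H, U", call. = FALSE)
  }
  primed <- grepl("'$", slot)
  partner <- rep(NA_character_, length(slot))
  is_s <- kind == "S"
  partner[is_s & !primed] <- paste0(slot_ids[is_s & !primed], "'")
  partner[is_s & primed] <- sub("'$", "", slot_ids[is_s & primed])
  if (any(is_s)) {
    missing_partner <- is_s & !(partner %in% slot_ids)
    if (any(missing_partner)) {
      stop("every S slot needs its primed partner; missing: ",
           paste(partner[missing_partner], collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(col_start)) col_start <- rep(NA_integer_, length(slot_ids))
  if (is.null(col_end)) col_end <- rep(NA_integer_, length(slot_ids))
  if (!all(is.na(col_start))) {
    o <- order(col_start)
    if (any(col_end < col_start) ||
        any(col_start[o][-1] <= col_end[o][-length(o)])) {
      stop("template column ranges must be disjoint and ascending",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    slot_id = slot_ids, region = region, slot = slot, kind = kind,
    primed = primed, partner = partner,
    col_start = as.integer(col_start), col_end = as.integer(col_end)
  )
  attr(out, "aliases") <- aliases
  class(out) <- c("homology_template", class(out))
  out
}

#' Read a helix-map TSV of per-taxon substructure segment lengths
#'
#' The dialect is one header line `taxon<TAB><slot_id>...` followed by one row
#' per taxon with integer segment lengths (>= 0; 0 means the substructure is
#' absent in that molecule). Returns the template implied by the header, the
#' length table, and per-taxon secondary structures synthesised from the slot
#' lengths (nested stems with `N` sequences), which decompose back to the same
#' lengths.
#'
#' @param path TSV file path.
#' @return List with `template` (homology_template), `lengths` (tibble,
#'   `taxon` + one column per slot) and `structures` (named list of
#'   `rna_structure`).
#' @export
load_structural_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "taxon") {
    stop("helix-map TSV must start with a 'taxon' column", call. = FALSE)
  }
  slot_ids <- header[-1]
  template <- homology_template(slot_ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ragged <- which(lengths(rows) != length(header))
  if (length(ragged)) {
    stop("ragged rows (expected ", length(header), " fields): lines ",
         paste(ragged + 1, collapse = ", "), call. = FALSE)
  }
  taxa <- vapply(rows, `[[`, character(1), 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  if (anyNA(vals) || any(vals < 0)) {
    stop("segment lengths must be non-negative integers", call. = FALSE)
  }
  colnames(vals) <- slot_ids
  lengths_tbl <- dplyr::bind_cols(tibble::tibble(taxon = taxa),
                                  tibble::as_tibble(vals))
  structures <- lapply(seq_along(taxa), function(i) {
    lengths_to_structure(stats::setNames(vals[i, ], slot_ids), template,
                         name = taxa[i])
  })
  names(structures) <- taxa
  list(template = template, lengths = lengths_tbl, structures = structures)
}

#' Write a helix-map TSV
#' @param lengths Tibble with a `taxon` column and one integer column per slot.
#' @param path Output path.
#' @export
write_structural_alignment <- function(lengths, path) {
  stopifnot("taxon" %in% names(lengths))
  readr::write_tsv(lengths, path, progress = FALSE)
  invisible(path)
}

# synthesise a canonical nested structure realising the given slot lengths;
# stems open at S slots and close at their primed partners
lengths_to_structure <- function(lens, template, name = "synthetic") {
  chars <- character(0)
  open <- character(0) # stack of open S slot ids
  for (k in seq_len(nrow(template))) {
    id <- template$slot_id[k]
    l <- lens[[id]]
    kind <- template$kind[k]
    if (kind == "S" && !template$primed[k]) {
      chars <- c(chars, rep("(", l))
      open <- c(open, id)
    } else if (kind == "S") {
      if (!length(open) || utils::tail(open, 1) != template$partner[k]) {
        stop("primed slot ", id, " does not close the innermost open stem",
             call. = FALSE)
      }
      chars <- c(chars, rep(")", l))
      open <- open[-length(open)]
    } else {
      chars <- c(chars, rep(".", l))
    }
  }
  db <- paste(chars, collapse = "")
  parse_dotbracket(db, strrep("N", nchar(db)), name = name)
}

#' Write an ordered multistate character matrix as NEXUS
#'
#' Emits a DATA block (with the full symbols list) and an ASSUMPTIONS block
#' declaring the characters linearly ordered; when ancestral states are
#' present they are written once as an `ANCSTATES` line so that the rooting
#' ancestor travels with the matrix.
#'
#' @param m A [character_matrix()].
#' @param path Output file.
#' @export
write_character_matrix <- function(m, path) {
  stopifnot(inherits(m, "character_matrix"))
  ab <- m$alphabet
  if (!all(m$states %in% c(ab, "?"))) {
    stop("matrix contains symbols outside its alphabet", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("DIMENSIONS NTAX=", length(m$taxa), " NCHAR=", length(m$characters), ";")
  w("FORMAT SYMBOLS=\"", paste(ab, collapse = ""), "\" MISSING=?;")
  w("CHARLABELS ", paste(gsub("[^A-Za-z0-9_.']", "_", m$characters),
                         collapse = " "), ";")
  w("MATRIX")
  lab <- gsub("[^A-Za-z0-9_.']", "_", m$taxa)
  pad <- max(nchar(lab)) + 2
  for (i in seq_along(m$taxa)) {
    w(formatC(lab[i], width = -pad), paste(m$states[i, ], collapse = ""))
  }
  w(";")
  w("END;")
  w("BEGIN ASSUMPTIONS;")
  w("OPTIONS DEFTYPE=", if (isTRUE(m$ordered)) "ord" else "unord", ";")
  if (!is.null(m$ancestral)) {
    w("ANCSTATES ancestor = ", paste(m$ancestral, collapse = ""), ";")
  }
  w("END;")
  invisible(path)
}

#' Read a NEXUS matrix written by [write_character_matrix()]
#' @param path NEXUS file.
#' @return A `character_matrix`.
#' @export
read_character_matrix <- function(path) {
  lines <- readLines(path)
  txt <- paste(lines, collapse = "\n")
  sym <- regmatches(txt, regexpr('SYMBOLS="[^"]*"', txt))
  if (!length(sym)) stop("no SYMBOLS line found", call. = FALSE)
  alphabet <- strsplit(sub('SYMBOLS="([^"]*)"', "\\1", sym), "")[[1]]
  im <- grep("^MATRIX$", lines)
  iend <- grep("^;$", lines)
  iend <- iend[iend > im][1]
  rows <- lines[(im + 1):(iend - 1)]
  parts <- strsplit(trimws(rows), "[[:space:]]+")
  taxa <- vapply(parts, `[[`, character(1), 1)
  states <- do.call(rbind, lapply(parts, function(p) strsplit(p[2], "")[[1]]))
  rownames(states) <- taxa
  cl <- regmatches(txt, regexpr("CHARLABELS [^;]*;", txt))
  if (length(cl)) {
    labs <- strsplit(trimws(sub("CHARLABELS ([^;]*);", "\\1", cl)),
                     "[[:space:]]+")[[1]]
    if (length(labs) == ncol(states)) colnames(states) <- labs
  }
  ordered <- grepl("DEFTYPE=ord", txt)
  anc <- regmatches(txt, regexpr("ANCSTATES ancestor = [^;]*;", txt))
  ancestral <- NULL
  if (length(anc)) {
    ancestral <- strsplit(sub("ANCSTATES ancestor = ([^;]*);", "\\1", anc),
                          "")[[1]]
  }
  character_matrix(states, ordered = ordered, alphabet = alphabet,
                   ancestral = ancestral)
}
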