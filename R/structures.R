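#' Parse a dot-bracket secondary structure
#'
#' Round brackets `()` denote nested (secondary-structure) pairs; square and
#' curly brackets denote pseudoknotted pairs, which are recorded separately and
#' flag the structure as pseudoknotted — they delimit helix regions during
#' decomposition but never form stems.
#'
#' @param structure Dot-bracket line.
#' @param sequence Nucleotide sequence over `A,C,G,U,N,-` (same length).
#' @param name Optional label.
#' @param min_hairpin Minimum unpaired span enclosed by a pair that the parser
#'   will accept; 0 by default so that hand-written toy structures parse, while
#'   [fold_baseline()] enforces the folding minimum of 3.
#' @return An object of class `rna_structure`: list with `name`, `sequence`,
#'   `pairs` (two-column matrix, i < j), `pk_pairs` and `pseudoknotted`.
#' @examples
#' parse_dotbracket("((..))", "GGAACC")$pairs
#' @export
parse_dotbracket <- function(structure, sequence, name = "structure",
                             min_hairpin = 0L) {
  st <- strsplit(structure, "")[[1]]
  sq <- strsplit(toupper(sequence), "")[[1]]
  if (length(st) != length(sq)) {
    stop("structure and sequence lengths differ (", length(st), " vs ",
         length(sq), ")", call. = FALSE)
  }
  bad <- setdiff(unique(sq), c("A", "C", "G", "U", "T", "N", "-"))
  if (length(bad)) {
    stop("sequence contains invalid characters: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  stacks <- list("(" = integer(), "[" = integer(), "{" = integer())
  pairs <- list("(" = NULL, "[" = NULL, "{" = NULL)
  closer_of <- c(")" = "(", "]" = "[", "}" = "{")
  for (k in seq_along(st)) {
    ch <- st[k]
    if (ch %in% names(openers)) {
      stacks[[ch]] <- c(stacks[[ch]], k)
    } else if (ch %in% names(closer_of)) {
      op <- closer_of[[ch]]
      if (!length(stacks[[op]])) {
        stop("unbalanced bracket '", ch, "' at position ", k, call. = FALSE)
      }
      i <- stacks[[op]][length(stacks[[op]])]
      stacks[[op]] <- stacks[[op]][-length(stacks[[op]])]
      pairs[[op]] <- rbind(pairs[[op]], c(i, k))
    } else if (ch != ".") {
      stop("unknown structure character '", ch, "' at position ", k,
           call. = FALSE)
    }
  }
  for (op in names(stacks)) {
    if (length(stacks[[op]])) {
      stop("unbalanced bracket '", op, "' at position ",
           stacks[[op]][1], call. = FALSE)
    }
  }
  p <- pairs[["("]]
  if (is.null(p)) p <- matrix(integer(), 0, 2) else p <- p[order(p[, 1]), , drop = FALSE]
  pk <- rbind(pairs[["["]], pairs[["{"]])
  if (is.null(pk)) pk <- matrix(integer(), 0, 2) else pk <- pk[order(pk[, 1]), , drop = FALSE]
  if (nrow(p) && min_hairpin > 0) {
    span <- p[, 2] - p[, 1] - 1L
    # only innermost pairs bound hairpins; approximate check on all pairs
    if (any(span < min_hairpin)) {
      stop("pair closing fewer than ", min_hairpin, " unpaired bases",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = paste(sq, collapse = ""), pairs = p,
         pk_pairs = pk, pseudoknotted = nrow(pk) > 0),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$name, ": ", nchar(x$sequence), " nt, ",
      nrow(x$pairs), " pairs",
      if (x$pseudoknotted) paste0(" (+", nrow(x$pk_pairs), " pseudoknot)"),
      "\n", sep = "")
  invisible(x)
}

#' Render an rna_structure back to a dot-bracket line
#' @param s An `rna_structure`.
#' @return Dot-bracket string.
#' @export
format_dotbracket <- function(s) {
  n <- nchar(s$sequence)
  out <- rep(".", n)
  if (nrow(s$pairs)) {
    out[s$pairs[, 1]] <- "("
    out[s$pairs[, 2]] <- ")"
  }
  if (nrow(s$pk_pairs)) {
    out[s$pk_pairs[, 1]] <- "["
    out[s$pk_pairs[, 2]] <- "]"
  }
  paste(out, collapse = "")
}

# partner vector: 0 = unpaired, else paired position (secondary pairs only)
partner_vector <- function(s) {
  n <- nchar(s$sequence)
  p <- integer(n)
  if (nrow(s$pairs)) {
    p[s$pairs[, 1]] <- s$pairs[, 2]
    p[s$pairs[, 2]] <- s$pairs[, 1]
  }
  p
}

#' Decompose a secondary structure into S/H/B/U substructure segments
#'
#' Structures are partitioned into helical stems (S), hairpin loops (H), bulge
#' and interior loops (B) and unpaired segments (U). A helix region is a chain
#' of stems connected through interior loops or bulges; regions are delimited
#' by multibranched loops, exterior segments and pseudoknot boundaries.
#' Interior loops contribute one B segment per strand pass. Segments are
#' listed by their 5' start position; S lengths are in base pairs, all others
#' in nucleotides, so summing lengths (counting S twice) recovers the number of
#' non-gap positions.
#'
#' @param s An `rna_structure` (possibly gapped/aligned: `-` contributes 0).
#' @param regions Optional homology template (see
#'   [load_structural_alignment()]); when given, `s` must be aligned to the
#'   template columns and segment lengths are read off the slot column ranges.
#' @return A tibble with columns `id`, `region`, `slot`, `kind`, `length`,
#'   `start`, `end` (5' span; S rows also carry `start3`, `end3`).
#' @examples
#' decompose_structure(parse_dotbracket(".((...)).", "ANNNNNNNNA"))
#' @export
decompose_structure <- function(s, regions = NULL) {
  if (!is.null(regions)) {
    return(decompose_with_template(s, regions))
  }
  seqv <- strsplit(s$sequence, "")[[1]]
  n <- length(seqv)
  p <- partner_vector(s)
  if (n == 0) {
    return(tibble::tibble(id = character(), region = character(),
                          slot = character(), kind = character(),
                          length = integer(), start = integer(),
                          end = integer(), start3 = integer(),
                          end3 = integer()))
  }
  pkpos <- unique(as.vector(s$pk_pairs))

  # maximal stems: runs of stacked pairs
  stems <- list()
  if (nrow(s$pairs)) {
    ord <- s$pairs[order(s$pairs[, 1]), , drop = FALSE]
    cur <- ord[1, , drop = FALSE]
    for (k in seq_len(nrow(ord))[-1]) {
      prev <- cur[nrow(cur), ]
      if (ord[k, 1] == prev[1] + 1 && ord[k, 2] == prev[2] - 1) {
        cur <- rbind(cur, ord[k, ])
      } else {
        stems[[length(stems) + 1]] <- cur
        cur <- ord[k, , drop = FALSE]
      }
    }
    stems[[length(stems) + 1]] <- cur
  }
  stem_of <- integer(n) # stem id per paired position
  for (i in seq_along(stems)) {
    stem_of[as.vector(stems[[i]])] <- i
  }

  # innermost enclosing pair for every position (0 = exterior)
  encl <- integer(n)
  depth_stack <- integer(0)
  for (k in seq_len(n)) {
    if (p[k] > k) { # opening
      encl[k] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
      depth_stack <- c(depth_stack, k)
    } else if (p[k] != 0 && p[k] < k) { # closing
      depth_stack <- depth_stack[-length(depth_stack)]
      encl[k] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
    } else {
      encl[k] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
    }
  }

  # loops: closing pair (i, p[i]) -> child stems directly inside
  loop_children <- list()
  for (st in seq_along(stems)) {
    outer <- stems[[st]][1, ] # outermost pair of the stem
    parent_pair <- encl[outer[1]]
    key <- as.character(parent_pair)
    loop_children[[key]] <- c(loop_children[[key]], st)
  }
  n_children <- function(closing_pos) {
    ch <- loop_children[[as.character(closing_pos)]]
    length(ch)
  }

  # unpaired runs and their classification
  runs <- list()
  k <- 1
  while (k <= n) {
    if (p[k] == 0) {
      j <- k
      while (j < n && p[j + 1] == 0) j <- j + 1
      runs[[length(runs) + 1]] <- c(k, j)
      k <- j + 1
    } else {
      k <- k + 1
    }
  }
  classify_run <- function(a, b) {
    cp <- encl[a]
    if (cp == 0) return("U")
    nk <- n_children(cp)
    if (nk == 0) return("H")
    if (nk == 1) return("B")
    "U" # multiloop segment
  }

  # chain stems into helix regions through interior loops (1-child loops),
  # breaking at pseudoknot-involved loops
  region_of <- seq_along(stems)
  if (length(stems) > 1) {
    for (st in seq_along(stems)) {
      outer <- stems[[st]][1, ]
      cp <- encl[outer[1]]
      if (cp == 0) next
      if (n_children(cp) == 1) {
        parent_stem <- stem_of[cp]
        # pseudoknot boundary: any pk position in the connecting loop breaks it
        inner_parent <- stems[[parent_stem]][nrow(stems[[parent_stem]]), ]
        gap5 <- seq2(inner_parent[1] + 1, outer[1] - 1)
        gap3 <- seq2(outer[2] + 1, inner_parent[2] - 1)
        if (length(pkpos) && any(c(gap5, gap3) %in% pkpos)) next
        region_of[st] <- region_of[parent_stem]
      }
    }
  }
  # normalize region ids in order of first appearance (by 5' start)
  if (length(stems)) {
    starts <- vapply(stems, function(m) m[1, 1], numeric(1))
    reg_first <- tapply(starts, region_of, min)
    reg_rank <- rank(reg_first)
    region_label <- paste0("R", reg_rank[as.character(region_of)])
  }

  seg <- list()
  add_seg <- function(kind, region, length, start, end, start3 = NA_integer_,
                      end3 = NA_integer_) {
    seg[[length(seg) + 1]] <<- list(kind = kind, region = region,
                                    length = length, start = start, end = end,
                                    start3 = start3, end3 = end3)
  }
  nongap <- function(a, b) {
    if (b < a) return(0L)
    sum(seqv[a:b] != "-")
  }
  for (st in seq_along(stems)) {
    m <- stems[[st]]
    add_seg("S", region_label[st], nrow(m), m[1, 1], m[nrow(m), 1],
            m[nrow(m), 2], m[1, 2])
  }
  for (r in runs) {
    kind <- classify_run(r[1], r[2])
    cp <- encl[r[1]]
    region <- if (kind %in% c("H", "B") && cp > 0) {
      region_label[stem_of[cp]]
    } else {
      "ext"
    }
    add_seg(kind, region, nongap(r[1], r[2]), r[1], r[2])
  }
  out <- dplyr::bind_rows(lapply(seg, tibble::as_tibble))
  out <- dplyr::arrange(out, .data$start)
  # slot numbering per region and kind, in 5' order
  out <- out |>
    dplyr::group_by(.data$region, .data$kind) |>
    dplyr::mutate(slot = paste0(.data$kind, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(id = paste(.data$region, .data$slot, sep = ".")) |>
    dplyr::select("id", "region", "slot", "kind", "length", "start", "end",
                  "start3", "end3")
  out
}

seq2 <- function(a, b) if (b < a) integer() else a:b

# template-guided decomposition of an aligned structure: slot lengths are the
# non-gap counts inside each slot's column range (5' span for stems)
decompose_with_template <- function(s, template) {
  stopifnot(inherits(template, "homology_template"))
  seqv <- strsplit(s$sequence, "")[[1]]
  if (any(is.na(template$col_start))) {
    stop("template carries no column ranges; cannot decompose an alignment",
         call. = FALSE)
  }
  if (max(template$col_end) > length(seqv)) {
    stop("structure shorter than template columns (", length(seqv), " < ",
         max(template$col_end), ")", call. = FALSE)
  }
  len <- mapply(function(a, b) sum(seqv[a:b] != "-"),
                template$col_start, template$col_end)
  tibble::tibble(
    id = template$slot_id, region = template$region, slot = template$slot,
    kind = template$kind, length = as.integer(len),
    start = template$col_start, end = template$col_end,
    start3 = NA_integer_, end3 = NA_integer_
  )
}
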