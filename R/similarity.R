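#' Convert a secondary structure into an ordered forest
#'
#' Standard forest representation for RNA structure comparison: each base pair
#' is a P node whose ordered children are the elements it encloses, each
#' unpaired base a B leaf. In-order traversal of the forest recovers the
#' sequence.
#'
#' @param s An `rna_structure` without crossing pairs.
#' @return Object of class `structure_forest`: list with `kind` (1 = P,
#'   0 = B), `parent` (0 = top level) in preorder, and `n`.
#' @export
structure_to_forest <- function(s) {
  p <- partner_vector(s)
  if (s$pseudoknotted) {
    stop("pseudoknotted structures are not supported by forest alignment",
         call. = FALSE)
  }
  n <- length(p)
  kind <- integer(0)
  parent <- integer(0)
  emit <- function(a, b, par) {
    k <- a
    while (k <= b) {
      if (p[k] > k) {
        kind <<- c(kind, 1L)
        parent <<- c(parent, par)
        my_id <- length(kind)
        emit(k + 1L, p[k] - 1L, my_id)
        k <- p[k] + 1L
      } else {
        kind <<- c(kind, 0L)
        parent <<- c(parent, par)
        k <- k + 1L
      }
    }
  }
  if (n > 0) emit(1L, n, 0L)
  structure(list(kind = kind, parent = parent, n = length(kind)),
            class = "structure_forest")
}

#' Local structural alignment score of two forests
#'
#' Structure-only local similarity: the best-scoring pair of closed subforests
#' under tree-alignment recurrences, with P-P matches rewarded strongly, B-B
#' matches weakly, insertions/deletions penalised per node, and P-B
#' substitution disallowed. Sequence identity does not contribute. The score
#' is floored at 0 (empty local alignment).
#'
#' @param f1,f2 `structure_forest` objects (or `rna_structure`, converted).
#' @param scoring Named list: `pair_match` (default 10), `base_match` (1),
#'   `gap` (-5).
#' @return Non-negative numeric score.
#' @examples
#' s <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
#' align_local(s, s) # 4 pairs * 10 + 4 bases * 1 = 44
#' @export
align_local <- function(f1, f2, scoring = list()) {
  sc <- utils::modifyList(list(pair_match = 10, base_match = 1, gap = -5),
                          scoring)
  if (inherits(f1, "rna_structure")) f1 <- structure_to_forest(f1)
  if (inherits(f2, "rna_structure")) f2 <- structure_to_forest(f2)
  if (f1$n == 0 || f2$n == 0) return(0)
  forest_align_cpp(f1$kind, f1$parent, f2$kind, f2$parent,
                   sc$pair_match, sc$base_match, sc$gap)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle via a random Eulerian walk on the dinucleotide
#' multigraph: the returned sequence has exactly the original's dinucleotide
#' count vector (hence also mononucleotide composition) and keeps the first
#' and last residues.
#'
#' @param seq Character string over `A,C,G,U,N`.
#' @return Shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 3) stop("sequence must have length >= 3", call. = FALSE)
  if (!all(chars %in% c("A", "C", "G", "U", "N"))) {
    stop("sequence must be over A, C, G, U, N", call. = FALSE)
  }
  verts <- unique(chars)
  last <- chars[length(chars)]
  # edges: successive dinucleotides
  from <- chars[-length(chars)]
  to <- chars[-1]
  edges_by <- split(to, factor(from, levels = verts))
  repeat {
    # pick a random "last exit" edge for every vertex except the final one
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      outs <- edges_by[[v]]
      if (!length(outs)) next
      last_edge[[v]] <- outs[sample.int(length(outs), 1)]
    }
    # the last-edge graph must connect every vertex (with out-edges) to `last`
    reach <- function(v) {
      seen <- character(0)
      while (!is.null(last_edge[[v]]) && !(v %in% seen) && v != last) {
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      v == last
    }
    for (v in names(last_edge)) {
      if (!reach(v)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # shuffle the remaining edges per vertex, append the reserved last edge
  walk_lists <- list()
  for (v in verts) {
    outs <- edges_by[[v]]
    if (!length(outs)) { walk_lists[[v]] <- character(0); next }
    le <- last_edge[[v]]
    if (!is.null(le)) {
      k <- match(le, outs)
      outs <- outs[-k]
    }
    outs <- if (length(outs) > 1) outs[sample.int(length(outs))] else outs
    walk_lists[[v]] <- c(outs, le)
  }
  # Eulerian walk from the first residue
  out <- character(length(chars))
  out[1] <- chars[1]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  v <- chars[1]
  for (k in seq2(2L, length(chars))) {
    nxt <- walk_lists[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[k] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Count the 16 (plus N) dinucleotides of a sequence
#' @param seq Sequence string.
#' @return Named integer vector of dinucleotide counts.
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  di <- paste0(chars[-length(chars)], chars[-1])
  b <- c("A", "C", "G", "U", "N")
  lv <- as.vector(t(outer(b, b, paste0)))
  c(table(factor(di, levels = lv)))
}

#' Fold a sequence by base-pair maximization
#'
#' Nussinov dynamic programming over Watson-Crick plus GU wobble pairs with a
#' minimum hairpin of `min_loop` unpaired bases; traceback is deterministic
#' (pair when optimal, leftmost partner first). This is the baseline folder
#' used to refold shuffled sequences in the Z-score null; an external
#' thermodynamic folder can be plugged into [zscore_screen()] instead.
#'
#' @param seq Sequence string.
#' @param min_loop Minimum unpaired span inside a hairpin (default 3).
#' @param name Label for the result.
#' @return An `rna_structure`.
#' @export
fold_baseline <- function(seq, min_loop = 3L, name = "folded") {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "U")) - 1L
  code[is.na(code)] <- 9L
  partner <- nussinov_cpp(code, as.integer(min_loop))
  pairs <- which(partner > seq_along(partner))
  pm <- cbind(pairs, partner[pairs])
  s <- parse_dotbracket(strrep(".", length(chars)), paste(chars, collapse = ""),
                        name = name)
  s$pairs <- if (length(pairs)) pm else matrix(integer(), 0, 2)
  s
}

#' Z-score significance screen of structural similarity
#'
#' Aligns a query structure (e.g. an ancestral rRNA helix) against a target
#' (e.g. a ribozyme substructure), then builds a null by shuffling the target
#' sequence with [dinucleotide_shuffle()], refolding each shuffle with
#' [fold_baseline()] (or a supplied folder), and re-aligning against the raw
#' query. Z = (score - null mean) / null sd; similarity is significant at
#' Z >= `threshold` (default 3.0).
#'
#' @param query,target `rna_structure` objects.
#' @param n_shuffles Null size (default 1000).
#' @param threshold Significance threshold on Z.
#' @param seed Seed for the shuffles.
#' @param scoring Passed to [align_local()].
#' @param folder Function `(sequence) -> rna_structure` used to refold
#'   shuffles; default [fold_baseline()].
#' @return Tibble of class `similarity_result`: `score`, `null_mean`,
#'   `null_sd`, `n_shuffles`, `z`, `significant`.
#' @export
zscore_screen <- function(query, target, n_shuffles = 1000, threshold = 3.0,
                          seed = NULL, scoring = list(), folder = NULL) {
  if (is.null(folder)) folder <- function(sq) fold_baseline(sq)
  fq <- structure_to_forest(query)
  score <- align_local(fq, structure_to_forest(target), scoring)
  seq_t <- gsub("-", "", target$sequence, fixed = TRUE)
  one <- function() {
    sh <- dinucleotide_shuffle(seq_t)
    align_local(fq, structure_to_forest(folder(sh)), scoring)
  }
  null <- if (is.null(seed)) {
    replicate(n_shuffles, one())
  } else {
    withr::with_seed(seed, replicate(n_shuffles, one()))
  }
  mu <- mean(null)
  sd0 <- stats::sd(null)
  z <- if (isTRUE(sd0 > 0)) (score - mu) / sd0 else NA_real_
  out <- tibble::tibble(
    score = score, null_mean = mu, null_sd = sd0,
    n_shuffles = as.integer(n_shuffles), z = z,
    significant = isTRUE(z >= threshold)
  )
  if (is.na(z)) {
    warning("null has zero variance: Z undefined, not significant",
            call. = FALSE)
  }
  class(out) <- c("similarity_result", class(out))
  out
}

#' Screen a set of rRNA helices against ribozyme substructures
#'
#' Evaluates the full helix-by-substructure cross product with
#' [zscore_screen()] and summarises the fraction of significant alignments
#' per nd age bin.
#'
#' @param helices Tibble with columns `id`, `nd` and `structure` (list column
#'   of `rna_structure`).
#' @param parts Tibble with columns `id` and `structure` (list column).
#' @param n_shuffles,threshold,seed,scoring Passed to [zscore_screen()].
#' @param bin_width Width of nd bins for the summary (default 0.1).
#' @return List with `results` (tibble: helix, nd, part, score, z,
#'   significant) and `by_bin` (tibble: nd_bin, n, frac_significant).
#' @export
screen_matrix <- function(helices, parts, n_shuffles = 1000, threshold = 3.0,
                          seed = NULL, scoring = list(), bin_width = 0.1) {
  if (!nrow(parts) || !nrow(helices)) {
    empty <- tibble::tibble(helix = character(), nd = numeric(),
                            part = character(), score = numeric(),
                            z = numeric(), significant = logical())
    return(list(results = empty,
                by_bin = tibble::tibble(nd_bin = numeric(), n = integer(),
                                        frac_significant = numeric())))
  }
  grid <- tidyr::expand_grid(hi = seq_len(nrow(helices)),
                             pj = seq_len(nrow(parts)))
  rows <- purrr::pmap(grid, function(hi, pj) {
    sub_seed <- if (is.null(seed)) NULL else seed + 1000L * hi + pj
    r <- zscore_screen(helices$structure[[hi]], parts$structure[[pj]],
                       n_shuffles = n_shuffles, threshold = threshold,
                       seed = sub_seed, scoring = scoring)
    tibble::tibble(helix = helices$id[hi], nd = helices$nd[hi],
                   part = parts$id[pj], score = r$score, z = r$z,
                   significant = r$significant)
  })
  results <- dplyr::bind_rows(rows)
  by_bin <- results |>
    dplyr::mutate(nd_bin = floor(.data$nd / bin_width) * bin_width) |>
    dplyr::group_by(.data$nd_bin) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_significant = mean(.data$significant),
                     .groups = "drop")
  list(results = results, by_bin = by_bin)
}
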