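#' Node-distance chronology of a rooted tree
#'
#' The relative age of a leaf is the number of internal nodes strictly between
#' the root and the leaf, divided by the maximum such count over all leaves,
#' so the most ancestral taxon has nd = 0 and the most recent nd = 1. On trees
#' of substructures grown by accretion, nd is a proxy for relative time.
#'
#' @param t Rooted `phylo` with >= 2 leaves.
#' @return Tibble of class `chronology` with columns `id` and `nd`, sorted by
#'   `nd` then `id`; the tree is attached as attribute `tree`.
#' @export
node_distance <- function(t) {
  stopifnot(inherits(t, "phylo"))
  ntip <- length(t$tip.label)
  if (ntip < 2) stop("need >= 2 leaves", call. = FALSE)
  depth <- node_depths(t)                 # edges from root, per node
  counts <- depth[seq_len(ntip)] - 1L     # internal nodes strictly between
  counts[counts < 0] <- 0L
  mx <- max(counts)
  if (mx == 0) {
    warning("all leaves are equidistant from the root: degenerate chronology",
            call. = FALSE)
    nd <- rep(0, ntip)
  } else {
    nd <- counts / mx
  }
  out <- tibble::tibble(id = t$tip.label, nd = nd) |>
    dplyr::arrange(.data$nd, .data$id)
  attr(out, "tree") <- t
  class(out) <- c("chronology", class(out))
  out
}

# number of edges on the path root -> node, for every node
node_depths <- function(t) {
  phy <- ape::reorder.phylo(t, "cladewise")
  nnode <- length(phy$tip.label) + phy$Nnode
  depth <- integer(nnode)
  root <- phy$edge[1, 1]
  depth[root] <- 0L
  for (k in seq_len(nrow(phy$edge))) {
    depth[phy$edge[k, 2]] <- depth[phy$edge[k, 1]] + 1L
  }
  depth
}

#' Tree imbalance statistics
#'
#' `n_bar` is the mean number of internal nodes between the root and the tips
#' (root counted, tip not); `cherries` counts internal nodes whose children
#' are all leaves. Accretion-driven phylogenies are pectinate: large `n_bar`,
#' few cherries.
#'
#' @param t Rooted `phylo` with >= 2 leaves.
#' @return Tibble with `n_bar` and `cherries`.
#' @export
imbalance_stats <- function(t) {
  stopifnot(inherits(t, "phylo"))
  ntip <- length(t$tip.label)
  depth <- node_depths(t)
  n_bar <- mean(depth[seq_len(ntip)])
  kids <- split(t$edge[, 2], t$edge[, 1])
  cherries <- sum(vapply(kids, function(ch) all(ch <= ntip), logical(1)))
  tibble::tibble(n_bar = n_bar, cherries = as.integer(cherries))
}

#' Null distributions of imbalance under Yule or uniform models
#'
#' Simulates rooted trees under the uniform-speciation (Yule) model (each
#' extant lineage equally likely to split) or the uniform/PDA topology model,
#' collects (n_bar, cherries), and reports two-sided Monte-Carlo tail
#' probabilities for an observed tree.
#'
#' @param n_leaves Leaves per simulated tree.
#' @param model `"yule"` or `"uniform_random"`.
#' @param reps Number of simulated trees (>= 100).
#' @param seed Seed.
#' @param observed Optional observed `phylo` to test.
#' @return List with `stats` (tibble of n_bar, cherries per rep) and, when an
#'   observed tree is given, `p_n_bar` and `p_cherries`.
#' @export
null_tree_ensemble <- function(n_leaves, model = c("yule", "uniform_random"),
                               reps = 1000, seed = NULL, observed = NULL) {
  model <- match.arg(model)
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  draw <- function() {
    t <- if (model == "yule") {
      yule_tree(n_leaves)
    } else {
      edge_to_phylo(random_topology_edge(n_leaves),
                    paste0("t", seq_len(n_leaves)))
    }
    imbalance_stats(t)
  }
  sim <- function() dplyr::bind_rows(replicate(reps, draw(), simplify = FALSE))
  stats_tbl <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  out <- list(stats = stats_tbl, model = model, reps = reps)
  if (!is.null(observed)) {
    obs <- imbalance_stats(observed)
    mc_p <- function(null, x) {
      lo <- (sum(null <= x) + 1) / (length(null) + 1)
      hi <- (sum(null >= x) + 1) / (length(null) + 1)
      min(1, 2 * min(lo, hi))
    }
    out$observed <- obs
    out$p_n_bar <- mc_p(stats_tbl$n_bar, obs$n_bar)
    out$p_cherries <- mc_p(stats_tbl$cherries, obs$cherries)
  }
  out
}

#' Assemble an event timeline from a chronology and annotation tables
#'
#' Annotations date structural events off the chronology: a contact (tRNA arm,
#' r-protein, A-minor, functional centre) takes the nd of the helix it
#' references; an intersubunit bridge takes, by default, the nd of the
#' acceptor element of its donor-acceptor pair (`bridge_rule = "acceptor"`),
#' or the younger of the two partners (`"max"`). Events are sorted by nd with
#' ties broken lexicographically by id.
#'
#' @param chron A [node_distance()] chronology (or any tibble with `id`,
#'   `nd`).
#' @param annotations Tibble with columns `id`, `class` and either `helix`
#'   (contacts) or `acceptor` + `donor` (bridges); other columns are carried
#'   through as annotation.
#' @param bridge_rule `"acceptor"` or `"max"`.
#' @return Tibble of class `timeline`: `id`, `class`, `nd`, plus carried
#'   columns.
#' @export
assemble_timeline <- function(chron, annotations,
                              bridge_rule = c("acceptor", "max")) {
  bridge_rule <- match.arg(bridge_rule)
  nd_of <- stats::setNames(chron$nd, chron$id)
  lookup <- function(ids) {
    unknown <- setdiff(stats::na.omit(unique(ids)), names(nd_of))
    if (length(unknown)) {
      stop("annotations reference unknown elements: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    unname(nd_of[ids])
  }
  if (!nrow(annotations)) {
    return(structure(tibble::tibble(id = character(), class = character(),
                                    nd = numeric()),
                     class = c("timeline", class(tibble::tibble()))))
  }
  ann <- tibble::as_tibble(annotations)
  is_bridge <- !is.na(ann[["acceptor"]] %||% rep(NA, nrow(ann)))
  nd <- numeric(nrow(ann))
  if (any(is_bridge)) {
    acc <- lookup(ann$acceptor[is_bridge])
    if (bridge_rule == "acceptor") {
      nd[is_bridge] <- acc
    } else {
      don <- lookup(ann$donor[is_bridge])
      nd[is_bridge] <- pmax(acc, don)
    }
  }
  if (any(!is_bridge)) {
    if (is.null(ann[["helix"]])) {
      stop("contact annotations need a 'helix' column", call. = FALSE)
    }
    nd[!is_bridge] <- lookup(ann$helix[!is_bridge])
  }
  out <- ann |>
    dplyr::mutate(nd = nd) |>
    dplyr::arrange(.data$nd, .data$id) |>
    dplyr::relocate("id", "class", "nd")
  class(out) <- c("timeline", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age of a protein from the ages of its domains
#'
#' A single-domain protein is as old as its domain. A multi-domain protein is
#' assigned the age of its youngest domain (largest nd_P): the fusion cannot
#' predate the newest part. When the age of the domain combination itself is
#' known and postdates every constituent domain, that is flagged
#' (`combination_postdates`) but the youngest-domain age is still reported.
#'
#' @param domains Tibble (or data frame) with columns `domain` and `nd_p`.
#' @param combination_age Optional nd_P of the fused domain combination.
#' @return Tibble with `nd_p`, `from_domain` and `combination_postdates`.
#' @examples
#' protein_age(tibble::tibble(domain = c("b.40.4", "b.34.5"),
#'                            nd_p = c(0.037, 0.347)))
#' @export
protein_age <- function(domains, combination_age = NULL) {
  if (!nrow(domains)) stop("empty domain list", call. = FALSE)
  k <- which.max(domains$nd_p)
  flag <- !is.null(combination_age) &&
    combination_age > max(domains$nd_p)
  tibble::tibble(nd_p = domains$nd_p[k], from_domain = domains$domain[k],
                 combination_postdates = flag)
}

#' Coevolution regression between rRNA and r-protein ages
#'
#' During early ribosomal history the ages of rRNA helices (nd) and of the
#' r-proteins contacting them (nd_P) follow a tight line; ordinary least
#' squares on early-era pairs gives the interpolation used to date the
#' youngest r-proteins from the helices they touch (and vice versa).
#'
#' @param pairs Tibble with columns `nd` and `nd_p` (>= 3 rows).
#' @param query Optional numeric values to map through the fit.
#' @param direction `"nd_to_nd_p"` (default: query values are nd) or
#'   `"nd_p_to_nd"`.
#' @param nd_max,nd_p_max Early-era cutoffs applied before fitting (defaults
#'   0.35 and 0.2); use `Inf` to fit all pairs.
#' @return Object of class `coevolution_fit` with the `lm` fit, `slope`,
#'   `intercept`, `r_squared`, `f_statistic`, `n`, and `predicted` when a
#'   query was given.
#' @export
interpolate_protein_age <- function(pairs, query = NULL,
                                    direction = c("nd_to_nd_p", "nd_p_to_nd"),
                                    nd_max = 0.35, nd_p_max = 0.2) {
  direction <- match.arg(direction)
  keep <- pairs$nd <= nd_max & pairs$nd_p <= nd_p_max
  dat <- pairs[keep, , drop = FALSE]
  if (nrow(dat) < 3) {
    stop("need >= 3 early-era pairs to fit (have ", nrow(dat), ")",
         call. = FALSE)
  }
  if (stats::var(dat$nd) == 0) {
    stop("zero variance in predictor", call. = FALSE)
  }
  fit <- stats::lm(nd_p ~ nd, data = dat)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  fstat <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
  predicted <- NULL
  if (!is.null(query)) {
    predicted <- if (direction == "nd_to_nd_p") {
      intercept + slope * query
    } else {
      (query - intercept) / slope
    }
  }
  structure(
    list(fit = fit, slope = slope, intercept = intercept,
         r_squared = sm$r.squared, f_statistic = fstat, n = nrow(dat),
         direction = direction, predicted = predicted),
    class = "coevolution_fit"
  )
}

#' @export
print.coevolution_fit <- function(x, ...) {
  cat(sprintf(
    "<coevolution_fit> nd_P = %.3f nd + %.3f (n = %d, R^2 = %.3f, F = %.1f)\n",
    x$slope, x$intercept, x$n, x$r_squared, x$f_statistic))
  invisible(x)
}

#' @export
glance.coevolution_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, f_statistic = x$f_statistic,
                 n = x$n)
}

#' @export
tidy.coevolution_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "nd"),
                 estimate = c(x$intercept, x$slope))
}

#' Heat-map colour table for nd values
#'
#' Ages are binned at 0.01 resolution onto a 101-entry colour map so that
#' structural elements can be painted by relative age in external 2D/3D
#' viewers. Values on another scale (e.g. raw nd_P) can be min-max rescaled to
#' 0-1 first.
#'
#' @param x Tibble with `id` and a value column `nd` (or `nd_p`).
#' @param palette Character vector of 101 colours; default a blue-to-red ramp.
#' @param rescale Min-max rescale values to 0-1 before binning.
#' @return Tibble with `id`, `value`, `bin`, `r`, `g`, `b`, `hex`.
#' @export
heatmap_colors <- function(x, palette = NULL, rescale = FALSE) {
  val_col <- intersect(c("nd", "nd_p", "value"), names(x))[1]
  if (is.na(val_col)) stop("no nd/nd_p/value column found", call. = FALSE)
  v <- x[[val_col]]
  if (rescale) {
    rng <- range(v)
    v <- if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  if (any(v < 0 | v > 1)) {
    stop("values outside [0, 1]; use rescale = TRUE", call. = FALSE)
  }
  if (is.null(palette)) {
    palette <- grDevices::colorRampPalette(c("blue", "red"))(101)
  }
  if (length(palette) != 101) stop("palette must have 101 entries",
                                   call. = FALSE)
  bin <- floor(v * 100 + 0.5) / 100
  hex <- palette[as.integer(bin * 100) + 1L]
  rgb <- grDevices::col2rgb(hex)
  tibble::tibble(id = x$id, value = x[[val_col]], bin = bin,
                 r = rgb[1, ], g = rgb[2, ], b = rgb[3, ], hex = hex)
}
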