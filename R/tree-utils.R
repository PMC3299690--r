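# Internal tree plumbing: conversion between ape "phylo" objects and the raw
# 1-based edge matrices the C++ kernels consume, plus tree generators used by
# stepwise addition, random-tree nulls and exhaustive search.

# renumber an arbitrary rooted edge matrix (tips 1..ntip) to ape convention
# (root = ntip+1, internals consecutive in preorder) and wrap as phylo
edge_to_phylo <- function(edge, tip_labels) {
  ntip <- length(tip_labels)
  kids <- split(edge[, 2], edge[, 1])
  is_child <- edge[, 2]
  root <- setdiff(edge[, 1], is_child)[1]
  new_id <- integer(max(edge))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip + 1L
  out <- matrix(0L, nrow(edge), 2)
  r <- 0L
  walk <- function(u) {
    if (u <= ntip) return(invisible())
    new_id[u] <<- nxt
    nxt <<- nxt + 1L
    for (v in kids[[as.character(u)]]) {
      r <<- r + 1L
      row <- r
      if (v <= ntip) {
        out[row, ] <<- c(new_id[u], v)
      } else {
        # fill child id after assignment below
        walk_child <- v
        out[row, 1] <<- new_id[u]
        walk(v)
        out[row, 2] <<- new_id[walk_child]
      }
    }
  }
  walk(root)
  phy <- structure(
    list(edge = out, tip.label = tip_labels, Nnode = max(out) - ntip),
    class = "phylo", order = "cladewise"
  )
  phy
}

# ape phylo -> raw pieces for the kernels
phylo_to_edge <- function(phy) {
  list(edge = phy$edge, ntip = length(phy$tip.label), labels = phy$tip.label)
}

# 0-based integer tip-state matrix in the order of tip_labels; "?" -> NA
tip_state_matrix <- function(m, tip_labels) {
  miss <- setdiff(tip_labels, m$taxa)
  if (length(miss)) {
    stop("leaves without data in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- m$states[tip_labels, , drop = FALSE]
  out <- matrix(NA_integer_, nrow(s), ncol(s))
  ok <- s != "?"
  out[ok] <- symbol_index(s[ok], m$alphabet)
  storage.mode(out) <- "integer"
  out
}

# star of three tips (trifurcating root = unrooted 3-taxon tree)
.start_tree3 <- function(ntip) {
  root <- ntip + 1L
  matrix(c(root, 1L, root, 2L, root, 3L), ncol = 2, byrow = TRUE)
}

# insert tip `t` on edge row k, using internal node id `x`
.insert_tip <- function(edge, k, t, x) {
  p <- edge[k, 1]; c0 <- edge[k, 2]
  rbind(edge[-k, , drop = FALSE],
        matrix(c(p, x, x, c0, x, t), ncol = 2, byrow = TRUE))
}

# random unrooted binary topology on ntip labelled tips, by sequential
# attachment to a uniformly chosen edge (uniform / PDA model)
random_topology_edge <- function(ntip) {
  if (ntip < 3) stop("need >= 3 tips", call. = FALSE)
  edge <- .start_tree3(ntip)
  nxt <- ntip + 2L
  for (t in seq2(4L, ntip)) {
    k <- sample.int(nrow(edge), 1)
    edge <- .insert_tip(edge, k, t, nxt)
    nxt <- nxt + 1L
  }
  edge
}

# all unrooted binary topologies on tips 1..ntip (edge matrices);
# (2*ntip-5)!! of them, usable up to ntip ~ 8
all_topologies_edge <- function(ntip) {
  stopifnot(ntip >= 3)
  trees <- list(.start_tree3(ntip))
  if (ntip == 3) return(trees)
  for (t in 4:ntip) {
    nxt_id <- ntip + t - 2L
    trees <- unlist(lapply(trees, function(e) {
      lapply(seq_len(nrow(e)), function(k) .insert_tip(e, k, t, nxt_id))
    }), recursive = FALSE)
  }
  trees
}

# grow a Yule (equal-rates) tree: split a uniformly chosen leaf until n leaves
yule_tree <- function(n) {
  stopifnot(n >= 2)
  # rooted; node ids assigned at the end
  parent <- c(NA, 1L, 1L) # node 1 = root with children 2, 3
  is_leaf <- c(FALSE, TRUE, TRUE)
  while (sum(is_leaf) < n) {
    leaves <- which(is_leaf)
    u <- leaves[sample.int(length(leaves), 1)]
    parent <- c(parent, u, u)
    is_leaf[u] <- FALSE
    is_leaf <- c(is_leaf, TRUE, TRUE)
  }
  leaves <- which(is_leaf)
  internals <- which(!is_leaf)
  ntip <- length(leaves)
  new_id <- integer(length(parent))
  new_id[leaves] <- seq_len(ntip)
  new_id[internals] <- ntip + seq_along(internals)
  edge <- cbind(new_id[parent[-1]], new_id[-1])
  phy <- structure(
    list(edge = edge, tip.label = paste0("t", seq_len(ntip)),
         Nnode = length(internals)),
    class = "phylo"
  )
  ape::reorder.phylo(phy, "cladewise")
}

# rooted caterpillar (pectinate) tree on n tips
caterpillar_tree <- function(n) {
  txt <- paste0(paste(rep("(", n - 1), collapse = ""), "t1,t2)",
                paste(vapply(seq2(3L, n), function(i) paste0(",t", i, ")"),
                      character(1)), collapse = ""), ";")
  ape::read.tree(text = txt)
}
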