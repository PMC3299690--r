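# Independent brute-force oracles used across the suite. These never call the
# code paths they check.

# minimum tree length by enumerating every internal-node state assignment
oracle_tree_length <- function(phy, tip_states, n_states) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  ints <- (ntip + 1):nn
  grid <- expand.grid(rep(list(0:(n_states - 1)), length(ints)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- integer(nn)
    a[seq_len(ntip)] <- tip_states
    a[ints] <- unlist(grid[r, ])
    best <- min(best, sum(abs(a[phy$edge[, 1]] - a[phy$edge[, 2]])))
  }
  best
}

# maximum nested base-pair count by recursive enumeration (memoized)
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  can <- function(a, b) {
    paste0(sort(c(ch[a], ch[b])), collapse = "") %in% c("AU", "CG", "GU")
  }
  memo <- new.env()
  f <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (can(k, j)) {
        v <- 1L + (if (k > i) f(i, k - 1) else 0L) +
          (if (k + 1 <= j - 1) f(k + 1, j - 1) else 0L)
        best <- max(best, v)
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) 0L else f(1, n)
}

# all dinucleotide-preserving rearrangements of a sequence (first and last
# residues fixed), by filtering interior permutations
oracle_shuffle_set <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  mid <- ch[2:(n - 1)]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  dicount <- function(x) {
    di <- paste0(x[-length(x)], x[-1])
    table(factor(di, levels = sort(unique(paste0(
      rep(c("A", "C", "G", "U", "N"), each = 5),
      c("A", "C", "G", "U", "N"))))))
  }
  ref <- dicount(ch)
  cand <- unique(vapply(perms(mid), function(p) {
    paste(c(ch[1], p, ch[n]), collapse = "")
  }, character(1)))
  cand[vapply(cand, function(s) {
    all(dicount(strsplit(s, "")[[1]]) == ref)
  }, logical(1))]
}

# exhaustive maximum-parsimony length over all topologies, via the scorer
# (used where the oracle targets the *search*, not the scorer)
exhaustive_best_length <- function(m) {
  ntip <- length(m$taxa)
  st <- riboclock:::tip_state_matrix(m, m$taxa)
  topos <- riboclock:::all_topologies_edge(ntip)
  min(vapply(topos, function(e) {
    riboclock:::score_edge_cpp(e, ntip, st, length(m$alphabet),
                               rep(1, ncol(st)))
  }, numeric(1)))
}

# quick random ordered matrix on digit states
random_digit_matrix <- function(ntip, nchar_, max_state = 7) {
  sym <- matrix(as.character(sample(0:max_state, ntip * nchar_, TRUE)),
                ntip, nchar_,
                dimnames = list(paste0("t", seq_len(ntip)),
                                paste0("c", seq_len(nchar_))))
  character_matrix(sym)
}

# random non-crossing structure via folding a random sequence
random_structure <- function(len, seed = NULL) {
  draw <- function() {
    paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
  }
  sq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  fold_baseline(sq)
}
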