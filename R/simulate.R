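#' Simulate an accretion-style structural alignment with planted ages
#'
#' Emulates a set of homologous RNA molecules whose universal helices were
#' born sequentially: older helices (low birth rank) start from longer stems,
#' and segment lengths drift by +/-1 along the branches of a Yule guide tree.
#' Older helices also drift less, reflecting the canalization premise that
#' ancient substructures are more ordered. The planted birth ranks are the
#' ground truth that [helix_ages()] should recover.
#'
#' Each helix region carries slots `S1`, `H1`, `S1'`; stem baselines decrease
#' linearly from `stem_max` with birth rank (floor `stem_min`), hairpins start
#' at 4 nt. The per-branch drift probability for a helix of rank r out of H is
#' `drift_prob * (0.25 + 0.75 * r / H)`.
#'
#' @param n_taxa Number of molecules (>= 4); default 30.
#' @param n_helices Number of universal helices (>= 4); default 20.
#' @param drift_prob Baseline per-branch, per-segment drift probability;
#'   default 0.1. 0 gives identical taxa (a degenerate, constant matrix).
#' @param stem_max,stem_min Baseline stem length (bp) of the oldest helix and
#'   the floor for the youngest.
#' @param seed Seed; the simulation is bit-reproducible given it.
#' @param dir Optional directory: writes `helix_map.tsv`, `truth.tsv` and
#'   `guide_tree.nwk`.
#' @param invert Tie age to *shorter* baselines instead (to exercise
#'   min-ancestral polarization).
#' @return List with `lengths` (helix-map tibble), `truth` (tibble: helix,
#'   birth_rank, baseline_stem), `guide_tree` (`phylo`), `params`.
#' @export
simulate_accretion <- function(n_taxa = 30, n_helices = 20, drift_prob = 0.1,
                               stem_max = 24, stem_min = 4, seed = 1,
                               dir = NULL, invert = FALSE) {
  if (n_taxa < 4 || n_helices < 4) {
    stop("need n_taxa >= 4 and n_helices >= 4", call. = FALSE)
  }
  if (drift_prob < 0 || drift_prob > 1) {
    stop("drift_prob must be in [0, 1]", call. = FALSE)
  }
  res <- withr::with_seed(seed, {
    guide <- yule_tree(n_taxa)
    guide$tip.label <- paste0("taxon", seq_len(n_taxa))
    ranks <- sample.int(n_helices) # birth rank per helix index
    helix <- paste0("h", seq_len(n_helices))
    eff_rank <- if (invert) n_helices + 1 - ranks else ranks
    base_stem <- pmax(stem_min,
                      round(stem_max - (eff_rank - 1) *
                              (stem_max - stem_min) / (n_helices - 1)))
    base_hairpin <- rep(4L, n_helices)
    p_h <- drift_prob * (0.25 + 0.75 * ranks / n_helices)
    # drift along the guide tree: value at node = parent value + step
    phy <- ape::reorder.phylo(guide, "cladewise")
    nnode <- n_taxa + phy$Nnode
    stem_val <- matrix(0L, nnode, n_helices)
    hp_val <- matrix(0L, nnode, n_helices)
    root <- phy$edge[1, 1]
    stem_val[root, ] <- base_stem
    hp_val[root, ] <- base_hairpin
    step <- function(v, p) {
      move <- stats::rbinom(length(v), 1, p) *
        sign(stats::runif(length(v)) - 0.5)
      pmax(0L, as.integer(v + move))
    }
    for (k in seq_len(nrow(phy$edge))) {
      a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
      stem_val[b, ] <- step(stem_val[a, ], p_h)
      hp_val[b, ] <- step(hp_val[a, ], p_h)
    }
    list(guide = guide, ranks = ranks, helix = helix, base_stem = base_stem,
         stem = stem_val[seq_len(n_taxa), , drop = FALSE],
         hp = hp_val[seq_len(n_taxa), , drop = FALSE])
  })
  slot_ids <- as.vector(vapply(res$helix, function(h) {
    paste0(h, c(".S1", ".H1", ".S1'"))
  }, character(3)))
  vals <- matrix(0L, n_taxa, length(slot_ids),
                 dimnames = list(NULL, slot_ids))
  for (j in seq_len(n_helices)) {
    vals[, 3 * j - 2] <- res$stem[, j]
    vals[, 3 * j - 1] <- res$hp[, j]
    vals[, 3 * j] <- res$stem[, j]
  }
  lengths_tbl <- dplyr::bind_cols(
    tibble::tibble(taxon = res$guide$tip.label),
    tibble::as_tibble(vals)
  )
  truth <- tibble::tibble(helix = res$helix, birth_rank = res$ranks,
                          baseline_stem = res$base_stem)
  if (drift_prob == 0) {
    warning("drift_prob = 0: all taxa identical, matrix is constant",
            call. = FALSE)
  }
  out <- list(lengths = lengths_tbl, truth = truth, guide_tree = res$guide,
              params = list(n_taxa = n_taxa, n_helices = n_helices,
                            drift_prob = drift_prob, stem_max = stem_max,
                            stem_min = stem_min, seed = seed,
                            invert = invert))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_structural_alignment(lengths_tbl, file.path(dir, "helix_map.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    ape::write.tree(res$guide, file.path(dir, "guide_tree.nwk"))
    out$files <- file.path(dir, c("helix_map.tsv", "truth.tsv",
                                  "guide_tree.nwk"))
  }
  out
}

#' Simulate a proteome-by-domain abundance census with planted domain ages
#'
#' Domain superfamilies get ages a in \[0, 1\] (1 = oldest); a domain is
#' present in a proteome with probability increasing in its age, and when
#' present its abundance is `1 + Poisson(exp(alpha + beta * a))`. With
#' `beta > 0` old domains are both widespread and abundant — the premise
#' behind 'K'-ancestral polarization; `beta = 0` removes the recoverable
#' signal (negative control).
#'
#' @param n_proteomes Default 50.
#' @param n_domains Default 30 (>= 4).
#' @param beta Age-abundance coupling; default 2.
#' @param alpha Baseline log-abundance; default 1.
#' @param seed Seed.
#' @param dir Optional output directory (`abundance.tsv`, `truth.tsv`).
#' @return List with `abundance` (tibble), `truth` (tibble: domain, age,
#'   birth_rank with 1 = oldest), `params`.
#' @export
simulate_census <- function(n_proteomes = 50, n_domains = 30, beta = 2,
                            alpha = 1, seed = 1, dir = NULL) {
  if (n_domains < 4) stop("need n_domains >= 4", call. = FALSE)
  if (n_proteomes < 2) {
    warning("very few proteomes: ages will be noisy", call. = FALSE)
  }
  res <- withr::with_seed(seed, {
    age <- stats::runif(n_domains)
    # presence coupling scales with beta so that beta = 0 removes *all*
    # age signal (abundance and spread alike)
    pres_p <- stats::plogis(-2 + 2.5 * beta * age)
    lam <- exp(alpha + beta * age)
    g <- matrix(0L, n_proteomes, n_domains)
    for (d in seq_len(n_domains)) {
      pres <- stats::rbinom(n_proteomes, 1, pres_p[d])
      g[, d] <- pres * (1L + stats::rpois(n_proteomes, lam[d]))
    }
    list(age = age, g = g)
  })
  domain <- sprintf("c.%d.1", seq_len(n_domains))
  colnames(res$g) <- domain
  abundance <- dplyr::bind_cols(
    tibble::tibble(proteome = sprintf("p%03d", seq_len(n_proteomes))),
    tibble::as_tibble(res$g)
  )
  truth <- tibble::tibble(domain = domain, age = res$age,
                          birth_rank = rank(-res$age, ties.method = "first"))
  out <- list(abundance = abundance, truth = truth,
              params = list(n_proteomes = n_proteomes, n_domains = n_domains,
                            beta = beta, alpha = alpha, seed = seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_abundance_table(abundance, file.path(dir, "abundance.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
    out$files <- file.path(dir, c("abundance.tsv", "truth.tsv"))
  }
  out
}

#' Small hand-checkable fixtures
#'
#' A 5-taxon, 4-character ordered matrix whose most-parsimonious length
#' (stored in `mp_length`) was computed by exhaustive search over all 15
#' topologies; bridge and contact annotation tables for the 4 helices; and a
#' query helix plus two ribozyme-like structures, one containing a planted
#' copy of the query substructure (`planted`), one unrelated (`control`).
#'
#' @return List with `matrix`, `mp_length`, `bridges`, `contacts`, `query`,
#'   `planted`, `control`.
#' @export
toy_fixtures <- function() {
  states <- matrix(
    c("0", "1", "5", "7",
      "1", "1", "5", "8",
      "4", "3", "5", "2",
      "5", "3", "6", "1",
      "8", "6", "6", "0"),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("h", 1:5), paste0("taxon", 1:4))
  )
  m <- character_matrix(states)
  bridges <- tibble::tibble(
    id = c("B1", "B2"), class = "bridge",
    acceptor = c("h1", "h2"), donor = c("h3", "h4")
  )
  contacts <- tibble::tibble(
    id = c("tRNA-acceptor", "S12"), class = c("contact", "protein"),
    helix = c("h2", "h1")
  )
  qdb <- "((((..((((....))))..((((....))))..))))"
  qsq <- "GGGGAACCGCAAAAGCGGAAGGCGAAAACGCCAACCCC"
  query <- parse_dotbracket(qdb, qsq, name = "query-helix")
  planted <- parse_dotbracket(
    paste0("...", qdb, strrep(".", 11)),
    paste0("AAA", qsq, strrep("A", 11)),
    name = "ribozyme-planted")
  cdb <- "..((....)).((....)).."
  csq <- "AAGGAAAACCAGGAAAACCAA"
  control <- parse_dotbracket(cdb, csq, name = "ribozyme-control")
  list(matrix = m, mp_length = 22L, bridges = bridges, contacts = contacts,
       query = query, planted = planted, control = control)
}
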