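#' Validate pipeline inputs without running anything
#'
#' Schema checks per input file plus cross-reference checks (annotation ids
#' must name helix regions of the template; taxon labels must be unique).
#' Nothing is mutated; problems are listed, not thrown.
#'
#' @param config Pipeline configuration list (or YAML path), see
#'   [run_pipeline()].
#' @return Tibble with columns `input`, `problem` (empty when clean).
#' @export
validate_inputs <- function(config) {
  config <- normalize_config(config)
  problems <- list()
  note <- function(input, msg) {
    problems[[length(problems) + 1]] <<- tibble::tibble(input = input,
                                                        problem = msg)
  }
  helix_map <- NULL
  if (!is.null(config$inputs$helix_map)) {
    path <- config$inputs$helix_map
    if (!file.exists(path)) {
      note("helix_map", paste0("file not found: ", path))
    } else {
      helix_map <- tryCatch(load_structural_alignment(path), error = identity)
      if (inherits(helix_map, "error")) {
        note("helix_map", conditionMessage(helix_map))
        helix_map <- NULL
      } else if (anyDuplicated(helix_map$lengths$taxon)) {
        dup <- unique(helix_map$lengths$taxon[
          duplicated(helix_map$lengths$taxon)])
        note("helix_map", paste0("duplicate taxon labels: ",
                                 paste(dup, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$inputs$abundance)) {
    path <- config$inputs$abundance
    if (!file.exists(path)) {
      note("abundance", paste0("file not found: ", path))
    } else {
      ab <- tryCatch(read_abundance_table(path), error = identity)
      if (inherits(ab, "error")) note("abundance", conditionMessage(ab))
    }
  }
  for (ann_name in c("bridges", "contacts")) {
    path <- config$inputs[[ann_name]]
    if (is.null(path)) next
    if (!file.exists(path)) {
      note(ann_name, paste0("file not found: ", path))
      next
    }
    ann <- tryCatch(readr::read_tsv(path, show_col_types = FALSE,
                                    progress = FALSE),
                    error = identity)
    if (inherits(ann, "error")) {
      note(ann_name, conditionMessage(ann))
      next
    }
    if (!is.null(helix_map)) {
      regions <- unique(helix_map$template$region)
      refs <- unique(stats::na.omit(unlist(
        ann[intersect(c("helix", "acceptor", "donor"), names(ann))])))
      unknown <- setdiff(refs, regions)
      if (length(unknown)) {
        note(ann_name, paste0("unknown helix ids: ",
                              paste(unknown, collapse = ", ")))
      }
    }
  }
  if (!length(problems)) {
    return(tibble::tibble(input = character(), problem = character()))
  }
  dplyr::bind_rows(problems)
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L, out_dir = "riboclock-out",
    stages = c("simulate", "code", "tree", "chronology", "census",
               "similarity"),
    inputs = list(),
    simulate = list(), census = list(), similarity = list(),
    polarize_rule = "max_ancestral",
    search = list(addition = "input_order", n_starts = 5, max_trees = 100),
    bootstrap_reps = 0, bridge_rule = "acceptor"
  )
  known <- names(defaults)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

#' Run the full structural-phylogenomics pipeline
#'
#' Orchestrates the stages end to end: input simulation (or loading), stem
#' character coding, parsimony tree inference with ancestor rooting, nd
#' chronology with timelines and heat-map colour tables, the abundance-census
#' nd_P chronology, and the ribozyme similarity screen. Every stochastic
#' stage is seeded from the global seed, so reruns with the same
#' configuration are byte-identical; a `manifest.json` records inputs,
#' parameters and seeds.
#'
#' @param config Named list or YAML path. Keys: `seed`, `out_dir`, `stages`
#'   (subset of simulate, code, tree, chronology, census, similarity),
#'   `inputs` (paths: helix_map, abundance, bridges, contacts),
#'   `polarize_rule`, `search` (addition, n_starts, max_trees),
#'   `bootstrap_reps`, `bridge_rule`, `simulate`/`census`/`similarity`
#'   (stage parameter lists). Unknown keys are rejected.
#' @return Invisible list of in-memory results (`chronology`, `fit`,
#'   `trees`, `census_ages`, `timeline`, `screen`, `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- normalize_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pieces <- list()
  if ("simulate" %in% config$stages) {
    pieces$accretion <- stage("simulate", do.call(simulate_accretion, c(
      config$simulate, list(seed = config$seed,
                            dir = file.path(config$out_dir, "simulated")))))
    pieces$census_sim <- stage("simulate", do.call(simulate_census, c(
      config$census, list(seed = config$seed + 1L,
                          dir = file.path(config$out_dir, "simulated")))))
    lengths <- pieces$accretion$lengths
    abundance <- pieces$census_sim$abundance
  } else {
    if (is.null(config$inputs$helix_map)) {
      stop("stage [code] failed: no helix_map input and simulate disabled",
           call. = FALSE)
    }
    loaded <- stage("code", load_structural_alignment(config$inputs$helix_map))
    lengths <- loaded$lengths
    abundance <- if (!is.null(config$inputs$abundance)) {
      stage("census", read_abundance_table(config$inputs$abundance))
    }
  }
  if ("code" %in% config$stages) {
    m <- stage("code", {
      m0 <- build_matrix(lengths, orientation = "substructure_rows")
      polarize(m0, rule = config$polarize_rule)
    })
    res$matrix <- m
    stage("code", write_character_matrix(
      m, file.path(config$out_dir, "characters.nex")))
  }
  if ("tree" %in% config$stages) {
    res$chronology <- stage("tree", do.call(helix_ages, c(
      list(lengths, rule = config$polarize_rule, seed = config$seed),
      config$search)))
    rooted <- attr(res$chronology, "tree")
    ape::write.tree(rooted, file.path(config$out_dir, "helix_tree.nwk"))
    res$fit <- stage("tree", fit_stats(rooted, res$matrix,
                                       n_random_trees = 200,
                                       seed = config$seed + 2L))
    readr::write_tsv(glance(res$fit),
                     file.path(config$out_dir, "fit_stats.tsv"),
                     progress = FALSE)
    if (config$bootstrap_reps > 0) {
      bs <- stage("tree", bootstrap_support(res$matrix,
                                            reps = config$bootstrap_reps,
                                            seed = config$seed + 3L))
      ape::write.tree(bs, file.path(config$out_dir, "bootstrap.nwk"))
    }
  }
  if ("chronology" %in% config$stages && !is.null(res$chronology)) {
    readr::write_tsv(tibble::as_tibble(res$chronology),
                     file.path(config$out_dir, "chronology.tsv"),
                     progress = FALSE)
    cols <- heatmap_colors(res$chronology)
    readr::write_tsv(cols, file.path(config$out_dir, "heatmap_colors.tsv"),
                     progress = FALSE)
    ann <- NULL
    if (!is.null(config$inputs$bridges)) {
      ann <- readr::read_tsv(config$inputs$bridges, show_col_types = FALSE,
                             progress = FALSE)
    }
    if (!is.null(ann)) {
      res$timeline <- stage("chronology", assemble_timeline(
        res$chronology, ann, bridge_rule = config$bridge_rule))
      readr::write_tsv(tibble::as_tibble(res$timeline),
                       file.path(config$out_dir, "timeline.tsv"),
                       progress = FALSE)
    }
  }
  if ("census" %in% config$stages && !is.null(abundance)) {
    res$census_ages <- stage("census", domain_ages(abundance,
                                                   seed = config$seed + 4L))
    readr::write_tsv(
      tibble::as_tibble(res$census_ages) |>
        dplyr::rename(domain = "id", nd_p = "nd"),
      file.path(config$out_dir, "domain_ages.tsv"), progress = FALSE)
  }
  if ("similarity" %in% config$stages) {
    toy <- toy_fixtures()
    helices <- tibble::tibble(id = "query-helix", nd = 0,
                              structure = list(toy$query))
    parts <- tibble::tibble(id = c(toy$planted$name, toy$control$name),
                            structure = list(toy$planted, toy$control))
    sim_opts <- utils::modifyList(list(n_shuffles = 200), config$similarity)
    res$screen <- stage("similarity", do.call(screen_matrix, c(
      list(helices, parts, seed = config$seed + 5L), sim_opts)))
    readr::write_tsv(res$screen$results,
                     file.path(config$out_dir, "similarity_screen.tsv"),
                     progress = FALSE)
  }
  manifest <- list(
    package = "riboclock",
    version = as.character(utils::packageVersion("riboclock")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[c("polarize_rule", "search", "bootstrap_reps",
                          "bridge_rule", "simulate", "census", "similarity")],
    inputs = config$inputs,
    outputs = list.files(config$out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
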