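write_tsv_meta <- function(tab, path, meta) {
  lines <- paste0("# ", names(meta), ": ", unlist(meta))
  readr::write_lines(lines, path)
  readr::write_tsv(as_tibble(tab), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the end-to-end discovery workflow
#'
#' Orchestrates the full pipeline from a configuration: load or synthesize
#' the prior network and per-condition contrasts, infer ITRs per condition,
#' build the cross-condition overlap matrix and common core, induce the
#' core interaction network with pathway enrichment when an interaction
#' graph / pathway sets are supplied, optionally derive a gene signature
#' for a chosen regulator and stratify a cohort, and optionally normalize a
#' screen plate and classify peaks. All tabular outputs are written as TSV
#' with `#`-prefixed metadata headers; the run is deterministic given the
#' config and seed.
#'
#' @param config A named list or path to a YAML file. Recognised fields:
#'   `seed` (default 1), `synthetic` (logical; generate inputs when TRUE),
#'   `conditions` (named list regulator -> direction per condition, for the
#'   synthetic scenario), `network_path`, `contrast_paths` (named),
#'   `top_n` (default 100), `min_conditions`, `signature_regulator`,
#'   `interactions_path`, `gene_sets_path`, `screen` (logical),
#'   `peaks` (logical).
#' @param out_dir Output directory (created if missing).
#' @return A `run_report`: list of result objects, output file paths and a
#'   provenance block (config hash, seed).
#' @export
run_discovery <- function(config, out_dir = tempfile("itr_run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  top_n <- config$top_n %||% 100
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  meta <- list(seed = seed, config_hash = rlang::hash(config))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  scfg <- scenario_config(seed = seed)
  if (isTRUE(config$synthetic)) {
    network <- stage("network", generate_prior_network(scfg))
    conditions <- config$conditions %||% default_conditions(network, scfg)
    conditions <- purrr::map(conditions, unlist)
    gen <- stage("contrasts", generate_contrasts(network, conditions, scfg))
    contrasts <- gen$contrasts
  } else {
    network <- stage("network", read_prior_network(config$network_path))
    contrasts <- stage("contrasts", purrr::imap(
      config$contrast_paths, ~ load_contrast(.x, condition = .y)
    ))
  }

  # --- inference per condition ---------------------------------------------
  rankings <- stage("infer", purrr::map(contrasts, function(tab) {
    infer_itrs(network, significant_set(tab,
                                        fdr_max = config$fdr_max %||% 0.05,
                                        min_abs_log2fc = config$min_abs_log2fc %||% 0))
  }))
  for (cond in names(rankings)) {
    p <- file.path(out_dir, paste0("itrs_", cond, ".tsv"))
    write_tsv_meta(rankings[[cond]], p, c(meta, condition = cond))
    paths[[paste0("itrs_", cond)]] <- p
  }

  # --- integration ----------------------------------------------------------
  overlap <- NULL
  core <- NULL
  if (length(rankings) >= 2) {
    overlap <- stage("overlap", topn_overlap_matrix(rankings, n = top_n))
    paths$overlap <- file.path(out_dir, "overlap_matrix.tsv")
    write_overlap_matrix(overlap, paths$overlap)
    core <- stage("core", common_core(
      rankings, n = top_n,
      min_conditions = config$min_conditions %||% length(rankings)
    ))
    paths$core <- file.path(out_dir, "core_set.tsv")
    write_tsv_meta(
      dplyr::mutate(core$membership,
                    conditions = purrr::map_chr(.data$conditions,
                                                paste, collapse = ",")),
      paths$core, meta
    )
  }

  core_net <- NULL
  enrichment <- NULL
  if (!is.null(core) && !is.null(config$interactions_path)) {
    graph <- stage("interactions", read_interactions(config$interactions_path))
    core_net <- stage("core_network", core_network(
      core, graph,
      types = unlist(config$regulator_types),
      exclude_types = config$exclude_types
    ))
    paths$core_network <- file.path(out_dir, "core_network_edges.tsv")
    write_tsv_meta(core_net$edges, paths$core_network, meta)
    if (!is.null(config$gene_sets_path)) {
      pathways <- stage("gene_sets", read_gene_sets(config$gene_sets_path))
      universe <- unique(c(graph$node_a, graph$node_b, core_net$nodes))
      enrichment <- stage("enrichment", pathway_enrichment(
        core_net$nodes, pathways, universe
      ))
      paths$enrichment <- file.path(out_dir, "pathway_enrichment.tsv")
      write_tsv_meta(enrichment, paths$enrichment, meta)
    }
  }

  profiles <- stage("z_profiles", z_profiles(
    rankings,
    regulators = if (!is.null(core)) core$regulators else NULL
  ))
  paths$z_profiles <- file.path(out_dir, "z_profiles.tsv")
  write_tsv_meta(profiles, paths$z_profiles, meta)

  # --- optional signature + survival ---------------------------------------
  signature <- NULL
  stratification <- NULL
  if (!is.null(config$signature_regulator)) {
    reg <- config$signature_regulator
    contributions <- stage("signature", dplyr::bind_rows(purrr::map(
      contrasts, function(tab) {
        itr_contributions(network, significant_set(tab), reg)
      }
    )))
    signature <- stage("signature", build_signature(
      reg, contributions,
      min_conditions = config$signature_min_conditions %||% 2
    ))
    paths$signature <- file.path(out_dir, "signature.tsv")
    write_tsv_meta(signature, paths$signature, c(meta, regulator = reg))
    if (isTRUE(config$cohort) || isTRUE(config$synthetic)) {
      gen_c <- stage("cohort", generate_cohort(signature, scfg))
      scores <- stage("scores", score_cohort(signature, gen_c$cohort))
      stratification <- stage("stratify", stratify_and_test(
        scores, gen_c$cohort, split = config$split %||% 0.5
      ))
      paths$stratification <- file.path(out_dir, "stratification.tsv")
      write_tsv_meta(glance(stratification), paths$stratification, meta)
    }
  }

  # --- optional screen stage -------------------------------------------------
  hits <- NULL
  if (isTRUE(config$screen)) {
    gen_p <- stage("screen", generate_plate(scfg))
    corrected <- stage("screen", loess_normalize(gen_p$plate))
    wr <- stage("screen", well_results(corrected))
    hits <- stage("screen", call_hits(wr[wr$role == "sample", ],
                                      threshold = config$hit_threshold %||% 1))
    paths$hits <- file.path(out_dir, "screen_hits.tsv")
    write_tsv_meta(hits, paths$hits, meta)
  }

  # --- optional peak stage ---------------------------------------------------
  peak_summary <- NULL
  if (isTRUE(config$peaks)) {
    fx <- stage("peaks", generate_genome_fixture(seed = seed))
    cls <- stage("peaks", classify_peaks(fx$peaks, fx$genes))
    peak_summary <- cls$summary
    paths$peak_context <- file.path(out_dir, "peak_context.tsv")
    write_tsv_meta(peak_summary, paths$peak_context, meta)
  }

  structure(
    list(
      rankings = rankings, overlap = overlap, core = core,
      core_network = core_net, enrichment = enrichment,
      z_profiles = profiles, signature = signature,
      stratification = stratification, hits = hits,
      peak_summary = peak_summary,
      paths = paths, out_dir = out_dir, provenance = meta
    ),
    class = "run_report"
  )
}

#' Default cross-condition scenario: shared core plus an unrelated condition
#'
#' Three related conditions plant a common core of regulators (mostly
#' inhibited, as oncogene-driven lines predominantly suppress their
#' regulator networks) plus a few condition-specific regulators each; a
#' fourth, unrelated condition plants a disjoint regulator set. This is the
#' structure behind a block-patterned top-N overlap matrix: high within-trio
#' overlap, low overlap between the trio and the unrelated condition.
#'
#' @param network A [prior_network()] with enough regulators
#'   (`n_core + 3 * n_specific + n_unrelated`).
#' @param n_core Size of the shared planted core (default 60).
#' @param n_specific Condition-specific planted regulators per trio member
#'   (default 15).
#' @param n_unrelated Planted regulators of the unrelated condition
#'   (default 75).
#' @return Named list of planted-direction vectors, one per condition.
#' @export
shared_core_conditions <- function(network, n_core = 60, n_specific = 15,
                                   n_unrelated = 75) {
  regs <- network$regulators
  need <- n_core + 3 * n_specific + n_unrelated
  if (length(regs) < need) {
    abort(paste0("Network has ", length(regs), " regulators; scenario needs ",
                 need, "."))
  }
  dirs <- function(n) rep(c(-1, 1), length.out = n)  # predominantly inhibited
  core <- regs[seq_len(n_core)]
  off <- n_core
  specific <- purrr::map(1:3, function(i) {
    s <- regs[off + (i - 1) * n_specific + seq_len(n_specific)]
    s
  })
  unrelated <- regs[off + 3 * n_specific + seq_len(n_unrelated)]
  trio <- purrr::map(specific, function(s) {
    stats::setNames(dirs(n_core + n_specific), c(core, s))
  })
  names(trio) <- c("mna_a", "mna_b", "mna_c")
  c(trio, list(unrelated = stats::setNames(dirs(n_unrelated), unrelated)))
}

default_conditions <- function(network, scfg) {
  shared_core_conditions(network)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$rankings), " condition(s); outputs in ",
      x$out_dir, "\n", sep = "")
  for (nm in names(x$paths)) cat("  - ", nm, ": ", x$paths[[nm]], "\n", sep = "")
  invisible(x)
}
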