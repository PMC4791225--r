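# Deterministic sub-seed: the master seed combined with a stable hash of the
# generator name, so adding a generator never perturbs another's stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Default synthetic scenario configuration
#'
#' The study conditions emulated by every generator: a desk-scale gene
#' universe and regulator census, regulator target modules with mixed edge
#' signs, planted regulator activities with imperfect (80%) sign
#' consistency over a 5% DE background, a 300-patient survival cohort with
#' a hazard ratio of 3 per score standard deviation and ~30% censoring, and
#' 384-well plates with a half-log2 spatial gradient, -1.5 log2 planted
#' hits and 10% multiplicative noise.
#'
#' @param seed Master seed; each generator derives its own sub-seed.
#' @param ... Overrides for any default field.
#' @return A named list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_genes = 5000,
    n_regulators = 200,
    mean_out_degree = 30,
    sign_fractions = c(activates = 0.6, represses = 0.35, unknown = 0.05),
    consistency = 0.8,
    background_rate = 0.05,
    n_patients = 300,
    hazard_ratio = 3.0,
    censoring = 0.3,
    gradient_amplitude = 0.5,
    hit_effect = -1.5,
    noise_cv = 0.1,
    n_hits = 16
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  stopifnot(
    all(cfg$sign_fractions >= 0), abs(sum(cfg$sign_fractions) - 1) < 1e-8,
    cfg$consistency >= 0, cfg$consistency <= 1,
    cfg$background_rate >= 0, cfg$background_rate <= 1,
    cfg$censoring >= 0, cfg$censoring < 1
  )
  structure(cfg, class = c("scenario_config", "list"))
}

synthetic_gene_ids <- function(n) sprintf("G%05d", seq_len(n))
synthetic_regulator_ids <- function(n) sprintf("R%03d", seq_len(n))

#' Generate a synthetic signed prior network
#'
#' Regulators receive Poisson(`mean_out_degree`) target modules (minimum 1),
#' targets drawn uniformly without replacement from the gene universe, edge
#' signs drawn per the configured fractions. Regulator identifiers live in
#' their own namespace (`R###`) so regulators are never confused with
#' measured genes.
#'
#' @param config A [scenario_config()].
#' @return A [prior_network()].
#' @export
generate_prior_network <- function(config = scenario_config()) {
  with_seed(sub_seed(config$seed, "prior_network"), {
    regs <- synthetic_regulator_ids(config$n_regulators)
    genes <- synthetic_gene_ids(config$n_genes)
    degrees <- pmax(1L, stats::rpois(length(regs), config$mean_out_degree))
    if (any(degrees > config$n_genes)) {
      abort("Out-degree exceeds the gene universe size.")
    }
    edges <- purrr::map2(regs, degrees, function(r, d) {
      tibble(
        regulator = r,
        target = sample(genes, d, replace = FALSE),
        sign = sample(names(config$sign_fractions), d, replace = TRUE,
                      prob = config$sign_fractions),
        weight = 1
      )
    }) %>%
      dplyr::bind_rows()
    prior_network(edges)
  })
}

#' Generate per-condition DE contrast tables with planted regulator activity
#'
#' For each condition, each planted active regulator (direction +1/-1)
#' makes each of its signed targets DE with probability `consistency` in
#' the predicted direction (edge sign x planted direction) and with
#' probability `1 - consistency` in the opposite direction; unknown-sign
#' targets are perturbed with a random direction. DE genes get
#' `|log2fc| ~ Normal(1.5, 0.5)` truncated above 0.2 and
#' `fdr ~ Uniform(0, 0.01)`; background genes are DE at `background_rate`
#' with random direction; non-DE genes get `fdr ~ Uniform(0.2, 1)` and a
#' small centred log2fc.
#'
#' @param network A [prior_network()].
#' @param conditions Named list: condition -> named numeric vector of
#'   planted regulator directions (+1/-1); may be an empty vector for a
#'   pure-background condition.
#' @param config A [scenario_config()].
#' @return List with `contrasts` (named list of [contrast_table()]) and
#'   `truth` (tibble `condition`, `regulator`, `direction`).
#' @export
generate_contrasts <- function(network, conditions,
                               config = scenario_config()) {
  genes <- sort(unique(c(network$targets,
                         synthetic_gene_ids(config$n_genes))))
  planted_all <- unlist(lapply(conditions, names))
  missing_regs <- setdiff(canon_id(planted_all), network$regulators)
  if (length(missing_regs) > 0) {
    abort(paste0("Planted regulator(s) absent from the network: ",
                 paste(missing_regs, collapse = ", ")))
  }
  truth <- purrr::imap(conditions, function(planted, cond) {
    if (length(planted) == 0) return(tibble())
    tibble(condition = cond, regulator = canon_id(names(planted)),
           direction = unname(planted))
  }) %>% dplyr::bind_rows()

  contrasts <- purrr::imap(conditions, function(planted, cond) {
    with_seed(sub_seed(config$seed, paste0("contrast_", cond)), {
      n <- length(genes)
      de_dir <- stats::setNames(rep(0, n), genes)

      for (reg in names(planted)) {
        d <- planted[[reg]]
        e <- network$edges[network$edges$regulator == canon_id(reg), , drop = FALSE]
        hit <- stats::runif(nrow(e)) < config$consistency
        predicted <- ifelse(e$sign == "activates", d,
                            ifelse(e$sign == "represses", -d,
                                   sample(c(-1, 1), nrow(e), replace = TRUE)))
        dir_obs <- ifelse(hit, predicted, -predicted)
        de_dir[e$target] <- dir_obs
      }

      background <- de_dir == 0 & stats::runif(n) < config$background_rate
      de_dir[background] <- sample(c(-1, 1), sum(background), replace = TRUE)

      is_de <- de_dir != 0
      n_de <- sum(is_de)
      mag <- numeric(n)
      mag[is_de] <- pmax(0.2, stats::rnorm(n_de, 1.5, 0.5))
      mag[!is_de] <- stats::rnorm(n - n_de, 0, 0.05)
      fdr <- numeric(n)
      fdr[is_de] <- stats::runif(n_de, 0, 0.01)
      fdr[!is_de] <- stats::runif(n - n_de, 0.2, 1)

      contrast_table(
        tibble(
          gene = genes,
          log2fc = ifelse(is_de, de_dir * mag, mag),
          p = fdr * stats::runif(n, 0.2, 1),
          fdr = fdr
        ),
        condition = cond
      )
    })
  })
  list(contrasts = contrasts, truth = truth)
}

#' Generate a synthetic patient cohort keyed to a signature
#'
#' Baseline expression is standard normal; each signature gene is shifted
#' by `direction x latent factor` per patient, so the signature score
#' recovers the latent factor. Survival times are exponential with the
#' hazard multiplied by `hazard_ratio^latent` (latent in sd units);
#' censoring is independent uniform, calibrated to the target fraction.
#'
#' @param signature A [build_signature()] tibble (or any tibble with
#'   `gene`, `direction`).
#' @param config A [scenario_config()] (uses `n_patients`, `hazard_ratio`,
#'   `censoring`, plus 200 unrelated background genes).
#' @param n_background Number of non-signature genes in the matrix.
#' @return List with `cohort` (a [cohort_data()]) and `truth` (tibble
#'   `patient`, `latent`, `true_time`, `censored`).
#' @export
generate_cohort <- function(signature, config = scenario_config(),
                            n_background = 200) {
  sig <- as_tibble(signature)
  if (nrow(sig) == 0) abort("Cannot generate a cohort for an empty signature.")
  with_seed(sub_seed(config$seed, "cohort"), {
    n <- config$n_patients
    patients <- sprintf("P%04d", seq_len(n))
    latent <- stats::rnorm(n)

    bg_genes <- setdiff(sprintf("B%04d", seq_len(n_background + nrow(sig))),
                        canon_id(sig$gene))[seq_len(n_background)]
    all_genes <- c(canon_id(sig$gene), bg_genes)
    expr <- matrix(stats::rnorm(length(all_genes) * n),
                   nrow = length(all_genes),
                   dimnames = list(all_genes, patients))
    expr[seq_len(nrow(sig)), ] <- expr[seq_len(nrow(sig)), ] +
      outer(sig$direction, latent)

    base_rate <- 1 / 2000  # median baseline survival ~ 1400 days
    rate <- base_rate * config$hazard_ratio^latent
    true_time <- stats::rexp(n, rate = rate)

    if (config$censoring > 0) {
      target <- config$censoring
      cens_frac <- function(q) mean(pmin(true_time / q, 1)) - target
      q <- stats::uniroot(cens_frac, c(1e-6, max(true_time) * 1e3))$root
      cens_time <- stats::runif(n, 0, q)
      censored <- cens_time < true_time
    } else {
      cens_time <- rep(Inf, n)
      censored <- rep(FALSE, n)
    }
    time <- pmin(true_time, cens_time)
    surv <- tibble(patient = patients, time = time,
                   event = as.integer(!censored))
    list(
      cohort = cohort_data(expr, surv),
      truth = tibble(patient = patients, latent = latent,
                     true_time = true_time, censored = censored)
    )
  })
}

#' Generate a synthetic 384-well screen plate with planted hits
#'
#' Log2 baseline plus a bilinear spatial gradient of the configured
#' amplitude, multiplicative noise of the configured CV, and `n_hits`
#' planted hit wells at `hit_effect` log2 units among the sample wells.
#' Controls occupy the default mask lines and carry the same gradient.
#'
#' @param config A [scenario_config()] (uses `gradient_amplitude`,
#'   `hit_effect`, `noise_cv`, `n_hits`, `seed`).
#' @param plate_id Plate identifier.
#' @return List with `plate` (a [plate_grid()] with gene annotation) and
#'   `truth` (tibble `well`, `gene`, `is_hit`).
#' @export
generate_plate <- function(config = scenario_config(), plate_id = "plate1") {
  with_seed(sub_seed(config$seed, paste0("plate_", plate_id)), {
    mask <- default_control_mask()
    rows <- rep(seq_len(16L), 24L)
    cols <- rep(seq_len(24L), each = 16L)
    rn <- (rows - 1) / 15 - 0.5
    cn <- (cols - 1) / 23 - 0.5
    gradient <- config$gradient_amplitude * (rn + cn + rn * cn)
    baseline <- log2(1e5)
    noise_sd <- config$noise_cv / log(2)
    log2sig <- baseline + gradient +
      if (config$noise_cv > 0) stats::rnorm(length(rows), 0, noise_sd) else 0

    sample_idx <- which(!as.vector(mask))
    hit_idx <- sample(sample_idx, config$n_hits)
    log2sig[hit_idx] <- log2sig[hit_idx] + config$hit_effect

    wells <- well_name(rows, cols)
    genes <- rep(NA_character_, length(wells))
    genes[sample_idx] <- sprintf("SG%04d", seq_along(sample_idx))
    annotation <- tibble(
      well = wells,
      gene = genes,
      role = ifelse(as.vector(mask), "neg_ctrl", "sample")
    )
    plate <- plate_grid(matrix(2^log2sig, 16L, 24L), plate_id = plate_id,
                        control_mask = mask, annotation = annotation)
    truth <- tibble(
      well = wells[sample_idx],
      gene = genes[sample_idx],
      is_hit = sample_idx %in% hit_idx
    )
    list(plate = plate, truth = truth)
  })
}

#' Generate a synthetic genome fixture with planted peak labels
#'
#' Places non-overlapping two-exon gene models on one synthetic chromosome
#' (alternating strands) and plants four peaks per gene at positions whose
#' intended genomic-context category is known by construction: a promoter,
#' an exon and an intron peak for every gene, and alternately an
#' immediate-downstream peak or a distal peak in the preceding intergenic
#' gap, so all five categories appear in the default 5-gene / 20-peak plan.
#'
#' @param n_genes Number of gene models (default 5).
#' @param seed Seed for reproducibility (placement is deterministic given
#'   it).
#' @return List with `genes` (gene-model tibble), `peaks` (tibble `chrom`,
#'   `start`, `end`), `truth` (character vector of intended labels) and
#'   `chrom_length`.
#' @export
generate_genome_fixture <- function(n_genes = 5, seed = 1) {
  with_seed(sub_seed(seed, "genome_fixture"), {
    gene_span <- 20000L
    gap <- 30000L
    chrom <- "chrS"
    starts <- gap + (seq_len(n_genes) - 1L) * (gene_span + gap)
    chrom_length <- starts[n_genes] + gene_span + gap
    strands <- rep(c("+", "-"), length.out = n_genes)
    ids <- sprintf("SYNGENE%02d", seq_len(n_genes))

    genes_tab <- tibble(
      gene = ids, chrom = chrom,
      start = starts, end = starts + gene_span, strand = strands
    )
    # Two exons: first and last 3 kb of the gene body; 14 kb intron between.
    exons_tab <- dplyr::bind_rows(
      tibble(gene = ids, start = starts, end = starts + 3000L),
      tibble(gene = ids, start = starts + gene_span - 3000L,
             end = starts + gene_span)
    )
    models <- gene_models(genes_tab, exons_tab)

    peak_w <- 200L
    mk_peak <- function(centre) {
      tibble(chrom = chrom, start = as.integer(centre - peak_w / 2),
             end = as.integer(centre + peak_w / 2))
    }
    peaks <- list(); truth <- character()
    for (i in seq_len(n_genes)) {
      plus <- strands[i] == "+"
      tss <- if (plus) starts[i] else starts[i] + gene_span
      tes <- if (plus) starts[i] + gene_span else starts[i]
      # promoter: 1 kb upstream of the TSS (inside the default 2 kb window)
      peaks <- c(peaks, list(mk_peak(tss + if (plus) -1000 else 1000)))
      truth <- c(truth, "promoter")
      # exon: middle of the second exon, away from promoter windows
      peaks <- c(peaks, list(mk_peak(starts[i] + gene_span - 1500)))
      truth <- c(truth, "exon")
      # intron: dead centre of the gene body
      peaks <- c(peaks, list(mk_peak(starts[i] + gene_span / 2)))
      truth <- c(truth, "intron")
      if (i %% 2 == 1) {
        # immediate downstream: 1 kb past the TES
        peaks <- c(peaks, list(mk_peak(tes + if (plus) 1000 else -1000)))
        truth <- c(truth, "immediate_downstream")
      } else {
        # distal: midpoint of the gap before this gene, 15 kb from any gene
        peaks <- c(peaks, list(mk_peak(starts[i] - gap / 2)))
        truth <- c(truth, "distal")
      }
    }
    peaks <- dplyr::bind_rows(peaks)
    list(genes = models, peaks = peaks, truth = truth,
         chrom_length = chrom_length)
  })
}
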