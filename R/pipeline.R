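#' Resolved configuration for a pipeline run
#'
#' Collects every knob the reporting commands honor. Each run writes its
#' resolved configuration as JSON next to its outputs, so any artifact can
#' be traced back to the exact settings that produced it.
#'
#' @param input Path to a long-format landscape CSV (ignored by
#'   [run_simulate()]).
#' @param outdir Output directory (created if absent).
#' @param transform Response transform for model fits.
#' @param floor Detection floor (`NULL` = derive from the table).
#' @param scale Effect scale for background/average effects.
#' @param max_order Deepest genetic interaction order (`NULL` = full L).
#' @param adjust Multiple-testing method for correlation families.
#' @param ambiguity Walk ambiguity rule, `"span"` or `"mean_sd"`.
#' @param start Walk starting genotype (`NULL` = all ancestral).
#' @param seed Integer seed for simulation.
#' @param noise_sigma Simulation replicate noise (log10 sd).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, outdir = "epiwalsh-out",
                       transform = c("log10", "identity"), floor = NULL,
                       scale = "log10", max_order = NULL, adjust = "BH",
                       ambiguity = "span", start = NULL, seed = 1L,
                       noise_sigma = 0.2) {
  transform <- match.arg(transform)
  structure(list(input = input, outdir = outdir, transform = transform,
                 floor = floor, scale = scale, max_order = max_order,
                 adjust = adjust, ambiguity = ambiguity, start = start,
                 seed = as.integer(seed), noise_sigma = noise_sigma),
            class = "run_config")
}

prepare_outdir <- function(config, stage) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$stage <- stage
  cfg$package_version <- as.character(utils::packageVersion("epiwalsh"))
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))],
                       file.path(config$outdir, paste0(stage, "-config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$outdir)
}

load_input <- function(config) {
  if (is.null(config$input)) stop("config$input is required for this command")
  table <- read_landscape_csv(config$input)
  comp <- completeness(table)
  if (!comp$complete) {
    stop(sprintf("input landscape is incomplete: %d missing cell(s): %s",
                 comp$n_missing,
                 paste(utils::head(paste(comp$missing$genotype,
                                         comp$missing$environment, sep = "@"), 8L),
                       collapse = ", ")))
  }
  table
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit Walsh models and partition variance per environment
#'
#' For every environment: coefficient tables for the nested genetic models
#' of order 1..max, the sequential variance partition, and the order-k vs
#' order-(k+1) nested comparisons (adjusted R-squared improvement and
#' likelihood-ratio test).
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of written file paths.
#' @export
run_fit <- function(config) {
  table <- load_input(config)
  prepare_outdir(config, "fit")
  L <- length(landscape_sites(table))
  max_order <- if (is.null(config$max_order)) L else min(config$max_order, L)
  spec <- design_spec(max_genetic_order = max_order, transform = config$transform,
                      floor = config$floor)
  paths <- list()
  partition_rows <- list()
  for (e in landscape_environments(table)) {
    vp <- variance_partition(table, e, spec)
    partition_rows[[e]] <- data.frame(environment = e, order = vp$order,
                                      increment_pct = vp$increment_pct,
                                      cumulative_pct = vp$cumulative_pct,
                                      stringsAsFactors = FALSE)
    coefs <- vp$fits[[max_order]]$coefficients
    p <- file.path(config$outdir, sprintf("fit-coefficients-%s.tsv", e))
    write_tsv(coefs, p)
    paths[[paste0("coefficients_", e)]] <- p
    comparisons <- lapply(seq_len(max_order - 1L), function(k) {
      cmp <- compare_nested(vp$fits[[k]], vp$fits[[k + 1L]])
      c(list(low_order = k, high_order = k + 1L), cmp)
    })
    p <- file.path(config$outdir, sprintf("fit-nested-%s.json", e))
    jsonlite::write_json(comparisons, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths[[paste0("nested_", e)]] <- p
  }
  p <- file.path(config$outdir, "fit-variance-partition.tsv")
  write_tsv(do.call(rbind, partition_rows), p)
  paths$variance_partition <- p
  invisible(paths)
}

#' Run greedy walks and optimum enumeration per environment
#'
#' Writes, per environment, the trajectory (JSON and DOT, dashed edges for
#' ambiguous steps) and the enumerated optima, plus a cross-environment
#' summary classifying each walk endpoint.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of written file paths.
#' @export
run_walk <- function(config) {
  table <- load_input(config)
  prepare_outdir(config, "walk")
  paths <- list()
  summary_rows <- list()
  for (e in landscape_environments(table)) {
    tr <- greedy_walk(table, start = config$start, environment = e,
                      ambiguity = config$ambiguity)
    opt <- find_optima(table, e, ambiguity = config$ambiguity)
    cls <- classify_endpoint(tr, opt)
    p <- file.path(config$outdir, sprintf("walk-%s.json", e))
    jsonlite::write_json(list(environment = e, start = tr$start,
                              steps = tr$steps, endpoint = tr$endpoint,
                              endpoint_class = tr$endpoint_class,
                              classification = cls,
                              optima = opt$optima,
                              global = opt$global),
                         p, auto_unbox = TRUE, digits = NA)
    paths[[paste0("walk_", e)]] <- p
    p <- file.path(config$outdir, sprintf("walk-%s.dot", e))
    write_trajectory_dot(tr, p)
    paths[[paste0("dot_", e)]] <- p
    summary_rows[[e]] <- data.frame(environment = e, endpoint = tr$endpoint,
                                    n_steps = nrow(tr$steps),
                                    endpoint_class = tr$endpoint_class,
                                    classification = cls,
                                    global = paste(opt$global, collapse = ","),
                                    n_local_optima = nrow(opt$optima),
                                    stringsAsFactors = FALSE)
  }
  p <- file.path(config$outdir, "walk-summary.tsv")
  write_tsv(do.call(rbind, summary_rows), p)
  paths$summary <- p
  invisible(paths)
}

#' Compute effect and interaction tables per environment
#'
#' Writes the background-dependent and average effects of every site in
#' every environment, the pairwise epistatic coefficients, all pairwise
#' cross-environment effect regressions (`E(E-1)/2` rows), and the
#' effect-versus-prior-substitutions correlations with adjusted p-values.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of written file paths.
#' @export
run_effects <- function(config) {
  table <- load_input(config)
  prepare_outdir(config, "effects")
  sites <- landscape_sites(table)
  envs <- landscape_environments(table)
  paths <- list()

  be_rows <- list()
  avg_rows <- list()
  for (e in envs) {
    for (s in sites) {
      be <- background_effects(table, s, e, scale = config$scale,
                               floor = config$floor)
      be$site <- s
      be$environment <- e
      be_rows[[paste(e, s)]] <- be
      avg_rows[[paste(e, s)]] <- data.frame(environment = e, site = s,
                                            average_effect = mean(be$effect),
                                            stringsAsFactors = FALSE)
    }
  }
  p <- file.path(config$outdir, "effects-backgrounds.tsv")
  write_tsv(do.call(rbind, be_rows), p)
  paths$backgrounds <- p
  p <- file.path(config$outdir, "effects-average.tsv")
  write_tsv(do.call(rbind, avg_rows), p)
  paths$average <- p

  pair_rows <- lapply(envs, function(e) {
    pc <- pairwise_epistasis_coefficients(table, e, transform = config$transform,
                                          floor = config$floor)
    pc$environment <- e
    pc
  })
  p <- file.path(config$outdir, "effects-pairwise.tsv")
  write_tsv(do.call(rbind, pair_rows), p)
  paths$pairwise <- p

  cross_rows <- list()
  if (length(envs) > 1L) {
    for (i in seq_len(length(envs) - 1L)) {
      for (j in seq((i + 1L), length(envs))) {
        cr <- cross_environment_effect_regression(table, envs[i], envs[j],
                                                  scale = config$scale,
                                                  floor = config$floor)
        cross_rows[[paste(i, j)]] <- data.frame(
          env_a = envs[i], env_b = envs[j], slope = cr$slope,
          intercept = cr$intercept, r_squared = cr$r_squared,
          p_value = cr$p_value, n = cr$n, n_excluded = cr$n_excluded,
          stringsAsFactors = FALSE)
      }
    }
  }
  p <- file.path(config$outdir, "effects-cross-environment.tsv")
  write_tsv(do.call(rbind, cross_rows), p)
  paths$cross_environment <- p

  corr_rows <- lapply(sites, function(s) {
    ef <- effect_vs_num_fixed(table, s, scale = config$scale,
                              floor = config$floor, adjust = config$adjust)
    ef$site <- s
    ef
  })
  p <- file.path(config$outdir, "effects-vs-num-fixed.tsv")
  write_tsv(do.call(rbind, corr_rows), p)
  paths$vs_num_fixed <- p
  invisible(paths)
}

#' Generate the study-mimicking synthetic landscape
#'
#' Writes the synthetic CSV (same dialect [read_landscape_csv()] accepts)
#' and its planted ground truth as JSON.
#'
#' @param config A [run_config()]; `seed` and `noise_sigma` are honored.
#' @return Invisibly, a named list of written file paths.
#' @export
run_simulate <- function(config) {
  prepare_outdir(config, "simulate")
  sim <- generate_study_mimic(seed = config$seed,
                              noise_sigma = config$noise_sigma)
  csv <- file.path(config$outdir, "synthetic-landscape.csv")
  write_landscape_csv(sim$table, csv)
  truth_path <- file.path(config$outdir, "synthetic-truth.json")
  truth <- sim$truth
  truth$spec <- NULL  # regenerate via generate_study_mimic(seed)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv, truth = truth_path))
}

#' Run the full analysis pipeline
#'
#' [run_fit()], [run_walk()] and [run_effects()] on one input table; when
#' `config$input` is `NULL`, first simulates the study-mimicking landscape
#' and analyzes that.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of all written file paths.
#' @export
run_all <- function(config) {
  if (is.null(config$input)) {
    sim <- run_simulate(config)
    config$input <- sim$csv
  }
  out <- c(run_fit(config), run_walk(config), run_effects(config))
  invisible(out)
}
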