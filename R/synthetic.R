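# parse a term name like "72x258" to site indices
term_sites <- function(term, site_labels) {
  parts <- strsplit(term, "x", fixed = TRUE)[[1L]]
  idx <- match(parts, site_labels)
  if (anyNA(idx)) stop(sprintf("term '%s' names unknown site(s)", term))
  if (anyDuplicated(idx)) stop(sprintf("term '%s' repeats a site", term))
  sort(idx)
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic landscape with planted ground truth
#'
#' Defines a complete factorial of `2^L` genotypes x environments x
#' replicates whose cell log10-mean activity is
#' `baseline + env_offset + sum(theta_T * prod u)` over planted Walsh
#' terms, with multiplicative replicate noise (Gaussian on log10 activity,
#' emulating assay scatter that scales with signal). Coefficients can be
#' planted explicitly (shared across environments, or per environment —
#' per-environment entries override shared ones and create GxE/GxGxE
#' structure) and/or drawn randomly per order.
#'
#' @param L Number of sites.
#' @param environments Environment labels.
#' @param replicates Replicates per cell (study design: 3).
#' @param baseline Baseline log10 activity.
#' @param genetic Named numeric of shared planted coefficients, names as in
#'   [genetic_terms()] (e.g. `c("258" = 0.5, "258x271" = 0.25)`).
#' @param env_genetic Named list environment -> named numeric of
#'   environment-specific coefficients (override shared values).
#' @param env_offsets Named numeric of per-environment log10 offsets.
#' @param order_sd Numeric vector, `order_sd[k]` = sd of random shared
#'   coefficients drawn for every order-k term (0 = none).
#' @param env_order_sd Like `order_sd` but drawn independently per
#'   environment and added to the shared value (planted GxE/GxGxE noise).
#' @param noise_sigma Replicate noise sd on the log10 scale.
#' @param noise `"log10"` (default, multiplicative) or `"additive"`
#'   (Gaussian on the raw activity scale, clamped at zero).
#' @param site_labels Site identifiers.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(L = 5L, environments = metal_environments(),
                           replicates = 3L, baseline = 1,
                           genetic = numeric(), env_genetic = list(),
                           env_offsets = numeric(),
                           order_sd = numeric(L), env_order_sd = numeric(L),
                           noise_sigma = 0, noise = c("log10", "additive"),
                           site_labels = make_site_labels(L)) {
  noise <- match.arg(noise)
  stopifnot(L >= 1L, replicates >= 1L, noise_sigma >= 0,
            length(site_labels) == L, all(order_sd >= 0), all(env_order_sd >= 0))
  order_sd <- rep_len(order_sd, L)
  env_order_sd <- rep_len(env_order_sd, L)
  for (term in names(genetic)) term_sites(term, site_labels)
  for (e in names(env_genetic)) {
    if (!e %in% environments) stop(sprintf("env_genetic names unknown environment '%s'", e))
    for (term in names(env_genetic[[e]])) term_sites(term, site_labels)
  }
  if (length(env_offsets) && !all(names(env_offsets) %in% environments)) {
    stop("env_offsets names unknown environment(s)")
  }
  structure(list(L = as.integer(L), environments = environments,
                 replicates = as.integer(replicates), baseline = baseline,
                 genetic = genetic, env_genetic = env_genetic,
                 env_offsets = env_offsets, order_sd = order_sd,
                 env_order_sd = env_order_sd, noise_sigma = noise_sigma,
                 noise = noise, site_labels = site_labels),
            class = "synthetic_spec")
}

#' Generate a synthetic landscape with its planted ground truth
#'
#' A pure function of `(spec, seed)`: identical inputs give identical
#' tables. Replicate noise draws are isolated from coefficient draws, so
#' two seeds differing only in noise share identical cell means when all
#' coefficients are planted explicitly.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for coefficient draws and replicate noise.
#' @return List with `table` (a `landscape`) and `truth` (list:
#'   `baseline`, `env_offsets`, `coefficients` — per-environment named
#'   vectors over all terms, `noise_sigma`, `seed`, `spec`).
#' @export
generate_landscape <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    L <- spec$L
    terms <- genetic_terms(spec$site_labels, L)
    n_terms <- nrow(terms)

    shared <- numeric(n_terms)
    names(shared) <- terms$term
    for (k in seq_len(L)) {
      if (spec$order_sd[k] > 0) {
        sel <- terms$order == k
        shared[sel] <- stats::rnorm(sum(sel), 0, spec$order_sd[k])
      }
    }
    shared[names(spec$genetic)] <- spec$genetic

    coefs <- list()
    for (e in spec$environments) {
      ce <- shared
      for (k in seq_len(L)) {
        if (spec$env_order_sd[k] > 0) {
          sel <- terms$order == k
          ce[sel] <- ce[sel] + stats::rnorm(sum(sel), 0, spec$env_order_sd[k])
        }
      }
      extra <- spec$env_genetic[[e]]
      if (!is.null(extra)) ce[names(extra)] <- extra
      coefs[[e]] <- ce
    }

    offsets <- stats::setNames(numeric(length(spec$environments)), spec$environments)
    offsets[names(spec$env_offsets)] <- spec$env_offsets

    gs <- all_genotypes(L)
    enc <- t(vapply(gs, function(g) encode_genotype(g, L, spec$site_labels),
                    numeric(n_terms)))
    if (n_terms == 1L) enc <- matrix(enc, ncol = 1L, dimnames = list(gs, terms$term))

    rows <- vector("list", length(spec$environments))
    for (ei in seq_along(spec$environments)) {
      e <- spec$environments[ei]
      mu <- spec$baseline + offsets[[e]] + drop(enc %*% coefs[[e]])
      noise <- matrix(stats::rnorm(length(gs) * spec$replicates, 0, spec$noise_sigma),
                      nrow = length(gs))
      if (spec$noise == "log10") {
        act <- 10^(mu + noise)
      } else {
        act <- pmax(10^mu + noise, 0)
      }
      rows[[ei]] <- data.frame(
        genotype = rep(gs, times = spec$replicates),
        environment = e,
        replicate = rep(seq_len(spec$replicates), each = length(gs)),
        activity = as.vector(act),
        stringsAsFactors = FALSE)
    }
    table <- landscape_table(do.call(rbind, rows),
                             site_labels = spec$site_labels,
                             environments = spec$environments)
    truth <- list(baseline = spec$baseline, env_offsets = offsets,
                  coefficients = coefs, noise_sigma = spec$noise_sigma,
                  seed = seed, spec = spec)
    list(table = table, truth = truth)
  })
}

#' Per-order variance shares implied by planted coefficients
#'
#' On a complete balanced factorial the Walsh columns are orthogonal, so
#' each planted coefficient `theta_T` contributes exactly `theta_T^2` to
#' the variance of cell log10-means; the share of order k is the summed
#' squared coefficients of that order over the total (optionally including
#' the replicate noise variance `sigma^2`). This closed form is the oracle
#' for [variance_partition()] parameter-recovery tests.
#'
#' @param truth Ground-truth list from [generate_landscape()].
#' @param environment Environment label.
#' @param include_noise Include `noise_sigma^2` in the denominator?
#' @return List: `per_order_pct` (length L), `cumulative_pct`,
#'   `epistatic_total_pct`, `noise_pct`.
#' @export
planted_variance_shares <- function(truth, environment, include_noise = FALSE) {
  spec <- truth$spec
  terms <- genetic_terms(spec$site_labels, spec$L)
  theta <- truth$coefficients[[environment]]
  if (is.null(theta)) stop(sprintf("no planted coefficients for environment '%s'", environment))
  per_order <- vapply(seq_len(spec$L), function(k)
    sum(theta[terms$order == k]^2), numeric(1L))
  total <- sum(per_order) + if (include_noise) truth$noise_sigma^2 else 0
  pct <- 100 * per_order / total
  list(per_order_pct = pct,
       cumulative_pct = cumsum(pct),
       epistatic_total_pct = sum(pct[-1L]),
       noise_pct = if (include_noise) 100 * truth$noise_sigma^2 / total else 0)
}

#' Synthetic landscape mimicking the five-site, eight-metal study design
#'
#' A complete 2^5 factorial over the sites 72/193/258/271/273, eight metal
#' environments, three replicates (768 records). The planted structure is
#' chosen so that first-order effects carry roughly 70% of the variance in
#' cell log-means, pairwise epistasis roughly 20%, orders 3-5 a few
#' percent, and replicate noise about 5%; site 271 is deleterious alone but
#' rescued by synergy with 258 and 273, and one environment (`Cd`) carries
#' a sign-flipped 258x271 interaction strong enough to move its global
#' optimum away from the all-derived genotype while every other
#' environment keeps all-derived as both the global optimum and the greedy
#' walk's destination. Per-environment offsets spread baseline activities
#' over two orders of magnitude.
#'
#' @param seed Integer seed for replicate noise.
#' @param noise_sigma Replicate noise sd on log10 activity (default 0.2,
#'   putting replicate noise near 5% of total variance;
#'   set 0 for the noiseless version used in closed-form recovery checks).
#' @param replicates Replicates per cell.
#' @return List with `table` and `truth`, as in [generate_landscape()].
#' @export
generate_study_mimic <- function(seed = 1L, noise_sigma = 0.2, replicates = 3L) {
  shared <- c(
    # first order: everything but 271 beneficial
    "72" = 0.35, "193" = 0.28, "258" = 0.50, "271" = -0.15, "273" = 0.28,
    # pairwise: a chain of synergies that opens the path to all-derived,
    # ending with 258/273 rescuing the deleterious 271; mild 72-258 antagonism
    "193x258" = 0.18, "193x273" = 0.18, "72x273" = 0.15,
    "258x271" = 0.28, "271x273" = 0.18, "72x258" = -0.10,
    # sparse higher orders
    "72x258x271" = 0.10, "193x258x273" = 0.08,
    "72x193x271x273" = 0.06, "72x193x258x271x273" = 0.05)
  env_genetic <- list(Cd = c("258x271" = -0.35, "271x273" = -0.05))
  env_offsets <- c(Ca = 0, Cd = -0.3, Co = 0.1, Cu = -0.1,
                   Mg = 0.2, Mn = -0.2, Ni = -0.8, Zn = 0.4)
  spec <- synthetic_spec(L = 5L, environments = metal_environments(),
                         replicates = replicates, baseline = 1,
                         genetic = shared, env_genetic = env_genetic,
                         env_offsets = env_offsets, noise_sigma = noise_sigma)
  generate_landscape(spec, seed = seed)
}
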