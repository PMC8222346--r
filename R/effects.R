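# resolve a site given as label ("271") or index (4) to its index
site_index <- function(table, site) {
  labels <- landscape_sites(table)
  if (is.character(site)) {
    i <- match(site, labels)
    if (is.na(i)) stop(sprintf("unknown site '%s'; sites are %s",
                               site, paste(labels, collapse = ", ")))
    return(i)
  }
  site <- as.integer(site)
  if (site < 1L || site > length(labels)) stop("site index out of range")
  site
}

# effect of deriving `site` in one background, on the requested scale
single_effect <- function(m_anc, m_der, scale, floor_val) {
  fl <- FALSE
  if (scale %in% c("log10", "fold")) {
    if (m_anc < floor_val) { m_anc <- floor_val; fl <- TRUE }
    if (m_der < floor_val) { m_der <- floor_val; fl <- TRUE }
    eff <- if (scale == "log10") log10(m_der / m_anc) else m_der / m_anc
  } else {
    eff <- m_der - m_anc
  }
  list(effect = eff, floored = fl)
}

#' Background-dependent effects of one mutation
#'
#' The effect of deriving one site in each of the `2^(L-1)` genetic
#' backgrounds that have it ancestral, in one environment — the raw
#' material of epistasis analysis. On the default `log10` scale the effect
#' is `log10(mean activity derived / mean activity ancestral)`, which is
#' antisymmetric under direction reversal; `"fold"` gives the raw ratio and
#' `"identity"` the difference of means. Means below the detection floor
#' are floored and flagged.
#'
#' @param table A `landscape` object.
#' @param site Site label (e.g. `"271"`) or index.
#' @param environment Environment label.
#' @param scale `"log10"` (default), `"fold"`, or `"identity"`.
#' @param floor Detection floor; `NULL` uses [detection_floor()].
#' @return Data frame with one row per background, ordered
#'   lexicographically by background label: `background`, `n_fixed` (count
#'   of derived alleles at the other sites), `effect`, `floored`.
#' @export
background_effects <- function(table, site, environment,
                               scale = c("log10", "fold", "identity"),
                               floor = NULL) {
  scale <- match.arg(scale)
  i <- site_index(table, site)
  means <- cell_means(table, environment)
  if (is.null(floor)) floor <- detection_floor(table)
  labels <- names(means)
  bit_i <- substr(labels, i, i)
  backgrounds <- sort(labels[bit_i == "0"])
  out <- lapply(backgrounds, function(bg) {
    der <- bg
    substr(der, i, i) <- "1"
    se <- single_effect(means[[bg]], means[[der]], scale, floor)
    bits <- strsplit(bg, "", fixed = TRUE)[[1L]]
    data.frame(background = bg,
               n_fixed = sum(bits[-i] == "1"),
               effect = se$effect, floored = se$floored,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average effect of a mutation across all backgrounds
#'
#' Arithmetic mean of the background-dependent effects over all `2^(L-1)`
#' backgrounds; on the log scale of a complete balanced design this equals
#' twice the first-order Walsh coefficient for the site.
#'
#' @inheritParams background_effects
#' @return Numeric scalar.
#' @export
average_effect <- function(table, site, environment,
                           scale = c("log10", "fold", "identity"),
                           floor = NULL) {
  mean(background_effects(table, site, environment, scale, floor)$effect)
}

#' Pairwise epistatic coefficients in one environment
#'
#' The second-order coefficients of the order-2 genetic Walsh fit: the
#' deviation of each site pair's joint effect from additivity, positive
#' when the derived-derived combination is synergistic. For L = 5 there are
#' 10 pairs.
#'
#' @param table A `landscape` object.
#' @param environment Environment label.
#' @param transform Response transform for the fit (default `"log10"`).
#' @param floor Detection floor; `NULL` uses the table default.
#' @return Data frame `pair`, `estimate`, `se`, ordered as in
#'   [genetic_terms()].
#' @export
pairwise_epistasis_coefficients <- function(table, environment,
                                            transform = c("log10", "identity"),
                                            floor = NULL) {
  transform <- match.arg(transform)
  spec <- design_spec(max_genetic_order = 2L, transform = transform, floor = floor)
  fit <- fit_ols(build_design(table, spec, environment = environment))
  cf <- fit$coefficients
  out <- cf[cf$type == "genetic" & cf$order == 2L, c("term", "estimate", "se")]
  names(out)[1L] <- "pair"
  rownames(out) <- NULL
  out
}

#' Cross-environment regression of background-dependent effects
#'
#' Concatenates the background-effect vectors of every site (L sites x
#' `2^(L-1)` backgrounds = 80 points for L = 5) in two environments and
#' regresses environment B's effects on environment A's. High R-squared
#' means epistasis is conserved between the environments; departures
#' quantify GxGxE interactions. Points whose numerator or denominator was
#' floored are excluded by default and counted.
#'
#' @param table A `landscape` object.
#' @param env_a,env_b Environment labels (predictor, response).
#' @param scale Effect scale, as in [background_effects()].
#' @param floor Detection floor.
#' @param exclude_floored Drop floored points from the regression?
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `n_excluded`, `degenerate` (TRUE when the predictor has no variance).
#' @export
cross_environment_effect_regression <- function(table, env_a, env_b,
                                                scale = "log10", floor = NULL,
                                                exclude_floored = TRUE) {
  sites <- landscape_sites(table)
  ea <- do.call(rbind, lapply(sites, function(s)
    background_effects(table, s, env_a, scale, floor)))
  eb <- do.call(rbind, lapply(sites, function(s)
    background_effects(table, s, env_b, scale, floor)))
  keep <- if (exclude_floored) !(ea$floored | eb$floored) else rep(TRUE, nrow(ea))
  x <- ea$effect[keep]
  y <- eb$effect[keep]
  if (stats::var(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                p_value = NA_real_, n = length(x),
                n_excluded = sum(!keep), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits (e.g. env_a == env_b); the R^2 is still 1
  sm <- suppressWarnings(summary(fit))
  pval <- if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else NA_real_
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = pval,
       n = length(x), n_excluded = sum(!keep), degenerate = FALSE)
}

#' Correlation between a mutation's effect and prior substitutions
#'
#' For one focal site, correlates its background-dependent effect with the
#' number of derived alleles already fixed at the other sites (0..L-1), per
#' environment. A significant positive correlation means the mutation
#' becomes more beneficial as other substitutions accumulate — the
#' signature of synergistic interactions involving the focal site. P-values
#' are adjusted across the family of environments for the focal site
#' (Benjamini-Hochberg by default).
#'
#' @param table A `landscape` object.
#' @param site Focal site label or index.
#' @param environment Optional single environment; when `NULL` (default)
#'   all environments are returned. The adjustment family is always all
#'   environments in the table.
#' @param scale Effect scale.
#' @param floor Detection floor.
#' @param method Correlation statistic: `"pearson"` (default) or
#'   `"spearman"`.
#' @param adjust Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Data frame: `environment`, `correlation`, `p_raw`, `p_adjusted`,
#'   `degenerate`.
#' @export
effect_vs_num_fixed <- function(table, site, environment = NULL,
                                scale = "log10", floor = NULL,
                                method = c("pearson", "spearman"),
                                adjust = "BH") {
  method <- match.arg(method)
  envs <- landscape_environments(table)
  rows <- lapply(envs, function(e) {
    be <- background_effects(table, site, e, scale, floor)
    if (stats::var(be$effect) == 0 || stats::var(be$n_fixed) == 0) {
      return(data.frame(environment = e, correlation = NA_real_,
                        p_raw = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(be$n_fixed, be$effect, method = method, exact = FALSE)
    data.frame(environment = e, correlation = unname(ct$estimate),
               p_raw = ct$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out <- out[, c("environment", "correlation", "p_raw", "p_adjusted", "degenerate")]
  if (!is.null(environment)) {
    if (!environment %in% envs) stop(sprintf("unknown environment '%s'", environment))
    out <- out[out$environment == environment, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Effect of a mutation conditional on the state of another site
#'
#' Mean background-dependent effect of `site` restricted to the
#' `2^(L-2)` backgrounds in which `given_site` is in `given_state`. The
#' unconditional average effect is the mean of the two conditional values,
#' and on the log scale of a noiseless landscape the derived-minus-
#' ancestral difference equals four times the planted pairwise Walsh
#' coefficient of the two sites.
#'
#' @inheritParams background_effects
#' @param given_site Conditioning site label or index (distinct from
#'   `site`).
#' @param given_state 0 (ancestral) or 1 (derived).
#' @return Numeric scalar.
#' @export
conditional_effect <- function(table, site, given_site, given_state, environment,
                               scale = c("log10", "fold", "identity"),
                               floor = NULL) {
  scale <- match.arg(scale)
  i <- site_index(table, site)
  j <- site_index(table, given_site)
  if (i == j) stop("site and given_site must differ")
  stopifnot(given_state %in% c(0L, 1L))
  be <- background_effects(table, site, environment, scale, floor)
  state <- substr(be$background, j, j)
  mean(be$effect[state == as.character(given_state)])
}
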