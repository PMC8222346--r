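#' Genetic interaction terms up to a given order
#'
#' Enumerates all site subsets of size 1..`max_order`. Term names join the
#' member site labels with `"x"` in sequence order (e.g. `"72x258"`), the
#' field's convention for naming epistatic pairs.
#'
#' @param site_labels Ordered site identifiers.
#' @param max_order Largest subset size, between 0 and L (0 = no genetic
#'   terms, as in an environment-only model).
#' @return Data frame with columns `term`, `order`, and a list column
#'   `sites` of member indices.
#' @export
genetic_terms <- function(site_labels, max_order) {
  L <- length(site_labels)
  stopifnot(max_order >= 0L, max_order <= L)
  terms <- list()
  k <- 0L
  for (ord in seq_len(max_order)) {
    combos <- utils::combn(L, ord, simplify = FALSE)
    for (idx in combos) {
      k <- k + 1L
      terms[[k]] <- list(term = paste(site_labels[idx], collapse = "x"),
                         order = ord, sites = idx)
    }
  }
  data.frame(term = vapply(terms, `[[`, character(1L), "term"),
             order = vapply(terms, `[[`, integer(1L), "order"),
             sites = I(lapply(terms, `[[`, "sites")),
             stringsAsFactors = FALSE)
}

#' Walsh coordinates of a genotype
#'
#' Each site is coded -1 for the ancestral state and +1 for the derived
#' state; the coordinate of a site subset is the product of its member
#' coordinates. On a complete factorial these columns are mutually
#' orthogonal, so coefficients at different orders are estimated
#' independently.
#'
#' @param g Genotype label or `genotype` object.
#' @param max_order Largest interaction order to encode (default 1).
#' @param site_labels Site identifiers (inferred from `g` when possible).
#' @return Named numeric vector of +/-1 coordinates, one per term.
#' @export
#' @examples
#' encode_genotype("11000", max_order = 2)
encode_genotype <- function(g, max_order = 1L, site_labels = NULL) {
  if (is.character(g)) {
    if (is.null(site_labels)) site_labels <- make_site_labels(nchar(g))
    g <- parse_genotype(g, site_labels)
  }
  u <- 2 * g$bits - 1
  tt <- genetic_terms(g$site_labels, max_order)
  out <- vapply(tt$sites, function(idx) prod(u[idx]), numeric(1L))
  names(out) <- tt$term
  out
}

#' Sylvester Hadamard matrix
#'
#' @param n Order; must be a power of two.
#' @return An `n x n` matrix of +/-1 with mutually orthogonal rows; first
#'   row and column all ones.
#' @export
hadamard_matrix <- function(n) {
  if (n < 1 || bitwAnd(n, n - 1L) != 0L) {
    stop("Sylvester construction requires n to be a power of two")
  }
  H <- matrix(1, 1L, 1L)
  while (nrow(H) < n) {
    H <- rbind(cbind(H, H), cbind(H, -H))
  }
  H
}

#' Hadamard contrast coordinates for categorical environments
#'
#' Each of E environment labels is assigned a unique coordinate vector of
#' length E-1: the rows of the order-E Sylvester Hadamard matrix with the
#' constant column removed, following the given label order. Any two
#' distinct labels' coordinates have dot product -1, each label's self dot
#' product is E-1, and every coordinate dimension sums to zero over the
#' labels, so environment effects are expressed relative to the grand mean.
#' When E is not a power of two (Sylvester doubling impossible) the
#' encoding falls back to sum-to-zero contrasts, which keeps the zero-sum
#' centering but not the equal pairwise dot products.
#'
#' @param labels Ordered character vector of E unique environment labels.
#' @return Numeric matrix with E rows (named by label) and E-1 columns
#'   named `"E1".."E<E-1>"`.
#' @export
#' @examples
#' encode_environments(metal_environments())[1, ]  # all +1
encode_environments <- function(labels) {
  stopifnot(!anyDuplicated(labels))
  E <- length(labels)
  if (E == 1L) {
    return(matrix(numeric(0), 1L, 0L, dimnames = list(labels, NULL)))
  }
  if (bitwAnd(E, E - 1L) == 0L) {
    M <- hadamard_matrix(E)[, -1L, drop = FALSE]
  } else {
    M <- stats::contr.sum(E)
  }
  dimnames(M) <- list(labels, paste0("E", seq_len(ncol(M))))
  M
}

#' Model-structure specification for a Walsh design
#'
#' @param max_genetic_order Largest genetic interaction order, 0..L
#'   (0 gives an environment-only model).
#' @param include_environment Add Hadamard environment coordinates?
#' @param gxe_order Largest genetic order crossed with environment
#'   coordinates (0 = no GxE terms; 2 adds environment-dependent pairwise
#'   epistasis, i.e. GxGxE).
#' @param transform Response transform: `"log10"` (default; activities span
#'   orders of magnitude and replicate noise is multiplicative) or
#'   `"identity"`.
#' @param floor Positive detection floor applied before `log10`; `NULL`
#'   derives [detection_floor()] from the table; `0` disables flooring (an
#'   error is raised if zero activities are then logged).
#' @return A `design_spec` list.
#' @export
design_spec <- function(max_genetic_order = 1L, include_environment = FALSE,
                        gxe_order = 0L, transform = c("log10", "identity"),
                        floor = NULL) {
  transform <- match.arg(transform)
  stopifnot(max_genetic_order >= 0L, gxe_order >= 0L)
  if (gxe_order > max_genetic_order) {
    stop("gxe_order cannot exceed max_genetic_order")
  }
  if (gxe_order > 0L && !include_environment) {
    stop("gxe_order > 0 requires include_environment = TRUE")
  }
  structure(list(max_genetic_order = as.integer(max_genetic_order),
                 include_environment = isTRUE(include_environment),
                 gxe_order = as.integer(gxe_order),
                 transform = transform, floor = floor),
            class = "design_spec")
}

#' Build a Walsh design matrix and response from a landscape
#'
#' One row per replicate record (or per genotype-by-environment cell mean
#' with `aggregate = "means"`). Columns: an all-ones intercept, genetic
#' Walsh coordinates for all site subsets up to `spec$max_genetic_order`,
#' Hadamard environment coordinates, and outer-product GxE columns (e.g.
#' `"72xE1"`). Column naming and ordering are deterministic.
#'
#' @param table A `landscape` object.
#' @param spec A [design_spec()].
#' @param environment Optional single environment to restrict to.
#' @param aggregate `"replicates"` (default: every record is a row) or
#'   `"means"` (one row per cell; gives exact interpolation at full order).
#' @return A `walsh_design` list with elements `X`, `y`, `terms`,
#'   `env_coords`, `floored`, `genotype`, `environment`, `spec`.
#' @export
build_design <- function(table, spec = design_spec(),
                         environment = NULL, aggregate = c("replicates", "means")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(spec, "design_spec"))
  site_labels <- landscape_sites(table)
  L <- length(site_labels)
  if (spec$max_genetic_order > L) {
    stop(sprintf("max_genetic_order %d exceeds the %d sites in the table",
                 spec$max_genetic_order, L))
  }
  sub <- if (is.null(environment)) table else
    table[table$environment %in% environment, , drop = FALSE]
  if (!nrow(sub)) stop("no records selected for the design")
  envs <- if (is.null(environment)) landscape_environments(table) else environment

  if (aggregate == "means") {
    agg <- stats::aggregate(activity ~ genotype + environment, data = sub, FUN = mean)
    rows <- agg[order(agg$environment, agg$genotype), , drop = FALSE]
  } else {
    rows <- sub[order(sub$environment, sub$genotype, sub$replicate), , drop = FALSE]
  }

  # response transform with detection floor
  floor_val <- spec$floor
  if (is.null(floor_val)) floor_val <- detection_floor(table)
  y <- rows$activity
  floored <- rep(FALSE, length(y))
  if (spec$transform == "log10") {
    if (floor_val <= 0) {
      if (any(y <= 0)) stop("log10 transform with flooring disabled, but zero activities present")
    } else {
      floored <- y < floor_val
      y <- pmax(y, floor_val)
    }
    y <- log10(y)
  }

  gt <- genetic_terms(site_labels, spec$max_genetic_order)
  ugen <- unique(rows$genotype)
  if (nrow(gt)) {
    enc <- t(vapply(ugen,
                    function(g) encode_genotype(g, spec$max_genetic_order, site_labels),
                    numeric(nrow(gt))))
    if (nrow(gt) == 1L) enc <- matrix(enc, ncol = 1L)  # vapply drops dims for p=1
    dimnames(enc) <- list(ugen, gt$term)
    Xg <- enc[rows$genotype, , drop = FALSE]
  } else {
    Xg <- matrix(numeric(0), nrow(rows), 0L)
  }

  X <- cbind(intercept = rep(1, nrow(rows)))
  terms <- data.frame(term = "intercept", type = "intercept", order = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(gt)) {
    X <- cbind(X, Xg)
    terms <- rbind(terms, data.frame(term = gt$term, type = "genetic",
                                     order = gt$order, stringsAsFactors = FALSE))
  }
  env_coords <- NULL
  if (spec$include_environment) {
    env_coords <- encode_environments(envs)
    if (ncol(env_coords)) {
      Xe <- env_coords[rows$environment, , drop = FALSE]
      rownames(Xe) <- NULL
      X <- cbind(X, Xe)
      terms <- rbind(terms, data.frame(term = colnames(env_coords),
                                       type = "environment", order = 1L,
                                       stringsAsFactors = FALSE))
      if (spec$gxe_order > 0L) {
        gxe_terms <- gt[gt$order <= spec$gxe_order, , drop = FALSE]
        for (i in seq_len(nrow(gxe_terms))) {
          for (j in seq_len(ncol(env_coords))) {
            nm <- paste0(gxe_terms$term[i], "x", colnames(env_coords)[j])
            X <- cbind(X, Xg[, gxe_terms$term[i]] * Xe[, j])
            colnames(X)[ncol(X)] <- nm
            terms <- rbind(terms, data.frame(term = nm, type = "gxe",
                                             order = gxe_terms$order[i] + 1L,
                                             stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  rownames(X) <- NULL
  structure(list(X = X, y = y, terms = terms, env_coords = env_coords,
                 floored = floored, genotype = rows$genotype,
                 environment = rows$environment, spec = spec),
            class = "walsh_design")
}

#' Ordinary least squares fit of a Walsh design
#'
#' Plain OLS with pinned fit statistics so nested comparisons are
#' reproducible bit-for-bit: `adj R^2 = 1 - (1 - R^2) (n - 1) / (n - p)`
#' with p counting all columns including the intercept, and the Gaussian
#' maximum-likelihood log-likelihood `-n/2 (log(2 pi RSS/n) + 1)`. A
#' constant response is reported as `R^2 = 0` by convention. A perfect
#' (zero-residual) fit has infinite Gaussian log-likelihood and is flagged
#' with `zero_residual = TRUE`.
#'
#' @param design A `walsh_design` from [build_design()], or a numeric
#'   matrix (then `response` must be given).
#' @param response Response vector when `design` is a bare matrix.
#' @return A `walsh_fit` list: `coefficients` data frame (term, type,
#'   order, estimate, se), `n`, `p`, `r_squared`, `adj_r_squared`,
#'   `log_likelihood`, `sigma`, `residuals`, `fitted`, `zero_residual`,
#'   `env_coords`, `response`.
#' @export
fit_ols <- function(design, response = NULL) {
  if (inherits(design, "walsh_design")) {
    X <- design$X
    y <- design$y
    terms <- design$terms
    env_coords <- design$env_coords
  } else {
    X <- as.matrix(design)
    y <- response
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    terms <- data.frame(term = colnames(X), type = "generic",
                        order = NA_integer_, stringsAsFactors = FALSE)
    env_coords <- NULL
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n < p) stop(sprintf("underdetermined fit: %d rows for %d parameters", n, p))
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design; collinear term(s): ", paste(bad, collapse = ", "),
         " (often caused by missing genotype cells)")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  adj <- if (n == p) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p)
  zero_residual <- rss <= .Machine$double.eps * max(1, tss)
  ll <- if (zero_residual) Inf else -n / 2 * (log(2 * pi * rss / n) + 1)
  sigma2 <- if (n > p) rss / (n - p) else NA_real_
  se <- if (is.na(sigma2)) rep(NA_real_, p) else {
    xtxinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
    sqrt(diag(xtxinv) * sigma2)
  }
  coef_df <- data.frame(term = colnames(X), stringsAsFactors = FALSE)
  coef_df <- merge(coef_df, terms, by = "term", sort = FALSE)
  coef_df <- coef_df[match(colnames(X), coef_df$term), , drop = FALSE]
  coef_df$estimate <- unname(beta)
  coef_df$se <- unname(se)
  rownames(coef_df) <- NULL
  structure(list(coefficients = coef_df, n = n, p = p,
                 r_squared = r2, adj_r_squared = adj,
                 log_likelihood = ll, sigma = sqrt(max(sigma2, 0)),
                 residuals = res, fitted = fitted,
                 zero_residual = zero_residual,
                 env_coords = env_coords, response = y),
            class = "walsh_fit")
}

#' @export
print.walsh_fit <- function(x, ...) {
  cat(sprintf("<walsh_fit: n=%d, p=%d, R2=%.4f, adjR2=%s, logLik=%s%s>\n",
              x$n, x$p, x$r_squared,
              formatC(x$adj_r_squared, format = "f", digits = 4),
              if (is.finite(x$log_likelihood))
                formatC(x$log_likelihood, format = "f", digits = 2) else "Inf",
              if (x$zero_residual) " [zero residual]" else ""))
  invisible(x)
}

#' Coefficient lookup in a fit
#' @param fit A `walsh_fit`.
#' @param term Term name, e.g. `"258x271"`.
#' @return Numeric estimate.
#' @export
coef_estimate <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop(sprintf("term '%s' not in the fit", term))
  fit$coefficients$estimate[i]
}

#' Compare two nested Walsh fits
#'
#' The lower-order model must use a strict subset of the higher-order
#' model's terms on the same response rows. Reports the adjusted-R-squared
#' improvement and the likelihood-ratio test `2 (logLik_high - logLik_low)`
#' against a chi-square with `p_high - p_low` degrees of freedom. When the
#' richer model interpolates the data exactly (zero residual) the Gaussian
#' likelihood diverges; the statistic is then reported as an `Inf` sentinel
#' with `zero_residual = TRUE` and a p-value of 0.
#'
#' @param fit_low,fit_high `walsh_fit` objects.
#' @return List with `delta_adj_r_squared`, `lrt`, `df`, `p_value`,
#'   `zero_residual`.
#' @export
compare_nested <- function(fit_low, fit_high) {
  tl <- fit_low$coefficients$term
  th <- fit_high$coefficients$term
  if (!all(tl %in% th)) {
    stop("models are not nested: ",
         paste(setdiff(tl, th), collapse = ", "), " absent from the richer model")
  }
  if (length(tl) == length(th)) {
    stop("models are not strictly nested: identical term sets")
  }
  if (fit_low$n != fit_high$n ||
      !isTRUE(all.equal(fit_low$response, fit_high$response))) {
    stop("nested comparison requires identical response rows")
  }
  df <- fit_high$p - fit_low$p
  zero <- fit_high$zero_residual
  lrt <- if (zero) Inf else 2 * (fit_high$log_likelihood - fit_low$log_likelihood)
  pval <- if (zero) 0 else stats::pchisq(lrt, df = df, lower.tail = FALSE)
  list(delta_adj_r_squared = fit_high$adj_r_squared - fit_low$adj_r_squared,
       lrt = lrt, df = df, p_value = pval, zero_residual = zero)
}

#' Sequential variance partition by interaction order
#'
#' Fits nested genetic models of order 1..L to one environment's
#' (transformed) replicate-level response and reports the sequential
#' R-squared increment contributed by each order. On a complete balanced
#' factorial the Walsh columns are orthogonal, so the increments are
#' nonnegative and invariant to the order in which same-order terms enter.
#' `epistatic_total` is everything beyond first order.
#'
#' @param table A `landscape` object.
#' @param environment Environment label.
#' @param spec A [design_spec()]; its `max_genetic_order` bounds the
#'   deepest model (default the full order L).
#' @param aggregate Passed to [build_design()].
#' @return A `variance_partition` list: `order` (1..max), `increment_pct`,
#'   `cumulative_pct`, `epistatic_total_pct`, `fits`.
#' @export
variance_partition <- function(table, environment, spec = NULL,
                               aggregate = c("replicates", "means")) {
  aggregate <- match.arg(aggregate)
  L <- length(landscape_sites(table))
  if (is.null(spec)) spec <- design_spec(max_genetic_order = L)
  max_order <- max(1L, spec$max_genetic_order)
  assert_complete(table, environment)
  fits <- vector("list", max_order)
  r2 <- numeric(max_order)
  for (k in seq_len(max_order)) {
    sk <- design_spec(max_genetic_order = k, transform = spec$transform,
                      floor = spec$floor)
    fits[[k]] <- fit_ols(build_design(table, sk, environment = environment,
                                      aggregate = aggregate))
    r2[k] <- fits[[k]]$r_squared
  }
  inc <- diff(c(0, r2)) * 100
  structure(list(environment = environment,
                 order = seq_len(max_order),
                 increment_pct = inc,
                 cumulative_pct = r2 * 100,
                 epistatic_total_pct = (r2[max_order] - r2[1L]) * 100,
                 fits = fits),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance partition, environment '%s'>\n", x$environment))
  for (k in x$order) {
    cat(sprintf("  order %d: +%6.2f%%  (cumulative %6.2f%%)\n",
                k, x$increment_pct[k], x$cumulative_pct[k]))
  }
  cat(sprintf("  epistatic total (orders >=2): %.2f%%\n", x$epistatic_total_pct))
  invisible(x)
}

#' Magnitude of one environment's effect on activity
#'
#' The dot product of the fitted environment coefficients with the label's
#' Hadamard coordinate vector: the modeled deviation of that environment
#' from the grand mean. Magnitudes sum to zero over all labels on a
#' complete balanced design.
#'
#' @param fit A `walsh_fit` whose design included environment terms.
#' @param label Environment label.
#' @return Numeric scalar on the response (transformed) scale.
#' @export
environment_effect_magnitude <- function(fit, label) {
  if (is.null(fit$env_coords)) stop("fit has no environment terms")
  if (!label %in% rownames(fit$env_coords)) {
    stop(sprintf("unknown environment label '%s'", label))
  }
  cf <- fit$coefficients
  env_cf <- cf$estimate[match(colnames(fit$env_coords), cf$term)]
  sum(env_cf * fit$env_coords[label, ])
}
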