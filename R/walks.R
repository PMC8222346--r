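# closed intervals [a1,a2], [b1,b2] overlap?
spans_overlap <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

# is interval `b` entirely below interval `a` (no touching)?
span_below <- function(b, a) b[2L] < a[1L]

#' Greedy adaptive walk under strong directional selection
#'
#' Projects the most likely evolutionary trajectory under strong
#' directional selection: from the current genotype, move to the
#' single-mutation neighbor (back-mutations included) with the greatest
#' improvement in mean activity, as long as the change is not negative;
#' repeat until no neighbor improves. Each step is annotated as ambiguous
#' when the replicate spans of the two genotypes overlap (the measurements
#' cannot resolve the order); ambiguity never blocks a step. Zero-
#' improvement steps are permitted (the rule is "not negative") but are
#' forced ambiguous, and a no-revisit guard halts the walk rather than
#' cycling. Ties between equally best neighbors break deterministically to
#' the lowest site index, with all tied candidates recorded.
#'
#' @param table A `landscape` object; the environment must be a complete
#'   factorial.
#' @param start Starting genotype label (default all-ancestral).
#' @param environment Environment label.
#' @param ambiguity `"span"` (default; replicate min-max interval) or
#'   `"mean_sd"` (mean +/- one standard deviation).
#' @return A `trajectory` list: `environment`, `start`, `steps` data frame
#'   (`from`, `to`, `site`, `delta_mean`, `ambiguous`, `tied`), `endpoint`,
#'   `endpoint_class` in `strict_optimum` / `tentative_optimum` /
#'   `stalled_no_improvement`, and `path` (visited genotypes in order).
#' @export
greedy_walk <- function(table, start = NULL, environment,
                        ambiguity = c("span", "mean_sd")) {
  ambiguity <- match.arg(ambiguity)
  sites <- landscape_sites(table)
  L <- length(sites)
  if (is.null(start)) start <- paste(rep("0", L), collapse = "")
  parse_genotype(start, sites)  # validates
  means <- cell_means(table, environment)
  spans <- cell_spans(table, environment, rule = ambiguity)

  current <- start
  visited <- start
  steps <- list()
  endpoint_class <- NULL
  repeat {
    nb <- neighbors(current)
    delta <- means[nb] - means[[current]]
    cand <- which(delta >= 0)
    if (!length(cand)) {
      endpoint_class <- classify_optimum_spans(current, nb, spans)
      break
    }
    best <- cand[delta[cand] == max(delta[cand])]
    pick <- best[1L]  # neighbors() is in site order: lowest site index wins
    to <- nb[pick]
    if (to %in% visited) {
      endpoint_class <- "stalled_no_improvement"
      break
    }
    amb <- spans_overlap(spans[current, ], spans[to, ]) || delta[pick] == 0
    steps[[length(steps) + 1L]] <- data.frame(
      from = current, to = to, site = sites[pick],
      delta_mean = unname(delta[pick]), ambiguous = amb,
      tied = paste(nb[best], collapse = ","),
      stringsAsFactors = FALSE)
    current <- to
    visited <- c(visited, to)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(from = character(), to = character(), site = character(),
               delta_mean = numeric(), ambiguous = logical(),
               tied = character(), stringsAsFactors = FALSE)
  structure(list(environment = environment, start = start, steps = steps,
                 endpoint = current, endpoint_class = endpoint_class,
                 path = visited, ambiguity = ambiguity),
            class = "trajectory")
}

# strict when every neighbor's span lies entirely below the endpoint's span
classify_optimum_spans <- function(g, nb, spans) {
  strict <- all(vapply(nb, function(x) span_below(spans[x, ], spans[g, ]),
                       logical(1L)))
  if (strict) "strict_optimum" else "tentative_optimum"
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory in '%s': %s -> %s (%d step(s), %s)>\n",
              x$environment, x$start, x$endpoint, nrow(x$steps), x$endpoint_class))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  %s -> %s  site %-4s d=%.4g%s\n",
                  x$steps$from[i], x$steps$to[i], x$steps$site[i],
                  x$steps$delta_mean[i],
                  if (x$steps$ambiguous[i]) "  [ambiguous]" else ""))
    }
  }
  invisible(x)
}

#' Enumerate all local and global optima of a landscape
#'
#' Exhaustively tests every genotype: a local optimum has a higher mean
#' activity than all of its L single-mutation neighbors; it is `strict`
#' when every neighbor's replicate span lies entirely below its own
#' (significantly lower measurements) and `tentative` otherwise. The
#' global optimum is the genotype with the maximum mean; exact ties are
#' all reported and flagged.
#'
#' @inheritParams greedy_walk
#' @return An `optima_set` list: `environment`, `optima` data frame
#'   (`genotype`, `mean`, `class`, `is_global`), `global` (labels),
#'   `global_tie` (logical).
#' @export
find_optima <- function(table, environment, ambiguity = c("span", "mean_sd")) {
  ambiguity <- match.arg(ambiguity)
  means <- cell_means(table, environment)
  spans <- cell_spans(table, environment, rule = ambiguity)
  gs <- names(means)
  is_opt <- vapply(gs, function(g) all(means[neighbors(g)] < means[[g]]), logical(1L))
  opt <- gs[is_opt]
  cls <- vapply(opt, function(g)
    classify_optimum_spans(g, neighbors(g), spans), character(1L))
  cls <- sub("_optimum$", "", cls)
  global <- gs[means == max(means)]
  optima <- data.frame(genotype = opt, mean = unname(means[opt]),
                       class = unname(cls), is_global = opt %in% global,
                       stringsAsFactors = FALSE)
  rownames(optima) <- NULL
  structure(list(environment = environment, optima = optima,
                 global = global, global_tie = length(global) > 1L),
            class = "optima_set")
}

#' @export
print.optima_set <- function(x, ...) {
  cat(sprintf("<optima in '%s': %d local optimum(a), global %s%s>\n",
              x$environment, nrow(x$optima), paste(x$global, collapse = "/"),
              if (x$global_tie) " [tie]" else ""))
  print(x$optima)
  invisible(x)
}

#' Classify a walk endpoint against the landscape's optima
#'
#' @param trajectory A [greedy_walk()] result.
#' @param optima_set A [find_optima()] result for the same environment.
#' @return `"reached_global"`, `"stranded_local"` (endpoint is a local but
#'   not global optimum), or `"stalled"` (halted by the cycle guard).
#' @export
classify_endpoint <- function(trajectory, optima_set) {
  if (trajectory$environment != optima_set$environment) {
    stop("trajectory and optima set are from different environments")
  }
  if (trajectory$endpoint_class == "stalled_no_improvement") return("stalled")
  if (trajectory$endpoint %in% optima_set$global) return("reached_global")
  if (trajectory$endpoint %in% optima_set$optima$genotype) return("stranded_local")
  stop(sprintf("internal inconsistency: endpoint %s is not in the optima set",
               trajectory$endpoint))
}

#' Per-step mutational-effect profile along a trajectory
#'
#' For every genotype visited by the walk, the effect of toggling each of
#' the L sites from that genotype (derived if currently ancestral, reversed
#' if currently derived), on the requested scale. Shows how the accumulated
#' substitutions reshape the effects of the remaining ones.
#'
#' @param trajectory A [greedy_walk()] result.
#' @param table The `landscape` it was computed from.
#' @param scale Effect scale, as in [background_effects()].
#' @param floor Detection floor.
#' @return Data frame: `step_index` (0 = start), `genotype`, `site`,
#'   `toggled_to`, `effect`, `floored`.
#' @export
walk_effect_profile <- function(trajectory, table,
                                scale = c("log10", "fold", "identity"),
                                floor = NULL) {
  scale <- match.arg(scale)
  if (is.null(floor)) floor <- detection_floor(table)
  sites <- landscape_sites(table)
  means <- cell_means(table, trajectory$environment)
  rows <- list()
  for (k in seq_along(trajectory$path)) {
    g <- trajectory$path[k]
    nb <- neighbors(g)
    for (i in seq_along(sites)) {
      se <- single_effect(means[[g]], means[[nb[i]]], scale, floor)
      rows[[length(rows) + 1L]] <- data.frame(
        step_index = k - 1L, genotype = g, site = sites[i],
        toggled_to = nb[i], effect = se$effect, floored = se$floored,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export a trajectory as a DOT graph
#'
#' One node per visited genotype, one directed edge per step; ambiguous
#' steps (overlapping replicate spans) are rendered dashed, matching the
#' dashed-arrow convention of trajectory diagrams.
#'
#' @param trajectory A [greedy_walk()] result.
#' @param path Output file; when `NULL` the DOT text is returned.
#' @return The DOT source as a character vector (invisibly when written).
#' @export
write_trajectory_dot <- function(trajectory, path = NULL) {
  lines <- c(sprintf("digraph trajectory_%s {", gsub("[^A-Za-z0-9]", "_",
                                                     trajectory$environment)),
             "  rankdir=LR;",
             sprintf("  \"%s\" [shape=star];", trajectory$start))
  if (nrow(trajectory$steps)) {
    for (i in seq_len(nrow(trajectory$steps))) {
      st <- trajectory$steps[i, ]
      style <- if (st$ambiguous) " [style=dashed]" else ""
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", st$from, st$to, style))
    }
  }
  lines <- c(lines,
             sprintf("  \"%s\" [peripheries=2];  // %s", trajectory$endpoint,
                     trajectory$endpoint_class),
             "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
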