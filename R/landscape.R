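#' Construct a validated landscape table
#'
#' A landscape table is the single source of truth for all downstream
#' analyses: a long-format table of replicate activity measurements keyed by
#' (genotype bitstring, environment label, replicate index). Activities are
#' nonnegative reals, e.g. lysate hydrolysis rates in nM/s normalized to
#' culture OD.
#'
#' @param records Data frame with columns `genotype` (character bitstring),
#'   `environment` (character), `replicate` (positive integer), `activity`
#'   (nonnegative numeric). Extra columns are preserved as metadata.
#' @param site_labels Ordered site identifiers; defaults to [mph_sites()]
#'   when L = 5, otherwise `"s1".."sL"`.
#' @param environments Ordered environment labels; defaults to order of
#'   first appearance.
#' @return A data frame of class `landscape` with attributes `site_labels`
#'   and `environments`.
#' @export
landscape_table <- function(records, site_labels = NULL, environments = NULL) {
  req <- c("genotype", "environment", "replicate", "activity")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$genotype <- as.character(records$genotype)
  records$environment <- as.character(records$environment)
  records$replicate <- as.integer(records$replicate)
  records$activity <- as.numeric(records$activity)

  lens <- nchar(records$genotype)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])
    stop("ragged genotype lengths; offending rows: ",
         paste(utils::head(off, 10L), collapse = ", "))
  }
  L <- lens[1L]
  bad_chars <- which(!grepl("^[01]+$", records$genotype))
  if (length(bad_chars)) {
    stop("non-binary genotype labels; offending rows: ",
         paste(utils::head(bad_chars, 10L), collapse = ", "))
  }
  neg <- which(is.na(records$activity) | records$activity < 0)
  if (length(neg)) {
    stop("negative or missing activity; offending rows: ",
         paste(utils::head(neg, 10L), collapse = ", "))
  }
  if (any(is.na(records$replicate)) || any(records$replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  key <- paste(records$genotype, records$environment, records$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (genotype, environment, replicate) keys; offending rows: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  if (is.null(site_labels)) site_labels <- make_site_labels(L)
  if (length(site_labels) != L) {
    stop(sprintf("site_labels has length %d but genotypes have %d sites",
                 length(site_labels), L))
  }
  if (is.null(environments)) environments <- unique(records$environment)
  if (!setequal(environments, unique(records$environment))) {
    stop("environments must match the labels present in the records")
  }
  structure(records,
            site_labels = as.character(site_labels),
            environments = as.character(environments),
            class = c("landscape", "data.frame"))
}

#' @export
print.landscape <- function(x, ...) {
  s <- attr(x, "site_labels")
  e <- attr(x, "environments")
  cat(sprintf("<landscape: %d records, L=%d sites [%s], %d environment(s)>\n",
              nrow(x), length(s), paste(s, collapse = ","), length(e)))
  comp <- completeness(x)
  cat(sprintf("  genotypes observed: %d / %d per environment; missing cells: %d\n",
              comp$n_genotypes_observed, comp$n_genotypes_expected, comp$n_missing))
  invisible(x)
}

#' Site labels of a landscape
#' @param table A `landscape` object.
#' @return Character vector of site labels.
#' @export
landscape_sites <- function(table) attr(table, "site_labels")

#' Environment labels of a landscape
#' @param table A `landscape` object.
#' @return Character vector of environment labels, in declared order.
#' @export
landscape_environments <- function(table) attr(table, "environments")

#' Completeness report for a landscape
#'
#' A full factorial design has all `2^L` genotypes in every environment.
#' This reports which genotype-by-environment cells are missing and the
#' replicate count per cell, without assuming the design is complete.
#'
#' @param table A `landscape` object.
#' @return List with `complete` (logical), `n_missing`, `missing` (data
#'   frame of absent cells), `n_genotypes_expected`, `n_genotypes_observed`,
#'   and `replicates` (per-cell replicate counts).
#' @export
completeness <- function(table) {
  L <- length(landscape_sites(table))
  envs <- landscape_environments(table)
  expected <- all_genotypes(L)
  counts <- as.data.frame(table(genotype = table$genotype,
                                environment = table$environment),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n_replicates"
  full <- expand.grid(genotype = expected, environment = envs,
                      stringsAsFactors = FALSE)
  merged <- merge(full, counts, by = c("genotype", "environment"), all.x = TRUE)
  merged$n_replicates[is.na(merged$n_replicates)] <- 0L
  missing <- merged[merged$n_replicates == 0L, c("genotype", "environment")]
  rownames(missing) <- NULL
  list(complete = nrow(missing) == 0L,
       n_missing = nrow(missing),
       missing = missing,
       n_genotypes_expected = length(expected),
       n_genotypes_observed = length(unique(table$genotype)),
       replicates = merged[merged$n_replicates > 0L, , drop = FALSE])
}

# stop unless every genotype x environment cell is populated for `environment`
assert_complete <- function(table, environment) {
  sub <- table[table$environment == environment, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("environment '%s' absent from the table", environment))
  L <- length(landscape_sites(table))
  missing <- setdiff(all_genotypes(L), unique(sub$genotype))
  if (length(missing)) {
    stop(sprintf("environment '%s' is missing %d genotype cell(s): %s",
                 environment, length(missing),
                 paste(utils::head(missing, 8L), collapse = ", ")))
  }
  invisible(sub)
}

#' Read a landscape from a long-format CSV
#'
#' Expected header: `genotype,environment,replicate,activity`, comma
#' separated, UTF-8. The genotype column is read as character so leading
#' zeros survive spreadsheet round trips.
#'
#' @param path CSV file path.
#' @param site_labels,environments Passed to [landscape_table()].
#' @return A validated `landscape` object.
#' @export
read_landscape_csv <- function(path, site_labels = NULL, environments = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(genotype = "character"))
  landscape_table(df, site_labels = site_labels, environments = environments)
}

#' Write a landscape to CSV
#'
#' Inverse of [read_landscape_csv()]: activities survive the round trip at
#' full double precision (written with 17 significant digits); the genotype
#' column is quoted to prevent integer mangling.
#'
#' @param table A `landscape` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(table, path) {
  out <- as.data.frame(table)
  out$activity <- sprintf("%.17g", out$activity)
  utils::write.csv(out, path, row.names = FALSE, quote = which(names(out) == "genotype"))
  invisible(path)
}

#' Replicate summary of one genotype-by-environment cell
#'
#' @param table A `landscape` object.
#' @param genotype Genotype label.
#' @param environment Environment label.
#' @return List with `mean` (arithmetic mean of replicates), `span`
#'   (closed interval `c(min, max)` of replicate measurements) and `n`.
#' @export
summarize_cell <- function(table, genotype, environment) {
  a <- table$activity[table$genotype == genotype & table$environment == environment]
  if (!length(a)) {
    stop(sprintf("no replicates for genotype '%s' in environment '%s'",
                 genotype, environment))
  }
  list(mean = mean(a), span = c(min(a), max(a)), n = length(a))
}

# named vector of cell means for one environment, genotypes in lex order
cell_means <- function(table, environment) {
  sub <- assert_complete(table, environment)
  m <- tapply(sub$activity, sub$genotype, mean)
  m[all_genotypes(length(landscape_sites(table)))]
}

# 2-column matrix of replicate spans (min, max), rows in lex genotype order
cell_spans <- function(table, environment, rule = c("span", "mean_sd")) {
  rule <- match.arg(rule)
  sub <- assert_complete(table, environment)
  gs <- all_genotypes(length(landscape_sites(table)))
  lo <- numeric(length(gs))
  hi <- numeric(length(gs))
  for (i in seq_along(gs)) {
    a <- sub$activity[sub$genotype == gs[i]]
    if (rule == "span") {
      lo[i] <- min(a); hi[i] <- max(a)
    } else {
      s <- if (length(a) > 1L) stats::sd(a) else 0
      lo[i] <- mean(a) - s; hi[i] <- mean(a) + s
    }
  }
  matrix(c(lo, hi), ncol = 2L, dimnames = list(gs, c("lo", "hi")))
}

#' Fold change in mean activity between two genotypes
#'
#' @param table A `landscape` object.
#' @param g_from,g_to Genotype labels.
#' @param environment Environment label.
#' @return `mean(g_to) / mean(g_from)`.
#' @export
#' @examples
#' tab <- landscape_table(data.frame(
#'   genotype = c("0", "0", "1", "1"), environment = "Zn",
#'   replicate = c(1, 2, 1, 2), activity = c(1, 3, 9, 11)))
#' fold_change(tab, "0", "1", "Zn")  # 5
fold_change <- function(table, g_from, g_to, environment) {
  from <- summarize_cell(table, g_from, environment)
  to <- summarize_cell(table, g_to, environment)
  if (from$mean <= 0) {
    stop(sprintf("fold change from '%s' in '%s' is undefined: mean activity %g is not positive",
                 g_from, environment, from$mean))
  }
  to$mean / from$mean
}

#' Detection floor for ratio and log computations
#'
#' Zero activities are legal in a landscape, but ratios and logarithms need
#' a positive value. The default floor is the smallest positive activity in
#' the table times `1e-2`; cells floored this way are flagged wherever the
#' floor is applied.
#'
#' @param table A `landscape` object.
#' @return Positive numeric scalar.
#' @export
detection_floor <- function(table) {
  pos <- table$activity[table$activity > 0]
  if (!length(pos)) stop("all activities are zero; no detection floor can be derived")
  min(pos) * 1e-2
}
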