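#' Default site labels for the five-site enzyme landscape
#'
#' The five active-site positions that separate the ancestral
#' dihydrocoumarin hydrolase from the derived methyl-parathion hydrolase,
#' ordered by sequence position. Bit i of a genotype label refers to
#' `mph_sites()[i]`, with `0` the ancestral and `1` the derived state.
#'
#' @return Character vector of length five: `"72" "193" "258" "271" "273"`.
#' @export
#' @examples
#' mph_sites()
mph_sites <- function() c("72", "193", "258", "271", "273")

#' Default environment labels for the eight-metal study design
#'
#' @return Character vector of the eight divalent-metal environment labels.
#' @export
metal_environments <- function() {
  c("Ca", "Cd", "Co", "Cu", "Mg", "Mn", "Ni", "Zn")
}

#' Parse a binary genotype label
#'
#' A genotype is an ordered bitstring over L biallelic sites: `0` marks the
#' ancestral state, `1` the derived state, and position i refers to
#' `site_labels[i]`.
#'
#' @param label Character scalar of `0`/`1` characters, one per site.
#' @param site_labels Ordered site identifiers; defaults to [mph_sites()].
#' @return An object of class `genotype` with fields `bits` (integer 0/1
#'   vector) and `site_labels`.
#' @export
#' @examples
#' parse_genotype("01100")
parse_genotype <- function(label, site_labels = mph_sites()) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  L <- length(site_labels)
  if (L < 1L) stop("site_labels must contain at least one site")
  chars <- strsplit(label, "", fixed = TRUE)[[1L]]
  if (length(chars) != L) {
    stop(sprintf("genotype label '%s' has %d characters but %d sites are defined",
                 label, length(chars), L))
  }
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("genotype label '%s' has a non-binary character '%s' at position %d",
                 label, chars[bad[1L]], bad[1L]))
  }
  structure(list(bits = as.integer(chars == "1"), site_labels = site_labels),
            class = "genotype")
}

#' Render a genotype back to its bitstring label
#'
#' @param g A `genotype` object or a character label (returned unchanged
#'   after validation).
#' @return Character scalar, e.g. `"01100"`.
#' @export
render_genotype <- function(g) {
  if (is.character(g)) g <- parse_genotype(g, make_site_labels(nchar(g)))
  stopifnot(inherits(g, "genotype"))
  paste(g$bits, collapse = "")
}

#' @export
format.genotype <- function(x, ...) {
  paste0("<genotype ", paste(x$bits, collapse = ""), " over sites [",
         paste(x$site_labels, collapse = ","), "]>")
}

#' @export
print.genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# generic site labels "s1".."sL" when a table declares none
make_site_labels <- function(L) {
  if (L == 5L) mph_sites() else paste0("s", seq_len(L))
}

#' Single-mutation neighbors of a genotype
#'
#' Returns the L genotypes at Hamming distance one, including back-mutations
#' (derived back to ancestral). Neighbor i toggles site i.
#'
#' @param g Genotype label (character) or `genotype` object.
#' @return Character vector of L neighbor labels, in site order.
#' @export
#' @examples
#' neighbors("00000")
neighbors <- function(g) {
  label <- if (is.character(g)) g else render_genotype(g)
  bits <- as.integer(strsplit(label, "", fixed = TRUE)[[1L]])
  if (any(!bits %in% c(0L, 1L))) stop("genotype label must be binary")
  vapply(seq_along(bits), function(i) {
    b <- bits
    b[i] <- 1L - b[i]
    paste(b, collapse = "")
  }, character(1L))
}

#' All genotype labels for an L-site landscape
#'
#' Labels are returned in lexicographic order, which for bitstrings is
#' binary counting order; this ordering is used consistently for design
#' rows, Walsh transforms, and background enumeration.
#'
#' @param L Number of sites.
#' @return Character vector of length `2^L`.
#' @export
all_genotypes <- function(L) {
  stopifnot(L >= 1L, L <= 25L)
  grid <- expand.grid(rep(list(0:1), L))[, L:1, drop = FALSE]
  sort(apply(grid, 1L, paste, collapse = ""))
}

# Hamming distance between two labels
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}
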