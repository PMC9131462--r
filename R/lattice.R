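## The partial-information (PI) lattice.
##
## A "collection" is a non-empty subset of the source variables, stored as a
## bitmask over source positions (source 0 = bit 0). A PI atom is an
## antichain of collections: a set of collections none of which contains
## another. Atoms are partially ordered by
##     alpha <= beta  iff  every B in beta has some A in alpha with A in B,
## equivalently D(beta) subset of D(alpha), where D(a) is the up-closure of
## a in the poset of collections (all collections that contain a member of
## a). D is stored as a bitmask over the 2^n - 1 collections, which makes
## order tests single bit operations. NOTE: the all-ones mask equals
## .Machine$integer.max, whose bitwise complement is INT_MIN = NA_integer_
## in R, so subset tests must be written bitwAnd(Dj, Di) == Dj and never via
## bitwNot().

.lattice_cache <- new.env(parent = emptyenv())

#' Enumerate the partial-information lattice
#'
#' Enumerates every antichain of non-empty subsets of `n_sources` sources,
#' the partial order between them, the strict down-set of each atom, and the
#' layer height of each atom (the length of the longest chain from the
#' bottom atom, which for this lattice coincides with the longest-chain
#' distance measured from the top). Atom counts are 4, 18, 166 and 7579 for
#' 2 to 5 sources. Results are cached per source count and reused.
#'
#' @param n_sources number of source variables, between 2 and 5. The cap
#'   exists because antichain counts grow like the Dedekind numbers.
#' @return An object of class `pi_lattice` with fields:
#'   \describe{
#'     \item{n_sources}{number of sources.}
#'     \item{atoms}{list of integer vectors; each atom is a sorted vector of
#'       collection bitmasks.}
#'     \item{labels}{canonical atom strings such as `"{0}{1}"` or `"{01}"`;
#'       collections sorted by size then by source indices.}
#'     \item{heights}{integer layer index per atom, bottom = 0.}
#'     \item{top_height}{maximum height.}
#'     \item{down_sets}{list of integer vectors: indices of the atoms
#'       strictly below each atom.}
#'     \item{up_masks}{the D bitmasks used for order tests.}
#'   }
#' @export
enumerate_lattice <- function(n_sources) {
  n_sources <- as.integer(n_sources)
  if (n_sources < 2L || n_sources > 5L)
    stop("the PI lattice is supported for 2 to 5 sources")
  key <- as.character(n_sources)
  if (!is.null(.lattice_cache[[key]])) return(.lattice_cache[[key]])

  atoms <- enumerate_antichains(n_sources)
  D <- vapply(atoms, up_mask, integer(1), n_sources = n_sources)
  na <- length(atoms)

  down_sets <- vector("list", na)
  for (j in seq_len(na)) {
    leq <- bitwAnd(D[j], D) == D[j]      # all i with atom_i <= atom_j
    leq[j] <- FALSE
    down_sets[[j]] <- which(leq)
  }
  sizes <- lengths(down_sets)
  heights <- integer(na)
  for (j in order(sizes))                # a linear extension of the order
    heights[j] <- if (sizes[j]) max(heights[down_sets[[j]]]) + 1L else 0L

  lab <- vapply(atoms, antichain_label, character(1))
  ## stable presentation order: by height, then canonical label
  ord <- order(heights, lab)
  rank <- integer(na); rank[ord] <- seq_len(na)
  lattice <- structure(
    list(n_sources  = n_sources,
         atoms      = atoms[ord],
         labels     = lab[ord],
         heights    = heights[ord],
         top_height = max(heights),
         down_sets  = lapply(down_sets[ord], function(ix) sort(rank[ix])),
         up_masks   = D[ord]),
    class = "pi_lattice")
  .lattice_cache[[key]] <- lattice
  lattice
}

#' @export
print.pi_lattice <- function(x, ...) {
  cat(sprintf("PI lattice on %d sources: %d atoms, heights 0..%d\n",
              x$n_sources, length(x$atoms), x$top_height))
  cat("  bottom:", x$labels[1], " top:", x$labels[length(x$labels)], "\n")
  invisible(x)
}

## depth-first enumeration of antichains over collection bitmasks 1..2^n-1;
## each atom is emitted as a sorted integer vector
enumerate_antichains <- function(n) {
  ncoll <- 2L^n - 1L
  out <- vector("list", 0L)
  recurse <- function(current, start) {
    if (start > ncoll) return(invisible(NULL))
    for (cc in start:ncoll) {
      ok <- TRUE
      for (m in current) {
        ab <- bitwAnd(m, cc)
        if (ab == m || ab == cc) { ok <- FALSE; break }   # comparable
      }
      if (ok) {
        nxt <- c(current, cc)
        out[[length(out) + 1L]] <<- nxt
        recurse(nxt, cc + 1L)
      }
    }
  }
  recurse(integer(0), 1L)
  out
}

## bitmask over the 2^n-1 collections: bit s-1 set iff collection s contains
## some member of the antichain
up_mask <- function(atom, n_sources) {
  ncoll <- 2L^n_sources - 1L
  m <- 0L
  for (s in 1:ncoll) {
    for (A in atom) {
      if (bitwAnd(A, s) == A) {
        m <- bitwOr(m, bitwShiftL(1L, s - 1L))
        break
      }
    }
  }
  m
}

#' Compare two PI atoms under the lattice order
#'
#' Returns `TRUE` when `a` precedes (or equals) `b`: every collection in `b`
#' must contain some collection in `a` as a subset. Atoms may be given as
#' canonical strings (`"{0}{1}"`, `"{01}{02}"`) or as lists/vectors of
#' integer source-index vectors.
#'
#' @param a,b antichains over the same source universe.
#' @param n_sources number of sources (needed to validate indices).
#' @return Logical scalar.
#' @examples
#' antichain_leq("{0}{1}", "{0}", n_sources = 2)   # TRUE
#' antichain_leq("{0}", "{12}", n_sources = 3)     # FALSE
#' @export
antichain_leq <- function(a, b, n_sources) {
  ma <- parse_antichain(a, n_sources)
  mb <- parse_antichain(b, n_sources)
  bitwAnd(up_mask(mb, n_sources), up_mask(ma, n_sources)) == up_mask(mb, n_sources)
}

## accepts "{0}{12}", list(0, c(1,2)), or an integer bitmask vector
parse_antichain <- function(x, n_sources) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    parts <- regmatches(x, gregexpr("\\{[0-9]+\\}", x))[[1]]
    if (!length(parts) || nchar(gsub("\\{[0-9]+\\}", "", x)) > 0)
      stop(sprintf("cannot parse antichain string '%s'", x))
    sets <- lapply(parts, function(p) {
      as.integer(strsplit(gsub("[{}]", "", p), "")[[1]])
    })
  } else if (is.list(x)) {
    sets <- lapply(x, as.integer)
  } else {
    masks <- sort(as.integer(x))
    check_antichain(masks, n_sources)
    return(masks)
  }
  masks <- vapply(sets, function(s) {
    if (any(s < 0L | s >= n_sources))
      stop(sprintf("source index out of range [0, %d)", n_sources))
    sum(bitwShiftL(1L, unique(s)))
  }, integer(1))
  masks <- sort(masks)
  check_antichain(masks, n_sources)
  masks
}

check_antichain <- function(masks, n_sources) {
  if (!length(masks)) stop("an antichain must contain at least one collection")
  if (any(masks < 1L | masks > 2L^n_sources - 1L))
    stop("collection out of range for the declared source count")
  if (anyDuplicated(masks)) stop("duplicate collection in antichain")
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (i != j && bitwAnd(masks[i], masks[j]) == masks[i])
      stop("collections in an antichain must be pairwise incomparable")
  }
  invisible(masks)
}

## canonical label: collections sorted by (size, source tuple), sources
## ascending inside braces, e.g. "{0}{1}{2}", "{01}{02}", "{012}"
antichain_label <- function(atom) {
  srcs <- lapply(atom, mask_sources)
  key <- vapply(srcs, function(s) sprintf("%02d%s", length(s), paste(s, collapse = "")),
                character(1))
  paste0(vapply(srcs[order(key)],
                function(s) paste0("{", paste(s, collapse = ""), "}"),
                character(1)),
         collapse = "")
}

mask_sources <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:30)) > 0) - 1L
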