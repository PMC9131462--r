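## Williams-Beer partial information decomposition of a joint past-future
## distribution. Sources are individual past nodes; the target is the joint
## future state (any column variable of the joint works).

#' Specific information of a source collection about one target state
#'
#' `I(coll; Y = y) = sum_{x_c} P(x_c | y) log2( P(y | x_c) / P(y) )`,
#' where `x_c` ranges over the joint states of the collection's variables.
#' This is the per-state quantity whose expected minimum over collections
#' defines the Williams-Beer redundancy.
#'
#' @param coll collection of source positions: an integer vector of 0-based
#'   indices into `sources` (e.g. `c(0, 2)`), or a single-collection string
#'   such as `"{02}"`.
#' @param y target state index (0-based column of the joint).
#' @param joint a [joint_past_future()] whose rows are joint states of
#'   `node_count` binary nodes.
#' @param sources integer vector of node indices acting as sources;
#'   positions in this vector are what `coll` refers to. Defaults to all
#'   nodes.
#' @return Specific information in bits.
#' @export
specific_information <- function(coll, y, joint, sources = NULL) {
  stopifnot(inherits(joint, "joint_past_future"))
  sources <- default_sources(joint, sources)
  mask <- collection_mask(coll, length(sources))
  py <- colSums(joint$probs)
  y <- as.integer(y)
  if (y < 0L || y >= joint$n_future) stop("target state index out of range")
  if (py[y + 1L] <= 0) stop(sprintf("target state %d has zero probability", y))
  SI <- specific_information_matrix(joint, sources, masks = mask)
  SI[1L, y + 1L]
}

#' Williams-Beer redundancy of an antichain of collections
#'
#' `I_WB(alpha; Y) = sum_y P(y) min_{A in alpha} I(A; Y = y)`: the expected
#' minimum information any collection in `alpha` carries about the realised
#' target state. It is non-negative and monotone along the lattice order.
#'
#' @param a an antichain: canonical string (`"{0}{1}"`), list of integer
#'   source-position vectors, or integer bitmask vector.
#' @param joint a [joint_past_future()].
#' @param sources node indices acting as sources (default all nodes).
#' @return Redundancy in bits.
#' @export
redundancy_iwb <- function(a, joint, sources = NULL) {
  stopifnot(inherits(joint, "joint_past_future"))
  sources <- default_sources(joint, sources)
  masks <- parse_antichain(a, length(sources))
  SI <- specific_information_matrix(joint, sources, masks = masks)
  py <- colSums(joint$probs)
  si <- SI[1L, ]
  for (r in seq_along(masks)[-1]) si <- pmin(si, SI[r, ])
  pos <- py > 0
  sum(py[pos] * si[pos])
}

## SI values for a set of collection bitmasks: rows = masks (in the given
## order), cols = target states. Zero-probability targets get SI = 0 and are
## skipped by callers.
specific_information_matrix <- function(joint, sources, masks) {
  J <- joint$probs
  nx <- nrow(J)
  py <- colSums(J)
  pos <- which(py > 0)
  x <- 0:(nx - 1)
  SI <- matrix(0, length(masks), ncol(J))
  for (r in seq_along(masks)) {
    nodes <- sources[mask_sources(masks[r]) + 1L]
    key <- rep(0L, nx)
    for (k in seq_along(nodes))
      key <- key + bitwShiftL(as.integer(bitwAnd(x, bitwShiftL(1L, nodes[k])) > 0), k - 1L)
    Pc <- rowsum(J, key)                     # P(x_c, y)
    pxc <- rowSums(Pc)
    for (yi in pos) {
      col <- Pc[, yi]
      nz <- col > 0
      SI[r, yi] <- sum((col[nz] / py[yi]) * log2(col[nz] / (pxc[nz] * py[yi])))
    }
  }
  SI
}

default_sources <- function(joint, sources) {
  if (is.null(sources)) {
    if (is.null(joint$node_count))
      stop("joint carries no node structure; supply `sources` explicitly")
    sources <- 0:(joint$node_count - 1L)
  }
  sources <- as.integer(sources)
  nb <- as.integer(round(log2(joint$n_past)))
  if (any(sources < 0L | sources >= nb))
    stop("source node indices out of range for the joint's past state space")
  sources
}

collection_mask <- function(coll, n_sources) {
  m <- parse_antichain(if (is.character(coll)) coll else list(coll), n_sources)
  if (length(m) != 1L) stop("`coll` must be a single collection, not an antichain")
  m
}

#' Partial information decomposition on the Williams-Beer lattice
#'
#' Computes the redundancy `Red(alpha)` of every atom of the PI lattice and
#' recovers the atom values by Moebius inversion in ascending height order:
#' `Pi(alpha) = Red(alpha) - sum_{beta < alpha} Pi(beta)`. Redundancies are
#' evaluated once per distinct collection (at most `2^n - 1` evaluations)
#' and shared across atoms. Atom values in `[-1e-12, 0)` are clipped to 0;
#' the atoms sum to the total mutual information by construction, which is
#' cross-checked against a direct evaluation.
#'
#' @param joint a [joint_past_future()].
#' @param sources integer vector of past node indices acting as sources
#'   (default: all nodes). Between 2 and 5 sources.
#' @param redundancy redundancy function: the string `"iwb"` (the only
#'   shipped measure) or a function with signature
#'   `function(masks, joint, sources)` returning the redundancy of the
#'   antichain given by collection bitmasks `masks`.
#' @return An object of class `pid_result`: a list with `atoms` and
#'   `redundancy` (named numeric vectors over canonical atom labels, bits),
#'   `total_mi` (bits), `n_sources`, and `heights`.
#' @examples
#' xor <- boolean_network(
#'   parents = list(c(0L, 1L), c(0L, 1L), c(0L, 1L)),
#'   tables  = list(c(.5, .5, .5, .5), c(.5, .5, .5, .5), c(0, 1, 1, 0)))
#' # not a driven circuit, just the update table; see gate_circuit() for those
#' @export
pid_atoms <- function(joint, sources = NULL, redundancy = "iwb") {
  stopifnot(inherits(joint, "joint_past_future"))
  sources <- default_sources(joint, sources)
  n <- length(sources)
  if (n < 2L || n > 5L) stop("PID requires between 2 and 5 sources")
  lattice <- enumerate_lattice(n)
  py <- colSums(joint$probs)
  pos <- py > 0

  if (identical(redundancy, "iwb")) {
    all_masks <- 1:(2L^n - 1L)
    SI <- specific_information_matrix(joint, sources, all_masks)
    red_fn <- function(masks) {
      si <- SI[masks[1], ]
      for (m in masks[-1]) si <- pmin(si, SI[m, ])
      sum(py[pos] * si[pos])
    }
  } else if (is.function(redundancy)) {
    red_fn <- function(masks) redundancy(masks, joint, sources)
  } else {
    stop(sprintf("unknown redundancy function '%s' (shipped: \"iwb\")",
                 as.character(redundancy)))
  }

  na <- length(lattice$atoms)
  Red <- vapply(lattice$atoms, red_fn, numeric(1))
  Pi <- numeric(na)
  for (j in order(lattice$heights))
    Pi[j] <- Red[j] - sum(Pi[lattice$down_sets[[j]]])
  Pi[Pi < 0 & Pi >= -1e-12] <- 0

  total <- Red[na]                         # top atom = all sources jointly
  mi_direct <- source_marginal_mi(joint, sources)
  if (abs(total - mi_direct) > 1e-6)
    stop(sprintf("internal inconsistency: Red(top) = %.9f but I(sources;Y) = %.9f",
                 total, mi_direct))
  structure(
    list(atoms = stats::setNames(Pi, lattice$labels),
         redundancy = stats::setNames(Red, lattice$labels),
         total_mi = total,
         n_sources = n,
         heights = stats::setNames(lattice$heights, lattice$labels)),
    class = "pid_result")
}

## I(X_sources; Y) from the joint, marginalising rows over non-source bits
source_marginal_mi <- function(joint, sources) {
  J <- joint$probs
  x <- 0:(nrow(J) - 1)
  key <- rep(0L, nrow(J))
  for (k in seq_along(sources))
    key <- key + bitwShiftL(as.integer(bitwAnd(x, bitwShiftL(1L, sources[k])) > 0), k - 1L)
  Jm <- rowsum(J, key)
  px <- rowSums(Jm)
  py <- colSums(Jm)
  nz <- Jm > 0
  denom <- outer(px, py)
  sum(Jm[nz] * log2(Jm[nz] / denom[nz]))
}

#' @export
print.pid_result <- function(x, n = 8, ...) {
  cat(sprintf("PID over %d sources: total MI = %.4f bits, %d atoms\n",
              x$n_sources, x$total_mi, length(x$atoms)))
  big <- sort(x$atoms[x$atoms > 1e-10], decreasing = TRUE)
  show <- utils::head(big, n)
  for (nm in names(show))
    cat(sprintf("  %-18s h=%-2d  %.4f bits\n", nm, x$heights[nm], show[nm]))
  if (length(big) > n) cat(sprintf("  ... %d more non-zero atoms\n", length(big) - n))
  invisible(x)
}

#' Partial information spectrum of a decomposition
#'
#' Groups the PI atoms by lattice height and reports the fraction of the
#' total mutual information carried by each layer:
#' `S_i = (sum of atoms at height i) / I(X;Y)`. Redundancy-dominated
#' systems are bottom-heavy, synergy-dominated systems top-heavy.
#'
#' @param pid a [pid_atoms()] result.
#' @return An object of class `pi_spectrum` with `layer_mass` (length
#'   `top_height + 1`, bottom layer first), `synergy_bias`,
#'   `redundancy_bias` and `total_mi`.
#' @export
pi_spectrum <- function(pid) {
  stopifnot(inherits(pid, "pid_result"))
  if (pid$total_mi <= 0)
    stop("spectrum undefined: total mutual information is zero")
  lattice <- enumerate_lattice(pid$n_sources)
  S <- numeric(lattice$top_height + 1L)
  mass <- tapply(pid$atoms, pid$heights, sum)
  S[as.integer(names(mass)) + 1L] <- mass / pid$total_mi
  bsyn <- sum((seq_along(S) - 1L) / lattice$top_height * S)
  structure(list(layer_mass = S,
                 synergy_bias = bsyn,
                 redundancy_bias = 1 - bsyn,
                 total_mi = pid$total_mi,
                 n_sources = pid$n_sources,
                 top_height = lattice$top_height),
            class = "pi_spectrum")
}

#' @export
print.pi_spectrum <- function(x, ...) {
  cat(sprintf("PI spectrum (%d sources, %d layers): B_syn = %.3f, B_red = %.3f\n",
              x$n_sources, length(x$layer_mass), x$synergy_bias, x$redundancy_bias))
  nz <- which(x$layer_mass > 1e-10)
  for (i in nz)
    cat(sprintf("  layer %2d: %.4f\n", i - 1L, x$layer_mass[i]))
  invisible(x)
}

#' Synergy bias of a PI spectrum
#'
#' The normalised height-weighted centre of mass of the spectrum:
#' `B_syn = sum_i (i / top_height) S_i`, in `[0, 1]`. All mass in the
#' bottom (fully redundant) layer gives 0; all mass in the top (fully
#' synergistic) atom gives 1. Dividing by the top height rather than by the
#' layer count makes biases comparable across lattices of different size.
#'
#' @param spec a [pi_spectrum()] (a [pid_atoms()] result is also accepted
#'   and converted).
#' @return Numeric scalar in `[0, 1]`.
#' @export
synergy_bias <- function(spec) {
  if (inherits(spec, "pid_result")) spec <- pi_spectrum(spec)
  stopifnot(inherits(spec, "pi_spectrum"))
  spec$synergy_bias
}

#' Redundancy bias of a PI spectrum
#'
#' The complement of the synergy bias measured from the top of the lattice:
#' `B_red = 1 - B_syn`.
#'
#' @inheritParams synergy_bias
#' @return Numeric scalar in `[0, 1]`.
#' @export
redundancy_bias <- function(spec) {
  if (inherits(spec, "pid_result")) spec <- pi_spectrum(spec)
  stopifnot(inherits(spec, "pi_spectrum"))
  spec$redundancy_bias
}
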