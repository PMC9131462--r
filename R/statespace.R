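## Joint-state indexing convention used throughout the package:
## a system of n binary nodes has 2^n joint states indexed 0..2^n-1,
## with node i stored at bit position i (node 0 = least-significant bit).
## All vectors/matrices over joint states are ordered by that index.

#' Define a Boolean network
#'
#' A Boolean network is a directed network of binary nodes updated
#' synchronously: at every timestep, node `i` draws its next state from a
#' Bernoulli distribution whose success probability is looked up in its
#' update table, indexed by the joint state of its parents. Deterministic
#' logic gates are the special case where all table entries are 0 or 1.
#'
#' @param parents list with one integer vector per node giving the parent
#'   node indices (0-based), in the order used to index the update table
#'   (first parent = least-significant bit). A node with no parents has an
#'   empty vector and a length-1 table.
#' @param tables list with one numeric vector per node; entry `k+1` is the
#'   probability that the node is 1 at the next step given that its parents'
#'   joint state has index `k`. Length must be `2^(number of parents)`.
#' @param labels optional character vector of node names.
#'
#' @return An object of class `boolean_network`.
#' @examples
#' # two nodes copying each other
#' net <- boolean_network(
#'   parents = list(1L, 0L),
#'   tables  = list(c(0, 1), c(0, 1))
#' )
#' build_tpm(net)
#' @export
boolean_network <- function(parents, tables, labels = NULL) {
  if (!is.list(parents) || !is.list(tables) || length(parents) != length(tables))
    stop("`parents` and `tables` must be lists of equal length (one entry per node)")
  n <- length(parents)
  if (n < 1L) stop("a Boolean network needs at least one node")
  for (i in seq_len(n)) {
    p <- parents[[i]]
    if (length(p) && (any(p < 0L) || any(p >= n)))
      stop(sprintf("node %d: parent indices must lie in [0, %d)", i - 1L, n))
    tab <- tables[[i]]
    if (length(tab) != 2^length(p))
      stop(sprintf("node %d: table has %d entries, expected %d for %d parent(s)",
                   i - 1L, length(tab), 2^length(p), length(p)))
    if (any(tab < 0 | tab > 1))
      stop(sprintf("node %d: table entries must be probabilities in [0, 1]", i - 1L))
  }
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` must have one name per node")
  structure(
    list(n_nodes = n,
         parents = lapply(parents, as.integer),
         tables  = lapply(tables, as.numeric),
         labels  = labels %||% paste0("n", seq_len(n) - 1L)),
    class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes, %d joint states\n", x$n_nodes, 2^x$n_nodes))
  for (i in seq_len(x$n_nodes)) {
    cat(sprintf("  %s <- {%s}  table: %s\n", x$labels[i],
                paste(x$parents[[i]], collapse = ","),
                paste(format(x$tables[[i]], digits = 3), collapse = " ")))
  }
  invisible(x)
}

#' Construct a transition probability matrix
#'
#' Validates and wraps a row-stochastic matrix of transition probabilities
#' over joint states. Rows index the current state, columns the next state,
#' both under the package's bit convention (node i = bit i).
#'
#' @param probs square numeric matrix; each row must sum to 1 within 1e-12
#'   (rows off by at most `renormalise_tol` are renormalised with a warning).
#' @param node_count number of binary nodes, when the state space is the
#'   joint state space of binary nodes; `NULL` for unstructured state spaces.
#' @param renormalise_tol tolerance within which slightly off rows are
#'   silently rescaled rather than rejected.
#'
#' @return An object of class `tpm` with fields `probs`, `n_states`,
#'   `node_count`.
#' @export
tpm <- function(probs, node_count = NULL, renormalise_tol = 1e-6) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("a transition matrix must be square")
  if (any(probs < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad)) {
    worst <- bad[which.max(abs(rs[bad] - 1))]
    if (max(abs(rs[bad] - 1)) > renormalise_tol)
      stop(sprintf("row %d sums to %.9g, not 1", worst - 1L, rs[worst]))
    warning(sprintf("renormalising %d row(s) whose sums deviate from 1 by at most %.3g",
                    length(bad), max(abs(rs[bad] - 1))))
    probs <- probs / rs
  }
  if (!is.null(node_count)) {
    node_count <- as.integer(node_count)
    if (2^node_count != nrow(probs))
      stop(sprintf("node_count %d implies %d states but matrix has %d rows",
                   node_count, 2^node_count, nrow(probs)))
  }
  structure(list(probs = unname(probs), n_states = nrow(probs),
                 node_count = node_count),
            class = "tpm")
}

#' @export
print.tpm <- function(x, ...) {
  cat(sprintf("Transition matrix over %d states", x$n_states))
  if (!is.null(x$node_count)) cat(sprintf(" (%d binary nodes)", x$node_count))
  cat("\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Build the transition probability matrix of a Boolean network
#'
#' Under synchronous update, nodes are conditionally independent given the
#' current joint state, so the transition probability factorises over nodes:
#' `P(y | x) = prod_i P(node i takes its bit in y | parent bits in x)`.
#'
#' @param net a [boolean_network()].
#' @return A [tpm()] over the `2^n_nodes` joint states.
#' @export
build_tpm <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  n <- net$n_nodes
  ns <- 2^n
  x <- 0:(ns - 1)
  probs <- matrix(1, ns, ns)
  for (i in seq_len(n)) {
    pars <- net$parents[[i]]
    idx <- rep(0L, ns)
    if (length(pars))
      for (k in seq_along(pars))
        idx <- idx + bitwShiftL(as.integer(bitwAnd(x, bitwShiftL(1L, pars[k])) > 0), k - 1L)
    p1 <- net$tables[[i]][idx + 1L]               # P(node i = 1 | x), per row
    ybit <- as.integer(bitwAnd(x, bitwShiftL(1L, i - 1L)) > 0)
    probs <- probs * outer(p1, ybit, function(p, b) b * p + (1 - b) * (1 - p))
  }
  tpm(probs, node_count = n)
}

#' Construct a distribution over joint states
#'
#' @param probs non-negative numeric vector summing to 1 within 1e-12.
#' @return An object of class `state_distribution` (a numeric vector).
#' @export
state_distribution <- function(probs) {
  probs <- as.numeric(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(probs, class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("State distribution over", length(x), "states\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi = pi P` restricted to a recurrent class. Recurrent classes are
#' found as the terminal strongly connected components of the positive-
#' support digraph; when several exist, the one containing the most states is
#' used, ties broken towards the class containing the lowest state index.
#' The restricted balance equations are solved by least squares, with power
#' iteration as a fallback.
#'
#' @param x a [tpm()].
#' @param tol residual tolerance on `||pi - pi P||_1`.
#' @param max_iter iteration cap for the power-iteration fallback.
#' @return A [state_distribution()] over all states (zero off the chosen
#'   recurrent class).
#' @export
stationary_distribution <- function(x, tol = 1e-12, max_iter = 1e6) {
  stopifnot(inherits(x, "tpm"))
  P <- x$probs
  ns <- nrow(P)
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  ## a class is recurrent iff no positive transition leaves it
  terminal <- vapply(seq_len(comp$no), function(k) {
    rows <- which(memb == k)
    all(P[rows, memb != k, drop = FALSE] == 0)
  }, logical(1))
  cand <- which(terminal)
  if (!length(cand)) stop("no recurrent class found (malformed transition matrix)")
  sizes <- comp$csize[cand]
  best <- cand[sizes == max(sizes)]
  if (length(best) > 1L) {
    lowest <- vapply(best, function(k) min(which(memb == k)), integer(1))
    best <- best[which.min(lowest)]
  }
  cls <- which(memb == best)
  Pc <- P[cls, cls, drop = FALSE]
  ## rows restricted to a recurrent class remain stochastic
  m <- length(cls)
  pi_c <- tryCatch({
    A <- rbind(t(Pc) - diag(m), rep(1, m))
    sol <- qr.solve(A, c(rep(0, m), 1))
    if (any(sol < -1e-9)) stop("negative mass")
    pmax(sol, 0) / sum(pmax(sol, 0))
  }, error = function(e) NULL)
  if (is.null(pi_c) || sum(abs(pi_c %*% Pc - pi_c)) > 1e-8) {
    pi_c <- rep(1 / m, m)
    it <- 0
    repeat {
      nxt <- as.vector(pi_c %*% Pc)
      if (sum(abs(nxt - pi_c)) < tol || it >= max_iter) break
      pi_c <- nxt
      it <- it + 1
    }
    res <- sum(abs(pi_c %*% Pc - pi_c))
    if (res > 1e-10)
      stop(sprintf("stationary distribution did not converge: residual %.3g after %d iterations",
                   res, it))
  }
  out <- numeric(ns)
  out[cls] <- pi_c
  state_distribution(out)
}

#' Push a state distribution through a transition matrix
#'
#' `P(Y) = P(X) %*% P(Y|X)`.
#'
#' @param x a [tpm()].
#' @param input_dist a [state_distribution()] over the same state space.
#' @return A [state_distribution()] over next states.
#' @export
output_distribution <- function(x, input_dist) {
  stopifnot(inherits(x, "tpm"))
  if (length(input_dist) != x$n_states)
    stop(sprintf("input distribution has %d states, matrix has %d",
                 length(input_dist), x$n_states))
  state_distribution(as.vector(as.numeric(input_dist) %*% x$probs))
}

#' Joint past-future distribution of a Markov system
#'
#' Weights each row of the transition matrix by the probability of that past
#' state: `P(x, y) = P(x) * P(y | x)`. The result is the bivariate
#' distribution on which the temporal mutual information and its
#' decomposition are computed.
#'
#' @param x a [tpm()].
#' @param input_dist a [state_distribution()] for the past state; typically
#'   the stationary distribution.
#' @return An object of class `joint_past_future` with fields `probs` (the
#'   matrix `P(x, y)`), `node_count`, `n_past`, `n_future`.
#' @export
joint_past_future <- function(x, input_dist) {
  stopifnot(inherits(x, "tpm"))
  if (length(input_dist) != x$n_states)
    stop(sprintf("input distribution has %d states, matrix has %d",
                 length(input_dist), x$n_states))
  new_joint(as.numeric(input_dist) * x$probs, node_count = x$node_count)
}

## internal constructor; also used for non-square joints (generic targets)
new_joint <- function(probs, node_count = NULL) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("joint probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("joint distribution must sum to 1")
  structure(list(probs = unname(probs),
                 node_count = node_count,
                 n_past = nrow(probs),
                 n_future = ncol(probs)),
            class = "joint_past_future")
}

#' @export
print.joint_past_future <- function(x, ...) {
  cat(sprintf("Joint past-future distribution: %d x %d states", x$n_past, x$n_future))
  if (!is.null(x$node_count)) cat(sprintf(" (%d past nodes)", x$node_count))
  cat(sprintf("\n  I(X;Y) = %.4f bits\n", temporal_mutual_information(x)))
  invisible(x)
}

#' Temporal mutual information
#'
#' The mutual information, in bits, between the joint past and joint future
#' states: `I(X;Y) = sum_{x,y} P(x,y) log2( P(x,y) / (P(x) P(y)) )`, with
#' `0 log 0 := 0`. It measures how much knowing the system's past reduces
#' uncertainty about its future; a point attractor gives 0 bits and a
#' deterministic permutation visited uniformly gives `log2(n)` bits.
#'
#' @param joint a [joint_past_future()].
#' @return Mutual information in bits (non-negative).
#' @export
temporal_mutual_information <- function(joint) {
  stopifnot(inherits(joint, "joint_past_future"))
  J <- joint$probs
  px <- rowSums(J)
  py <- colSums(J)
  nz <- J > 0
  denom <- outer(px, py)
  max(0, sum(J[nz] * log2(J[nz] / denom[nz])))
}

## Shannon entropy of a probability vector, in bits
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Partition of a micro state space into macro states
#'
#' @param map integer vector: `map[x+1]` is the macro state index (0-based)
#'   of micro state `x`. The macro indices must form `0:(max)` with every
#'   class non-empty.
#' @param weights optional per-micro-state weights; within each macro class
#'   they must sum to 1. When omitted, coarse-graining conditions on a
#'   stationary distribution instead.
#' @return An object of class `state_partition`.
#' @export
state_partition <- function(map, weights = NULL) {
  map <- as.integer(map)
  if (any(map < 0L)) stop("macro indices must be non-negative")
  n_macro <- max(map) + 1L
  if (!setequal(unique(map), 0:(n_macro - 1L)))
    stop("partition must be onto: every macro state needs at least one micro state")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(map)) stop("one weight per micro state required")
    ws <- tapply(weights, map, sum)
    if (any(abs(ws - 1) > 1e-9))
      stop("within-class weights must sum to 1 in every macro class")
  }
  structure(list(map = map, weights = weights, n_micro = length(map),
                 n_macro = n_macro),
            class = "state_partition")
}

#' Coarse-grain a transition matrix over a state partition
#'
#' The macro transition probability is the within-class weighted average of
#' the micro rows, with columns summed over each target class:
#' `P_macro(a, b) = sum_{x in a} w(x|a) sum_{y in b} P(x, y)`.
#' By default the within-class weights are the micro stationary distribution
#' conditioned on each class; supplying `part$weights` (or uniform weights
#' via `weights = "uniform"`) overrides that.
#'
#' @param x a [tpm()].
#' @param part a [state_partition()] over the micro states of `x`.
#' @param weights `NULL` (use `part$weights`, else stationary-conditional),
#'   `"uniform"`, or a numeric per-micro-state weight vector.
#' @return A [tpm()] over the macro states.
#' @export
coarse_grain_tpm <- function(x, part, weights = NULL) {
  stopifnot(inherits(x, "tpm"), inherits(part, "state_partition"))
  if (part$n_micro != x$n_states)
    stop("partition and transition matrix cover different numbers of states")
  w <- weights
  if (is.null(w)) w <- part$weights
  if (is.null(w)) {
    pi0 <- as.numeric(stationary_distribution(x))
    w <- pi0
    cls_mass <- tapply(w, part$map, sum)
    zero <- which(cls_mass == 0)
    if (length(zero)) {
      ## classes with no stationary mass fall back to uniform conditioning
      for (a in as.integer(names(cls_mass))[zero]) {
        idx <- which(part$map == a)
        w[idx] <- 1 / length(idx)
      }
      cls_mass <- tapply(w, part$map, sum)
    }
    w <- as.numeric(w / cls_mass[as.character(part$map)])
  } else if (identical(w, "uniform")) {
    cnt <- table(part$map)
    w <- 1 / as.numeric(cnt[as.character(part$map)])
  } else {
    w <- as.numeric(w)
    ws <- tapply(w, part$map, sum)
    if (any(abs(ws - 1) > 1e-9)) stop("supplied weights must sum to 1 within each class")
  }
  ## columns first (plain sums), then weighted row aggregation
  colagg <- t(rowsum(t(x$probs), part$map))
  macro <- rowsum(colagg * w, part$map)
  node_count <- if (!is.null(x$node_count) &&
                    part$n_macro == 2^(x$node_count - 1L)) x$node_count - 1L else NULL
  tpm(unname(macro), node_count = node_count)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
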