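## Equivalence-class expansion: the inverse of coarse-graining. A node of a
## macroscale system is bifurcated into two children whose joint state
## refines the macro value; transition probability into each macro state is
## re-allocated across its micro refinements by fixed within-class weights.
## Because every micro row within a class equals its macro row (re-weighted
## on the columns only), the construction is exactly lumpable: projecting
## back recovers the macro system, the expansion has zero dynamical
## inconsistency, and the temporal mutual information is identical at both
## scales -- any change in the synergy bias is therefore pure information
## conversion, not information loss.

#' Random positive-Gaussian transition matrix
#'
#' Entries are absolute values of independent standard normal draws, rows
#' normalised to probability distributions. With probability 1 every entry
#' is positive, so the chain is ergodic with a full-support stationary
#' distribution. The 8x8 default describes a fully connected three-node
#' binary system.
#'
#' @param n_states number of joint states (default 8).
#' @param seed optional integer seed for reproducibility.
#' @return A [tpm()]; `node_count` is set when `n_states` is a power of 2.
#' @export
gaussian_tpm <- function(n_states = 8, seed = NULL) {
  if (n_states < 2) stop("need at least 2 states")
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(abs(stats::rnorm(n_states * n_states)), n_states, n_states)
  P <- P / rowSums(P)
  tpm(P, node_count = node_count_of(n_states))
}

#' Random near-deterministic transition matrix
#'
#' Each state transitions to the state given by a uniformly random
#' fixed-point-free successor map with probability `p_main`; the remaining
#' probability is spread evenly over the other states, which keeps the chain
#' ergodic with a full-support stationary distribution and no point
#' attractor. Drawing the successor as an arbitrary fixed-point-free map
#' (rather than a permutation) lets the ensemble span many deterministic
#' skeletons with genuinely different information structure.
#'
#' @param n_states number of joint states (>= 3; default 8).
#' @param p_main probability of the designated transition, in (0, 1).
#' @param seed optional integer seed.
#' @return A [tpm()].
#' @export
deterministic_tpm <- function(n_states = 8, p_main = 0.99, seed = NULL) {
  if (n_states < 3) stop("need at least 3 states")
  if (p_main <= 0 || p_main >= 1) stop("`p_main` must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  succ <- vapply(seq_len(n_states), function(s)
    sample(setdiff(seq_len(n_states), s), 1L), integer(1))
  P <- matrix((1 - p_main) / (n_states - 1), n_states, n_states)
  P[cbind(seq_len(n_states), succ)] <- p_main
  tpm(P, node_count = node_count_of(n_states))
}

node_count_of <- function(n_states) {
  nb <- round(log2(n_states))
  if (2^nb == n_states) as.integer(nb) else NULL
}

#' Specification of a node bifurcation
#'
#' Splitting node `node` replaces its bit by two child bits (the original
#' position and a new highest-index node). The `class_map` assigns each of
#' the four child-pair states (encoded `b_orig + 2 * b_new`: 0 = (0,0),
#' 1 = (1,0), 2 = (0,1), 3 = (1,1)) to a macro node value, and `weights`
#' give the within-class re-allocation of transition probability (summing
#' to 1 inside each class).
#'
#' Shipped maps:
#' \describe{
#'   \item{`"conjunctive"` (default)}{macro value 1 iff both children are 1
#'     (`A = alpha AND beta`); class 0 holds the three remaining pair states
#'     at uniform weight 1/3. A genuinely Boolean bifurcation: the macro
#'     value is realised jointly by the children.}
#'   \item{`"copy"`}{the first child carries the macro value and the new
#'     child is a free bit at uniform weight 1/2. The added bit is
#'     independent noise, so this expansion perturbs the decomposition in a
#'     system-independent way; useful as a degenerate baseline.}
#'   \item{`"exclusive"`}{macro value = XOR of the children, uniform
#'     weights; the children encode the macro value synergistically.}
#' }
#'
#' @param node node index to split (default 0).
#' @param kind one of `"conjunctive"`, `"copy"`, `"exclusive"`, or `NULL`
#'   when `class_map` is supplied directly.
#' @param class_map integer vector of length 4 mapping pair states to macro
#'   values 0/1 (both values must occur).
#' @param weights numeric vector of length 4; within each class the weights
#'   must sum to 1. Defaults to uniform within class.
#' @return An object of class `expansion_spec`.
#' @export
expansion_spec <- function(node = 0L,
                           kind = c("conjunctive", "copy", "exclusive"),
                           class_map = NULL, weights = NULL) {
  if (is.null(class_map)) {
    kind <- match.arg(kind)
    class_map <- switch(kind,
                        conjunctive = c(0L, 0L, 0L, 1L),
                        copy        = c(0L, 1L, 0L, 1L),
                        exclusive   = c(0L, 1L, 1L, 0L))
  } else {
    kind <- "custom"
    class_map <- as.integer(class_map)
    if (length(class_map) != 4L || !setequal(unique(class_map), 0:1))
      stop("`class_map` must assign the 4 child-pair states onto macro values {0, 1}")
  }
  if (is.null(weights)) {
    weights <- numeric(4)
    for (a in 0:1) {
      idx <- which(class_map == a)
      weights[idx] <- 1 / length(idx)
    }
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != 4L || any(weights < 0))
      stop("`weights` must be 4 non-negative numbers")
    for (a in 0:1)
      if (abs(sum(weights[class_map == a]) - 1) > 1e-12)
        stop(sprintf("weights in class %d must sum to 1", a))
  }
  structure(list(node = as.integer(node), kind = kind,
                 class_map = class_map, weights = weights),
            class = "expansion_spec")
}

#' Bifurcate one node of a transition matrix into an equivalence class
#'
#' Produces the micro transition matrix
#' `T_micro(x, y) = T_macro(g(x), g(y)) * w(y)` where `g` projects each
#' micro state to its macro class and `w(y)` is the within-class weight of
#' the micro future state. All micro rows within a class are identical, so
#' the expansion is exactly lumpable: [coarse_grain_tpm()] with the returned
#' partition recovers the macro matrix entrywise, the micro stationary
#' distribution is the macro one refined by the class weights, and the
#' temporal mutual information is identical at both scales.
#'
#' @param x a [tpm()] with node structure (`node_count` set).
#' @param spec an [expansion_spec()]; default splits node 0 conjunctively.
#' @return A list with components `tpm` (the micro [tpm()], one node more)
#'   and `partition` (a [state_partition()] mapping micro states to macro
#'   states, carrying the within-class weights).
#' @export
split_node <- function(x, spec = expansion_spec()) {
  stopifnot(inherits(x, "tpm"), inherits(spec, "expansion_spec"))
  if (is.null(x$node_count))
    stop("node-structured transition matrix required (node_count not set)")
  n <- x$node_count
  k <- spec$node
  if (k < 0L || k >= n) stop(sprintf("node %d out of range [0, %d)", k, n))
  ns <- x$n_states
  ms <- 2L * ns
  st <- 0:(ms - 1)
  b_orig <- as.integer(bitwAnd(st, bitwShiftL(1L, k)) > 0)
  b_new  <- bitwShiftR(st, n)                       # new child at bit n
  pair <- b_orig + 2L * b_new
  a <- spec$class_map[pair + 1L]
  ## macro state: replace bit k by the class value, drop the new bit
  low <- bitwAnd(st, ns - 1L)
  g <- bitwOr(bitwAnd(low, bitwNot(bitwShiftL(1L, k))), bitwShiftL(a, k))
  w <- spec$weights[pair + 1L]
  micro <- x$probs[g + 1L, g + 1L] * matrix(w, ms, ms, byrow = TRUE)
  list(tpm = tpm(micro, node_count = n + 1L),
       partition = state_partition(g, weights = w))
}

#' Repeatedly expand a system while preserving its mutual information
#'
#' Applies [split_node()] `n_splits` times, each time bifurcating the node
#' created from the original split target (node `spec$node`, then its first
#' child at the same position). Two splits of a three-node system yield the
#' four-node mesoscale and five-node microscale used in the ensemble
#' experiments.
#'
#' @param x a [tpm()] with node structure.
#' @param n_splits number of bifurcations (>= 1).
#' @param spec an [expansion_spec()] applied at every split.
#' @return A list of `n_splits` elements, each `list(tpm =, partition =)`
#'   as returned by [split_node()], ordered from first to last split.
#' @export
expand_chain <- function(x, n_splits = 2L, spec = expansion_spec()) {
  stopifnot(n_splits >= 1L)
  if (x$node_count + n_splits > 5L)
    stop("expansion would exceed the 5-source PID cap")
  out <- vector("list", n_splits)
  cur <- x
  for (s in seq_len(n_splits)) {
    step <- split_node(cur, spec)
    out[[s]] <- step
    cur <- step$tpm
  }
  out
}

#' Synergy bias of a system at its stationary drive
#'
#' Convenience wrapper: stationary distribution, joint past-future, PID
#' over all nodes, spectrum, synergy bias.
#'
#' @param x a node-structured [tpm()].
#' @return A list with `mi` (bits) and `synergy_bias`.
#' @export
stationary_synergy_bias <- function(x) {
  stopifnot(inherits(x, "tpm"))
  joint <- joint_past_future(x, stationary_distribution(x))
  pid <- pid_atoms(joint, sources = 0:(x$node_count - 1L))
  list(mi = pid$total_mi, synergy_bias = pi_spectrum(pid)$synergy_bias)
}

#' Ensemble experiment: synergy-bias change under expansion
#'
#' Generates `n_systems` random three-node macroscale systems (Gaussian or
#' near-deterministic), expands each by `n_splits` equivalence-class
#' bifurcations, computes the stationary-input synergy bias at every scale,
#' and summarises the change `delta = B_syn(macro) - B_syn(deepest scale)`
#' against the macroscale bias.
#'
#' @param kind `"gaussian"` or `"deterministic"`.
#' @param n_systems number of systems (the reference experiments use 200
#'   Gaussian and 185 deterministic systems).
#' @param n_splits expansions per system (default 2: macro -> meso -> micro).
#' @param seed master seed; per-system seeds are derived by counter.
#' @param spec an [expansion_spec()] used for every split.
#' @param n_states macro state count (default 8 = three binary nodes).
#' @param p_main designated-transition probability for the deterministic
#'   ensemble.
#' @return An object of class `scale_ensemble`: a list with `systems` (data
#'   frame: `system`, `seed`, `mi_bits`, one `bsyn_*` column per scale,
#'   `delta`), `summary` (list: `pearson_r`, `n_delta_positive`,
#'   `n_systems`, `n_excluded`, `kind`, `n_splits`).
#' @export
scale_experiment <- function(kind = c("gaussian", "deterministic"),
                             n_systems = 200L, n_splits = 2L, seed = 1L,
                             spec = expansion_spec(), n_states = 8L,
                             p_main = 0.99) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  scale_names <- if (n_splits == 2L) c("bsyn_macro", "bsyn_meso", "bsyn_micro")
                 else paste0("bsyn_scale", 0:n_splits)
  rows <- vector("list", n_systems)
  excluded <- 0L
  for (i in seq_len(n_systems)) {
    sys_seed <- (seed + i - 1L) %% .Machine$integer.max
    macro <- if (kind == "gaussian") gaussian_tpm(n_states, seed = sys_seed)
             else deterministic_tpm(n_states, p_main = p_main, seed = sys_seed)
    chain <- expand_chain(macro, n_splits = n_splits, spec = spec)
    scales <- c(list(macro), lapply(chain, `[[`, "tpm"))
    res <- lapply(scales, stationary_synergy_bias)
    mis <- vapply(res, `[[`, numeric(1), "mi")
    if (mis[1] <= 1e-12) {
      message(sprintf("system %d (seed %d): zero mutual information, excluded", i, sys_seed))
      excluded <- excluded + 1L
      next
    }
    biases <- vapply(res, `[[`, numeric(1), "synergy_bias")
    row <- data.frame(system = i, seed = sys_seed, mi_bits = mis[1])
    for (s in seq_along(biases)) row[[scale_names[s]]] <- biases[s]
    row$delta <- biases[1] - biases[length(biases)]
    row$mi_spread <- max(mis) - min(mis)      # MI must be scale-invariant
    rows[[i]] <- row
  }
  systems <- do.call(rbind, rows)
  summary <- list(
    pearson_r = pearson_r(systems[[scale_names[1]]], systems$delta),
    n_delta_positive = sum(systems$delta > 0),
    n_systems = nrow(systems),
    n_excluded = excluded,
    kind = kind,
    n_splits = n_splits)
  structure(list(systems = systems, summary = summary), class = "scale_ensemble")
}

#' @export
print.scale_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scale ensemble (%s, %d systems, %d splits)\n",
              s$kind, s$n_systems, s$n_splits))
  cat(sprintf("  delta = B_syn(macro) - B_syn(deepest):  %d/%d positive\n",
              s$n_delta_positive, s$n_systems))
  cat(sprintf("  Pearson r(macro bias, delta) = %.3f\n", s$pearson_r))
  if (s$n_excluded) cat(sprintf("  %d degenerate system(s) excluded\n", s$n_excluded))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param xs,ys numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("`xs` and `ys` must have equal length")
  if (length(xs) < 3L) stop("need at least 3 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(xs, ys)
}
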