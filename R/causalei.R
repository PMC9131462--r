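## Effective information: the mutual information between interventions and
## effects when the intervention distribution is maximum entropy over all
## states. EI splits exactly into a determinism term (how predictable the
## next state is) minus a degeneracy term (how much retrodictive information
## is lost because transitions run together).

#' Effective information of a transition matrix
#'
#' `EI = I(X;Y)` computed with `P(X)` uniform over all states (a maximum-
#' entropy intervention, applied over a single timestep). A deterministic
#' permutation attains `log2(n)`; identical rows give 0.
#'
#' @param x a [tpm()].
#' @return Bits.
#' @export
effective_information <- function(x) {
  stopifnot(inherits(x, "tpm"))
  u <- state_distribution(rep(1 / x$n_states, x$n_states))
  temporal_mutual_information(joint_past_future(x, u))
}

#' Determinism term of the effective information
#'
#' `log2(n)` minus the mean row entropy: the information gained about the
#' future relative to a maximally entropic reference system. Zero when all
#' rows are uniform, `log2(n)` when every transition is certain.
#'
#' @param x a [tpm()].
#' @return Bits, in `[0, log2(n)]`.
#' @export
determinism_term <- function(x) {
  stopifnot(inherits(x, "tpm"))
  log2(x$n_states) - mean(apply(x$probs, 1, shannon_entropy))
}

#' Degeneracy term of the effective information
#'
#' `log2(n)` minus the entropy of the average transition profile
#' `<p(y)>` under uniform inputs: how concentrated the system's futures are
#' regardless of where it starts, i.e. the retrodictive information lost
#' when causal paths run together. Zero for a permutation, `log2(n)` when
#' all states map to one state.
#'
#' @param x a [tpm()].
#' @return Bits, in `[0, log2(n)]`.
#' @export
degeneracy_term <- function(x) {
  stopifnot(inherits(x, "tpm"))
  log2(x$n_states) - shannon_entropy(colMeans(x$probs))
}

#' Effective information decomposed into determinism and degeneracy
#'
#' @param x a [tpm()].
#' @return An object of class `ei_decomposition` with fields `ei`,
#'   `determinism`, `degeneracy`, `n_states`; `ei = determinism -
#'   degeneracy` holds to numerical precision.
#' @export
ei_decompose <- function(x) {
  structure(list(ei = effective_information(x),
                 determinism = determinism_term(x),
                 degeneracy = degeneracy_term(x),
                 n_states = x$n_states),
            class = "ei_decomposition")
}

#' @export
print.ei_decomposition <- function(x, ...) {
  cat(sprintf("EI over %d states: %.4f bits = determinism %.4f - degeneracy %.4f\n",
              x$n_states, x$ei, x$determinism, x$degeneracy))
  invisible(x)
}

#' Effective information at two scales
#'
#' Decomposes the effective information of a micro system and of its
#' coarse-graining under a state partition. Because EI intervenes with a
#' maximum-entropy distribution, the macro transition matrix conditions
#' uniformly within each class (there is no stationary distribution to
#' condition on under intervention). Coarse-graining can raise EI when the
#' macro transitions are more deterministic or less degenerate - causal
#' emergence - but never when the micro system is already fully
#' deterministic and non-degenerate.
#'
#' @param x a micro [tpm()].
#' @param part a [state_partition()] of its states.
#' @return A list with components `micro` and `macro`, each an
#'   [ei_decompose()] result.
#' @export
ei_across_scales <- function(x, part) {
  macro <- coarse_grain_tpm(x, part, weights = "uniform")
  list(micro = ei_decompose(x), macro = ei_decompose(macro))
}
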