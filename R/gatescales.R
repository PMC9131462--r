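## Logic-gate circuits at two scales. A macroscale gate (AND, OR, XOR) is a
## three-element system: two exogenous inputs A, B and the gate itself. Its
## microscale is a feedforward circuit of simpler gates computing the same
## function. Inputs are open (exogenous): they are redrawn i.i.d. from the
## maximum-entropy distribution at every timestep, while gates update
## synchronously from the previous joint state. The comparison between
## scales therefore uses the same maximum-entropy input distribution at
## both, and the gates' own state distribution is the stationary one induced
## by that drive.

GATE_FUNCTIONS <- c("AND", "OR", "XOR", "NAND")

#' Define a feedforward gate circuit
#'
#' @param inputs character vector of exogenous input element names.
#' @param gates list of gates; each gate is `list(fn =, args =)` with `fn`
#'   one of `"AND"`, `"OR"`, `"XOR"`, `"NAND"` and `args` a length-2 vector
#'   of element ids (0-based: inputs first, then gates in order). Wiring
#'   must be acyclic; gates may read inputs or earlier gates. Reading a
#'   later gate is rejected.
#' @param labels optional element names for the gates.
#' @return An object of class `gate_circuit`.
#' @examples
#' make_micro_circuit("XOR")
#' @export
gate_circuit <- function(inputs, gates, labels = NULL) {
  n_in <- length(inputs)
  for (g in seq_along(gates)) {
    gt <- gates[[g]]
    if (!gt$fn %in% GATE_FUNCTIONS)
      stop(sprintf("gate %d: unknown function '%s'", g, gt$fn))
    if (length(gt$args) != 2L)
      stop(sprintf("gate %d: gates take exactly two operands", g))
    if (any(gt$args < 0L) || any(gt$args >= n_in + g - 1L))
      stop(sprintf("gate %d: operand ids must refer to inputs or earlier gates", g))
  }
  structure(list(inputs = inputs,
                 gates = gates,
                 n_elements = n_in + length(gates),
                 labels = c(inputs, labels %||% vapply(seq_along(gates), function(g)
                   sprintf("%s%d", tolower(gates[[g]]$fn), g), character(1)))),
            class = "gate_circuit")
}

#' @export
print.gate_circuit <- function(x, ...) {
  cat(sprintf("Gate circuit: %d elements (%d inputs, %d gates)\n",
              x$n_elements, length(x$inputs), length(x$gates)))
  for (g in seq_along(x$gates)) {
    gt <- x$gates[[g]]
    cat(sprintf("  %s = %s(%s, %s)\n", x$labels[length(x$inputs) + g], gt$fn,
                x$labels[gt$args[1] + 1L], x$labels[gt$args[2] + 1L]))
  }
  invisible(x)
}

apply_gate <- function(fn, a, b) {
  switch(fn,
         AND  = a & b,
         OR   = a | b,
         XOR  = xor(a, b),
         NAND = !(a & b))
}

#' Macroscale logic gate
#'
#' The three-element macroscale of a binary gate: exogenous inputs A, B and
#' one gate element applying the named function to the previous inputs.
#'
#' @param kind `"AND"`, `"OR"` or `"XOR"`.
#' @return A [gate_circuit()] with 3 elements.
#' @export
make_macro_gate <- function(kind = c("AND", "OR", "XOR")) {
  kind <- match.arg(kind)
  gate_circuit(c("A", "B"),
               list(list(fn = kind, args = c(0L, 1L))),
               labels = kind)
}

#' Microscale circuit implementing a logic gate
#'
#' NAND-based microscale realisations of the three macroscale gates:
#' \describe{
#'   \item{AND}{`g1 = NAND(A,B)`, `g2 = NAND(g1,g1)` - 4 elements.}
#'   \item{OR}{`g1 = NAND(A,A)`, `g2 = NAND(B,B)`, `g3 = NAND(g1,g2)` -
#'     5 elements.}
#'   \item{XOR}{`g1 = OR(A,B)`, `g2 = NAND(A,B)`, `g3 = AND(g1,g2)` -
#'     5 elements; the classic OR/NAND/AND realisation (none of the parts
#'     is itself an XOR).}
#' }
#' Each circuit settles to the macroscale truth table after `depth` steps on
#' held inputs.
#'
#' @inheritParams make_macro_gate
#' @return A [gate_circuit()].
#' @export
make_micro_circuit <- function(kind = c("AND", "OR", "XOR")) {
  kind <- match.arg(kind)
  switch(kind,
    AND = gate_circuit(c("A", "B"),
                       list(list(fn = "NAND", args = c(0L, 1L)),
                            list(fn = "NAND", args = c(2L, 2L)))),
    OR  = gate_circuit(c("A", "B"),
                       list(list(fn = "NAND", args = c(0L, 0L)),
                            list(fn = "NAND", args = c(1L, 1L)),
                            list(fn = "NAND", args = c(2L, 3L)))),
    XOR = gate_circuit(c("A", "B"),
                       list(list(fn = "OR",   args = c(0L, 1L)),
                            list(fn = "NAND", args = c(0L, 1L)),
                            list(fn = "AND",  args = c(2L, 3L)))))
}

#' Boolean network of an input-driven circuit
#'
#' Converts a circuit to a [boolean_network()] in which input elements are
#' parentless coin-flip nodes (probability 1/2, the maximum-entropy drive)
#' and gate elements apply their function to the previous joint state.
#' Element `k` of the circuit becomes node `k` (bit `k`).
#'
#' @param circ a [gate_circuit()].
#' @return A [boolean_network()].
#' @export
circuit_network <- function(circ) {
  stopifnot(inherits(circ, "gate_circuit"))
  n_in <- length(circ$inputs)
  parents <- c(rep(list(integer(0)), n_in),
               lapply(circ$gates, function(g) as.integer(g$args)))
  tables <- c(rep(list(0.5), n_in),
              lapply(circ$gates, function(g)
                vapply(0:3, function(s)
                  as.numeric(apply_gate(g$fn, bitwAnd(s, 1L) > 0, bitwAnd(s, 2L) > 0)),
                  numeric(1))))
  boolean_network(parents, tables, labels = circ$labels)
}

#' Stationary distribution of an input-driven circuit
#'
#' The joint distribution over (inputs, gates) reached when inputs are
#' redrawn i.i.d. uniform at every timestep and gates update synchronously.
#' Because the circuit is feedforward this is exact: it is the stationary
#' distribution of the driven Markov chain, which settles after depth-many
#' steps.
#'
#' @param circ a [gate_circuit()].
#' @return A [state_distribution()] over the `2^n_elements` joint states.
#' @export
driven_stationary <- function(circ) {
  stationary_distribution(build_tpm(circuit_network(circ)))
}

#' Joint past-future distribution of an input-driven circuit
#'
#' Past = the joint (inputs, gates) state at driven stationarity; future =
#' the state after one synchronous step in which each gate applies its
#' function to the past operands and inputs are redrawn uniformly.
#'
#' @param circ a [gate_circuit()].
#' @return A [joint_past_future()].
#' @export
circuit_joint <- function(circ) {
  tm <- build_tpm(circuit_network(circ))
  joint_past_future(tm, driven_stationary(circ))
}

#' Temporal mutual information of a circuit
#'
#' @param circ a [gate_circuit()].
#' @return Bits.
#' @export
circuit_mi <- function(circ) {
  temporal_mutual_information(circuit_joint(circ))
}

#' PID and PI spectrum of a circuit
#'
#' Sources are the past states of all elements (inputs and gates
#' individually); the target is the joint future of all elements. Because
#' future inputs are redrawn independently of everything, they contribute
#' no information and the atoms reflect the gates' future alone.
#'
#' @param circ a [gate_circuit()] with at most 5 elements.
#' @return A list with components `pid` ([pid_atoms()] result) and
#'   `spectrum` ([pi_spectrum()]).
#' @export
circuit_pid <- function(circ) {
  if (circ$n_elements > 5L)
    stop("PID supports at most 5 sources; this circuit has more elements")
  pid <- pid_atoms(circuit_joint(circ), sources = 0:(circ$n_elements - 1L))
  list(pid = pid, spectrum = pi_spectrum(pid))
}

#' Micro/macro information comparison for the three basic gates
#'
#' For each of AND, OR and XOR, computes the temporal mutual information and
#' synergy bias of the macroscale gate and of its microscale circuit, under
#' the same maximum-entropy input drive.
#'
#' @return A data frame with columns `gate`, `micro_mi`, `macro_mi`,
#'   `micro_syn_bias`, `macro_syn_bias` (MI in bits, biases dimensionless).
#' @export
gate_scale_table <- function() {
  kinds <- c("AND", "OR", "XOR")
  rows <- lapply(kinds, function(k) {
    micro <- make_micro_circuit(k)
    macro <- make_macro_gate(k)
    data.frame(gate = k,
               micro_mi = circuit_mi(micro),
               macro_mi = circuit_mi(macro),
               micro_syn_bias = circuit_pid(micro)$spectrum$synergy_bias,
               macro_syn_bias = circuit_pid(macro)$spectrum$synergy_bias)
  })
  do.call(rbind, rows)
}
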