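---
title: "Measuring information conversion across scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information conversion across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidscales)
```

## The model and its assumptions

`pidscales` analyses synchronous discrete dynamical systems. The canonical
input is a Boolean network: binary nodes, each updated at every timestep by
a (possibly stochastic) lookup table over its parents' previous joint
state. Under synchronous update the nodes are conditionally independent
given the previous joint state, so the system is fully described by a
row-stochastic transition probability matrix (TPM) over the $2^n$ joint
states; arbitrary TPMs that do not factorise over nodes are accepted
everywhere as well. Joint states are indexed with node $i$ at bit position
$i$, node 0 least significant — every file format and function in the
package uses this one convention.

The central quantity is the temporal mutual information
$I(X;Y)$ between the joint past $X$ and the joint future $Y$ one step
later, computed from the joint distribution $P(x,y) = P(x)\,P(y\mid x)$.
The input distribution $P(x)$ is the system's stationary distribution
unless stated otherwise: it is the only distribution that does not bias the
measurement towards any transient. Two limits anchor the scale: a point
attractor transmits 0 bits, and a deterministic permutation visited
uniformly transmits $\log_2 n$ bits.

Stationary distributions are found structurally rather than by blind
iteration: the recurrent classes of the chain are the terminal strongly
connected components of the positive-support digraph (via `igraph`), the
balance equations are solved by least squares restricted to the chosen
class, and power iteration (tolerance $10^{-12}$, capped at $10^6$ steps)
is kept as a fallback. When several recurrent classes exist the largest is
used, ties broken towards the class containing the lowest state index —
the tie-break is a package convention chosen purely so that results are
deterministic.

## The decomposition

With more than two elements, $I(X;Y)$ says nothing about *where*
information lives. Partial information decomposition assigns it to atoms
indexed by antichains of source collections. The package enumerates the
full antichain lattice (4, 18, 166 and 7579 atoms for 2–5 sources; the
growth is Dedekind-like, which is why 5 sources is a hard cap), computes
the Williams–Beer redundancy
$I_{WB}(\alpha;Y) = \sum_y P(y) \min_{A \in \alpha} I(A; Y{=}y)$
for every atom, and recovers atom values by Möbius inversion in ascending
height order. $I_{WB}$ was chosen as the shipped redundancy measure because
it is non-negative by construction, defined for any number of sources, and
cheap: it depends only on the $2^n - 1$ collection-level specific
informations, which are computed once and shared across all atoms. The
redundancy measure is a plug-in (`pid_atoms(..., redundancy = fn)`), but
no alternative is shipped.

Implementation notes that matter for correctness:

* Order tests use the up-closure bitmask $D(\alpha)$ of each antichain in
  the collection poset: $\alpha \preceq \beta \iff D(\beta) \subseteq
  D(\alpha)$, a single `bitwAnd`. One genuine R pitfall is documented in
  the source: the all-ones 31-bit mask equals `.Machine$integer.max`, whose
  bitwise complement is `NA_integer_`, so subset tests are written without
  `bitwNot`.
* The lattice turns out to be *graded*: the longest-chain height from the
  bottom always equals $|D(\text{bottom})| - |D(\alpha)|$, so heights
  measured from the bottom and from the top coincide. The test suite
  asserts this for all supported source counts, which removes any
  ambiguity about how layers are assigned.
* Atom values in $[-10^{-12}, 0)$ are clipped to zero. $I_{WB}$ guarantees
  non-negative atoms mathematically; the clip absorbs floating-point noise
  without masking real violations (anything below $-10^{-12}$ still
  surfaces).
* Lattices, heights and down-sets are cached per source count. A 5-source
  decomposition costs about a second; the 200-system ensemble below reuses
  one cached lattice throughout.

The PI spectrum divides the atom mass at each lattice height by the total
MI, and the synergy bias is its centre of mass normalised by the **top
height** (not by the number of layers): $B_{syn} = \sum_i (i/h_{top})
S_i$. With this normalisation the three-element system whose whole bit
sits in the two-input atom `{01}` (height 5 of 6) has $B_{syn} = 5/6$,
and the all-bottom and all-top limits are exactly 0 and 1. Normalising by
the layer count instead would compress the range to $[0, h_{top}/(h_{top}+1)]$
and make biases of different-sized lattices incomparable, which defeats
the purpose of the measure. The spectrum (and both biases) are undefined
at zero MI and the package refuses to fabricate a value there.

## Logic-gate circuits

`make_macro_gate()` and `make_micro_circuit()` ship one fixed scale pair
per gate kind: the three-element macroscale (inputs A, B, one gate) and
feedforward microscales built from NAND-level parts (2 NANDs for AND;
3 NANDs for OR; OR + NAND + AND for XOR — note none of the XOR microscale
parts is itself an XOR). These open circuits have no closed stationary
dynamics, so the driving convention matters and is fixed package-wide:
**inputs are redrawn i.i.d. maximum-entropy at every timestep**, gates
update synchronously from the previous joint state, and the past
distribution is the exact stationary distribution of that driven chain
(computed by propagating the input distribution, not sampled). Under this
convention the circuit MIs have closed forms — e.g. the AND microscale
gives $2\,H(1/4) \approx 1.623$ bits and the OR microscale
$2 + H(1/4) \approx 2.811$ — which the tests check against the pipeline.
Alternative conventions (holding inputs, copying them into the future, or
initialising gates at maximum entropy) each break at least one of those
closed forms, which is how the convention was pinned down.

Because future inputs are redrawn independently of everything, they carry
no decomposition mass; the test suite verifies that marginalising them out
of the target leaves every atom unchanged.

## Equivalence-class expansion

Coarse-graining can only destroy information, so any bias shift it causes
could be dismissed as selective loss. The expansion experiment removes
that objection by running the comparison in the direction that preserves
MI exactly. A node is bifurcated into two children; each macro state gains
micro refinements, and the micro TPM is
$T(\tilde x, \tilde y) = T_{macro}(g\tilde x, g\tilde y)\, w(\tilde y)$
with $g$ the projection and $w$ fixed within-class weights. Because rows
within a class are identical and the column reallocation depends only on
the future class, the construction is exactly lumpable: projecting back
recovers the macro TPM entrywise, the micro stationary distribution is the
macro one refined by $w$, and the temporal MI is bit-for-bit identical at
both scales (the ensemble tests require agreement within $10^{-9}$ and
observe $\sim 10^{-15}$).

The default class map is **conjunctive**: macro value 1 corresponds to the
single child pair $(1,1)$, macro value 0 to the remaining three pairs at
uniform weight $1/3$. This was a genuinely open design point and the
reasoning is worth recording. The obvious alternative — the first child
copies the macro value and the second is a free uniform bit (`kind =
"copy"`) — makes the added node independent noise. Under it, the micro
bias is an exact affine function of the macro bias, identically across
systems, so ensemble statistics relating the two become degenerate
(correlations of exactly 1). The conjunctive map instead realises the
macro value *jointly* in the children, the way a Boolean mechanism would,
and perturbs each system's decomposition in a system-dependent way while
still satisfying every lumpability property above. An `"exclusive"` map
(macro value = XOR of the children) and fully custom maps/weights are
available; the invariants tested are properties of the construction, not
of any particular map.

`scale_experiment()` runs the full study: random 3-node macroscales,
two expansions each (16- then 32-state systems — "meso" and "micro"),
stationary-input PID at every scale, and the summary statistics
$\Delta = B_{syn}(\text{macro}) - B_{syn}(\text{micro})$, the count of
systems with $\Delta > 0$, and the Pearson correlation of $\Delta$ against
the macro bias. Two generators are shipped:

* **Gaussian** — $|N(0,1)|$ entries, rows normalised. Ergodic with full
  support almost surely; these systems are strongly stochastic and sit at
  high synergy bias (ensemble mean $\approx 0.70$). At the shipped
  defaults all 200 systems show $\Delta > 0$ and the correlation lands
  near 0.8 (the acceptance band used in the tests is 0.70–0.92 across
  seeds).
* **Near-deterministic** — each state follows a uniformly random
  fixed-point-free successor map with probability 0.99, the remainder
  spread evenly (keeping the chain ergodic, full-support and free of point
  attractors). The successor is deliberately an arbitrary fixed-point-free
  *map*, not a permutation: all single-cycle permutation systems are the
  same channel up to state relabelling and give essentially identical
  biases, collapsing the ensemble's variance to zero; random maps span
  many deterministic skeletons and produce the intended spread of low
  synergy biases (ensemble mean $\approx 0.38$, mostly losing synergy at
  the macroscale below bias 0.5, with the same positive
  bias-versus-$\Delta$ relationship).

Seeding is by counter: system $i$ uses `seed + i - 1`, so ensembles are
reproducible and individual systems can be regenerated in isolation.
Degenerate zero-MI draws would be excluded with a message; neither
generator can actually produce one.

## Effective information

`ei_decompose()` computes $EI = I(X;Y)$ under a uniform (maximum-entropy
intervention) input over one timestep, together with the exact split
$EI = \text{determinism} - \text{degeneracy}$, where determinism is
$\log_2 N$ minus the mean row entropy and degeneracy is $\log_2 N$ minus
the entropy of the column-averaged transition profile. The identity is
algebraic and the tests hold it to $10^{-10}$ over a thousand random
matrices. For EI across scales the macro TPM conditions uniformly within
classes — under intervention there is no stationary distribution to
condition on, and uniform is the maximum-entropy choice consistent with
EI's definition. Deterministic non-degenerate systems can only lose EI
under coarse-graining; grouping noisy interchangeable states can raise it.

## Sizes, tolerances and limitations

Problem sizes used throughout the shipped experiments: 3–5 node systems
(8–32 states), 200 Gaussian and 185 near-deterministic ensemble members,
lattices up to 7579 atoms. A full 200-system ensemble takes on the order
of a minute on one CPU. Validation tolerances: row-stochasticity and
distribution normalisation $10^{-12}$ (file readers renormalise silently
drifted rows up to $10^{-6}$ with a warning and reject worse); atom
accounting $10^{-9}$; cross-checks against a naive from-definition
decomposition $10^{-8}$.

What the generators emulate — and what they do not. The random ensembles
probe fully connected, homogeneous, stationary binary systems. Real
regulatory or neural systems are sparse, heterogeneous, often
non-stationary, and frequently larger than five elements, where this
package cannot go: the redundancy lattice explodes combinatorially, and
$I_{WB}$ itself is only one member of a contested family of redundancy
measures. Passing tests therefore certify the machinery and the
behaviour of these model classes, not universality of the phenomenon in
empirical data. Pointwise/local decompositions, alternative redundancy
measures, asynchronous or multi-valued dynamics, and automated search for
bias- or EI-optimal coarse-grainings are out of scope.
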