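## Independent, from-definition reference implementation of the
## Williams-Beer decomposition, kept deliberately naive (plain lists and
## loops, no bitmask up-closures, no cached lattices) so it shares no code
## path with the package.

## all non-empty subsets of 0:(n-1) as sorted integer vectors
oracle_collections <- function(n) {
  out <- list()
  for (size in 1:n)
    out <- c(out, utils::combn(0:(n - 1), size, simplify = FALSE))
  out
}

oracle_is_subset <- function(a, b) all(a %in% b)

## brute force: filter all subsets of the collection list for pairwise
## incomparability (feasible up to n = 4: 2^15 candidate subsets)
oracle_antichains <- function(n) {
  colls <- oracle_collections(n)
  k <- length(colls)
  out <- list()
  for (code in 1:(2^k - 1)) {
    idx <- which(bitwAnd(code, 2^(0:(k - 1))) > 0)
    sel <- colls[idx]
    ok <- TRUE
    if (length(sel) > 1) {
      for (i in seq_along(sel)) {
        for (j in seq_along(sel)) {
          if (i != j && oracle_is_subset(sel[[i]], sel[[j]])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) out[[length(out) + 1]] <- sel
  }
  out
}

## antichain count by a different route: recursion over the collection
## poset. A(S) counts antichains (including the empty one) within S:
## pick x in S; antichains avoiding x, plus antichains containing x
## (which must avoid everything comparable to x).
oracle_antichain_count <- function(n) {
  colls <- oracle_collections(n)
  k <- length(colls)
  comparable <- matrix(FALSE, k, k)
  for (i in 1:k) for (j in 1:k)
    comparable[i, j] <- i != j &&
      (oracle_is_subset(colls[[i]], colls[[j]]) ||
       oracle_is_subset(colls[[j]], colls[[i]]))
  count <- function(S) {
    if (!length(S)) return(1)
    x <- S[1]
    rest <- S[-1]
    count(rest) + count(rest[!comparable[x, rest]])
  }
  count(1:k) - 1   # drop the empty antichain
}

## lattice order from the definition
oracle_leq <- function(a, b) {
  for (B in b) {
    hit <- FALSE
    for (A in a) if (oracle_is_subset(A, B)) { hit <- TRUE; break }
    if (!hit) return(FALSE)
  }
  TRUE
}

oracle_label <- function(atom) {
  key <- vapply(atom, function(s) sprintf("%02d%s", length(s), paste(s, collapse = "")),
                character(1))
  paste0(vapply(atom[order(key)],
                function(s) paste0("{", paste(s, collapse = ""), "}"),
                character(1)), collapse = "")
}

## specific information I(coll; Y = y) by explicit summation over the
## collection's joint states; J is the full P(x, y) matrix over joint past
## states of n_nodes binary nodes
oracle_specific_info <- function(J, n_nodes, coll, y) {
  nx <- nrow(J)
  py <- sum(J[, y + 1])
  ## marginal key of each past state restricted to the collection's nodes
  keys <- vapply(0:(nx - 1), function(x) {
    paste(vapply(coll, function(nd) (x %/% 2^nd) %% 2, numeric(1)), collapse = "")
  }, character(1))
  total <- 0
  for (kk in unique(keys)) {
    rows <- which(keys == kk)
    pxy <- sum(J[rows, y + 1])
    px <- sum(J[rows, ])
    if (pxy > 0)
      total <- total + (pxy / py) * log2(pxy / (px * py))
  }
  total
}

oracle_redundancy <- function(J, n_nodes, atom) {
  py <- colSums(J)
  total <- 0
  for (y in which(py > 0) - 1) {
    si <- vapply(atom, function(coll) oracle_specific_info(J, n_nodes, coll, y),
                 numeric(1))
    total <- total + py[y + 1] * min(si)
  }
  total
}

## full decomposition: memoised top-down recursion of the Moebius relation
oracle_pid <- function(J, n_nodes) {
  atoms <- oracle_antichains(n_nodes)
  labels <- vapply(atoms, oracle_label, character(1))
  memo <- new.env(parent = emptyenv())
  value <- function(i) {
    key <- labels[i]
    if (!is.null(memo[[key]])) return(memo[[key]])
    below <- setdiff(which(vapply(atoms, function(b)
      oracle_leq(b, atoms[[i]]), logical(1))), i)
    v <- oracle_redundancy(J, n_nodes, atoms[[i]]) -
      sum(vapply(below, value, numeric(1)))
    memo[[key]] <- v
    v
  }
  stats::setNames(vapply(seq_along(atoms), value, numeric(1)), labels)
}

## random joint past-future distribution over n binary nodes
random_joint <- function(n_nodes, n_future = NULL) {
  nx <- 2^n_nodes
  ny <- n_future %||% nx
  J <- matrix(stats::runif(nx * ny), nx, ny)
  J / sum(J)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shannon_entropy_vec <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

## shared heavyweight fixtures, built once per test run
gate_table_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- gate_scale_table()
    val
  }
})

scratch_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "pidscales-tests")
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    }
    dir
  }
})
scratch_file <- function(name) file.path(scratch_dir(), name)
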