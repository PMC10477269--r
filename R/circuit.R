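#' Quantum gate and circuit containers
#'
#' A `gate` is a named operation on explicit qubit indices (0-based, controls
#' first, target last) with an optional classical control pattern: entry j of
#' `control_pattern` is the value (0 or 1) the j-th control qubit must hold for
#' the gate to fire. A `circuit` is an ordered gate list over named registers
#' plus one classical bit for the terminal strip measurement.
#'
#' @param name one of `H`, `X`, `T`, `Tdg`, `RY`, `U`, `CX`, `CRY`, `MCRY`,
#'   `MCX`, `MEASURE`.
#' @param qubits integer vector of 0-based qubit indices, controls first,
#'   target last.
#' @param params numeric parameter vector (`RY`/`CRY`/`MCRY`: one angle;
#'   `U`: theta, phi, lambda).
#' @param control_pattern integer 0/1 vector, one entry per control qubit;
#'   defaults to all-1 controls.
#' @return `gate()` returns an object of class `gate`.
#' @export
gate <- function(name, qubits, params = numeric(0), control_pattern = NULL) {
  qubits <- as.integer(qubits)
  n_ctrl <- switch(name,
    H = , X = , T = , Tdg = , RY = , U = , MEASURE = 0L,
    CX = , CRY = 1L,
    MCRY = , MCX = length(qubits) - 1L,
    stop("unknown gate name: ", name))
  n_par <- switch(name,
    RY = , CRY = , MCRY = 1L,
    U = 3L,
    0L)
  if (length(qubits) != n_ctrl + 1L)
    stop(name, " takes exactly ", n_ctrl + 1L, " qubit(s)")
  if (name %in% c("MCRY", "MCX") && n_ctrl < 1L)
    stop(name, " requires at least one control")
  if (anyDuplicated(qubits))
    stop("gate qubits must be distinct")
  if (length(params) != n_par)
    stop(name, " takes exactly ", n_par, " parameter(s)")
  if (is.null(control_pattern)) control_pattern <- rep(1L, n_ctrl)
  control_pattern <- as.integer(control_pattern)
  if (length(control_pattern) != n_ctrl ||
      any(!control_pattern %in% c(0L, 1L)))
    stop("'control_pattern' must be a 0/1 vector with one entry per control")
  structure(list(name = name, params = as.numeric(params), qubits = qubits,
                 control_pattern = control_pattern),
            class = "gate")
}

#' @param n_qubits total number of qubits.
#' @param gates list of [gate()] objects.
#' @param registers named list of 0-based qubit index vectors (e.g. `strip`,
#'   `index`, `value`).
#' @param n_clbits number of classical bits.
#' @rdname gate
#' @return `circuit()` returns an object of class `circuit`.
#' @export
circuit <- function(n_qubits, gates = list(), registers = list(),
                    n_clbits = 0L) {
  n_qubits <- as.integer(n_qubits)
  for (g in gates) {
    if (!inherits(g, "gate")) stop("all elements of 'gates' must be gate objects")
    if (any(g$qubits < 0L | g$qubits >= n_qubits))
      stop("gate qubit index out of range for ", n_qubits, "-qubit circuit")
  }
  structure(list(n_qubits = n_qubits, registers = registers,
                 gates = gates, n_clbits = as.integer(n_clbits)),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("Quantum circuit: %d qubits, %d classical bit(s), %d gates\n",
              x$n_qubits, x$n_clbits, length(x$gates)))
  if (length(x$registers))
    cat("  registers:",
        paste(sprintf("%s=[%s]", names(x$registers),
                      vapply(x$registers, function(q)
                        paste(q, collapse = ","), "")),
              collapse = " "), "\n")
  cnt <- gate_counts(x)$by_name
  cat("  gates:", paste(sprintf("%s:%d", names(cnt), cnt), collapse = " "),
      "\n")
  cat("  depth:", circuit_depth(x), "\n")
  invisible(x)
}

#' Build the strip-qubit FRQI comparison circuit
#'
#' Constructs the parallel-comparison circuit for two encoded sequences:
#' Hadamards put the strip qubit and the k index qubits into uniform
#' superposition; for each position i and each strip value s (0 selects the
#' reference branch, 1 the compared branch) one multi-controlled RY writes the
#' position's state angle onto the value qubit; a final Hadamard on the strip
#' interferes the two branches, and the strip qubit is measured. The strip
#' qubit's probability of reading 1 is then
#' `P1 = (1 - mean(cos(alpha - beta))) / 2` over the FRQI half-angles of the
#' two sequences.
#'
#' Register layout is `[strip, index_(k-1) .. index_0, value]` with the
#' position index big-endian on the index register; qubit q occupies bit q of
#' the little-endian statevector basis index.
#'
#' @param ref,cmp [encode_sequence()] results with equal `n_index_qubits`
#'   (pad to match before calling).
#' @param drop_zero_angles if `TRUE`, omit MCRY gates with zero rotation
#'   (padding/G positions); the default keeps them, mirroring the uniform
#'   construction.
#' @return A [circuit()] on `2 + k` qubits and 1 classical bit whose final
#'   gate is the strip measurement.
#' @examples
#' ref <- encode_sequence("AAAA")
#' cmp <- encode_sequence("TTTT")
#' qc <- build_comparison_circuit(ref, cmp)
#' circuit_depth(qc)
#' @export
build_comparison_circuit <- function(ref, cmp, drop_zero_angles = FALSE) {
  stopifnot(inherits(ref, "encoded_seq"), inherits(cmp, "encoded_seq"))
  if (ref$n_index_qubits != cmp$n_index_qubits)
    stop("index register size mismatch: ", ref$n_index_qubits, " vs ",
         cmp$n_index_qubits, " qubits; pad the sequences to match")
  k <- ref$n_index_qubits
  strip <- 0L
  index <- if (k > 0L) seq_len(k) else integer(0)  # index[1] = MSB
  value <- k + 1L
  gates <- list()
  add <- function(g) gates[[length(gates) + 1L]] <<- g
  add(gate("H", strip))
  for (q in index) add(gate("H", q))
  n_pos <- 2L^k
  for (i in seq_len(n_pos) - 1L) {
    # bits of position i, big-endian across index[1..k]
    ibits <- if (k > 0L) as.integer(intToBits(i))[k:1] else integer(0)
    for (s in 0:1) {
      theta <- if (s == 0L) ref$state_angles[i + 1L] else
        cmp$state_angles[i + 1L]
      if (drop_zero_angles && abs(theta) < 1e-15) next
      add(gate("MCRY", c(strip, index, value), params = theta,
               control_pattern = c(s, ibits)))
    }
  }
  add(gate("H", strip))
  add(gate("MEASURE", strip))
  circuit(n_qubits = k + 2L, gates = gates,
          registers = list(strip = strip, index = index, value = value),
          n_clbits = 1L)
}

#' Canonical Toffoli (CCX) basis-gate decomposition
#'
#' The standard 15-gate decomposition of the doubly-controlled NOT over
#' `{H, T, Tdg, CX}`: nine single-qubit gates and six CNOTs, with an
#' as-soon-as-possible dependency depth of 11. Its 8x8 unitary equals the CCX
#' permutation exactly (no global phase).
#'
#' @return A 3-qubit [circuit()]; qubits 0 and 1 are controls, qubit 2 is the
#'   target.
#' @export
toffoli_basis_circuit <- function() {
  g <- list(
    gate("H", 2L),
    gate("CX", c(1L, 2L)),
    gate("Tdg", 2L),
    gate("CX", c(0L, 2L)),
    gate("T", 2L),
    gate("CX", c(1L, 2L)),
    gate("Tdg", 2L),
    gate("CX", c(0L, 2L)),
    gate("T", 1L),
    gate("T", 2L),
    gate("CX", c(0L, 1L)),
    gate("H", 2L),
    gate("T", 0L),
    gate("Tdg", 1L),
    gate("CX", c(0L, 1L)))
  circuit(3L, g, registers = list(control = c(0L, 1L), target = 2L))
}

#' Circuit depth under as-soon-as-possible layering
#'
#' Each gate is placed at one plus the maximum current layer over its qubits;
#' gates on disjoint qubits share a layer. `MEASURE` gates are excluded. No
#' commutation or cancellation is applied.
#'
#' @param c a [circuit()].
#' @return integer depth; 0 for an empty circuit.
#' @export
circuit_depth <- function(c) {
  stopifnot(inherits(c, "circuit"))
  layer <- rep(0L, c$n_qubits)
  for (g in c$gates) {
    if (g$name == "MEASURE") next
    q <- g$qubits + 1L
    layer[q] <- max(layer[q]) + 1L
  }
  if (length(layer) == 0L) 0L else max(layer)
}

#' Gate counts by name and by arity
#'
#' @param c a [circuit()].
#' @return list with `by_name` (named integer vector) and `by_arity` (named
#'   integer vector keyed by qubit count, e.g. `"1"`, `"2"`); `MEASURE` is
#'   counted under `by_name` only.
#' @export
gate_counts <- function(c) {
  stopifnot(inherits(c, "circuit"))
  nm <- vapply(c$gates, `[[`, "", "name")
  by_name <- if (length(nm)) table(nm) else table(character(0))
  nonmeas <- c$gates[nm != "MEASURE"]
  ar <- vapply(nonmeas, function(g) length(g$qubits), integer(1L))
  by_arity <- if (length(ar)) table(ar) else table(integer(0))
  list(by_name = stats::setNames(as.integer(by_name), names(by_name)),
       by_arity = stats::setNames(as.integer(by_arity), names(by_arity)))
}
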