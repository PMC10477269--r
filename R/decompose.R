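#' Decompose a multi-controlled RY to basis gates
#'
#' Rewrites an `MCRY` (or `CRY`/`RY`) gate as an ancilla-free sequence over
#' single-qubit `U` gates and `CX` only. Controls on 0 are realized by
#' X-conjugation (as `U(pi, 0, pi)`) of the corresponding control qubit; the
#' all-ones-controlled rotation is then expanded with the Gray-code
#' uniformly-controlled rotation ladder: `2^c` RY rotations on the target
#' interleaved with `2^c` CNOTs, whose per-branch rotation sums telescope to
#' the requested angle on the selected control pattern and to zero elsewhere.
#' The product of the returned gates' unitaries equals the input gate's
#' unitary to within 1e-9 (verified by dense-matrix tests); no ancilla qubits
#' are used.
#'
#' @param g a [gate()] of name `MCRY`, `CRY` or `RY`.
#' @return list of [gate()] objects over `{U, CX}`.
#' @examples
#' length(mcry_to_basis(gate("CRY", c(0, 1), params = pi / 3)))  # 4
#' @export
mcry_to_basis <- function(g) {
  stopifnot(inherits(g, "gate"))
  if (!g$name %in% c("MCRY", "CRY", "RY"))
    stop("mcry_to_basis expects an RY-family gate, got ", g$name)
  theta <- g$params[[1L]]
  n_ctrl <- length(g$qubits) - 1L
  target <- g$qubits[length(g$qubits)]
  u_ry <- function(a, q) gate("U", q, params = c(a, 0, 0))
  u_x <- function(q) gate("U", q, params = c(pi, 0, pi))
  if (n_ctrl == 0L) return(list(u_ry(theta, target)))

  ctrls <- g$qubits[seq_len(n_ctrl)]
  pattern <- g$control_pattern
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x
  zeros <- ctrls[pattern == 0L]
  for (q in zeros) add(u_x(q))

  # Gray-code multiplexed RY for the all-ones control pattern:
  # rotation j gets angle theta/2^c * (-1)^popcount(gray(j) & ones_pattern)
  # followed by CX from the control whose bit flips between gray(j), gray(j+1).
  m <- 2L^n_ctrl
  ones <- m - 1L  # after X-conjugation the active pattern is all ones
  popcount <- function(x) sum(as.integer(intToBits(x)))
  for (j in seq_len(m) - 1L) {
    gray_j <- bitwXor(j, bitwShiftR(j, 1L))
    sign <- if (popcount(bitwAnd(gray_j, ones)) %% 2L == 0L) 1 else -1
    add(u_ry(sign * theta / m, target))
    # bit flipped next in the Gray sequence: lowest set bit of j+1 (wrap: MSB)
    b <- if (j == m - 1L) n_ctrl - 1L else {
      jp <- j + 1L
      which(as.integer(intToBits(bitwAnd(jp, -jp))) == 1L) - 1L
    }
    # ctrls[1] is the first-listed control; map bit b to a control qubit.
    # Bit 0 of the branch label corresponds to the last-listed control.
    add(gate("CX", c(ctrls[n_ctrl - b], target)))
  }
  for (q in zeros) add(u_x(q))
  out
}

#' Decompose every composite gate of a circuit to basis gates
#'
#' Expands `MCRY`/`CRY` gates via [mcry_to_basis()]; a two-control `MCX`
#' (Toffoli) is replaced by the phase-exact 15-gate decomposition of
#' [toffoli_basis_circuit()], with 0-controls X-conjugated. Gates already in
#' the basis pass through unchanged.
#'
#' @param c a [circuit()].
#' @return a [circuit()] over `{H, X, T, Tdg, RY, U, CX, MEASURE}`.
#' @export
decompose_circuit <- function(c) {
  stopifnot(inherits(c, "circuit"))
  out <- list()
  for (g in c$gates) {
    expanded <- switch(g$name,
      MCRY = , CRY = mcry_to_basis(g),
      MCX = {
        n_ctrl <- length(g$qubits) - 1L
        if (n_ctrl == 1L) {
          if (g$control_pattern[1L] == 0L)
            list(gate("X", g$qubits[1L]), gate("CX", g$qubits),
                 gate("X", g$qubits[1L]))
          else list(gate("CX", g$qubits))
        } else if (n_ctrl == 2L) {
          remap <- g$qubits  # toffoli template is on qubits 0,1,2
          body <- lapply(toffoli_basis_circuit()$gates, function(t)
            gate(t$name, remap[t$qubits + 1L], params = t$params))
          zeros <- g$qubits[seq_len(2L)][g$control_pattern == 0L]
          xs <- lapply(zeros, function(q) gate("X", q))
          c(xs, body, xs)
        } else {
          stop("MCX decomposition supported for at most 2 controls")
        }
      },
      list(g))
    out <- c(out, expanded)
  }
  circuit(c$n_qubits, out, registers = c$registers, n_clbits = c$n_clbits)
}
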