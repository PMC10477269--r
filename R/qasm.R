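#' Export a circuit as OpenQASM 2.0
#'
#' Emits `OPENQASM 2.0` text with `qreg`/`creg` declarations and
#' `h`/`x`/`t`/`tdg`/`ry`/`u3`/`cx`/`measure` statements. Composite gates
#' (`CRY`, `MCRY`, `MCX`) are decomposed to the basis first via
#' [decompose_circuit()]. Angles are printed with 17 significant digits so a
#' re-import is bit-faithful.
#'
#' @param c a [circuit()].
#' @return a single character string of QASM source.
#' @examples
#' cat(export_qasm(toffoli_basis_circuit()))
#' @export
export_qasm <- function(c) {
  stopifnot(inherits(c, "circuit"))
  c <- decompose_circuit(c)
  num <- function(x) sprintf("%.17g", x)
  lines <- c("OPENQASM 2.0;",
             "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", max(c$n_qubits, 1L)))
  if (c$n_clbits > 0L)
    lines <- c(lines, sprintf("creg c[%d];", c$n_clbits))
  clbit <- 0L
  for (g in c$gates) {
    stmt <- switch(g$name,
      H = sprintf("h q[%d];", g$qubits),
      X = sprintf("x q[%d];", g$qubits),
      T = sprintf("t q[%d];", g$qubits),
      Tdg = sprintf("tdg q[%d];", g$qubits),
      RY = sprintf("ry(%s) q[%d];", num(g$params[1L]), g$qubits),
      U = sprintf("u3(%s,%s,%s) q[%d];", num(g$params[1L]),
                  num(g$params[2L]), num(g$params[3L]), g$qubits),
      CX = sprintf("cx q[%d],q[%d];", g$qubits[1L], g$qubits[2L]),
      MEASURE = {
        s <- sprintf("measure q[%d] -> c[%d];", g$qubits, clbit)
        clbit <- clbit + 1L
        s
      },
      stop("cannot export gate: ", g$name))
    lines <- c(lines, stmt)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
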