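#' Exact statevector simulation
#'
#' Applies each gate's unitary in order to the all-zero initial state and
#' returns the final complex amplitude vector. Basis index `b` holds qubit
#' `q`'s value in bit `q` (little-endian), so amplitude `b + 1` corresponds to
#' the bitstring with qubit 0 as the least significant bit. The terminal
#' `MEASURE` gate is skipped: outcome probabilities are read analytically
#' with [strip_p1()] and sampled with [sample_strip()].
#'
#' @param c a [circuit()].
#' @param max_qubits refuse circuits larger than this (memory cap).
#' @return an object of class `statevector`: list with `n_qubits` and
#'   `amplitudes` (complex vector of length `2^n_qubits`, unit norm).
#' @examples
#' sv <- run_statevector(circuit(1L, list(gate("H", 0L))))
#' Mod(sv$amplitudes)^2  # 0.5 0.5
#' @export
run_statevector <- function(c, max_qubits = 20L) {
  stopifnot(inherits(c, "circuit"))
  if (c$n_qubits > max_qubits)
    stop("circuit has ", c$n_qubits, " qubits; cap is ", max_qubits)
  n <- max(c$n_qubits, 1L)
  amp <- complex(real = c(1, rep(0, 2^n - 1)))
  for (g in c$gates) {
    if (g$name == "MEASURE") next
    amp <- apply_gate(amp, g, n)
  }
  structure(list(n_qubits = n, amplitudes = amp), class = "statevector")
}

# 2x2 matrix of each single-qubit gate
single_qubit_matrix <- function(name, params) {
  switch(name,
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    T = diag(c(1, exp(1i * pi / 4))),
    Tdg = diag(c(1, exp(-1i * pi / 4))),
    RY = {
      a <- params[1L] / 2
      matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    },
    U = {
      th <- params[1L] / 2; ph <- params[2L]; la <- params[3L]
      matrix(c(cos(th), exp(1i * ph) * sin(th),
               -exp(1i * la) * sin(th), exp(1i * (ph + la)) * cos(th)), 2, 2)
    },
    stop("no single-qubit matrix for gate ", name))
}

# Apply one gate to a length-2^n complex amplitude vector (little-endian).
apply_gate <- function(amp, g, n) {
  target <- g$qubits[length(g$qubits)]
  n_ctrl <- length(g$qubits) - 1L
  m <- switch(g$name,
    CX = , MCX = single_qubit_matrix("X", numeric(0)),
    CRY = , MCRY = single_qubit_matrix("RY", g$params),
    single_qubit_matrix(g$name, g$params))
  b <- 0:(2^n - 1)
  sel <- bitwAnd(b, bitwShiftL(1L, target)) == 0L  # target bit clear
  if (n_ctrl > 0L) {
    ctrls <- g$qubits[seq_len(n_ctrl)]
    for (j in seq_len(n_ctrl)) {
      bit <- bitwAnd(bitwShiftR(b, ctrls[j]), 1L)
      sel <- sel & (bit == g$control_pattern[j])
    }
  }
  i0 <- b[sel] + 1L
  i1 <- i0 + 2L^target
  a0 <- amp[i0]; a1 <- amp[i1]
  amp[i0] <- m[1, 1] * a0 + m[1, 2] * a1
  amp[i1] <- m[2, 1] * a0 + m[2, 2] * a1
  amp
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("Statevector on %d qubit(s) (%d amplitudes)\n",
              x$n_qubits, length(x$amplitudes)))
  invisible(x)
}

#' Marginal probability of reading 1 on one qubit
#'
#' Sums `|amplitude|^2` over all basis states in which the given qubit's bit
#' is set.
#'
#' @param s a [run_statevector()] result.
#' @param strip_qubit 0-based qubit index (default 0, the strip qubit of
#'   [build_comparison_circuit()]).
#' @return probability in `[0, 1]`.
#' @export
strip_p1 <- function(s, strip_qubit = 0L) {
  stopifnot(inherits(s, "statevector"))
  strip_qubit <- as.integer(strip_qubit)
  if (strip_qubit < 0L || strip_qubit >= s$n_qubits)
    stop("qubit index ", strip_qubit, " out of range")
  b <- 0:(length(s$amplitudes) - 1L)
  set <- bitwAnd(bitwShiftR(b, strip_qubit), 1L) == 1L
  p <- sum(Mod(s$amplitudes[set])^2)
  min(max(p, 0), 1)
}

#' Seeded finite-shot sampling of the strip qubit
#'
#' Draws `shots` independent Bernoulli(p1) measurement outcomes with a local,
#' explicitly seeded Mersenne-Twister stream (the caller's RNG state is left
#' untouched). The same seed always reproduces the same counts.
#'
#' @param p1 probability of outcome 1, in `[0, 1]`.
#' @param shots number of measurement repetitions (>= 1).
#' @param seed integer RNG seed; required, so no run is silently
#'   nondeterministic.
#' @return an object of class `shot_counts`: list with `shots`, `counts`
#'   (named integer vector `c("0" = n0, "1" = n1)`) and `seed`.
#' @examples
#' sample_strip(0.37, shots = 8000, seed = 1)
#' @export
sample_strip <- function(p1, shots, seed) {
  if (!is.numeric(p1) || length(p1) != 1L || is.na(p1) || p1 < -1e-12 ||
      p1 > 1 + 1e-12)
    stop("'p1' must be a probability in [0, 1], got ", p1)
  p1 <- min(max(p1, 0), 1)
  shots <- as.integer(shots)
  if (is.na(shots) || shots < 1L) stop("'shots' must be a positive integer")
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("'seed' is required for shot sampling")
  seed <- as.integer(seed)
  n1 <- local_seeded(seed, stats::rbinom(1L, size = shots, prob = p1))
  structure(list(shots = shots,
                 counts = c("0" = shots - n1, "1" = n1),
                 seed = seed),
            class = "shot_counts")
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
local_seeded <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv())
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_state) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.shot_counts <- function(x, ...) {
  cat(sprintf("Shot counts (%d shots, seed %d): 0 -> %d, 1 -> %d\n",
              x$shots, x$seed, x$counts[["0"]], x$counts[["1"]]))
  invisible(x)
}

#' Serialize shot counts as a JSON histogram
#'
#' @param x a [sample_strip()] result.
#' @return JSON text `{"0": n0, "1": n1, "shots": N, "seed": s}`.
#' @export
shot_counts_json <- function(x) {
  stopifnot(inherits(x, "shot_counts"))
  jsonlite::toJSON(list("0" = x$counts[["0"]], "1" = x$counts[["1"]],
                        shots = x$shots, seed = x$seed),
                   auto_unbox = TRUE)
}
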