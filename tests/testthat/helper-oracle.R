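# Independent dense-matrix oracle: builds the full 2^n x 2^n unitary of a
# gate list by explicit basis-state bookkeeping (little-endian, bit q = qubit
# q). Deliberately separate from the package's vectorized statevector path.

oracle_1q_matrix <- function(name, params) {
  switch(name,
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    T = diag(c(1, exp(1i * pi / 4))),
    Tdg = diag(c(1, exp(-1i * pi / 4))),
    RY = , CRY = , MCRY = {
      a <- params[1] / 2
      matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    },
    CX = , MCX = matrix(c(0, 1, 1, 0), 2, 2),
    U = {
      th <- params[1] / 2; ph <- params[2]; la <- params[3]
      matrix(c(cos(th), exp(1i * ph) * sin(th),
               -exp(1i * la) * sin(th), exp(1i * (ph + la)) * cos(th)), 2, 2)
    },
    stop("oracle: unsupported gate ", name))
}

oracle_full_matrix <- function(gates, n) {
  N <- 2^n
  U <- diag(1 + 0i, N)
  for (g in gates) {
    if (g$name == "MEASURE") next
    M <- matrix(0 + 0i, N, N)
    tq <- g$qubits[length(g$qubits)]
    nc <- length(g$qubits) - 1L
    m <- oracle_1q_matrix(g$name, g$params)
    for (b in 0:(N - 1)) {
      active <- TRUE
      if (nc > 0L) for (j in seq_len(nc))
        if (bitwAnd(bitwShiftR(b, g$qubits[j]), 1L) != g$control_pattern[j])
          active <- FALSE
      tb <- bitwAnd(bitwShiftR(b, tq), 1L)
      if (!active) {
        M[b + 1, b + 1] <- 1
      } else {
        b0 <- b - tb * 2^tq
        b1 <- b0 + 2^tq
        M[b0 + 1, b + 1] <- m[1, tb + 1]
        M[b1 + 1, b + 1] <- m[2, tb + 1]
      }
    }
    U <- M %*% U
  }
  U
}

# CCX permutation on 3 qubits (controls 0,1; target 2; little-endian):
# swaps basis states 3 (011) and 7 (111).
oracle_ccx_matrix <- function() {
  M <- diag(1 + 0i, 8)
  M[c(4, 8), c(4, 8)] <- matrix(c(0, 1, 1, 0), 2, 2)
  M
}

# Minimal OpenQASM 2.0 reader for the statement subset the package emits;
# returns a list(n_qubits, gates) with gates in the package's gate() format.
parse_qasm <- function(text) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  stopifnot(lines[1] == "OPENQASM 2.0;")
  n_qubits <- 0L
  gates <- list()
  qidx <- function(s) as.integer(sub("^q\\[(\\d+)\\]$", "\\1", s))
  for (ln in lines[-1]) {
    if (grepl("^include", ln)) next
    if (grepl("^qreg", ln)) {
      n_qubits <- as.integer(sub("^qreg q\\[(\\d+)\\];$", "\\1", ln))
      next
    }
    if (grepl("^creg", ln)) next
    stmt <- sub(";$", "", ln)
    if (grepl("^measure", stmt)) {
      q <- qidx(sub("^measure (q\\[\\d+\\]) -> c\\[\\d+\\]$", "\\1", stmt))
      gates[[length(gates) + 1]] <- frqiseq::gate("MEASURE", q)
      next
    }
    op <- sub("^([a-z0-9]+).*$", "\\1", stmt)
    args <- sub("^[a-z0-9]+(\\([^)]*\\))?\\s+", "", stmt)
    qs <- vapply(strsplit(args, ",")[[1]], qidx, integer(1))
    pars <- if (grepl("\\(", stmt)) {
      as.numeric(strsplit(sub("^[a-z0-9]+\\(([^)]*)\\).*$", "\\1", stmt),
                          ",")[[1]])
    } else numeric(0)
    g <- switch(op,
      h = frqiseq::gate("H", qs),
      x = frqiseq::gate("X", qs),
      t = frqiseq::gate("T", qs),
      tdg = frqiseq::gate("Tdg", qs),
      ry = frqiseq::gate("RY", qs, params = pars),
      u3 = frqiseq::gate("U", qs, params = pars),
      cx = frqiseq::gate("CX", qs),
      stop("parse_qasm: unsupported op ", op))
    gates[[length(gates) + 1]] <- g
  }
  list(n_qubits = n_qubits, gates = gates)
}

# Uniform random DNA-ish sequence for property tests
random_seq <- function(len, symbols = c("A", "C", "G", "T")) {
  paste0(sample(symbols, len, replace = TRUE), collapse = "")
}
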