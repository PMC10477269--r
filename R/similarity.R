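#' Closed-form strip-qubit probability
#'
#' The comparison circuit's strip qubit reads 1 with probability
#' `P1 = (1 - mean_i cos(alpha_i - beta_i)) / 2`, where `alpha`, `beta` are
#' the FRQI half-angles of the two sequences and the mean runs over the `2^k`
#' padded positions. Identical sequences give 0; with all state angles in
#' `[0, pi]` every per-position overlap is nonnegative, so `P1 <= 0.5`.
#'
#' @param ref,cmp [encode_sequence()] results of equal padded length.
#' @return probability in `[0, 0.5]` (for angle maps on `[0, pi]`).
#' @examples
#' p1_analytic(encode_sequence("AAAA"), encode_sequence("TTTT"))  # 0.3706...
#' @export
p1_analytic <- function(ref, cmp) {
  stopifnot(inherits(ref, "encoded_seq"), inherits(cmp, "encoded_seq"))
  if (length(ref$state_angles) != length(cmp$state_angles))
    stop("padded length mismatch: ", length(ref$state_angles), " vs ",
         length(cmp$state_angles))
  a <- ref$frqi_angles
  b <- cmp$frqi_angles
  p <- (1 - mean(cos(a - b))) / 2
  min(max(p, 0), 1)
}

#' Similarity score from the strip-qubit probability
#'
#' `sim = 1 - 2 * P1`: 1 for identical encoded sequences, 0 when the two
#' branches are orthogonal. Values of `p1` above 0.5 are outside the range
#' reachable by any angle map on `[0, pi]` and are rejected.
#'
#' @param p1 probability in `[0, 0.5]`.
#' @return similarity score in `[0, 1]`.
#' @export
similarity_score <- function(p1) {
  if (!is.numeric(p1) || length(p1) != 1L || is.na(p1))
    stop("'p1' must be a single probability")
  if (p1 < -1e-9 || p1 > 0.5 + 1e-9)
    stop("p1 = ", p1, " is outside [0, 0.5], the range reachable by the ",
         "encoding")
  1 - 2 * min(max(p1, 0), 0.5)
}

#' Padding-corrected similarity score
#'
#' Right-padding adds positions that always match (both sequences carry the
#' pad angle), inflating the raw score. With `N = n_real + n_pad` padded
#' positions, the summed per-position overlap is `N * (1 - 2 * p1)`; removing
#' the `n_pad` guaranteed unit overlaps and renormalizing by `n_real` gives
#' the corrected mean overlap `(N * (1 - 2 * p1) - n_pad) / n_real`, clipped
#' to `[-1, 1]` for numerical safety.
#'
#' @param p1 raw strip-qubit probability of the padded pair.
#' @param n_real original (unpadded) sequence length, >= 1.
#' @param n_pad number of padded positions.
#' @return corrected similarity; equals `similarity_score(p1)` when
#'   `n_pad = 0`.
#' @export
similarity_corrected <- function(p1, n_real, n_pad) {
  n_real <- as.integer(n_real); n_pad <- as.integer(n_pad)
  if (is.na(n_real) || n_real < 1L) stop("'n_real' must be >= 1")
  if (is.na(n_pad) || n_pad < 0L) stop("'n_pad' must be >= 0")
  n_total <- n_real + n_pad
  corrected <- (n_total * (1 - 2 * p1) - n_pad) / n_real
  min(max(corrected, -1), 1)
}

#' Pairwise quantum sequence comparison
#'
#' The package's main entry point: encodes two residue strings under an angle
#' map, obtains the strip-qubit probability `P1` by the requested method, and
#' returns the similarity score `sim = 1 - 2 * P1` (plus a padding-corrected
#' score when padding was applied).
#'
#' Methods: `"analytic"` evaluates the closed form
#' `P1 = (1 - mean cos(alpha - beta)) / 2` directly; `"statevector"` builds
#' the strip-qubit comparison circuit and simulates it exactly;
#' `"shots"` additionally draws seeded finite-shot measurements of the strip
#' qubit and estimates `P1` as the fraction of 1 outcomes.
#'
#' @param ref_seq,cmp_seq residue strings (case-insensitive).
#' @param map an [angle_map()]; defaults to [dna_angle_map()].
#' @param method `"analytic"` (default), `"statevector"` or `"shots"`.
#' @param shots number of measurement shots (`method = "shots"`); the default
#'   8000 mirrors the original experiment.
#' @param seed integer RNG seed, required when `method = "shots"`.
#' @param pad if `TRUE`, right-pad the shorter sequence with the map's pad
#'   symbol; unequal lengths are an error otherwise.
#' @param ref_id,cmp_id identifiers recorded in the result.
#' @param drop_zero_angles passed to [build_comparison_circuit()].
#' @return An object of class `seqsim`: list with `p1`, `similarity`,
#'   `similarity_corrected` (`NA` when no padding), `method`, `ref_id`,
#'   `cmp_id`, `n_real` (lengths of the two inputs), `n_pad`, `n_qubits`,
#'   and, for `method = "shots"`, `shots`, `seed` and `counts`.
#' @examples
#' seqsim("AAAA", "TTTT")
#' seqsim("AAAA", "TTTT", method = "shots", seed = 7)
#' @seealso [p1_analytic()], [build_comparison_circuit()], [sample_strip()]
#' @export
seqsim <- function(ref_seq, cmp_seq, map = dna_angle_map(),
                   method = c("analytic", "statevector", "shots"),
                   shots = 8000L, seed = NULL, pad = FALSE,
                   ref_id = "ref", cmp_id = "cmp",
                   drop_zero_angles = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(map, "angle_map"))
  n_ref <- nchar(ref_seq); n_cmp <- nchar(cmp_seq)
  if (n_ref != n_cmp) {
    if (!pad)
      stop("sequence lengths differ (", n_ref, " vs ", n_cmp,
           "); set pad = TRUE to right-pad the shorter sequence")
    fill <- strrep(map$pad_symbol, abs(n_ref - n_cmp))
    if (n_ref < n_cmp) ref_seq <- paste0(ref_seq, fill)
    else cmp_seq <- paste0(cmp_seq, fill)
  }
  ref <- encode_sequence(ref_seq, map)
  cmp <- encode_sequence(cmp_seq, map)
  k <- max(ref$n_index_qubits, cmp$n_index_qubits)
  if (ref$n_index_qubits != k) ref <- encode_sequence(ref_seq, map, k)
  if (cmp$n_index_qubits != k) cmp <- encode_sequence(cmp_seq, map, k)

  counts <- NULL
  if (method == "analytic") {
    p1 <- p1_exact <- p1_analytic(ref, cmp)
  } else {
    qc <- build_comparison_circuit(ref, cmp,
                                   drop_zero_angles = drop_zero_angles)
    p1_exact <- strip_p1(run_statevector(qc), qc$registers$strip)
    if (method == "statevector") {
      p1 <- p1_exact
    } else {
      if (is.null(seed)) stop("'seed' is required when method = \"shots\"")
      sc <- sample_strip(p1_exact, shots = shots, seed = seed)
      counts <- sc$counts
      p1 <- counts[["1"]] / sc$shots
    }
  }
  # only joint power-of-two padding is guaranteed to match on both sides;
  # cross-length fill (pad = TRUE) faces real residues and counts as real
  n_real <- max(n_ref, n_cmp)
  n_pad <- length(ref$state_angles) - n_real
  sim <- 1 - 2 * p1
  structure(list(p1 = p1,
                 p1_exact = p1_exact,
                 similarity = sim,
                 similarity_corrected = if (n_pad > 0L)
                   similarity_corrected(p1, n_real, n_pad) else NA_real_,
                 method = method,
                 ref_id = ref_id, cmp_id = cmp_id,
                 ref_seq = ref$symbols, cmp_seq = cmp$symbols,
                 n_real = n_real, n_pad = n_pad,
                 n_index_qubits = k, n_qubits = k + 2L,
                 map_name = map$name,
                 shots = if (method == "shots") as.integer(shots) else NULL,
                 seed = if (method == "shots") as.integer(seed) else NULL,
                 counts = counts),
            class = "seqsim")
}

#' @export
print.seqsim <- function(x, digits = 3, ...) {
  cat(sprintf("Quantum pairwise sequence comparison (%s)\n", x$method))
  cat(sprintf("  %s (%d nt) vs %s (%d nt), %d index qubit(s), %d pad\n",
              x$ref_id, nchar(x$ref_seq), x$cmp_id, nchar(x$cmp_seq),
              x$n_index_qubits, x$n_pad))
  cat(sprintf("  P1         = %.*f\n", digits, x$p1))
  cat(sprintf("  similarity = %.*f\n", digits, x$similarity))
  if (!is.na(x$similarity_corrected))
    cat(sprintf("  similarity (padding-corrected) = %.*f\n", digits,
                x$similarity_corrected))
  if (x$method == "shots")
    cat(sprintf("  shots = %d (seed %d): counts 0 -> %d, 1 -> %d\n",
                x$shots, x$seed, x$counts[["0"]], x$counts[["1"]]))
  invisible(x)
}

#' @export
summary.seqsim <- function(object, ...) {
  print(object, digits = 6)
  ham <- sum(strsplit(object$ref_seq, "")[[1L]][seq_len(object$n_real)] !=
             strsplit(object$cmp_seq, "")[[1L]][seq_len(object$n_real)])
  cat(sprintf("  mismatching positions (of %d real): %d\n",
              object$n_real, ham))
  invisible(object)
}

#' Resample shot measurements of a comparison
#'
#' Draws `nsim` fresh finite-shot estimates of `P1` for a fitted comparison,
#' one seeded binomial sample per replicate, around the comparison's exact
#' (noiseless) `P1`.
#'
#' @param object a [seqsim()] result.
#' @param nsim number of replicates.
#' @param seed base RNG seed; replicate r uses `seed + r - 1`.
#' @param shots shots per replicate (default: the object's, or 8000).
#' @param ... unused.
#' @return numeric vector of `nsim` estimated probabilities.
#' @export
simulate.seqsim <- function(object, nsim = 1, seed = 1L, shots = NULL, ...) {
  shots <- if (is.null(shots)) {
    if (is.null(object$shots)) 8000L else object$shots
  } else as.integer(shots)
  p1 <- object$p1_exact
  vapply(seq_len(nsim), function(r) {
    sample_strip(p1, shots, seed = as.integer(seed) + r - 1L)$counts[["1"]] /
      shots
  }, numeric(1L))
}

#' @export
as.data.frame.seqsim <- function(x, ...) {
  data.frame(ref_id = x$ref_id, cmp_id = x$cmp_id,
             length = x$n_real, method = x$method,
             p1 = x$p1, similarity = x$similarity,
             similarity_corrected = x$similarity_corrected,
             shots = if (is.null(x$shots)) NA_integer_ else x$shots,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             stringsAsFactors = FALSE)
}

#' Serialize a comparison result
#'
#' `seqsim_json()` emits a JSON object matching the schema shipped at
#' `system.file("extdata", "comparison_result_schema.json",
#' package = "frqiseq")`; `seqsim_tsv()` emits a header plus one TSV row.
#'
#' @param x a [seqsim()] result.
#' @return character scalar (JSON text or TSV text).
#' @export
seqsim_json <- function(x) {
  stopifnot(inherits(x, "seqsim"))
  obj <- list(ref_id = x$ref_id, cmp_id = x$cmp_id,
              length = x$n_real, n_pad = x$n_pad,
              method = x$method, p1 = x$p1, similarity = x$similarity)
  if (!is.na(x$similarity_corrected))
    obj$similarity_corrected <- x$similarity_corrected
  if (x$method == "shots") {
    obj$shots <- x$shots
    obj$seed <- x$seed
    obj$counts <- list("0" = x$counts[["0"]], "1" = x$counts[["1"]])
  }
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname seqsim_json
#' @export
seqsim_tsv <- function(x) {
  stopifnot(inherits(x, "seqsim"))
  df <- as.data.frame(x)
  paste0(paste(names(df), collapse = "\t"), "\n",
         paste(vapply(df[1L, ], function(v)
           if (is.numeric(v)) sprintf("%.10g", v) else as.character(v), ""),
           collapse = "\t"), "\n")
}
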