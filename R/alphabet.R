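#' Residue-to-angle alphabet maps
#'
#' An `angle_map` assigns each residue symbol a quantum state-representation
#' angle theta in radians. Under the FRQI convention used throughout this
#' package, a residue with angle theta is stored on the value qubit as
#' `cos(theta/2)|0> + sin(theta/2)|1>`, so angles must lie in `[0, pi]` for the
#' per-position overlaps (and hence the similarity score) to stay in `[0, 1]`.
#'
#' @param entries named numeric vector; names are single uppercase residue
#'   characters, values are angles in radians, all in `[0, pi]`.
#' @param pad_symbol single character used for right-padding; must be one of
#'   `names(entries)`. Padding positions contribute a guaranteed match, which
#'   [similarity_corrected()] can remove.
#' @param name short identifier for the map.
#' @return An object of class `angle_map`: a list with elements `name`,
#'   `entries` (named numeric) and `pad_symbol`.
#' @examples
#' dna <- dna_angle_map()
#' dna$entries[["A"]]  # pi
#' @export
angle_map <- function(entries, pad_symbol, name = "custom") {
  if (!is.numeric(entries) || is.null(names(entries)) || length(entries) == 0)
    stop("'entries' must be a non-empty named numeric vector")
  syms <- names(entries)
  if (any(nchar(syms) != 1L))
    stop("residue symbols must be single characters: ",
         paste(syms[nchar(syms) != 1L], collapse = ", "))
  syms <- toupper(syms)
  if (anyDuplicated(syms))
    stop("duplicate residue symbols: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  if (any(!is.finite(entries)) || any(entries < 0) || any(entries > pi + 1e-12))
    stop("all angles must be finite and in [0, pi]")
  pad_symbol <- toupper(pad_symbol)
  if (!is.character(pad_symbol) || length(pad_symbol) != 1L ||
      !(pad_symbol %in% syms))
    stop("'pad_symbol' must be one of the map's residue symbols")
  entries <- pmin(as.numeric(entries), pi)
  names(entries) <- syms
  structure(list(name = name, entries = entries, pad_symbol = pad_symbol),
            class = "angle_map")
}

#' Default DNA angle map
#'
#' The built-in nucleotide encoding: A maps to pi, C to pi/2, T to pi/6 and
#' G to 0. G (zero rotation) is the padding symbol.
#'
#' @return An [angle_map()] with the four DNA entries.
#' @export
dna_angle_map <- function() {
  angle_map(c(A = pi, C = pi / 2, T = pi / 6, G = 0),
            pad_symbol = "G", name = "dna")
}

#' @export
print.angle_map <- function(x, ...) {
  cat("Residue angle map '", x$name, "' (", length(x$entries),
      " symbols, pad = ", x$pad_symbol, ")\n", sep = "")
  for (s in names(x$entries))
    cat(sprintf("  %s -> %.6f rad (%.1f deg)\n", s, x$entries[[s]],
                x$entries[[s]] * 180 / pi))
  invisible(x)
}

#' Read or write an angle map as plain text
#'
#' The on-disk format is one `symbol<TAB>angle_radians` pair per line; lines
#' starting with `#` are comments. The first line may be `# pad: <symbol>`
#' to set the padding symbol (default: the symbol with the smallest angle).
#'
#' @param path file path.
#' @param map an [angle_map()] (for writing).
#' @param name identifier for the map read from disk.
#' @return `read_angle_map` returns an [angle_map()]; `write_angle_map`
#'   returns `path` invisibly.
#' @export
read_angle_map <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("angle map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pad <- NULL
  m <- regmatches(lines, regexec("^#\\s*pad:\\s*(\\S)", lines))
  for (hit in m) if (length(hit) == 2L) pad <- hit[[2L]]
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(lines) == 0L) stop("angle map file has no entries: ", path)
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) != 2L)) stop("malformed angle map line in ", path)
  syms <- vapply(parts, `[[`, "", 1L)
  angs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(angs)) stop("non-numeric angle in ", path)
  names(angs) <- syms
  if (is.null(pad)) pad <- syms[which.min(angs)]
  angle_map(angs, pad_symbol = pad, name = name)
}

#' @rdname read_angle_map
#' @export
write_angle_map <- function(map, path) {
  stopifnot(inherits(map, "angle_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pad: %s", map$pad_symbol),
               sprintf("%s\t%.17g", names(map$entries), map$entries)), con)
  invisible(path)
}

#' Encode a residue string as FRQI angles
#'
#' Uppercases the input, looks up each residue's state-representation angle,
#' and right-pads with the map's padding symbol to the next power of two so
#' the position index fits a k-qubit register (`2^k >= length`, smallest such
#' k; k = 0 for a single residue).
#'
#' @param seq residue string (case-insensitive). Ambiguity codes or any symbol
#'   absent from the map are rejected, naming the offending character and its
#'   1-based position.
#' @param map an [angle_map()]; defaults to [dna_angle_map()].
#' @param min_index_qubits pad at least to `2^min_index_qubits` positions;
#'   used to pad both members of a compared pair identically.
#' @return An object of class `encoded_seq`: list with `symbols` (the input,
#'   uppercased), `state_angles` (theta per padded position), `frqi_angles`
#'   (theta/2), `n_index_qubits`, `n_real`, `n_pad`, `map_name`, `pad_symbol`.
#' @examples
#' enc <- encode_sequence("ACGT")
#' enc$state_angles
#' @export
encode_sequence <- function(seq, map = dna_angle_map(), min_index_qubits = 0L) {
  stopifnot(inherits(map, "angle_map"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("'seq' must be a single non-empty residue string")
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1L]]
  known <- chars %in% names(map$entries)
  if (!all(known)) {
    i <- which(!known)[1L]
    stop(sprintf("unknown residue symbol '%s' at position %d", chars[i], i))
  }
  n_real <- length(chars)
  k <- max(ceiling(log2(n_real)), as.integer(min_index_qubits))
  n_total <- 2L^k
  n_pad <- n_total - n_real
  theta <- c(unname(map$entries[chars]),
             rep(map$entries[[map$pad_symbol]], n_pad))
  structure(list(symbols = seq,
                 state_angles = theta,
                 frqi_angles = theta / 2,
                 n_index_qubits = as.integer(k),
                 n_real = n_real,
                 n_pad = n_pad,
                 map_name = map$name,
                 pad_symbol = map$pad_symbol),
            class = "encoded_seq")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("Encoded sequence '%s': %d residues + %d pad (%d index qubits)\n",
              x$symbols, x$n_real, x$n_pad, x$n_index_qubits))
  invisible(x)
}

#' FRQI half-angles of an encoded sequence
#'
#' The value-qubit amplitude parameterization: alpha_i = theta_i / 2, so the
#' value qubit at position i ends in `cos(alpha_i)|0> + sin(alpha_i)|1>`.
#'
#' @param enc an [encode_sequence()] result.
#' @return numeric vector of half-angles, all in `[0, pi/2]`.
#' @export
frqi_half_angles <- function(enc) {
  stopifnot(inherits(enc, "encoded_seq"))
  enc$state_angles / 2
}

#' Decode state angles back to residues
#'
#' Inverse lookup through the map; exact angle match is required. Used for
#' round-trip checks on pad-free encodings.
#'
#' @param enc an `encoded_seq`.
#' @param map the [angle_map()] used to encode.
#' @return the decoded residue string (real positions only).
#' @export
decode_sequence <- function(enc, map = dna_angle_map()) {
  stopifnot(inherits(enc, "encoded_seq"), inherits(map, "angle_map"))
  theta <- enc$state_angles[seq_len(enc$n_real)]
  idx <- vapply(theta, function(a) {
    j <- which(abs(map$entries - a) < 1e-12)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1L))
  if (anyNA(idx)) stop("angle not uniquely decodable under map '",
                       map$name, "'")
  paste0(names(map$entries)[idx], collapse = "")
}
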