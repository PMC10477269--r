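#' Read sequence records from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` that splits each header
#' into an id (first whitespace-separated token) and a description, and
#' rejects empty records.
#'
#' @param path FASTA file path.
#' @return list of records, each a list with `id`, `description` and
#'   `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    residues <- gsub("\\s", "", as.character(set[[i]]))
    if (nchar(residues) == 0L)
      stop("empty sequence for record '", headers[i], "' in ", path)
    id <- sub("\\s.*$", "", headers[i])
    desc <- sub("^\\S+\\s*", "", headers[i])
    list(id = id, description = desc, residues = residues)
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records list of records as returned by [read_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, `[[`, "", "residues")
  ids <- vapply(records, function(r) {
    d <- if (is.null(r$description)) "" else r$description
    if (nzchar(d)) paste(r$id, d) else r$id
  }, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a mutated fixture pair
#'
#' Draws a uniform random reference sequence over the map's symbols, mutates
#' `n_mutations` distinct positions to a different random symbol, and records
#' the closed-form expected `P1` of the pair. Deterministic for a given seed.
#'
#' @param length sequence length.
#' @param n_mutations number of mutated positions, `0 <= n_mutations <=
#'   length`.
#' @param seed integer RNG seed.
#' @param map an [angle_map()].
#' @return An object of class `fixture_pair`: list with `ref` and `cmp`
#'   records (as in [read_fasta()]), `mutated_positions` (1-based, sorted)
#'   and `expected_p1`.
#' @export
generate_fixture <- function(length, n_mutations, seed,
                             map = dna_angle_map()) {
  stopifnot(inherits(map, "angle_map"))
  length <- as.integer(length); n_mutations <- as.integer(n_mutations)
  if (length < 1L) stop("'length' must be >= 1")
  if (n_mutations < 0L || n_mutations > length)
    stop("'n_mutations' must be between 0 and 'length'")
  syms <- names(map$entries)
  drawn <- local_seeded(as.integer(seed), {
    ref_chars <- sample(syms, length, replace = TRUE)
    pos <- sort(sample.int(length, n_mutations))
    cmp_chars <- ref_chars
    for (i in pos)
      cmp_chars[i] <- sample(setdiff(syms, ref_chars[i]), 1L)
    list(ref = ref_chars, cmp = cmp_chars, pos = pos)
  })
  ref_str <- paste0(drawn$ref, collapse = "")
  cmp_str <- paste0(drawn$cmp, collapse = "")
  expected <- p1_analytic(encode_sequence(ref_str, map),
                          encode_sequence(cmp_str, map))
  structure(list(
    ref = list(id = "ref", description = sprintf("random length=%d seed=%d",
                                                 length, as.integer(seed)),
               residues = ref_str),
    cmp = list(id = "cmp", description = sprintf("%d mutation(s)",
                                                 n_mutations),
               residues = cmp_str),
    mutated_positions = drawn$pos,
    expected_p1 = expected), class = "fixture_pair")
}

#' @export
print.fixture_pair <- function(x, ...) {
  cat(sprintf("Fixture pair (%d nt, %d mutation(s), expected P1 = %.4f)\n",
              nchar(x$ref$residues), length(x$mutated_positions),
              x$expected_p1))
  invisible(x)
}
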