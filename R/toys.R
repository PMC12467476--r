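## Toy-sequence generator: sequences with obvious, known patterning used
## for calibration, property tests and illustration. Each toy carries its
## ground truth so tests can check detected features against construction.

#' Generate a toy sequence with known patterning
#'
#' Four kinds are available:
#' \describe{
#'   \item{tandem_repeat}{`motif` repeated (and truncated) to `length`.}
#'   \item{blocks}{contiguous same-residue blocks of `blockResidues` in the
#'     stated order, equal sizes filling `length`.}
#'   \item{alternating_bands}{`nBands` pure patches of `bandResidue`
#'     (length `bandLength`) evenly interleaved with equal-length diverse
#'     spacers drawn uniformly from the other 19 standard residues.}
#'   \item{random}{i.i.d. uniform over `alphabet` (default five residue
#'     types, each equally likely).}
#' }
#' The random kinds use the current RNG state.
#'
#' @param kind one of `"tandem_repeat"`, `"blocks"`,
#'   `"alternating_bands"`, `"random"`.
#' @param length target sequence length (default 200).
#' @param alphabet residue types for `random` (default A, G, P, Q, S).
#' @param motif repeat unit for `tandem_repeat` (default "PAQGS").
#' @param blockResidues block residues, in order, for `blocks`.
#' @param bandResidue,bandLength,nBands band parameters for
#'   `alternating_bands`.
#' @param id sequence id (default `"toy_<kind>"`).
#' @return list with elements `sequence` (named character scalar) and
#'   `truth` (kind-specific ground-truth record: motif/period, block or
#'   band coordinates, or the alphabet).
#' @examples
#' makeToySequence("tandem_repeat", length = 10, motif = "QN")$sequence
#' @export
makeToySequence <- function(kind = c("tandem_repeat", "blocks",
                                     "alternating_bands", "random"),
                            length = 200, alphabet = c("A", "G", "P",
                                                       "Q", "S"),
                            motif = "PAQGS", blockResidues = alphabet,
                            bandResidue = "Q", bandLength = 8, nBands = 6,
                            id = NULL) {
  kind <- match.arg(kind)
  if (is.null(id)) id <- paste0("toy_", kind)
  if (kind == "tandem_repeat") {
    if (nchar(motif) > length) stop("motif longer than requested length")
    res <- substr(strrep(motif, ceiling(length / nchar(motif))), 1L, length)
    truth <- list(kind = kind, motif = motif, period = nchar(motif))
  } else if (kind == "blocks") {
    sizes <- rep(length %/% base::length(blockResidues),
                 base::length(blockResidues))
    sizes[base::length(sizes)] <- length - sum(sizes[-base::length(sizes)])
    res <- paste(strrep(blockResidues, sizes), collapse = "")
    ends <- as.integer(cumsum(sizes))
    truth <- list(kind = kind, residues = blockResidues,
                  start = as.integer(ends - sizes + 1L), end = ends)
  } else if (kind == "alternating_bands") {
    if (nBands < 2L) stop("alternating bands need nBands >= 2")
    spacerAlphabet <- setdiff(AA20, bandResidue)
    spacer <- max(1L, (length - nBands * bandLength) %/% (nBands - 1L))
    parts <- character(2L * nBands - 1L)
    parts[seq(1L, 2L * nBands - 1L, 2L)] <- strrep(bandResidue, bandLength)
    for (i in seq_len(nBands - 1L))
      parts[2L * i] <- paste(sample(spacerAlphabet, spacer, replace = TRUE),
                             collapse = "")
    res <- paste(parts, collapse = "")
    starts <- as.integer((seq_len(nBands) - 1L) * (bandLength + spacer) + 1L)
    truth <- list(kind = kind, residue = bandResidue,
                  start = starts, end = as.integer(starts + bandLength - 1L))
  } else {
    res <- paste(sample(alphabet, length, replace = TRUE), collapse = "")
    truth <- list(kind = kind, alphabet = alphabet)
  }
  list(sequence = setNames(res, id), truth = truth)
}
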