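## Protein FASTA input/output and alphabet normalization.

#' Normalize raw residue strings to the 21-letter alphabet
#'
#' Uppercases, strips stop (`*`) and gap (`-`, `.`) characters, and maps any
#' remaining non-standard letters (B, J, O, U, Z, ...) to X with a warning.
#'
#' @param x character vector of residue strings.
#' @return character vector over `{ACDEFGHIKLMNPQRSTVWYX}`.
#' @export
normalizeResidues <- function(x) {
  x <- toupper(x)
  x <- gsub("[-*.[:space:]]", "", x)
  bad <- gsub(paste0("[", paste(AA21, collapse = ""), "]"), "", x)
  bad <- unique(strsplit(paste(bad, collapse = ""), "")[[1L]])
  if (length(bad)) {
    warning("mapping unknown residue letter(s) ",
            paste(bad, collapse = ", "), " to X")
    for (b in bad) x <- gsub(b, "X", x, fixed = TRUE)
  }
  x
}

#' Read a protein FASTA file
#'
#' Records are returned in file order as a named character vector of
#' normalized residue strings (see [normalizeResidues()]); names are the
#' first whitespace-delimited header token, and the full headers are kept in
#' the `"description"` attribute.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MKV", ">b", "ppq"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("not a valid FASTA file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L)
    stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, character(1L), 1L)
  seqs <- normalizeResidues(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA record(s) with zero residues: ",
         paste(ids[empty], collapse = ", "))
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write FASTA sub-sequences for annotated regions
#'
#' Emits one record per region, with header
#' `<seq_id>/<start>-<end> <signature> p=<p_value>` and the residue
#' substring as body (1-based inclusive coordinates), wrapped at 60 columns.
#'
#' @param seqs sequence set (named character vector or `AAStringSet`)
#'   containing every `seqId` referenced by `regions`.
#' @param regions a [BiasRegions-class] object.
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
writeRegionFasta <- function(seqs, regions, path) {
  seqs <- .asSequenceSet(seqs)
  if (length(regions)) {
    miss <- setdiff(unique(regions@seqId), names(seqs))
    if (length(miss))
      stop("regions reference unknown sequence id(s): ",
           paste(miss, collapse = ", "))
    L <- nchar(seqs)[regions@seqId]
    out <- regions@start < 1L | regions@end > L
    if (any(out))
      stop("region(s) outside sequence bounds: ",
           paste(sprintf("%s:%d-%d (L=%d)", regions@seqId[out],
                         regions@start[out], regions@end[out], L[out]),
                 collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions)) {
    sig <- biasSignature(regions)
    for (i in seq_len(length(regions))) {
      body <- substr(seqs[[regions@seqId[i]]], regions@start[i],
                     regions@end[i])
      writeLines(sprintf(">%s/%d-%d %s p=%.6g", regions@seqId[i],
                         regions@start[i], regions@end[i], sig[i],
                         regions@pValue[i]), con)
      writeLines(substring(body, seq(1L, nchar(body), 60L),
                           pmin(seq(1L, nchar(body), 60L) + 59L,
                                nchar(body))), con)
    }
  }
  invisible(length(regions))
}
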