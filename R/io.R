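# Readers and writers for standard RNA structure/sequence file formats:
# bpseq ("index base partner", 1-based, partner 0 = unpaired), the
# 6-column CT format, and FASTA (via seqinr).

#' Read a bpseq file
#'
#' @param path File with one "index base partner" line per position.
#' @param ... Passed to [rna_structure()] (e.g. \code{validate = FALSE}).
#' @return List with \code{sequence} (string) and \code{structure}
#'   (\code{rna_structure}).
#' @export
read_bpseq <- function(path, ...) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("index", "base", "partner"),
                           colClasses = c("integer", "character", "integer"))
  tab <- tab[order(tab$index), ]
  if (!identical(tab$index, seq_len(nrow(tab))))
    stop("bpseq indices are not 1..n")
  pv <- tab$partner
  bad <- which(pv != 0L & pv[pmax(pv, 1L)] != tab$index)
  if (length(bad))
    stop(sprintf("bpseq pairing is not symmetric at position %d", bad[1L]))
  arcs <- .pv_to_arcs(pv)
  list(sequence = paste(toupper(tab$base), collapse = ""),
       structure = rna_structure(nrow(tab), arcs, ...))
}

#' Write a bpseq file
#'
#' @param S A consistent \code{rna_structure}.
#' @param path Output file.
#' @param sequence Optional sequence (string of length \code{S$n}); "N"
#'   placeholders are used when missing.
#' @export
write_bpseq <- function(S, path, sequence = NULL) {
  stopifnot(.is_structure(S))
  base <- if (is.null(sequence)) rep("N", S$n) else {
    b <- strsplit(sequence, "")[[1]]
    if (length(b) != S$n) stop("sequence length does not match structure")
    b
  }
  pv <- pair_vector(S)
  writeLines(sprintf("%d %s %d", seq_len(S$n), base, pv), path)
}

#' Read a CT (connectivity table) file
#'
#' Expects the common 6-column body: index, base, index-1, index+1,
#' partner (0 = unpaired), index. A header line is skipped when its first
#' field gives the sequence length.
#'
#' @inheritParams read_bpseq
#' @return List with \code{sequence} and \code{structure}.
#' @export
read_ct <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]]
  body <- if (length(first) != 6L || is.na(suppressWarnings(as.integer(first[5L]))))
    lines[-1L] else lines
  fields <- strsplit(trimws(body), "[[:space:]]+")
  if (any(vapply(fields, length, integer(1)) < 6L))
    stop("malformed CT line (need 6 columns)")
  idx <- as.integer(vapply(fields, `[`, "", 1L))
  base <- vapply(fields, `[`, "", 2L)
  pv <- as.integer(vapply(fields, `[`, "", 5L))
  ord <- order(idx)
  idx <- idx[ord]; base <- base[ord]; pv <- pv[ord]
  if (!identical(idx, seq_along(idx))) stop("CT indices are not 1..n")
  list(sequence = paste(toupper(base), collapse = ""),
       structure = rna_structure(length(idx), .pv_to_arcs(pv), ...))
}

#' Write a CT file
#'
#' @inheritParams write_bpseq
#' @export
write_ct <- function(S, path, sequence = NULL) {
  stopifnot(.is_structure(S))
  base <- if (is.null(sequence)) rep("N", S$n) else {
    b <- strsplit(sequence, "")[[1]]
    if (length(b) != S$n) stop("sequence length does not match structure")
    b
  }
  pv <- pair_vector(S)
  n <- S$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d pkinv structure", n), con)
  writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), base,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L)[seq_len(n)],
                     pv, seq_len(n)), con)
}

#' Read RNA sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (T mapped to U).
#' @export
read_fasta_rna <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- vapply(recs, function(x) toupper(as.character(x)), "")
  gsub("T", "U", out)
}

#' Write RNA sequences to a FASTA file
#'
#' @param sequences Character vector of sequences.
#' @param path Output file.
#' @param names Sequence names (default \code{seq_1}, ...).
#' @export
write_fasta_rna <- function(sequences, path, names = NULL) {
  if (is.null(names))
    names <- if (!is.null(base::names(sequences))) base::names(sequences)
             else sprintf("seq_%d", seq_along(sequences))
  seqinr::write.fasta(as.list(sequences), names = names, file.out = path)
}
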