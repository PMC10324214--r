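#' Read a FASTA file of genome sequences
#'
#' Loads nucleotide sequences, uppercases soft-masked (lowercase) residues and
#' records for each sequence its total length and its valid length, i.e. the
#' number of non-N residues. Valid length is the denominator of all
#' microsatellite abundance/density statistics.
#'
#' Only the residues A, C, G, T and N (either case) are accepted; IUPAC
#' ambiguity codes and anything else are rejected with the offending position.
#'
#' @param path Path to a FASTA file (may be gzip-compressed).
#' @return A `genome_set`: a named list of `genome_sequence` objects, each a
#'   list with elements `id`, `residues` (uppercase character string),
#'   `length` and `valid_length`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTN"), tf)
#' g <- read_fasta(tf)
#' g$s1$valid_length  # 4
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(), class = "genome_set"))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("sequence data before first FASTA header in ", path)
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    body <- lines[rec == i & !is_hdr]
    seq <- toupper(paste0(body, collapse = ""))
    bad <- regexpr("[^ACGTN]", seq)
    if (bad > 0L) {
      stop(sprintf(
        "invalid residue '%s' at position %d of sequence '%s' (only A,C,G,T,N allowed)",
        substr(seq, bad, bad), bad, ids[i]
      ))
    }
    out[[i]] <- new_genome_sequence(ids[i], seq)
  }
  structure(out, class = "genome_set")
}

new_genome_sequence <- function(id, residues) {
  n <- nchar(residues)
  structure(
    list(
      id = id,
      residues = residues,
      length = n,
      valid_length = n - lengths(regmatches(residues, gregexpr("N", residues, fixed = TRUE)))[[1L]]
    ),
    class = "genome_sequence"
  )
}

#' Write genome sequences to FASTA
#'
#' @param genomes A `genome_set` (or a single `genome_sequence`).
#' @param path Output path.
#' @param width Line-wrap width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  dna <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$residues, ""))
  names(dna) <- vapply(genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(dna, path, width = as.integer(width))
  invisible(path)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf(
    "<genome_sequence> %s: %d bp (%d valid, %d N)\n",
    x$id, x$length, x$valid_length, x$length - x$valid_length
  ))
  invisible(x)
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d sequence(s), %s bp total\n",
              length(x), format(sum(vapply(x, function(g) g$length, 0)), big.mark = ",")))
  for (g in x) print(g)
  invisible(x)
}

# Total and valid length over a genome_set.
genome_set_lengths <- function(genomes) {
  c(
    length = sum(vapply(genomes, function(g) g$length, 0)),
    valid_length = sum(vapply(genomes, function(g) g$valid_length, 0))
  )
}
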