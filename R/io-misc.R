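#' Read a GFF3 annotation file
#'
#' Thin wrapper around [rtracklayer::readGFF()] returning a plain data.frame
#' with 1-based inclusive coordinates and resolved `ID`/`Parent` attribute
#' columns.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `seq_id`, `source`, `feature_type`,
#'   `start`, `end`, `strand`, `id`, `parent`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  parent <- if ("Parent" %in% names(g)) {
    vapply(g$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  } else {
    rep(NA_character_, nrow(g))
  }
  out <- data.frame(
    seq_id = as.character(g$seqid),
    source = as.character(g$source),
    feature_type = as.character(g$type),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    id = if ("ID" %in% names(g)) as.character(g$ID) else NA_character_,
    parent = parent,
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("GFF3 feature with start > end in ", path)
  out
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @param require_branch_lengths If `TRUE` (the default), a tree lacking any
#'   branch length is rejected — trees destined for ancestral-state
#'   reconstruction need branch lengths on every edge.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, require_branch_lengths = TRUE) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick file ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file ", path)
  if (require_branch_lengths) {
    if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
      stop("tree in ", path, " is missing branch lengths, which are required ",
           "for ancestral-state reconstruction")
    }
    if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in ", path)
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a table as TSV
#'
#' Writes with a header row, no quoting and no row names, preserving column
#' order, so output tables are deterministic and diffable.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
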