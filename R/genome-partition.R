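#' Merge intervals into a disjoint sorted union
#'
#' Overlapping and adjacent (end + 1 = next start) 1-based inclusive intervals
#' coalesce.
#'
#' @param intervals Data frame (or matrix) with columns `start`, `end`.
#' @return Data frame of disjoint sorted intervals with `start`, `end`.
#' @export
merge_intervals <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (any(intervals$start > intervals$end)) stop("interval with start > end")
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start, intervals$end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Partition a genome into exonic, intronic, intergenic and gap territory
#'
#' Genic territory is the union of gene spans (`gene` features; `mRNA` spans
#' are used only for genes with no `gene` rows). Exonic territory is the union
#' of exons clipped to genic territory; intronic is genic minus exonic;
#' intergenic is everything else, so
#' `exon_bp + intron_bp + intergenic_bp = genome_length` exactly.
#' Introns are enumerated per gene as the gaps between that gene's merged
#' exons (so alternative isoforms never double-count intronic bp); counts and
#' mean lengths come from this enumeration. Runs of N of at least
#' `gap_min_run` bp intersected with intronic/intergenic territory give the
#' two gap tallies.
#'
#' @param features GFF3 feature table from [read_gff3()].
#' @param genomes A `genome_set` from [read_fasta()].
#' @param gap_min_run Minimum N-run length (bp) counted as an assembly gap.
#' @return A `genome_partition`: one-row data.frame with `genome_length`,
#'   `exon_bp`, `intron_bp`, `intergenic_bp`, `intronic_gap_bp`,
#'   `intergenic_gap_bp`, `exon_count`, `intron_count`, `mean_exon_len`,
#'   `mean_intron_len` (means are 0 when the count is 0).
#' @export
partition_genome <- function(features, genomes, gap_min_run = 10) {
  stopifnot(inherits(genomes, "genome_set") || is.list(genomes))
  seq_lengths <- vapply(genomes, function(g) g$length, 0)
  names(seq_lengths) <- vapply(genomes, function(g) g$id, "")
  if (nrow(features) > 0L && !all(features$seq_id %in% names(seq_lengths))) {
    missing <- setdiff(unique(features$seq_id), names(seq_lengths))
    stop("GFF3 sequence(s) absent from FASTA: ", paste(missing, collapse = ", "))
  }

  totals <- list(
    exon_bp = 0, intron_bp = 0, intergenic_bp = 0,
    intronic_gap_bp = 0, intergenic_gap_bp = 0,
    exon_count = 0L, intron_count = 0L,
    exon_len_sum = 0, intron_len_sum = 0
  )
  for (sid in names(seq_lengths)) {
    part <- partition_one_sequence(
      features[features$seq_id == sid, , drop = FALSE],
      genomes[[which(names(seq_lengths) == sid)]],
      gap_min_run
    )
    for (f in names(totals)) totals[[f]] <- totals[[f]] + part[[f]]
  }

  out <- data.frame(
    genome_length = sum(seq_lengths),
    exon_bp = totals$exon_bp,
    intron_bp = totals$intron_bp,
    intergenic_bp = totals$intergenic_bp,
    intronic_gap_bp = totals$intronic_gap_bp,
    intergenic_gap_bp = totals$intergenic_gap_bp,
    exon_count = totals$exon_count,
    intron_count = totals$intron_count,
    mean_exon_len = if (totals$exon_count > 0) totals$exon_len_sum / totals$exon_count else 0,
    mean_intron_len = if (totals$intron_count > 0) totals$intron_len_sum / totals$intron_count else 0
  )
  class(out) <- c("genome_partition", "data.frame")
  out
}

partition_one_sequence <- function(feat, genome, gap_min_run) {
  L <- genome$length
  genes <- feat[feat$feature_type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    genes <- feat[feat$feature_type == "mRNA" & is.na(feat$parent), , drop = FALSE]
  }
  exons <- feat[feat$feature_type == "exon", , drop = FALSE]

  gene_ir <- IRanges::IRanges(genes$start, genes$end)
  genic <- IRanges::reduce(gene_ir)
  exon_ir <- IRanges::IRanges(exons$start, exons$end)
  exonic <- IRanges::intersect(IRanges::reduce(exon_ir), genic)
  intronic <- IRanges::setdiff(genic, exonic)
  genome_ir <- IRanges::IRanges(1L, L)
  intergenic <- IRanges::setdiff(genome_ir, genic)

  # per-gene intron/exon enumeration
  exon_count <- 0L
  intron_count <- 0L
  exon_len_sum <- 0
  intron_len_sum <- 0
  if (nrow(genes) > 0L && nrow(exons) > 0L) {
    gene_of_exon <- resolve_gene(exons, feat, genes)
    for (gi in seq_len(nrow(genes))) {
      gid <- genes$id[gi]
      ex <- exons[gene_of_exon == gid, , drop = FALSE]
      if (nrow(ex) == 0L) next
      if (any(ex$start < genes$start[gi] | ex$end > genes$end[gi])) {
        bad <- ex$id[which(ex$start < genes$start[gi] | ex$end > genes$end[gi])[1L]]
        stop("exon ", bad, " extends outside the span of its gene ", gid)
      }
      merged <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
      exon_count <- exon_count + length(merged)
      exon_len_sum <- exon_len_sum + sum(IRanges::width(merged))
      if (length(merged) > 1L) {
        intron_w <- IRanges::start(merged)[-1L] - IRanges::end(merged)[-length(merged)] - 1L
        intron_w <- intron_w[intron_w > 0L]
        intron_count <- intron_count + length(intron_w)
        intron_len_sum <- intron_len_sum + sum(intron_w)
      }
    }
  }

  # N-run gaps
  intronic_gap_bp <- 0
  intergenic_gap_bp <- 0
  nruns <- n_runs(genome$residues, gap_min_run)
  if (length(nruns) > 0L) {
    intronic_gap_bp <- sum(IRanges::width(IRanges::intersect(nruns, intronic)))
    intergenic_gap_bp <- sum(IRanges::width(IRanges::intersect(nruns, intergenic)))
  }

  list(
    exon_bp = sum(IRanges::width(exonic)),
    intron_bp = sum(IRanges::width(intronic)),
    intergenic_bp = sum(IRanges::width(intergenic)),
    intronic_gap_bp = intronic_gap_bp,
    intergenic_gap_bp = intergenic_gap_bp,
    exon_count = exon_count,
    intron_count = intron_count,
    exon_len_sum = exon_len_sum,
    intron_len_sum = intron_len_sum
  )
}

# Map each exon to its gene by following Parent pointers (exon -> transcript
# -> gene, or exon -> gene directly).
resolve_gene <- function(exons, feat, genes) {
  parent_of <- setNames(feat$parent, feat$id)
  gene_ids <- genes$id
  vapply(seq_len(nrow(exons)), function(i) {
    p <- exons$parent[i]
    for (hop in 1:5) {
      if (is.na(p)) break
      if (p %in% gene_ids) return(p)
      p <- if (p %in% names(parent_of)) parent_of[[p]] else NA_character_
    }
    stop("exon ", exons$id[i], " has no resolvable gene ancestor")
  }, "")
}

# IRanges of runs of N at least min_run long.
n_runs <- function(residues, min_run) {
  m <- gregexpr(sprintf("N{%d,}", as.integer(min_run)), residues)[[1L]]
  if (m[1L] == -1L) return(IRanges::IRanges())
  IRanges::IRanges(as.integer(m), width = attr(m, "match.length"))
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("<genome_partition> %s bp genome\n", format(x$genome_length, big.mark = ",")))
  cat(sprintf("  exonic     %12.0f bp (%5.2f%%), %d exons, mean %.1f bp\n",
              x$exon_bp, 100 * x$exon_bp / x$genome_length, x$exon_count, x$mean_exon_len))
  cat(sprintf("  intronic   %12.0f bp (%5.2f%%), %d introns, mean %.1f bp; gaps %.0f bp\n",
              x$intron_bp, 100 * x$intron_bp / x$genome_length, x$intron_count,
              x$mean_intron_len, x$intronic_gap_bp))
  cat(sprintf("  intergenic %12.0f bp (%5.2f%%); gaps %.0f bp\n",
              x$intergenic_bp, 100 * x$intergenic_bp / x$genome_length,
              x$intergenic_gap_bp))
  invisible(x)
}
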