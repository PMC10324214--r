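# Default neutral substitution rate, per site per year, for anuran LTR dating.
LTR_NEUTRAL_RATE <- 1.38e-8

#' Globally align two sequences
#'
#' End-to-end (Needleman-Wunsch) optimal alignment with linear gap penalty and
#' a deterministic tie-break in the traceback (diagonal, then gap in the
#' second sequence, then gap in the first), so results are reproducible.
#'
#' @param seq_a,seq_b Nucleotide strings (A, C, G, T, N), non-empty.
#' @param match,mismatch,gap Scoring constants.
#' @return A list with the two aligned strings (`a`, `b`, gaps as `"-"`) and
#'   the alignment `score`.
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b)) {
    stop("sequences must contain only A, C, G, T, N")
  }
  .nw_align_cpp(seq_a, seq_b, match, mismatch, gap)
}

#' Proportion of differing sites in an alignment
#'
#' `p` = mismatched columns / comparable columns, where a comparable column
#' has two non-gap, non-N residues. Gap and N columns are excluded from both
#' numerator and denominator.
#'
#' @param alignment A list with aligned strings `a` and `b` of equal length
#'   (as from [align_pair()]).
#' @return The raw p-distance in \[0, 1\].
#' @export
p_distance <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1L]]
  b <- strsplit(alignment$b, "")[[1L]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  comparable <- a != "-" & b != "-" & a != "N" & b != "N"
  if (!any(comparable)) stop("no comparable columns: all positions gapped or ambiguous")
  sum(a[comparable] != b[comparable]) / sum(comparable)
}

#' Jukes-Cantor corrected divergence
#'
#' `k = -(3/4) ln(1 - 4p/3)`, the expected number of substitutions per site
#' under the JC69 model given a raw proportion `p` of differing sites. Defined
#' for `p < 0.75`; beyond that the divergence is saturated.
#'
#' @param p Raw p-distance(s) in \[0, 0.75).
#' @return Corrected divergence `k >= p`.
#' @export
#' @examples
#' jc69_distance(0.1)  # 0.107326
jc69_distance <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= 0.75)) stop("saturated divergence: p must be < 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' LTR insertion age from divergence
#'
#' The two LTRs of a retrotransposon are identical at insertion, so their
#' divergence dates the insertion: `T = k / (2 r)` years, with `k` the
#' JC-corrected divergence between the 5' and 3' LTR and `r` the neutral
#' substitution rate (default 1.38e-8 per site per year).
#'
#' @param k JC-corrected divergence(s) per site, >= 0.
#' @param r Neutral substitution rate per site per year, > 0.
#' @return Insertion age(s) in years.
#' @export
#' @examples
#' insertion_time(0.0276)  # 1e6 years
insertion_time <- function(k, r = LTR_NEUTRAL_RATE) {
  if (any(k < 0)) stop("k must be nonnegative")
  if (!is.numeric(r) || any(r <= 0)) stop("r must be positive")
  k / (2 * r)
}

#' Date a set of LTR pairs
#'
#' Runs align -> p-distance -> JC69 -> `T = k/2r` for each 5'/3' LTR pair.
#'
#' @param pairs Either a list of elements each holding `element_id`, `seq5`,
#'   `seq3`, or a `genome_set`/named list of sequences where records pair up
#'   by shared prefix with suffixes `_5` and `_3`.
#' @param r Neutral substitution rate per site per year.
#' @return A data.frame: `element_id`, `p`, `k`, `age_years`.
#' @export
ltr_insertion_times <- function(pairs, r = LTR_NEUTRAL_RATE) {
  if (inherits(pairs, "genome_set") ||
      (is.list(pairs) && length(pairs) && inherits(pairs[[1L]], "genome_sequence"))) {
    pairs <- pair_ltr_records(pairs)
  }
  rows <- lapply(pairs, function(pr) {
    aln <- align_pair(pr$seq5, pr$seq3)
    p <- p_distance(aln)
    k <- jc69_distance(p)
    data.frame(element_id = pr$element_id, p = p, k = k,
               age_years = insertion_time(k, r), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(element_id = character(0), p = numeric(0), k = numeric(0),
                      age_years = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Pair FASTA records named <element>_5 / <element>_3.
pair_ltr_records <- function(genomes) {
  ids <- vapply(genomes, function(g) g$id, "")
  base <- sub("_[53]$", "", ids)
  side <- sub("^.*_", "", ids)
  if (!all(side %in% c("5", "3"))) {
    stop("paired-LTR FASTA records must be named <element>_5 and <element>_3")
  }
  elements <- unique(base)
  lapply(elements, function(e) {
    i5 <- which(base == e & side == "5")
    i3 <- which(base == e & side == "3")
    if (length(i5) != 1L || length(i3) != 1L) {
      stop("element ", e, " does not have exactly one _5 and one _3 record")
    }
    list(element_id = e, seq5 = genomes[[i5]]$residues, seq3 = genomes[[i3]]$residues)
  })
}

#' Bin insertion ages into a histogram
#'
#' @param ages Insertion ages in years.
#' @param bin_my Bin width in million years (default 0.5).
#' @param max_my Upper limit of the histogram in million years; older
#'   insertions land in the last bin.
#' @return Data frame `bin_low_my`, `bin_high_my`, `count`; insertions younger
#'   than 1 My (the conventional "recent" boundary) are in the first two bins
#'   at the default width.
#' @export
age_histogram <- function(ages, bin_my = 0.5, max_my = 25) {
  stopifnot(bin_my > 0, max_my > bin_my)
  my <- ages / 1e6
  edges <- seq(0, max_my, by = bin_my)
  bin <- pmin(findInterval(my, edges, rightmost.closed = FALSE), length(edges) - 1L)
  bin[my == 0] <- 1L
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  data.frame(
    bin_low_my = edges[-length(edges)],
    bin_high_my = edges[-1L],
    count = counts
  )
}
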