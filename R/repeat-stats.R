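TE_SUBCLASSES <- c("LINE", "SINE", "LTR", "DNA", "ROLLING_CIRCLE", "SATELLITE",
                   "SIMPLE", "LOW_COMPLEXITY", "UNKNOWN", "OTHER")

# The four subclasses the diversity indices are computed over by default.
TE_DIVERSITY_SUBCLASSES <- c("LINE", "SINE", "LTR", "DNA")

#' Classify a RepeatMasker class/family string into a TE subclass
#'
#' The token before the first "/" decides the subclass; a trailing "?"
#' (RepeatMasker's uncertainty marker) is stripped before matching. The
#' function is total: any unrecognized token maps to `"OTHER"`.
#'
#' @param class_family Character vector of raw class/family strings, e.g.
#'   `"LINE/L1"`, `"DNA?/hAT"`, `"Unknown"`.
#' @return Character vector of subclass labels, one of
#'   `LINE, SINE, LTR, DNA, ROLLING_CIRCLE, SATELLITE, SIMPLE, LOW_COMPLEXITY,
#'   UNKNOWN, OTHER`.
#' @export
#' @examples
#' classify_te(c("LINE/L1", "DNA?/hAT", "Simple_repeat", "ARTEFACT"))
classify_te <- function(class_family) {
  stopifnot(is.character(class_family), all(nzchar(class_family)))
  token <- sub("/.*$", "", class_family)
  token <- sub("\\?$", "", token)
  map <- c(
    LINE = "LINE", SINE = "SINE", LTR = "LTR", DNA = "DNA",
    RC = "ROLLING_CIRCLE", Satellite = "SATELLITE",
    Simple_repeat = "SIMPLE", Low_complexity = "LOW_COMPLEXITY",
    Unknown = "UNKNOWN", Unspecified = "UNKNOWN"
  )
  out <- unname(map[token])
  out[is.na(out)] <- "OTHER"
  out
}

#' Per-subclass repeat totals
#'
#' Sums aligned bp per TE subclass and expresses each as a percentage of the
#' genome. By default overlapping annotations are not resolved (each record
#' contributes its full aligned span, as in raw RepeatMasker tallies); with
#' `merge = TRUE` overlapping records of the same subclass on the same
#' sequence are flattened so shared bp are counted once.
#'
#' @param records Repeat records (data.frame from [read_repeatmasker_out()]).
#' @param genome_length Total genome length in bp (> 0).
#' @param merge Resolve within-subclass overlaps before counting?
#' @return A data.frame with one row per subclass: `subclass`, `bp`,
#'   `pct_of_genome`.
#' @export
compute_te_totals <- function(records, genome_length, merge = FALSE) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop("genome_length must be positive")
  }
  bp <- setNames(numeric(length(TE_SUBCLASSES)), TE_SUBCLASSES)
  if (nrow(records) > 0L) {
    if (any(records$q_end > genome_length)) {
      stop("repeat record extends beyond the declared genome length")
    }
    sub <- classify_te(records$class_family)
    if (merge) {
      key <- split(seq_len(nrow(records)), list(sub, records$query_id), drop = TRUE)
      for (idx in key) {
        ir <- IRanges::reduce(IRanges::IRanges(records$q_begin[idx], records$q_end[idx]))
        bp[[sub[idx[1L]]]] <- bp[[sub[idx[1L]]]] + sum(IRanges::width(ir))
      }
    } else {
      span <- records$q_end - records$q_begin + 1
      agg <- tapply(span, sub, sum)
      bp[names(agg)] <- agg
    }
  }
  data.frame(
    subclass = TE_SUBCLASSES,
    bp = unname(bp),
    pct_of_genome = unname(100 * bp / genome_length),
    stringsAsFactors = FALSE
  )
}

#' Build a TE divergence landscape
#'
#' Bins the genome coverage of each TE subclass by percent divergence from the
#' repeat consensus (the "Kimura substitution level" axis of a repeat
#' landscape). Each record contributes its aligned bp to the half-open bin
#' `[i, i + bin_width)` containing its `pct_div`. Records at or beyond
#' `max_div` are dropped and counted.
#'
#' @param records Repeat records.
#' @param genome_length Genome length in bp (> 0).
#' @param max_div Upper end of the divergence axis, percent (default 50, the
#'   conventional landscape range).
#' @param bin_width Bin width in percent; must divide `max_div`.
#' @return A `divergence_landscape`: list with `coverage` (bins x subclass
#'   matrix of genome percentages), `bin_edges`, `genome_length`,
#'   `dropped_records`, `dropped_bp`.
#' @export
compute_landscape <- function(records, genome_length, max_div = 50, bin_width = 1) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop("genome_length must be positive")
  }
  if (max_div %% bin_width != 0) stop("bin_width must divide max_div")
  nbins <- as.integer(max_div / bin_width)
  edges <- seq(0, max_div, by = bin_width)
  cov <- matrix(0, nrow = nbins, ncol = length(TE_SUBCLASSES),
                dimnames = list(NULL, TE_SUBCLASSES))
  dropped <- 0L
  dropped_bp <- 0
  if (nrow(records) > 0L) {
    sub <- classify_te(records$class_family)
    span <- records$q_end - records$q_begin + 1
    drop <- records$pct_div >= max_div
    dropped <- sum(drop)
    dropped_bp <- sum(span[drop])
    if (any(!drop)) {
      bin <- floor(records$pct_div[!drop] / bin_width) + 1L
      for (i in seq_along(bin)) {
        cov[bin[i], sub[!drop][i]] <- cov[bin[i], sub[!drop][i]] + span[!drop][i]
      }
    }
  }
  structure(
    list(
      coverage = 100 * cov / genome_length,
      bin_edges = edges,
      bin_width = bin_width,
      genome_length = genome_length,
      dropped_records = dropped,
      dropped_bp = dropped_bp
    ),
    class = "divergence_landscape"
  )
}

#' @export
print.divergence_landscape <- function(x, ...) {
  tot <- colSums(x$coverage)
  cat(sprintf("<divergence_landscape> %d bins of %g%% over a %s bp genome\n",
              nrow(x$coverage), x$bin_width,
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  total coverage: %.2f%%; dropped records: %d (%.0f bp)\n",
              sum(tot), x$dropped_records, x$dropped_bp))
  nz <- tot[tot > 0]
  if (length(nz)) {
    cat("  per subclass (%):",
        paste(sprintf("%s %.2f", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a divergence landscape as a stacked histogram
#'
#' @param x A `divergence_landscape`.
#' @param max_div_display Truncate the divergence axis for display (default 40,
#'   matching the conventional 0-40 plotting range); binning is unaffected.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.divergence_landscape <- function(x, max_div_display = 40, ...) {
  keep_bins <- x$bin_edges[-length(x$bin_edges)] < max_div_display
  m <- t(x$coverage[keep_bins, , drop = FALSE])
  keep_sub <- rowSums(m) > 0
  if (!any(keep_sub)) keep_sub[] <- TRUE
  m <- m[keep_sub, , drop = FALSE]
  cols <- hcl.colors(nrow(m), "Dark 3")
  barplot(m, names.arg = x$bin_edges[-length(x$bin_edges)][keep_bins],
          col = cols, border = NA, space = 0,
          xlab = "Divergence from consensus (%)",
          ylab = "Genome coverage (%)", ...)
  legend("topright", legend = rownames(m), fill = cols, bty = "n", cex = 0.8)
  invisible(x)
}

#' Convert a landscape to a long-format table
#'
#' @param x A `divergence_landscape`.
#' @param ... Unused.
#' @return Data frame with `bin_low`, `bin_high`, one column per subclass.
#' @export
as.data.frame.divergence_landscape <- function(x, ...) {
  data.frame(
    bin_low = x$bin_edges[-length(x$bin_edges)],
    bin_high = x$bin_edges[-1L],
    x$coverage,
    stringsAsFactors = FALSE
  )
}

#' Classify the shape of a divergence landscape
#'
#' Smooths the total-coverage-per-bin series with a centered moving average,
#' detects peaks (local maxima at least `prominence_fraction` of the global
#' maximum) and labels the landscape: one peak at divergence <= 5% is
#' L-shaped (a recent TE burst), one older peak is unimodal-old, exactly two
#' peaks bimodal, and more than two multi-peaked.
#'
#' @param landscape A `divergence_landscape`.
#' @param smoothing_window Centered moving-average width in bins (odd).
#' @param prominence_fraction Minimum peak height as a fraction of the global
#'   maximum of the smoothed series.
#' @return A `landscape_shape`: list with `label` (one of `L_SHAPED`,
#'   `BIMODAL`, `MULTI_PEAKED`, `UNIMODAL_OLD`), `peak_bins` (lower bin edges
#'   of detected peaks) and the smoothed series.
#' @export
classify_landscape_shape <- function(landscape, smoothing_window = 3,
                                     prominence_fraction = 0.2) {
  stopifnot(inherits(landscape, "divergence_landscape"))
  y <- rowSums(landscape$coverage)
  if (all(y == 0)) stop("no coverage: cannot classify an all-zero landscape")
  s <- moving_average(y, smoothing_window)
  peaks <- find_peaks(s, prominence_fraction)
  lower_edges <- landscape$bin_edges[peaks]
  label <- if (length(peaks) == 1L) {
    if (lower_edges[1L] <= 5) "L_SHAPED" else "UNIMODAL_OLD"
  } else if (length(peaks) == 2L) {
    "BIMODAL"
  } else {
    "MULTI_PEAKED"
  }
  structure(
    list(label = label, peak_bins = lower_edges, smoothed = s),
    class = "landscape_shape"
  )
}

#' @export
print.landscape_shape <- function(x, ...) {
  cat(sprintf("<landscape_shape> %s (peaks at divergence %s%%)\n",
              x$label, paste(x$peak_bins, collapse = ", ")))
  invisible(x)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(y, window) {
  if (window %% 2 == 0) stop("smoothing_window must be odd")
  h <- (window - 1L) / 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, 0)
}

# Local maxima of a series at least `frac` of the global max. Plateaus count
# once, at their first bin.
find_peaks <- function(s, frac) {
  n <- length(s)
  thr <- frac * max(s)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || s[i - 1L] < s[i]
    right_ok <- j == n || s[j + 1L] < s[i]
    if (left_ok && right_ok && s[i] >= thr && s[i] > 0) peaks <- c(peaks, i)
    i <- j + 1L
  }
  peaks
}

#' Simpson's diversity index of TE subclasses
#'
#' `D = 1 - sum(n_i * (n_i - 1)) / (N * (N - 1))` where `n_i` is the number of
#' base pairs occupied by subclass i and `N` the total TE bp. D is the
#' probability that two TE base pairs drawn without replacement belong to
#' different subclasses; it ranges from 0 (one subclass) towards
#' `1 - 1/k` for k equally abundant subclasses.
#'
#' @param n_by_subclass Named or unnamed nonnegative bp counts per subclass.
#' @return Simpson's D in \[0, 1\].
#' @export
#' @examples
#' simpson_index(c(LINE = 40, SINE = 30, LTR = 20, DNA = 10))
simpson_index <- function(n_by_subclass) {
  n <- as.numeric(n_by_subclass)
  if (any(n < 0)) stop("counts must be nonnegative")
  N <- sum(n)
  if (N < 2) stop("index undefined: total count must be at least 2")
  1 - sum(n * (n - 1)) / (N * (N - 1))
}

#' Shannon diversity index of TE subclasses
#'
#' `H = -sum(p_i * ln(p_i))` with `p_i` the proportion of TE bp in subclass i;
#' zero-proportion subclasses contribute nothing. H is 0 for a single subclass
#' and at most `ln(k)` over k subclasses.
#'
#' @param n_by_subclass Nonnegative bp counts per subclass.
#' @return Shannon's H (natural log) >= 0.
#' @export
shannon_index <- function(n_by_subclass) {
  n <- as.numeric(n_by_subclass)
  if (any(n < 0)) stop("counts must be nonnegative")
  N <- sum(n)
  if (N <= 0) stop("index undefined: total count must be positive")
  p <- n[n > 0] / N
  -sum(p * log(p))
}

#' TE diversity profile of a repeat annotation
#'
#' Computes occupied bp per subclass and the Simpson and Shannon indices. By
#' default diversity is assessed over the four interspersed TE subclasses
#' (LINE, SINE, LTR, DNA), treating subclasses as the "species" of an
#' ecological community; `level = "family"` computes the same indices over
#' raw class/family strings for sensitivity analysis.
#'
#' @param records Repeat records.
#' @param level `"subclass"` (default, four TE subclasses) or `"family"`.
#' @return A list with `n` (named bp counts), `N`, `simpson`, `shannon`.
#' @export
te_diversity <- function(records, level = c("subclass", "family")) {
  level <- match.arg(level)
  span <- records$q_end - records$q_begin + 1
  if (level == "subclass") {
    sub <- classify_te(records$class_family)
    keep <- sub %in% TE_DIVERSITY_SUBCLASSES
    n <- setNames(numeric(length(TE_DIVERSITY_SUBCLASSES)), TE_DIVERSITY_SUBCLASSES)
    agg <- tapply(span[keep], sub[keep], sum)
    n[names(agg)] <- agg
  } else {
    n <- tapply(span, records$class_family, sum)
    n <- setNames(as.numeric(n), names(n))
  }
  list(
    n = n,
    N = sum(n),
    simpson = simpson_index(n),
    shannon = shannon_index(n)
  )
}
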