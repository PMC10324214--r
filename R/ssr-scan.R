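# Default minimum repeat counts per motif length (mono..hexa), the
# conventional thresholds of genome-wide SSR surveys.
SSR_MIN_REPEATS <- c(`1` = 12, `2` = 7, `3` = 5, `4` = 4, `5` = 4, `6` = 4)

#' Standardize a microsatellite motif
#'
#' Canonical form: the lexicographically smallest string among all cyclic
#' rotations of the motif and all cyclic rotations of its reverse complement.
#' This groups the motifs that describe the same tandem repeat read from
#' either strand or starting at any phase (e.g. GT, TG, AC, CA are all "AC").
#'
#' @param motif Motif of length 1-6 over A, C, G, T.
#' @return The canonical motif.
#' @export
#' @examples
#' standardize_motif("GT")   # "AC"
#' standardize_motif("GAA")  # "AAG"
standardize_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  k <- nchar(motif)
  if (k < 1L || k > 6L) stop("motif length must be 1-6")
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  min(c(rotations(motif), rotations(revcomp(motif))))
}

rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k), function(i) {
    paste0(substr(s, i, k), substr(s, 1L, i - 1L))
  }, "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# TRUE if the motif is not a tandem repetition of a shorter motif.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect perfect microsatellites (P-SSRs)
#'
#' Scans a sequence for maximal, non-extendable tandem runs of primitive
#' motifs of length 1-6 bp. Runs containing N are never reported, a run is
#' reported under its shortest period (so `(ATAT)x4` is the dinucleotide
#' `AT x 8`, never a tetranucleotide), and the returned loci are
#' non-overlapping, selected leftmost-first.
#'
#' @param seq A `genome_sequence` (from [read_fasta()]) or a plain character
#'   string of A, C, G, T, N.
#' @param min_repeats Named numeric vector of minimum repeat counts per motif
#'   length (`"1"` through `"6"`); the defaults (12, 7, 5, 4, 4, 4 for mono
#'   through hexa) are the usual genome-survey settings. Repeat counts may be
#'   fractional: a run's repeat number is its length divided by the motif
#'   length.
#' @return A data.frame of SSR loci: `seq_id`, `start`, `end` (1-based
#'   inclusive), `motif`, `standard_motif`, `repeats`, `length`, `kind`
#'   (`"PERFECT"`), `edits` (0).
#' @export
find_perfect_ssrs <- function(seq, min_repeats = SSR_MIN_REPEATS) {
  g <- as_genome_sequence(seq)
  min_repeats <- check_min_repeats(min_repeats)
  s <- strsplit(g$residues, "")[[1L]]
  n <- length(s)
  valid <- s != "N"
  loci <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    # positions i (> k) where the sequence repeats with period k
    eq <- s[(k + 1L):n] == s[1:(n - k)] & valid[(k + 1L):n] & valid[1:(n - k)]
    r <- rle(eq)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1L
    hit <- which(r$values & r$lengths >= k)  # at least 2 full motifs
    for (h in hit) {
      start <- starts_rel[h]            # run covers [start, end + k] in seq
      end <- ends_rel[h] + k
      len <- end - start + 1L
      reps <- len / k
      if (reps < min_repeats[[k]]) next
      motif <- paste0(s[start:(start + k - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      loci[[length(loci) + 1L]] <- list(
        start = start, end = end, motif = motif, k = k, repeats = reps
      )
    }
  }
  build_ssr_table(loci, g$id, kind = "PERFECT", edits = 0L)
}

check_min_repeats <- function(min_repeats) {
  min_repeats <- min_repeats[as.character(1:6)]
  if (anyNA(min_repeats)) stop("min_repeats must name motif lengths '1'..'6'")
  if (any(min_repeats[2:6] < 2)) stop("minimum repeats must be >= 2 for motifs > 1 bp")
  min_repeats
}

# Resolve a candidate list into the final non-overlapping, leftmost-first
# locus table. Candidates at the same start prefer the shorter motif.
build_ssr_table <- function(loci, seq_id, kind, edits = NULL) {
  if (length(loci) == 0L) return(empty_ssr_table())
  d <- data.frame(
    seq_id = seq_id,
    start = vapply(loci, function(x) as.integer(x$start), 0L),
    end = vapply(loci, function(x) as.integer(x$end), 0L),
    motif = vapply(loci, function(x) x$motif, ""),
    k = vapply(loci, function(x) as.integer(x$k), 0L),
    repeats = vapply(loci, function(x) as.numeric(x$repeats), 0),
    edits = if (is.null(edits)) vapply(loci, function(x) as.integer(x$edits), 0L) else edits,
    stringsAsFactors = FALSE
  )
  d <- d[order(d$start, d$k, -d$end), , drop = FALSE]
  keep <- logical(nrow(d))
  last_end <- 0L
  for (i in seq_len(nrow(d))) {
    if (d$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- d$end[i]
    }
  }
  d <- d[keep, , drop = FALSE]
  data.frame(
    seq_id = d$seq_id,
    start = d$start,
    end = d$end,
    motif = d$motif,
    standard_motif = vapply(d$motif, standardize_motif, ""),
    repeats = d$repeats,
    length = d$end - d$start + 1L,
    kind = kind,
    edits = d$edits,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

empty_ssr_table <- function() {
  data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    motif = character(0), standard_motif = character(0), repeats = numeric(0),
    length = integer(0), kind = character(0), edits = integer(0),
    stringsAsFactors = FALSE
  )
}

as_genome_sequence <- function(seq) {
  if (inherits(seq, "genome_sequence")) return(seq)
  if (is.character(seq) && length(seq) == 1L) {
    return(new_genome_sequence("seq", toupper(seq)))
  }
  stop("seq must be a genome_sequence or a single character string")
}

#' Detect imperfect microsatellites (I-SSRs)
#'
#' Greedy seed-and-extend: perfect tandem runs meeting the seed thresholds
#' (possibly below the P-SSR thresholds) are extended left and right, allowing
#' mismatches and single-base indels, while the running alignment score stays
#' positive and no more than `max_consecutive_edits` edits occur in a row.
#' Each extension is trimmed back to its best-scoring point. A locus is
#' reported if its final score (match +1, mismatch -1, gap -2) reaches
#' `min_score`; loci fully explained as perfect SSRs (no edits, meeting the
#' P-SSR thresholds) are excluded — they belong to [find_perfect_ssrs()]
#' output.
#'
#' @param seq A `genome_sequence` or character string.
#' @param seed_min_repeats Minimum repeat count of a perfect seed.
#' @param seed_min_length Minimum seed length in bp.
#' @param max_consecutive_edits Maximum run of consecutive edited positions.
#' @param min_score Minimum final alignment score to report a locus.
#' @param match,mismatch,gap Scoring constants.
#' @param perfect_min_repeats P-SSR thresholds used for the exclusion rule.
#' @return A data.frame of loci as in [find_perfect_ssrs()], `kind`
#'   `"IMPERFECT"`, `edits` = mismatches + indels.
#' @export
find_imperfect_ssrs <- function(seq, seed_min_repeats = 3, seed_min_length = 8,
                                max_consecutive_edits = 2, min_score = 12,
                                match = 1, mismatch = -1, gap = -2,
                                perfect_min_repeats = SSR_MIN_REPEATS) {
  stopifnot(seed_min_repeats > 0, seed_min_length > 0,
            max_consecutive_edits > 0, min_score > 0)
  g <- as_genome_sequence(seq)
  s <- strsplit(g$residues, "")[[1L]]
  n <- length(s)
  seeds <- find_seed_runs(s, seed_min_repeats, seed_min_length)
  if (nrow(seeds) == 0L) return(empty_ssr_table())
  seeds <- seeds[order(seeds$start, seeds$k), , drop = FALSE]
  loci <- list()
  covered_to <- 0L
  for (i in seq_len(nrow(seeds))) {
    if (seeds$start[i] <= covered_to) next  # inside an already-reported locus
    ext <- extend_seed(s, seeds$start[i], seeds$end[i], seeds$k[i],
                       max_consecutive_edits, match, mismatch, gap)
    if (ext$score < min_score) next
    # fully perfect and above P-SSR thresholds: belongs to the P-SSR output
    reps <- (ext$end - ext$start + 1) / seeds$k[i]
    if (ext$edits == 0L && reps >= perfect_min_repeats[[seeds$k[i]]]) {
      covered_to <- max(covered_to, ext$end)
      next
    }
    loci[[length(loci) + 1L]] <- list(
      start = ext$start, end = ext$end,
      motif = seeds$motif[i], k = seeds$k[i],
      repeats = reps, edits = ext$edits
    )
    covered_to <- max(covered_to, ext$end)
  }
  build_ssr_table(loci, g$id, kind = "IMPERFECT")
}

# Perfect tandem runs (any primitive motif, length 1-6) meeting the seed
# thresholds; the raw material for imperfect-SSR extension.
find_seed_runs <- function(s, min_reps, min_len) {
  n <- length(s)
  valid <- s != "N"
  out <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    eq <- s[(k + 1L):n] == s[1:(n - k)] & valid[(k + 1L):n] & valid[1:(n - k)]
    r <- rle(eq)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1L
    hit <- which(r$values & r$lengths >= k)
    for (h in hit) {
      start <- starts_rel[h]
      end <- ends_rel[h] + k
      len <- end - start + 1L
      if (len < min_len || len / k < min_reps) next
      motif <- paste0(s[start:(start + k - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = end, k = k, motif = motif,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), k = integer(0),
                      motif = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Extend a perfect seed in both directions, tracking the expected motif phase.
# At each step: a matching base extends for `match`; otherwise a one-step
# lookahead chooses between substitution, insertion (extra base in the
# sequence) and deletion (missing motif base), preferring whichever realigns
# the next base, substitution first. Extension stops at sequence ends, at N,
# when the running score drops to 0, or when the consecutive-edit limit is
# exceeded; each side is then trimmed to its best-scoring point.
extend_seed <- function(s, start, end, k, max_consec, match, mismatch, gap) {
  n <- length(s)
  motif <- s[start:(start + k - 1L)]
  seed_score <- (end - start + 1L) * match

  walk <- function(pos0, phase0, dir) {
    pos <- pos0
    phase <- phase0
    score <- 0
    consec <- 0L
    edits <- 0L
    best <- list(score = 0, pos = pos0 - dir, edits = 0L)
    repeat {
      if (pos < 1L || pos > n || s[pos] == "N") break
      expected <- motif[phase]
      if (s[pos] == expected) {
        score <- score + match
        consec <- 0L
        if (score > best$score) best <- list(score = score, pos = pos, edits = edits)
        pos <- pos + dir
        phase <- step_phase(phase, k, dir)
      } else {
        nxt <- pos + dir
        next_base <- if (nxt >= 1L && nxt <= n) s[nxt] else NA_character_
        sub_ok <- !is.na(next_base) && next_base == motif[step_phase(phase, k, dir)]
        ins_ok <- !is.na(next_base) && next_base == expected
        del_ok <- s[pos] == motif[step_phase(phase, k, dir)]
        if (sub_ok || (!ins_ok && !del_ok)) {        # substitution
          score <- score + mismatch
          pos <- pos + dir
          phase <- step_phase(phase, k, dir)
        } else if (ins_ok) {                          # inserted base: skip it
          score <- score + gap
          pos <- pos + dir
        } else {                                      # deleted motif base
          score <- score + gap
          phase <- step_phase(phase, k, dir)
        }
        edits <- edits + 1L
        consec <- consec + 1L
        if (consec > max_consec || seed_score + score <= 0) break
      }
    }
    best
  }

  right <- walk(end + 1L, step_phase(k, k, 1L), 1L)
  left <- walk(start - 1L, step_phase(1L, k, -1L), -1L)
  list(
    start = min(left$pos, start),
    end = max(right$pos, end),
    score = seed_score + left$score + right$score,
    edits = left$edits + right$edits
  )
}

step_phase <- function(phase, k, dir) {
  ((phase - 1L + dir) %% k) + 1L
}

#' Summarize SSR loci per motif-size class
#'
#' Computes the locus count, total bp, relative abundance (loci per Mb of
#' valid, non-N genome length), relative density (bp per Mb of valid length)
#' and percent of the valid genome covered, per motif-size class
#' (mono- through hexanucleotide) and overall.
#'
#' @param loci SSR locus table from [find_perfect_ssrs()] /
#'   [find_imperfect_ssrs()] (or both, row-bound).
#' @param valid_length Valid (non-N) genome length in bp (> 0).
#' @return A data.frame with one row per motif-size class plus an `"all"` row:
#'   `motif_class`, `locus_count`, `total_bp`, `relative_abundance`,
#'   `relative_density`, `pct_of_genome`.
#' @export
summarize_ssrs <- function(loci, valid_length) {
  if (!is.numeric(valid_length) || valid_length <= 0) {
    stop("valid_length must be positive")
  }
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  klen <- nchar(loci$motif)
  mb <- valid_length / 1e6
  row_for <- function(idx, label) {
    total_bp <- sum(loci$length[idx])
    data.frame(
      motif_class = label,
      locus_count = length(idx),
      total_bp = total_bp,
      relative_abundance = length(idx) / mb,
      relative_density = total_bp / mb,
      pct_of_genome = 100 * total_bp / valid_length,
      stringsAsFactors = FALSE
    )
  }
  per <- lapply(1:6, function(k) row_for(which(klen == k), classes[k]))
  rbind(do.call(rbind, per), row_for(seq_len(nrow(loci)), "all"))
}
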