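#' Read a RepeatMasker annotation (.out) file
#'
#' Parses the standard RepeatMasker ".out" layout: two header lines and one
#' blank line, followed by whitespace-separated columns
#' `score %div %del %ins query begin end (left) strand repeat class/family
#' repeat_begin repeat_end (left) ID [*]`.
#' Query coordinates are kept 1-based inclusive; a strand of `"C"`
#' (complement) is normalized to `"-"`. The parenthesized "(left)" columns are
#' validated but not retained.
#'
#' @param path Path to a RepeatMasker .out file.
#' @return A data.frame of repeat records with columns `sw_score`, `pct_div`,
#'   `pct_del`, `pct_ins`, `query_id`, `q_begin`, `q_end`, `strand`,
#'   `repeat_name`, `class_family`, `record_id`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path)
  # skip the two header lines plus the blank separator when present
  body_start <- 1L
  if (length(lines) >= 1L && grepl("\\bSW\\b|score", lines[1])) {
    body_start <- 2L
    if (length(lines) >= 2L && grepl("score|div\\.", lines[2])) body_start <- 3L
    if (length(lines) >= body_start && !nzchar(trimws(lines[body_start]))) {
      body_start <- body_start + 1L
    }
  }
  body <- lines[seq_len(length(lines)) >= body_start]
  body_ln <- which(seq_len(length(lines)) >= body_start)
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- body_ln[keep]
  if (length(body) == 0L) return(empty_repeat_table())

  rows <- strsplit(trimws(body), "\\s+")
  nfld <- lengths(rows)
  ok <- nfld == 15L | nfld == 16L  # optional trailing "*" (overlap flag)
  if (any(!ok)) {
    stop(sprintf("line %d of %s: expected 15 columns (16 with '*'), found %d",
                 body_ln[which(!ok)[1L]], path, nfld[which(!ok)[1L]]))
  }
  fld <- function(i) vapply(rows, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(fld(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("line %d of %s: non-numeric %s '%s'",
                   body_ln[bad], path, what, fld(i)[bad]))
    }
    v
  }
  strand <- fld(9)
  if (!all(strand %in% c("+", "C", "-"))) {
    stop("unrecognized strand value in ", path)
  }
  strand[strand == "C"] <- "-"
  out <- data.frame(
    sw_score = num(1, "score"),
    pct_div = num(2, "%div"),
    pct_del = num(3, "%del"),
    pct_ins = num(4, "%ins"),
    query_id = fld(5),
    q_begin = as.integer(num(6, "query begin")),
    q_end = as.integer(num(7, "query end")),
    strand = strand,
    repeat_name = fld(10),
    class_family = fld(11),
    record_id = as.integer(num(15, "record ID")),
    stringsAsFactors = FALSE
  )
  if (any(out$q_begin > out$q_end)) {
    bad <- which(out$q_begin > out$q_end)[1L]
    stop(sprintf("line %d of %s: q_begin > q_end", body_ln[bad], path))
  }
  if (any(out$pct_div < 0)) stop("negative divergence in ", path)
  out
}

empty_repeat_table <- function() {
  data.frame(
    sw_score = numeric(0), pct_div = numeric(0), pct_del = numeric(0),
    pct_ins = numeric(0), query_id = character(0), q_begin = integer(0),
    q_end = integer(0), strand = character(0), repeat_name = character(0),
    class_family = character(0), record_id = integer(0),
    stringsAsFactors = FALSE
  )
}

rm_out_header <- function() {
  c(
    "   SW  perc perc perc  query     position in query             matching            repeat            position in repeat",
    "score  div. del. ins.  sequence  begin end          (left)     repeat              class/family    begin  end    (left)  ID",
    ""
  )
}

#' Write repeat records in RepeatMasker .out layout
#'
#' @param records Data frame as returned by [read_repeatmasker_out()]. An
#'   optional `q_left` column supplies the "(left)" field; otherwise 0 is
#'   written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(records, path) {
  lines <- rm_out_header()
  if (nrow(records) > 0L) {
    left <- if ("q_left" %in% names(records)) records$q_left else 0L
    strand <- ifelse(records$strand == "-", "C", "+")
    lines <- c(lines, sprintf(
      "%5d %4.1f %4.1f %4.1f %s %d %d (%d) %s %s %s %d %d (%d) %d",
      as.integer(records$sw_score), records$pct_div, records$pct_del,
      records$pct_ins, records$query_id, records$q_begin, records$q_end,
      as.integer(left), strand, records$repeat_name, records$class_family,
      1L, as.integer(records$q_end - records$q_begin + 1L), 0L,
      records$record_id
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
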