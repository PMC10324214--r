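# Independent brute-force oracles used to verify the package's
# implementations. These deliberately avoid the algorithms used in R/.

# --- Brownian-motion ancestral states: multivariate-normal conditioning -----

# Full tip + internal-node covariance from shared root-to-node path lengths;
# ancestral estimates as the conditional means given the tips, with the root
# state plugged in at its GLS estimate.
oracle_anc_states <- function(tree, x) {
  n <- length(tree$tip.label)
  root <- n + 1L
  N <- n + tree$Nnode
  parent <- integer(N)
  blen <- numeric(N)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    blen[tree$edge[e, 2L]] <- tree$edge.length[e]
  }
  path_to_root <- function(v) {
    p <- v
    out <- v
    while (p != root) {
      p <- parent[p]
      out <- c(out, p)
    }
    out
  }
  depth <- numeric(N)
  for (v in seq_len(N)) {
    if (v == root) next
    pth <- path_to_root(v)
    depth[v] <- sum(blen[setdiff(pth, root)])
  }
  shared <- function(a, b) {
    if (a == b) return(depth[a])
    common <- intersect(path_to_root(a), path_to_root(b))
    max(depth[common])
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) C[i, j] <- shared(i, j)
  Ci <- solve(C)
  x <- as.numeric(x[tree$tip.label])
  mu <- sum(Ci %*% x) / sum(Ci)
  sigma2 <- as.numeric(t(x - mu) %*% Ci %*% (x - mu)) / n
  nodes <- (n + 1L):N
  est <- vapply(nodes, function(v) {
    cv <- vapply(seq_len(n), function(t) shared(v, t), 0)
    mu + as.numeric(cv %*% Ci %*% (x - mu))
  }, 0)
  vr <- vapply(nodes, function(v) {
    cv <- vapply(seq_len(n), function(t) shared(v, t), 0)
    sigma2 * (depth[v] - as.numeric(t(cv) %*% Ci %*% cv) +
                (1 - sum(Ci %*% cv))^2 / sum(Ci))
  }, 0)
  list(node = nodes, estimate = est, variance = vr, sigma2 = sigma2, root = mu)
}

# Random rooted tree with strictly positive branch lengths.
random_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  tree
}

# --- Perfect SSRs: exhaustive per-position tandem-run enumeration -----------

oracle_is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && motif == strrep(substr(motif, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

# Enumerate every maximal tandem run of every primitive motif (1-6 bp) by
# direct per-position extension, then apply the reporting rules: repeat
# threshold, no N, leftmost-first non-overlap (shorter motif wins ties).
oracle_perfect_ssrs <- function(seqstr, min_repeats) {
  s <- strsplit(seqstr, "")[[1L]]
  n <- length(s)
  cand <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    idx <- seq_len(n - 2L * k + 1L)
    pre <- substring(seqstr, idx, idx + k - 1L) ==
      substring(seqstr, idx + k, idx + 2L * k - 1L)
    for (i in idx[pre]) {
      motif <- substr(seqstr, i, i + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!oracle_is_primitive(motif)) next
      # left-maximality: the position before must not continue the period
      if (i > 1L && s[i - 1L] != "N" && s[i - 1L] == s[i - 1L + k]) next
      j <- i + 2L * k
      while (j <= n && s[j] != "N" && s[j] == s[j - k]) j <- j + 1L
      e <- j - 1L
      reps <- (e - i + 1L) / k
      if (reps >= min_repeats[[as.character(k)]]) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i, end = e, motif = motif, k = k, repeats = reps,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), motif = character(0),
                      repeats = numeric(0), stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, cand)
  d <- d[order(d$start, d$k, -d$end), , drop = FALSE]
  keep <- logical(nrow(d))
  last_end <- 0L
  for (i in seq_len(nrow(d))) {
    if (d$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- d$end[i]
    }
  }
  d <- d[keep, c("start", "end", "motif", "repeats")]
  row.names(d) <- NULL
  d
}

random_dna_string <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# --- Global alignment: exhaustive search over the alignment space -----------

# Best score over all global alignments of two short strings, by recursion
# over the three moves. Exponential; only for tiny inputs.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      sc <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + sc)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# --- Random gene annotations for partition conservation ---------------------

random_annotation <- function(seq_len_bp, n_genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genes)) {
    gs <- sample.int(seq_len_bp - 50L, 1L)
    ge <- min(seq_len_bp, gs + sample(20:400, 1L))
    gid <- sprintf("g%d", g)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = "s1", source = "sim", feature_type = "gene", start = gs, end = ge,
      strand = "+", id = gid, parent = NA_character_, stringsAsFactors = FALSE
    )
    n_ex <- sample(1:4, 1L)
    for (e in seq_len(n_ex)) {
      es <- sample(gs:ge, 1L)
      ee <- min(ge, es + sample(5:80, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = "s1", source = "sim", feature_type = "exon", start = es, end = ee,
        strand = "+", id = sprintf("%s.e%d", gid, e), parent = gid,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

as_genome_set <- function(id, residues) {
  g <- repeatscape:::new_genome_sequence(id, residues)
  structure(setNames(list(g), id), class = "genome_set")
}
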