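#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the state of every internal node of a rooted tree for a
#' continuous trait evolving by Brownian motion. Each node's estimate is the
#' generalized-least-squares root estimate of the tree re-rooted at that node
#' (the recursive inverse-branch-length-weighted mean of the tips), computed
#' in two message-passing sweeps over the tree, so polytomies are handled
#' natively. Variances come from the same conditional normal, scaled by the
#' ML Brownian rate.
#'
#' @param tree A rooted `phylo` object (a basal polytomy is treated as rooted
#'   at the basal node); every branch length present and > 0.
#' @param traits Named numeric vector of tip values; names must cover all tips.
#' @return An `anc_states` object: data.frame with `node` (label), `estimate`,
#'   `variance`, plus attributes `sigma2` (ML Brownian rate) and `root`
#'   (root-state estimate).
#' @export
#' @examples
#' tree <- ape::read.tree(text = "(A:1,B:3);")
#' anc_states_ml(tree, c(A = 0, B = 4))  # root estimate 1.0
anc_states_ml <- function(tree, traits) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  # a basal polytomy (e.g. a star tree) is treated as rooted at the basal node
  tree <- ape::collapse.singles(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length <= 0)) {
    stop("zero-length branch: collapse zero branches before reconstruction")
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(traits))) {
    stop("tip(s) without a trait value: ",
         paste(setdiff(tips, names(traits)), collapse = ", "))
  }
  x <- as.numeric(traits[tips])
  if (anyNA(x)) stop("missing trait values are not allowed")

  n_tip <- length(tips)
  if (n_tip < 2L) stop("need at least two tips")
  n_node <- tree$Nnode
  root <- n_tip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  parent <- po$edge[, 1L]
  child <- po$edge[, 2L]
  blen <- po$edge.length

  # Upward sweep: message (mean, variance) each subtree sends to its parent
  # node, in units of the Brownian rate. Sequential pairwise merging
  # accumulates the GLS sum of squares that yields the ML rate.
  up_m <- numeric(n_tip + n_node)
  up_w <- numeric(n_tip + n_node)
  up_m[seq_len(n_tip)] <- x
  ss <- 0
  edges_of <- split(seq_along(parent), parent)
  node_order <- unique(parent)  # postorder guarantees children first
  for (v in node_order) {
    e <- edges_of[[as.character(v)]]
    m <- up_m[child[e]]
    w <- up_w[child[e]] + blen[e]
    cm <- m[1L]
    cw <- w[1L]
    if (length(e) > 1L) {
      for (i in 2L:length(e)) {
        ss <- ss + (cm - m[i])^2 / (cw + w[i])
        prec <- 1 / cw + 1 / w[i]
        cm <- (cm / cw + m[i] / w[i]) / prec
        cw <- 1 / prec
      }
    }
    up_m[v] <- cm
    up_w[v] <- cw
  }
  sigma2 <- ss / n_tip

  # Downward sweep: message each node receives from the rest of the tree
  # through its parent (precision 0 = no message, at the root).
  down_m <- numeric(n_tip + n_node)
  down_p <- numeric(n_tip + n_node)  # precision
  for (v in rev(node_order)) {       # root first
    e <- edges_of[[as.character(v)]]
    for (ei in e) {
      c_node <- child[ei]
      if (c_node <= n_tip) next
      others <- setdiff(e, ei)
      pr <- 0
      ms <- 0
      for (oi in others) {
        p_i <- 1 / (up_w[child[oi]] + blen[oi])
        pr <- pr + p_i
        ms <- ms + p_i * up_m[child[oi]]
      }
      if (down_p[v] > 0) {
        pr <- pr + down_p[v]
        ms <- ms + down_p[v] * down_m[v]
      }
      if (pr <= 0) stop("internal node with a single neighbor; collapse it first")
      down_m[c_node] <- ms / pr
      down_p[c_node] <- 1 / (1 / pr + blen[ei])
    }
  }

  internal <- (n_tip + 1L):(n_tip + n_node)
  est <- numeric(n_node)
  vr <- numeric(n_node)
  for (i in seq_along(internal)) {
    v <- internal[i]
    e <- edges_of[[as.character(v)]]
    pr <- 1 / (up_w[child[e]] + blen[e])
    ms <- sum(pr * up_m[child[e]])
    pr <- sum(pr)
    if (down_p[v] > 0) {
      ms <- ms + down_p[v] * down_m[v]
      pr <- pr + down_p[v]
    }
    est[i] <- ms / pr
    vr[i] <- sigma2 / pr
  }

  labels <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    as.character(internal)
  }
  out <- data.frame(node = labels, estimate = est, variance = vr,
                    stringsAsFactors = FALSE)
  attr(out, "sigma2") <- sigma2
  attr(out, "root") <- est[internal == root]
  class(out) <- c("anc_states", "data.frame")
  out
}

#' @export
print.anc_states <- function(x, ...) {
  cat(sprintf("<anc_states> Brownian-motion ML reconstruction, %d internal node(s)\n",
              nrow(x)))
  cat(sprintf("  sigma2 = %.6g, root estimate = %.6g\n",
              attr(x, "sigma2"), attr(x, "root")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Ordinary least-squares fit of y on x
#'
#' Wraps [stats::lm()] and extracts the quantities used throughout the
#' correlation battery: slope, intercept, R-squared and the F-test p-value
#' for a zero slope.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped. At least 3 complete pairs and non-constant x are required.
#' @return An `ols_fit`: list with `n`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `residual_se` and the underlying `lm` fit.
#' @export
ols_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (length(unique(x)) == 1L) stop("x is constant: regression undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits trigger a noisy warning
  if (var(y) == 0) {
    # constant response: nothing to explain
    r2 <- 0
    p <- 1
  } else {
    r2 <- sm$r.squared
    p <- if (is.null(sm$fstatistic)) 1 else {
      unname(pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                lower.tail = FALSE))
    }
  }
  structure(
    list(
      n = length(x),
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = r2,
      p_value = p,
      residual_se = sm$sigma,
      fit = fit
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<ols_fit> n = %d: y = %.4g + %.4g x, R^2 = %.3f, p = %.3g\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value
  ))
  invisible(x)
}

#' Habitat niche width per species
#'
#' Niche width is the number of distinct habitat types recorded for a
#' species. Duplicate (species, habitat) rows are deduplicated; species with
#' no habitat rows (when a full species list is supplied) are excluded and
#' reported.
#'
#' @param habitat_table Data frame with columns `species` and `habitat_type`,
#'   one row per species-habitat pair.
#' @param all_species Optional character vector of the full species panel;
#'   members absent from the table are flagged as excluded.
#' @return Data frame `species`, `niche_width`, with attribute `excluded`.
#' @export
niche_width <- function(habitat_table, all_species = NULL) {
  stopifnot(all(c("species", "habitat_type") %in% names(habitat_table)))
  tab <- unique(habitat_table[, c("species", "habitat_type")])
  counts <- tapply(tab$habitat_type, tab$species, function(h) length(unique(h)))
  out <- data.frame(
    species = names(counts),
    niche_width = as.integer(counts),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  excluded <- if (is.null(all_species)) character(0) else setdiff(all_species, out$species)
  if (length(excluded)) {
    warning("species without habitat data excluded: ",
            paste(excluded, collapse = ", "))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Regress every panel metric against genome size
#'
#' Runs one [ols_fit()] of each metric column against the genome-size column;
#' metrics with fewer than 3 non-missing species are skipped with a warning.
#'
#' @param trait_table Data frame keyed by species with a `genome_size` column
#'   plus numeric metric columns.
#' @param size_col Name of the genome-size column.
#' @return Data frame with one row per fitted metric: `metric`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_value`.
#' @export
correlate_panel <- function(trait_table, size_col = "genome_size") {
  if (!size_col %in% names(trait_table)) {
    stop("trait table has no '", size_col, "' column")
  }
  metrics <- setdiff(names(trait_table), c(size_col, "species"))
  metrics <- metrics[vapply(trait_table[metrics], is.numeric, TRUE)]
  rows <- list()
  for (m in metrics) {
    ok <- stats::complete.cases(trait_table[[size_col]], trait_table[[m]])
    if (sum(ok) < 3L) {
      warning("metric '", m, "' skipped: fewer than 3 non-missing species")
      next
    }
    f <- ols_fit(trait_table[[size_col]], trait_table[[m]])
    rows[[m]] <- data.frame(
      metric = m, n = f$n, slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, p_value = f$p_value, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(metric = character(0), n = integer(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
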