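# class/family strings emitted for planted TE copies, per subclass
SYNTH_CLASS_FAMILY <- c(
  LINE = "LINE/L1", SINE = "SINE/tRNA", LTR = "LTR/Gypsy", DNA = "DNA/hAT",
  ROLLING_CIRCLE = "RC/Helitron", SATELLITE = "Satellite",
  SIMPLE = "Simple_repeat", LOW_COMPLEXITY = "Low_complexity",
  UNKNOWN = "Unknown", OTHER = "ARTEFACT"
)

set_sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

# Background segment whose first/last base avoids the given characters.
guarded_dna <- function(n, gc, first_not = NULL, last_not = NULL) {
  if (n <= 0L) return("")
  s <- strsplit(random_dna(n, gc), "")[[1L]]
  forbid_first <- first_not
  forbid_last <- last_not
  if (n == 1L) {
    forbid_first <- c(first_not, last_not)
    forbid_last <- NULL
  }
  if (!is.null(forbid_first) && s[1L] %in% forbid_first) {
    s[1L] <- sample(setdiff(c("A", "C", "G", "T"), forbid_first), 1L)
  }
  if (!is.null(forbid_last) && s[n] %in% forbid_last) {
    s[n] <- sample(setdiff(c("A", "C", "G", "T"), forbid_last), 1L)
  }
  paste0(s, collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Substitute each site independently with probability `rate`, uniformly to
# one of the three alternative bases. Returns the mutated string and the
# realized proportion of changed sites.
mutate_sequence <- function(seq, rate) {
  s <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  list(seq = paste0(s, collapse = ""), realized = length(hit) / length(s))
}

#' Simulation configuration for a synthetic genome
#'
#' @param seed Integer seed; fully determines the output.
#' @param genome_length Genome length in bp.
#' @param gc_content GC fraction of the background sequence.
#' @param te_plan Data frame with columns `consensus_id`, `subclass`,
#'   `copy_count`, `target_divergence` (percent), `consensus_length` (bp).
#' @param ssr_plan Data frame with columns `motif`, `repeats`, `edits`.
#' @param gene_plan Data frame with columns `exon_count`, `exon_len`,
#'   `intron_len`.
#' @param gap_plan Numeric vector of N-run lengths.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, genome_length, gc_content = 0.4,
                              te_plan = NULL, ssr_plan = NULL,
                              gene_plan = NULL, gap_plan = numeric(0)) {
  stopifnot(genome_length > 0, gc_content >= 0, gc_content <= 1)
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, te_plan = te_plan, ssr_plan = ssr_plan,
         gene_plan = gene_plan, gap_plan = gap_plan),
    class = "simulation_config"
  )
}

#' Simulate a genome with planted repeats, SSRs, genes and gaps
#'
#' Plants every feature of the plan at a non-overlapping position (features
#' separated by at least 1 bp of background), fills the rest with i.i.d.
#' background nucleotides at the configured GC content, and returns the
#' genome together with a RepeatMasker-style annotation of the planted TE
#' copies, a GFF3-style annotation of the planted genes and a truth table of
#' every planted feature.
#'
#' TE copies are the consensus mutated by i.i.d. per-site substitution
#' (uniform over the three alternative bases, no indels) at the target
#' divergence; the emitted `pct_div` is the realized proportion of mutated
#' sites x 100, so planted truth is exact.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_genome`: list with `genome` (a `genome_set` of one
#'   sequence named `"synth1"`), `repeats` (repeat-record data.frame),
#'   `genes` (GFF3-style feature data.frame), `truth` (truth table) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set_sim_seed(config$seed)
  gc <- config$gc_content
  L <- config$genome_length

  # realize every planted feature's sequence (order: TEs, SSRs, genes, gaps)
  feats <- list()
  add <- function(type, id, seq, extra = list()) {
    feats[[length(feats) + 1L]] <<- c(
      list(type = type, id = id, seq = seq, len = nchar(seq)), extra
    )
  }
  if (!is.null(config$te_plan) && nrow(config$te_plan) > 0L) {
    tp <- config$te_plan
    for (i in seq_len(nrow(tp))) {
      consensus <- random_dna(tp$consensus_length[i], gc)
      for (cp in seq_len(tp$copy_count[i])) {
        mut <- mutate_sequence(consensus, tp$target_divergence[i] / 100)
        add("te", sprintf("%s#%d", tp$consensus_id[i], cp), mut$seq,
            list(subclass = tp$subclass[i], realized_div = 100 * mut$realized,
                 target_div = tp$target_divergence[i],
                 consensus_id = tp$consensus_id[i]))
      }
    }
  }
  if (!is.null(config$ssr_plan) && nrow(config$ssr_plan) > 0L) {
    sp <- config$ssr_plan
    for (i in seq_len(nrow(sp))) {
      tract <- strrep(sp$motif[i], sp$repeats[i])
      n_ed <- sp$edits[i]
      if (n_ed > 0L) {
        pos <- sample(nchar(tract), n_ed)
        t2 <- strsplit(tract, "")[[1L]]
        for (p in pos) t2[p] <- sample(setdiff(c("A", "C", "G", "T"), t2[p]), 1L)
        tract <- paste0(t2, collapse = "")
      }
      add("ssr", sprintf("ssr#%d", i), tract,
          list(motif = sp$motif[i], repeats = sp$repeats[i], edits = n_ed))
    }
  }
  if (!is.null(config$gene_plan) && nrow(config$gene_plan) > 0L) {
    gp <- config$gene_plan
    for (i in seq_len(nrow(gp))) {
      glen <- gp$exon_count[i] * gp$exon_len[i] +
        max(0L, gp$exon_count[i] - 1L) * gp$intron_len[i]
      add("gene", sprintf("gene%d", i), random_dna(glen, gc),
          list(exon_count = gp$exon_count[i], exon_len = gp$exon_len[i],
               intron_len = gp$intron_len[i]))
    }
  }
  if (length(config$gap_plan) > 0L) {
    for (i in seq_along(config$gap_plan)) {
      add("gap", sprintf("gap%d", i), strrep("N", config$gap_plan[i]))
    }
  }

  nf <- length(feats)
  total <- sum(vapply(feats, function(f) f$len, 0))
  slack <- L - total
  if (slack < nf + 1L) {
    # name the first feature that no longer fits with 1 bp separators
    used <- 1L
    for (f in feats) {
      if (used + f$len + 1L > L + 1L) {
        stop("infeasible plan: feature '", f$id, "' does not fit in the genome")
      }
      used <- used + f$len + 1L
    }
    stop("infeasible plan: features do not fit in the genome")
  }

  # random background spacers, each at least 1 bp
  spacer <- rep(1L, nf + 1L)
  extra <- slack - (nf + 1L)
  if (extra > 0L && nf + 1L > 0L) {
    spread <- tabulate(sample.int(nf + 1L, extra, replace = TRUE), nbins = nf + 1L)
    spacer <- spacer + spread
  }

  # guard characters so planted SSR tracts stay maximal tandem runs: the
  # background base next to a tract must not continue its period
  guards <- lapply(feats, function(f) {
    if (f$type != "ssr") return(list(left = NULL, right = NULL))
    k <- nchar(f$motif)
    list(left = substr(f$seq, k, k),
         right = substr(f$seq, f$len - k + 1L, f$len - k + 1L))
  })
  pieces <- character(2L * nf + 1L)
  pos <- 1L
  for (i in seq_len(nf)) {
    last_not <- guards[[i]]$left
    first_not <- if (i > 1L) guards[[i - 1L]]$right else NULL
    pieces[2L * i - 1L] <- guarded_dna(spacer[i], gc, first_not, last_not)
    pos <- pos + spacer[i]
    feats[[i]]$start <- pos
    feats[[i]]$end <- pos + feats[[i]]$len - 1L
    pieces[2L * i] <- feats[[i]]$seq
    pos <- pos + feats[[i]]$len
  }
  pieces[2L * nf + 1L] <- guarded_dna(spacer[nf + 1L], gc,
                                      if (nf > 0L) guards[[nf]]$right else NULL,
                                      NULL)
  genome_str <- paste0(pieces, collapse = "")
  stopifnot(nchar(genome_str) == L)
  genome <- new_genome_sequence("synth1", genome_str)

  # RepeatMasker-style records for planted TEs
  te_feats <- Filter(function(f) f$type == "te", feats)
  repeats <- if (length(te_feats)) {
    data.frame(
      sw_score = vapply(te_feats, function(f) as.numeric(f$len), 0),
      pct_div = round(vapply(te_feats, function(f) f$realized_div, 0), 4),
      pct_del = 0, pct_ins = 0,
      query_id = "synth1",
      q_begin = vapply(te_feats, function(f) f$start, 0L),
      q_end = vapply(te_feats, function(f) f$end, 0L),
      strand = "+",
      repeat_name = vapply(te_feats, function(f) f$consensus_id, ""),
      class_family = unname(SYNTH_CLASS_FAMILY[vapply(te_feats, function(f) f$subclass, "")]),
      record_id = seq_along(te_feats),
      stringsAsFactors = FALSE
    )
  } else {
    empty_repeat_table()
  }

  # GFF3-style rows for planted genes
  gene_feats <- Filter(function(f) f$type == "gene", feats)
  genes <- gff_rows_for_genes(gene_feats)

  truth <- do.call(rbind, lapply(feats, function(f) {
    data.frame(
      type = f$type, id = f$id, start = f$start, end = f$end,
      true_divergence = if (f$type == "te") f$realized_div else NA_real_,
      target_divergence = if (f$type == "te") f$target_div else NA_real_,
      subclass = if (f$type == "te") f$subclass else NA_character_,
      motif = if (f$type == "ssr") f$motif else NA_character_,
      repeats = if (f$type == "ssr") f$repeats else NA_real_,
      edits = if (f$type == "ssr") f$edits else NA_integer_,
      sequence = f$seq,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(truth)) truth <- data.frame()

  structure(
    list(genome = structure(setNames(list(genome), "synth1"), class = "genome_set"),
         repeats = repeats, genes = genes, truth = truth, config = config),
    class = "synthetic_genome"
  )
}

gff_rows_for_genes <- function(gene_feats) {
  rows <- list()
  for (f in gene_feats) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = "synth1", source = "repeatscape_sim", feature_type = "gene",
      start = f$start, end = f$end, strand = "+", id = f$id,
      parent = NA_character_, stringsAsFactors = FALSE
    )
    for (e in seq_len(f$exon_count)) {
      es <- f$start + (e - 1L) * (f$exon_len + f$intron_len)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = "synth1", source = "repeatscape_sim", feature_type = "exon",
        start = es, end = es + f$exon_len - 1L, strand = "+",
        id = sprintf("%s.exon%d", f$id, e), parent = f$id,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(0), source = character(0),
                      feature_type = character(0), start = integer(0),
                      end = integer(0), strand = character(0), id = character(0),
                      parent = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a GFF3 feature table
#'
#' @param features Feature data.frame in [read_gff3()] layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  lines <- "##gff-version 3"
  if (nrow(features) > 0L) {
    attrs <- ifelse(
      is.na(features$parent),
      sprintf("ID=%s", features$id),
      sprintf("ID=%s;Parent=%s", features$id, features$parent)
    )
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
      features$seq_id, features$source, features$feature_type,
      features$start, features$end, features$strand, attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write all files of a simulated genome
#'
#' @param sim A `synthetic_genome` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    out = file.path(dir, "repeats.out"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(sim$genome, paths[["fasta"]])
  write_repeatmasker_out(sim$repeats, paths[["out"]])
  write_gff3(sim$genes, paths[["gff"]])
  write_tsv(sim$truth, paths[["truth"]])
  paths
}

#' Simulate 5'/3' LTR pairs of known insertion age
#'
#' Each element starts from one random ancestral LTR; the two copies then
#' independently accumulate substitutions with per-site probability
#' `rate x age` (uniform over the three alternative bases), so the expected
#' pairwise divergence is `k ~= 2 x rate x age` and the dating pipeline
#' should recover the planted age.
#'
#' @param n Number of elements.
#' @param ages Insertion ages in years (recycled to length `n`); must be
#'   nonnegative.
#' @param rate Substitution rate per site per year.
#' @param consensus_length LTR length in bp.
#' @param seed Integer seed.
#' @return List of elements, each with `element_id`, `seq5`, `seq3`,
#'   `true_age`.
#' @export
simulate_ltr_pairs <- function(n, ages, rate = LTR_NEUTRAL_RATE,
                               consensus_length = 1000, seed = 1) {
  stopifnot(n >= 1, consensus_length >= 1, rate > 0)
  if (any(ages < 0)) stop("ages must be nonnegative")
  ages <- rep_len(ages, n)
  set_sim_seed(seed)
  lapply(seq_len(n), function(i) {
    anc <- random_dna(consensus_length, 0.5)
    q <- rate * ages[i]
    list(
      element_id = sprintf("ltr%d", i),
      seq5 = mutate_sequence(anc, q)$seq,
      seq3 = mutate_sequence(anc, q)$seq,
      true_age = ages[i]
    )
  })
}

#' Write simulated LTR pairs as a paired FASTA
#'
#' Records are named `<element>_5` and `<element>_3`, the layout accepted by
#' [ltr_insertion_times()].
#'
#' @param pairs Output of [simulate_ltr_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ltr_pairs <- function(pairs, path) {
  lines <- unlist(lapply(pairs, function(p) {
    c(paste0(">", p$element_id, "_5"), p$seq5,
      paste0(">", p$element_id, "_3"), p$seq3)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Trait increments along each branch are independent Gaussian with variance
#' `sigma2 x branch_length`, starting from `root_state` at the root.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param root_state Trait value at the root.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, root_state, sigma2, seed = 1) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set_sim_seed(seed)
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  state <- numeric(n_tip + tree$Nnode)
  state[n_tip + 1L] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    c_ <- tree$edge[e, 2L]
    state[c_] <- state[p] + rnorm(1L, 0, sqrt(sigma2 * tree$edge.length[e]))
  }
  setNames(state[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a species trait panel
#'
#' Emulates a comparative panel of anuran-scale genomes: genome sizes uniform
#' on 1.1-6.8 Gb; total repeat content and SSR count linear in genome size
#' plus Gaussian noise calibrated so the population R-squared of each
#' regression hits a target; and a species-habitat table drawn from a pool of
#' IUCN-style habitat classes.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed.
#' @param r2_repeat Target population R-squared of repeat bp on genome size.
#' @param r2_ssr Target population R-squared of SSR count on genome size.
#' @return List with `traits` (data.frame `species`, `genome_size` in Gb,
#'   `repeat_bp`, `ssr_count`) and `habitat` (data.frame `species`,
#'   `habitat_type`).
#' @export
simulate_species_panel <- function(n_species = 14, seed = 1,
                                   r2_repeat = 0.95, r2_ssr = 0.89) {
  if (n_species < 2) stop("n_species must be at least 2: regression undefined")
  stopifnot(r2_repeat > 0, r2_repeat <= 1, r2_ssr > 0, r2_ssr <= 1)
  set_sim_seed(seed)
  size <- runif(n_species, 1.1, 6.8)
  var_x <- (6.8 - 1.1)^2 / 12  # population variance of the size distribution

  noise_sd <- function(b, r2) {
    if (r2 >= 1) 0 else sqrt(b^2 * var_x * (1 - r2) / r2)
  }
  # repeat content rises from ~34% of a 1.1 Gb genome to ~62% of a 6.8 Gb one
  b_rep <- 0.68e9
  a_rep <- -0.38e9
  repeat_bp <- a_rep + b_rep * size + rnorm(n_species, 0, noise_sd(b_rep, r2_repeat))
  b_ssr <- 6e5
  a_ssr <- 2e5
  ssr_count <- round(a_ssr + b_ssr * size + rnorm(n_species, 0, noise_sd(b_ssr, r2_ssr)))

  species <- sprintf("sp%02d", seq_len(n_species))
  pool <- c("Forest", "Savanna", "Shrubland", "Grassland", "Wetlands",
            "Rocky areas", "Desert", "Artificial-Terrestrial",
            "Artificial-Aquatic", "Caves")
  habitat <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    k <- sample(1:6, 1L)
    data.frame(species = species[i],
               habitat_type = sample(pool, k),
               stringsAsFactors = FALSE)
  }))
  list(
    traits = data.frame(species = species, genome_size = size,
                        repeat_bp = repeat_bp, ssr_count = ssr_count,
                        stringsAsFactors = FALSE),
    habitat = habitat
  )
}
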