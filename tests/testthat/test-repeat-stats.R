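make_records <- function(pct_div, span, class_family, start = NULL) {
  n <- length(pct_div)
  span <- rep_len(span, n)
  class_family <- rep_len(class_family, n)
  if (is.null(start)) start <- cumsum(c(1, head(span, -1) + 10))
  data.frame(
    sw_score = span, pct_div = pct_div, pct_del = 0, pct_ins = 0,
    query_id = "chr1", q_begin = as.integer(start),
    q_end = as.integer(start + span - 1L), strand = "+",
    repeat_name = "rep", class_family = class_family,
    record_id = seq_len(n), stringsAsFactors = FALSE
  )
}

test_that("classify_te maps class/family strings totally", {
  expect_equal(
    classify_te(c("LINE/L1", "SINE/tRNA", "LTR/Gypsy", "DNA/hAT", "DNA?/hAT",
                  "RC/Helitron", "Satellite", "Simple_repeat", "Low_complexity",
                  "Unknown", "Unspecified", "ARTEFACT", "rRNA")),
    c("LINE", "SINE", "LTR", "DNA", "DNA", "ROLLING_CIRCLE", "SATELLITE",
      "SIMPLE", "LOW_COMPLEXITY", "UNKNOWN", "UNKNOWN", "OTHER", "OTHER")
  )
})

test_that("compute_te_totals sums spans per subclass", {
  r <- make_records(1.0, 500, "LINE/L1", start = 1000)
  tot <- compute_te_totals(r, 10000)
  expect_equal(tot$bp[tot$subclass == "LINE"], 500)
  expect_equal(tot$pct_of_genome[tot$subclass == "LINE"], 5.0)
  expect_true(all(tot$bp[tot$subclass != "LINE"] == 0))

  empty <- compute_te_totals(repeatscape:::empty_repeat_table(), 1000)
  expect_true(all(empty$bp == 0))

  r_over <- make_records(1.0, 500, "LINE/L1", start = 9900)
  expect_error(compute_te_totals(r_over, 10000), "beyond")
})

test_that("merge mode counts overlapping identical records once", {
  r <- rbind(make_records(1, 500, "LINE/L1", start = 100),
             make_records(1, 500, "LINE/L1", start = 100))
  raw <- compute_te_totals(r, 10000)
  merged <- compute_te_totals(r, 10000, merge = TRUE)
  expect_equal(raw$bp[raw$subclass == "LINE"], 1000)
  expect_equal(merged$bp[merged$subclass == "LINE"], 500)
})

test_that("compute_landscape bins coverage by divergence", {
  r <- make_records(3.4, 500, "LINE/L1", start = 100)
  ls <- compute_landscape(r, 10000)
  expect_s3_class(ls, "divergence_landscape")
  expect_equal(unname(ls$coverage[4, "LINE"]), 5.0)  # bin [3,4)
  expect_equal(sum(ls$coverage), 5.0)

  ls0 <- compute_landscape(repeatscape:::empty_repeat_table(), 10000)
  expect_true(all(ls0$coverage == 0))

  r50 <- make_records(50, 100, "LINE/L1", start = 100)
  ls50 <- compute_landscape(r50, 10000, max_div = 50)
  expect_equal(ls50$dropped_records, 1L)
  expect_true(all(ls50$coverage == 0))

  expect_error(compute_landscape(r, 0), "positive")
  expect_error(compute_landscape(r, 1000, max_div = 50, bin_width = 3), "divide")
})

test_that("landscape bin totals reconcile with compute_te_totals", {
  set.seed(11)
  r <- make_records(runif(200, 0, 60), sample(50:400, 200, replace = TRUE),
                    sample(c("LINE/L1", "LTR/Gypsy", "DNA/hAT"), 200, replace = TRUE))
  L <- max(r$q_end) + 100
  ls <- compute_landscape(r, L)
  tot <- compute_te_totals(r, L)
  dropped_pct <- 100 * ls$dropped_bp / L
  expect_equal(sum(ls$coverage), sum(tot$pct_of_genome) - dropped_pct,
               tolerance = 1e-12)
  # per-subclass reconciliation for subclasses with no dropped records
  sub <- classify_te(r$class_family)
  for (s in c("LINE", "LTR", "DNA")) {
    drop_bp <- sum((r$q_end - r$q_begin + 1)[sub == s & r$pct_div >= 50])
    expect_equal(sum(ls$coverage[, s]),
                 tot$pct_of_genome[tot$subclass == s] - 100 * drop_bp / L,
                 tolerance = 1e-12)
  }
})

test_that("landscape shapes are classified per the peak rules", {
  # single young peak at bin [2,3)
  r <- make_records(rep(2.5, 50), 200, "LINE/L1")
  expect_equal(classify_landscape_shape(compute_landscape(r, 1e5))$label, "L_SHAPED")

  # peaks near 4% and 30%
  r2 <- make_records(c(rep(4.5, 50), rep(30.5, 50)), 200, "LINE/L1")
  s2 <- classify_landscape_shape(compute_landscape(r2, 1e5))
  expect_equal(s2$label, "BIMODAL")

  # three separated peaks
  r3 <- make_records(c(rep(3.5, 40), rep(18.5, 40), rep(33.5, 40)), 200, "LINE/L1")
  expect_equal(classify_landscape_shape(compute_landscape(r3, 1e5))$label, "MULTI_PEAKED")

  # one old peak
  r4 <- make_records(rep(25.5, 50), 200, "LINE/L1")
  expect_equal(classify_landscape_shape(compute_landscape(r4, 1e5))$label, "UNIMODAL_OLD")

  ls0 <- compute_landscape(repeatscape:::empty_repeat_table(), 1e5)
  expect_error(classify_landscape_shape(ls0), "no coverage")
})

test_that("Simpson index matches its formula and the resampling oracle", {
  expect_equal(simpson_index(c(40, 30, 20, 10)), 1 - 2900 / 9900)
  expect_equal(simpson_index(c(LTR = 100)), 0)
  # analytic limit: 4 equal counts, D -> 0.75 as N grows
  expect_equal(simpson_index(rep(1e7, 4)), 0.75, tolerance = 1e-6)
  expect_error(simpson_index(c(1, 0)), "undefined")
  expect_error(simpson_index(c(-1, 5)), "nonnegative")

  # brute-force oracle: enumerate all ordered pairs drawn without replacement
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:60, sample(2:5, 1))
    labels <- rep(seq_along(n), n)
    pairs_differ <- outer(labels, labels, "!=")
    diag(pairs_differ) <- NA
    expect_equal(simpson_index(n), mean(pairs_differ, na.rm = TRUE))
  }
})

test_that("Shannon index matches its formula", {
  expect_equal(shannon_index(c(100)), 0)
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(2, 1, 1)), 1.5 * log(2))
  expect_error(shannon_index(numeric(0)), "undefined")
  # upper bound: H <= ln(number of nonzero subclasses)
  set.seed(7)
  for (rep in 1:10) {
    n <- runif(sample(2:6, 1), 0, 100)
    expect_lte(shannon_index(n), log(sum(n > 0)) + 1e-12)
  }
})

test_that("diversity indices are permutation-invariant", {
  set.seed(9)
  n <- c(400, 30, 125, 7)
  for (rep in 1:5) {
    perm <- sample(n)
    expect_equal(simpson_index(perm), simpson_index(n))
    expect_equal(shannon_index(perm), shannon_index(n))
  }
})

test_that("te_diversity computes over the four interspersed subclasses", {
  r <- make_records(rep(1, 5), c(400, 30, 125, 7, 999),
                    c("LINE/L1", "SINE/tRNA", "LTR/Gypsy", "DNA/hAT", "Satellite"))
  dv <- te_diversity(r)
  expect_equal(unname(dv$n), c(400, 30, 125, 7))  # satellite excluded
  expect_equal(dv$N, 562)
  expect_equal(dv$simpson, simpson_index(c(400, 30, 125, 7)))
  dv_fam <- te_diversity(r, level = "family")
  expect_equal(dv_fam$N, 1561)
})

test_that("planted divergence cohorts are recovered as landscape shapes", {
  cfg2 <- simulation_config(
    seed = 21, genome_length = 150000,
    te_plan = data.frame(
      consensus_id = c("young", "old"), subclass = c("LINE", "LTR"),
      copy_count = c(50, 50), target_divergence = c(3, 30),
      consensus_length = c(400, 400), stringsAsFactors = FALSE
    )
  )
  sim2 <- simulate_genome(cfg2)
  shape2 <- classify_landscape_shape(compute_landscape(sim2$repeats, 150000))
  expect_equal(shape2$label, "BIMODAL")

  cfg1 <- simulation_config(
    seed = 22, genome_length = 80000,
    te_plan = data.frame(
      consensus_id = "young", subclass = "LINE", copy_count = 60,
      target_divergence = 2, consensus_length = 400, stringsAsFactors = FALSE
    )
  )
  sim1 <- simulate_genome(cfg1)
  shape1 <- classify_landscape_shape(compute_landscape(sim1$repeats, 80000))
  expect_equal(shape1$label, "L_SHAPED")
})
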