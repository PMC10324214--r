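test_that("standardize_motif picks the minimal rotation over both strands", {
  expect_equal(standardize_motif("GT"), "AC")
  expect_equal(standardize_motif("A"), "A")
  expect_equal(standardize_motif("GAA"), "AAG")
  expect_error(standardize_motif("AXT"), "A, C, G, T")
  expect_error(standardize_motif("ACGTACG"), "length")
})

test_that("standardize_motif is idempotent and rotation/revcomp invariant", {
  set.seed(5)
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    m <- paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    std <- standardize_motif(m)
    expect_equal(standardize_motif(std), std)
    for (rot in repeatscape:::rotations(m)) {
      expect_equal(standardize_motif(rot), std)
    }
    expect_equal(standardize_motif(repeatscape:::revcomp(m)), std)
  }
})

test_that("perfect SSRs respect thresholds and maximality", {
  expect_equal(nrow(find_perfect_ssrs(strrep("A", 12))), 1L)
  a12 <- find_perfect_ssrs(strrep("A", 12))
  expect_equal(a12$repeats, 12)
  expect_equal(a12$length, 12L)
  expect_equal(nrow(find_perfect_ssrs(strrep("A", 11))), 0L)

  flank <- function(x) paste0("GCGGATGTCG", x, "TGCAGGCATG")
  hit <- find_perfect_ssrs(flank(strrep("AC", 7)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 14L)
  expect_equal(hit$motif, "AC")
  expect_equal(nrow(find_perfect_ssrs(flank(strrep("AC", 6)))), 0L)
})

test_that("a tandem of a shorter motif is reported under the shorter motif", {
  # (ATAT)x4 is (AT)x8: reported as the dinucleotide, never the tetra
  hit <- find_perfect_ssrs(paste0("GCGGC", strrep("ATAT", 4), "GGCCG"))
  expect_equal(hit$motif, "AT")
  expect_equal(hit$repeats, 8)
})

test_that("runs containing N are never reported", {
  hit <- find_perfect_ssrs(paste0(strrep("A", 6), "N", strrep("A", 6)))
  expect_equal(nrow(hit), 0L)
  hit2 <- find_perfect_ssrs(paste0(strrep("A", 12), "N", strrep("A", 12)))
  expect_equal(nrow(hit2), 2L)
  expect_true(all(hit2$length == 12L))
})

test_that("perfect SSR scan equals the exhaustive enumeration oracle", {
  set.seed(101)
  thr <- c(`1` = 12, `2` = 7, `3` = 5, `4` = 4, `5` = 4, `6` = 4)
  for (rep in 1:15) {
    # low-entropy alphabet mixes make tandem runs frequent
    gc <- runif(1, 0.2, 0.8)
    s <- random_dna_string(3000, gc)
    # splice in some planted runs to exercise all motif lengths
    s <- paste0(s, "AAAAAAAAAAAAA", random_dna_string(50),
                strrep("ACG", 6), random_dna_string(50), strrep("ACGT", 5))
    got <- find_perfect_ssrs(s, thr)
    want <- oracle_perfect_ssrs(s, thr)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$motif, want$motif)
    expect_equal(got$repeats, want$repeats)
  }
})

test_that("imperfect SSRs are found by seed-and-extend", {
  # one interruption: both arms joined in a single imperfect locus
  s <- paste0("GCGGATGTCG", strrep("AC", 5), "T", strrep("AC", 5), "TGCAGGCATG")
  hit <- find_imperfect_ssrs(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$edits, 1L)
  expect_equal(hit$start, 11L)
  expect_equal(hit$end, 31L)

  # an exact perfect repeat is not re-reported as imperfect
  expect_equal(nrow(find_imperfect_ssrs(paste0("GCGGATGTCG", strrep("AC", 7)))), 0L)
})

test_that("every reported imperfect locus re-scores at or above min_score", {
  set.seed(33)
  rescore <- function(locus, s) {
    # align the locus sequence against a perfect tandem of its motif
    obs <- substr(s, locus$start, locus$end)
    best <- -Inf
    for (phase in repeatscape:::rotations(locus$motif)) {
      ref <- strrep(phase, ceiling(nchar(obs) / nchar(locus$motif)) + 1)
      for (len in max(1, nchar(obs) - locus$edits - 1):(nchar(obs) + locus$edits + 1)) {
        aln <- align_pair(obs, substr(ref, 1, len))
        best <- max(best, aln$score)
      }
    }
    best
  }
  n_checked <- 0L
  for (rep in 1:3) {
    # random background plus planted interrupted tracts
    s <- paste0(
      random_dna_string(4000, 0.5),
      strrep("AC", 4), "T", strrep("AC", 4), random_dna_string(2000, 0.5),
      strrep("AAG", 4), "AG", strrep("AAG", 4), random_dna_string(4000, 0.5)
    )
    loci <- find_imperfect_ssrs(s)
    for (i in seq_len(nrow(loci))) {
      expect_gte(rescore(loci[i, ], s), 12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 2L)
})

test_that("planted SSR tracts are recovered with exact coordinates", {
  cfg <- simulation_config(
    seed = 77, genome_length = 60000,
    ssr_plan = data.frame(
      motif = c("A", "AC", "AAG", "ACGT", "AACGT", "AACGGT"),
      repeats = c(15L, 9L, 6L, 5L, 5L, 5L),
      edits = 0L, stringsAsFactors = FALSE
    ),
    gap_plan = c(40)
  )
  sim <- simulate_genome(cfg)
  loci <- find_perfect_ssrs(sim$genome$synth1)
  truth <- sim$truth[sim$truth$type == "ssr", ]
  for (i in seq_len(nrow(truth))) {
    j <- which(loci$start == truth$start[i])
    expect_length(j, 1L)
    expect_equal(loci$end[j], truth$end[i])
    expect_equal(loci$motif[j], truth$motif[i])
  }
  # no locus overlaps the planted N run
  gap <- sim$truth[sim$truth$type == "gap", ]
  expect_false(any(loci$start <= gap$end & loci$end >= gap$start))
})

test_that("summarize_ssrs computes abundance and density per Mb of valid length", {
  loci <- data.frame(
    seq_id = "s", start = 1L, end = 15L, motif = c(rep("A", 4), rep("AC", 6)),
    standard_motif = "A", repeats = 15, length = 15L, kind = "PERFECT",
    edits = 0L, stringsAsFactors = FALSE
  )
  sm <- summarize_ssrs(loci, 1e6)
  all_row <- sm[sm$motif_class == "all", ]
  expect_equal(all_row$locus_count, 10L)
  expect_equal(all_row$total_bp, 150)
  expect_equal(all_row$relative_abundance, 10)
  expect_equal(all_row$relative_density, 150)
  expect_equal(all_row$pct_of_genome, 0.015)
  expect_equal(sm$locus_count[sm$motif_class == "mono"], 4L)
  expect_equal(sm$locus_count[sm$motif_class == "di"], 6L)
  expect_equal(sum(sm$locus_count[sm$motif_class != "all"]), all_row$locus_count)

  none <- summarize_ssrs(repeatscape:::empty_ssr_table(), 1e6)
  expect_true(all(none$locus_count == 0))
  expect_true(all(none$relative_density == 0))
  expect_error(summarize_ssrs(loci, 0), "positive")
})
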