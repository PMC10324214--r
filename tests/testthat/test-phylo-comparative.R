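test_that("ancestral states match closed-form cases", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(anc_states_ml(t2, c(A = 2, B = 4))$estimate, 3.0)

  t_uneven <- ape::read.tree(text = "(A:1,B:3);")
  expect_equal(anc_states_ml(t_uneven, c(A = 0, B = 4))$estimate, 1.0)

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(anc_states_ml(star, c(A = 1, B = 2, C = 3))$estimate, 2.0)
})

test_that("ancestral states equal the multivariate-normal conditioning oracle", {
  set.seed(55)
  for (rep in 1:20) {
    tree <- random_tree(sample(3:8, 1))
    x <- setNames(rnorm(ape::Ntip(tree), 5, 2), tree$tip.label)
    got <- anc_states_ml(tree, x)
    want <- oracle_anc_states(tree, x)
    expect_lt(max(abs(got$estimate - want$estimate)), 1e-8)
    expect_lt(max(abs(got$variance - want$variance)), 1e-8)
    expect_equal(attr(got, "sigma2"), want$sigma2, tolerance = 1e-10)
  }
})

test_that("ancestral estimates agree with phytools::fastAnc", {
  set.seed(56)
  for (rep in 1:5) {
    tree <- random_tree(8)
    x <- setNames(rnorm(8, 0, 3), tree$tip.label)
    got <- anc_states_ml(tree, x)
    ref <- phytools::fastAnc(tree, x)
    expect_equal(got$estimate, unname(as.numeric(ref)), tolerance = 1e-6)
  }
})

test_that("reconstruction is location/scale equivariant and rejects bad input", {
  set.seed(57)
  tree <- random_tree(6)
  x <- setNames(rnorm(6), tree$tip.label)
  base <- anc_states_ml(tree, x)
  shifted <- anc_states_ml(tree, 3 * x + 7)
  expect_equal(shifted$estimate, 3 * base$estimate + 7)
  expect_equal(shifted$variance, 9 * base$variance)

  expect_error(anc_states_ml(tree, x[-1]), "without a trait")
  tree0 <- tree
  tree0$edge.length[1] <- 0
  expect_error(anc_states_ml(tree0, x), "zero-length")
})

test_that("polytomies are handled natively", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  x <- c(A = 1, B = 2, C = 3, D = 10)
  got <- anc_states_ml(poly, x)
  want <- oracle_anc_states(poly, x)
  expect_lt(max(abs(got$estimate - want$estimate)), 1e-10)
})

test_that("Brownian simulation matches its Gaussian oracle", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  flat <- simulate_bm_traits(t2, root_state = 5, sigma2 = 0, seed = 1)
  expect_equal(unname(flat), c(5, 5))
  expect_identical(simulate_bm_traits(t2, 0, 1, seed = 3),
                   simulate_bm_traits(t2, 0, 1, seed = 3))

  # tip variance ~= sigma2 * depth over replicates
  reps <- vapply(1:2000, function(i) simulate_bm_traits(t2, 0, 1, seed = i)[["A"]], 0)
  expect_equal(var(reps), 1.0, tolerance = 0.07)
})

test_that("root-state recovery is unbiased over replicates", {
  set.seed(58)
  tree <- random_tree(10)
  roots <- vapply(1:300, function(i) {
    x <- simulate_bm_traits(tree, root_state = 2, sigma2 = 0.5, seed = 1000 + i)
    attr(anc_states_ml(tree, x), "root")
  }, 0)
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - 2), 2 * se + 1e-9)
})

test_that("ols_fit matches closed-form least squares", {
  f <- ols_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  fc <- ols_fit(1:5, rep(3, 5))
  expect_equal(fc$r_squared, 0)

  f2 <- ols_fit(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(f2$slope, 0.6)
  expect_equal(f2$r_squared, 0.36)

  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ols_fit(1:2, 1:2), "at least 3")

  # R^2 invariant under linear rescaling of both variables
  set.seed(59)
  x <- rnorm(20)
  y <- 2 * x + rnorm(20)
  expect_equal(ols_fit(10 * x - 3, -2 * y + 5)$r_squared, ols_fit(x, y)$r_squared)
})

test_that("niche_width counts distinct habitat types with set semantics", {
  hab <- data.frame(
    species = c("a", "a", "a", "a", "b"),
    habitat_type = c("Forest", "Wetlands", "Grassland", "Forest", "Desert"),
    stringsAsFactors = FALSE
  )
  nw <- niche_width(hab)
  expect_equal(nw$niche_width[nw$species == "a"], 3L)
  expect_equal(nw$niche_width[nw$species == "b"], 1L)

  expect_warning(nw2 <- niche_width(hab, all_species = c("a", "b", "c")),
                 "excluded")
  expect_equal(attr(nw2, "excluded"), "c")
})

test_that("correlate_panel fits every metric against genome size", {
  panel <- simulate_species_panel(14, seed = 3, r2_repeat = 1, r2_ssr = 1)
  res <- correlate_panel(panel$traits)
  expect_setequal(res$metric, c("repeat_bp", "ssr_count"))
  expect_equal(res$r_squared, c(1, 1), tolerance = 1e-9)

  panel$traits$broken <- NA_real_
  expect_warning(res2 <- correlate_panel(panel$traits), "skipped")
  expect_false("broken" %in% res2$metric)
})

test_that("panel regressions recover the configured population R-squared", {
  r2s <- vapply(1:120, function(i) {
    p <- simulate_species_panel(14, seed = 5000 + i, r2_repeat = 0.9)
    correlate_panel(p$traits["ssr_count" != names(p$traits)])$r_squared[1]
  }, 0)
  expect_equal(mean(r2s), 0.9, tolerance = 0.06)
})
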