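test_that("posterior mean slope tracks the closed-form OLS slope", {
  set.seed(5)
  n <- 300
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, sd = 0.8)
  zx <- (x - mean(x)) / sd(x); zy <- (y - mean(y)) / sd(y)
  ols <- unname(coef(lm(zy ~ zx))[2])
  set.seed(99)
  fit <- bayes_slr(zx, zy, n_draws = 4000)
  expect_lt(abs(fit$slope_mean - ols), 0.02)

  # perfectly correlated standardized data: slope concentrates at 1
  set.seed(100)
  fit1 <- bayes_slr(zx, zx, n_draws = 2000)
  expect_lt(abs(fit1$slope_mean - 1), 0.02)

  # independent data: slope concentrates at the (near-zero) OLS value
  set.seed(101)
  y0 <- rnorm(n)
  zy0 <- (y0 - mean(y0)) / sd(y0)
  ols0 <- unname(coef(lm(zy0 ~ zx))[2])
  fit0 <- bayes_slr(zx, zy0, n_draws = 4000)
  expect_lt(abs(fit0$slope_mean - ols0), 0.02)
})

test_that("select_index picks the least richness-coupled index", {
  b <- scenario_bundle(small_scenario(51))
  sel <- select_index(b$scores, seed = 51, n_draws = 2000)
  expect_true(sel$chosen %in% c("AvTD", "PDi"))
  z <- function(v) (v - mean(v)) / sd(v)
  ols_pd <- unname(coef(lm(z(b$scores$pdi) ~ z(b$scores$richness)))[2])
  ols_avtd <- unname(coef(lm(z(b$scores$avtd) ~ z(b$scores$richness)))[2])
  expect_lt(abs(sel$slope_pd - ols_pd), 0.02)
  expect_lt(abs(sel$slope_avtd - ols_avtd), 0.02)
  # degenerate variance errors name the offender
  flat <- b$scores; flat$avtd <- 1
  expect_error(select_index(flat, seed = 1), "avtd")
})

test_that("quantile classification forms balanced rank groups", {
  q <- classify_quantiles(1:10)
  expect_equal(as.character(q), rep(paste0("Q", 1:5), each = 2))
  expect_equal(which(q == "Q5"), c(9L, 10L))

  # ties broken by stable cell id
  q2 <- classify_quantiles(rep(1, 10), cell_ids = 10:1)
  expect_equal(as.character(q2), rev(rep(paste0("Q", 1:5), each = 2)))

  # large random input: balanced sizes, ordered group ranges
  set.seed(8)
  v <- runif(1000)
  q3 <- classify_quantiles(v)
  expect_true(all(table(q3) == 200))
  expect_gte(min(v[q3 == "Q5"]), max(v[q3 == "Q4"]))
  expect_gte(min(v[q3 == "Q2"]), max(v[q3 == "Q1"]))

  # idempotent and permutation-invariant up to the tie rule
  perm <- sample(1000)
  q4 <- classify_quantiles(v[perm], cell_ids = perm)
  expect_equal(as.character(q4), as.character(q3)[perm])

  expect_error(classify_quantiles(1:4), "at least 5")

  # value-break mode exists and respects ordering
  q5 <- classify_quantiles(c(1, 1, 1, 1, 1, 1, 2, 3, 4, 5), method = "breaks")
  expect_true(as.integer(sub("Q", "", q5[10])) >= 4)
})

test_that("jackknife at full subset size keeps every cell in place", {
  b <- scenario_bundle(small_scenario(61))
  jk <- jackknife_stability(b$ts, b$grid, subset_fractions = 1, reps = 5,
                            seed = 61, scores = b$scores)
  expect_true(all(jk$per_cell$stay_prob == 1))
  expect_equal(jk$per_size$mean_stay_prob, 1)
})

test_that("jackknife is seed-deterministic and self-tallying", {
  b <- scenario_bundle(small_scenario(62))
  jk1 <- jackknife_stability(b$ts, b$grid, reps = 4, seed = 3, scores = b$scores)
  jk2 <- jackknife_stability(b$ts, b$grid, reps = 4, seed = 3, scores = b$scores)
  expect_identical(jk1$per_cell, jk2$per_cell)

  # independent tally over the stored replicate labels
  full <- as.character(jk1$per_cell$full_label)
  for (s in unique(jk1$replicate_sizes)) {
    cols <- which(jk1$replicate_sizes == s)
    tally <- mean(jk1$replicate_labels[, cols] == full)
    expect_equal(jk1$per_size$mean_stay_prob[jk1$per_size$n_trees == s], tally)
  }
  overall <- rowMeans(jk1$replicate_labels == full)
  expect_equal(jk1$per_cell$stay_prob, unname(overall))

  # exact binomial interval brackets the estimate
  expect_true(all(jk1$per_cell$ci_low <= jk1$per_cell$stay_prob + 1e-12))
  expect_true(all(jk1$per_cell$ci_high >= jk1$per_cell$stay_prob - 1e-12))

  expect_error(jackknife_stability(b$ts, b$grid, subset_fractions = 2,
                                   scores = b$scores), "subset size")
})

test_that("planted dissimilarity blocks are recovered with silhouette 1", {
  n_per <- 4
  b <- matrix(1, 3 * n_per, 3 * n_per)
  for (k in 0:2) b[k * n_per + 1:n_per, k * n_per + 1:n_per] <- 0
  diag(b) <- 0
  bm <- structure(list(labels = seq_len(12), b = b), class = "beta_matrix")
  cl <- cluster_cells(bm, k = 3)
  expect_equal(cl$mean_silhouette, 1)
  truth <- rep(1:3, each = n_per)
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
  expect_named(cl$silhouette_by_k)
})

test_that("all-equal dissimilarities give silhouette near zero", {
  n <- 9
  b <- matrix(0.5, n, n); diag(b) <- 0
  bm <- structure(list(labels = seq_len(n), b = b), class = "beta_matrix")
  cl <- cluster_cells(bm, k = 3, k_range = 2:3)
  expect_lt(abs(cl$mean_silhouette), 0.3)
})

test_that("silhouette widths match the direct a(i)/b(i) formula", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 15
    centers <- sample(1:3, n, replace = TRUE)
    d <- abs(outer(centers, centers, `-`)) / 3 +
      matrix(runif(n * n, 0, 0.15), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    d <- pmin(d, 1)
    bm <- structure(list(labels = seq_len(n), b = d), class = "beta_matrix")
    cl <- cluster_cells(bm, k = 3, k_range = 2:3)
    lab <- as.integer(sub("C", "", cl$labels))
    expect_lt(max(abs(cl$silhouette - silhouette_oracle(d, lab))), 1e-9)
  }
})

test_that("cluster_cells rejects malformed dissimilarity input", {
  b <- matrix(runif(16, 0, 1), 4, 4)
  bm <- structure(list(labels = 1:4, b = b), class = "beta_matrix")
  expect_error(cluster_cells(bm, k = 2), "symmetric")
  b2 <- matrix(2, 4, 4); diag(b2) <- 0
  bm2 <- structure(list(labels = 1:4, b = b2), class = "beta_matrix")
  expect_error(cluster_cells(bm2, k = 2), "outside")
})
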