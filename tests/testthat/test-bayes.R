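test_that("proposal grid is the inclusive row-major Cartesian product", {
  g <- make_proposal_grid()
  expect_equal(nrow(g), 6000L)                       # 60 radii x 100 thresholds
  expect_equal(unique(g$r_nm), seq(5, 300, 5))
  expect_equal(g$T[1:100], seq(5, 500, 5))           # T is the inner loop
  expect_equal(nrow(make_proposal_grid(50, 50, 5, 10, 10, 5)), 1L)
  expect_equal(make_proposal_grid(5, 8, 10, 5, 8, 10),
               data.frame(r_nm = 5, T = 5))          # step larger than range
})

test_that("all-background labeling has the closed-form score", {
  tbl <- simulate_ground_truth(ground_truth_config(
    n_clusters = 2, locs_per_cluster = 25, seed = 6))
  params <- bayes_params(roi(3000, 3000), p_b = 0.5, alpha = 20)
  s <- score_labels(tbl, rep(0L, nrow(tbl)), params)
  expect_equal(s, nrow(tbl) * log(0.5 / 9e6))

  # one extra far-away background point shifts the score by exactly log(p_b/A)
  tbl2 <- localization_table(c(tbl$x_nm, 2900), c(tbl$y_nm, 2900),
                             c(tbl$sd_nm, 15))
  s2 <- score_labels(tbl2, c(tbl$true_label, 0L), params)
  s1 <- score_labels(tbl, tbl$true_label, params)
  expect_equal(s2 - s1, log(0.5 / 9e6), tolerance = 1e-10)
})

test_that("score is exchangeable and rejects empty cluster labels", {
  set.seed(20)
  tbl <- simulate_ground_truth(ground_truth_config(
    n_clusters = 3, locs_per_cluster = 20, seed = 20))
  params <- bayes_params(roi(3000, 3000))
  perm <- sample(nrow(tbl))
  expect_equal(score_labels(tbl[perm, , drop = FALSE], tbl$true_label[perm],
                            params),
               score_labels(tbl, tbl$true_label, params))
  expect_error(score_labels(tbl, c(rep(0L, nrow(tbl) - 1L), 2L), params),
               "empty cluster")
})

test_that("cluster marginal likelihood matches 2D quadrature to 1e-6", {
  set.seed(21)
  A <- 9e6
  params1 <- function(sigma) bayes_params(roi(3000, 3000), p_b = 0.5,
                                          alpha = 20, sigma_grid_nm = sigma)
  for (case in 1:4) {
    n_k <- sample(3:8, 1)
    sigma <- runif(1, 20, 120)
    x <- rnorm(n_k, 1000, 60)
    y <- rnorm(n_k, 1200, 60)
    sd <- runif(n_k, 5, 45)                          # distinct precisions
    tbl <- localization_table(x, y, sd)
    # isolate log m_k from the full score of the single-cluster labeling
    s <- score_labels(tbl, rep(1L, n_k), params1(sigma))
    crp <- log(20) + lgamma(n_k) + lgamma(20) - lgamma(20 + n_k)
    log_mk <- s - n_k * log(0.5) - crp
    expect_equal(log_mk, quad_marginal(x, y, sd, sigma, A),
                 tolerance = 1e-6)
  }
  # multi-sigma grids average the per-sigma marginals with uniform weights
  n_k <- 5
  x <- rnorm(n_k, 500, 50); y <- rnorm(n_k, 500, 50)
  sd <- runif(n_k, 10, 30)
  tbl <- localization_table(x, y, sd)
  sigmas <- c(25, 50, 100)
  crp <- log(20) + lgamma(n_k) + lgamma(20) - lgamma(20 + n_k)
  per_sigma <- vapply(sigmas, function(s0)
    score_labels(tbl, rep(1L, n_k), params1(s0)) - n_k * log(0.5) - crp, 0)
  combined <- score_labels(tbl, rep(1L, n_k), params1(sigmas)) -
    n_k * log(0.5) - crp
  mx <- max(per_sigma)
  expect_equal(combined, mx + log(mean(exp(per_sigma - mx))), tolerance = 1e-12)
})

test_that("engine results are independent of the worker count", {
  tbl <- simulate_ground_truth(ground_truth_config(
    n_clusters = 3, locs_per_cluster = 30, seed = 31))
  params <- bayes_params(roi(3000, 3000))
  grid <- make_proposal_grid(40, 120, 20, 5, 20, 5)  # 5 x 4 = 20 proposals
  seq_run <- run_engine(tbl, "tomato", grid, params, n_workers = 1)
  par_run <- run_engine(tbl, "tomato", grid, params, n_workers = 4)
  expect_identical(seq_run$scores$log_score, par_run$scores$log_score)
  expect_identical(seq_run$labels, par_run$labels)
  expect_identical(seq_run$best$tomato, par_run$best$tomato)
})

test_that("selection takes the maximum score with the r-then-T tie rule", {
  fake <- structure(list(
    scores = data.frame(method = "dbscan", r_nm = c(10, 5, 5),
                        T = c(5, 10, 5), n_clusters = c(2L, 2L, 2L),
                        log_score = c(-10, -10, -10)),
    labels = list(1L, 2L, 3L)), class = "scored_proposals")
  b <- select_best(fake)
  expect_equal(c(b$r_nm, b$T), c(5, 5))              # smaller r, then smaller T

  one <- structure(list(scores = fake$scores[1, ], labels = list(1L)),
                   class = "scored_proposals")
  expect_equal(select_best(one)$index, 1L)

  set.seed(40)
  fake$scores$log_score <- rnorm(3)
  expect_equal(select_best(fake)$log_score, max(fake$scores$log_score))

  # grid of one proposal: the engine's best is that proposal
  tbl <- simulate_ground_truth(ground_truth_config(
    n_clusters = 2, locs_per_cluster = 15, seed = 32))
  params <- bayes_params(roi(3000, 3000))
  res <- run_engine(tbl, "dbscan", data.frame(r_nm = 50, T = 10), params)
  expect_equal(res$best$dbscan$index, 1L)
})
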