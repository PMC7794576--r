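# Brute-force Bayes posterior for the three-component regression mixture,
# kept deliberately independent of the package's E-step implementation.
brute_force_responsibilities <- function(x, y, init, noise_max = 8) {
  n <- length(y)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    f <- c(init$weights[1] *
             exp(-(y[i] - init$mu_gf)^2 / (2 * init$sigma_gf^2)) /
             sqrt(2 * pi * init$sigma_gf^2),
           init$weights[2] *
             exp(-(y[i] - (init$c_ef - x[i]))^2 / (2 * init$sigma_ef^2)) /
             sqrt(2 * pi * init$sigma_ef^2),
           init$weights[3] * (y[i] >= 0 && y[i] <= noise_max) / noise_max)
    out[i, ] <- f / sum(f)
  }
  out
}

test_that("E-step responsibilities equal brute-force Bayes posteriors", {
  x <- c(0.5, 2, 4, 7, 9, 10, 11, 12, 13, 14)
  y <- c(2.1, 1.9, 2.4, 5.0, 2.9, 2.0, 1.2, 0.3, 7.5, 2.2)
  init <- mixture_init(mu_gf = 2, c_ef = 12, sigma_gf = 0.4, sigma_ef = 0.3,
                       weights = c(0.5, 0.3, 0.2))
  fit <- em_fit(x, y, init = init, max_iter = 1, min_n = 5)
  expect_lt(max(abs(fit$responsibilities -
                      brute_force_responsibilities(x, y, init))), 1e-12)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
})

test_that("EM log-likelihood is monotone non-decreasing at every iteration", {
  d <- sim_mixture_data(n = 1000, seed = 3)
  for (init in list(mixture_init(mu_gf = 1.5, c_ef = 29),
                    mixture_init(mu_gf = 3, c_ef = 31),
                    mixture_init(mu_gf = 2, c_ef = 30.5))) {
    fit <- em_fit(d$x, d$y, init = init)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  }
})

test_that("well-separated clusters are recovered to generator truth", {
  d <- sim_mixture_data(n = 2000, w = c(0.6, 0.3, 0.1), mu_gf = 2,
                        sigma_gf = 0.3, c_ef = 30, sigma_ef = 0.2, seed = 5)
  fit <- grid_fit(d$x, d$y, default_init_grid(29))
  expect_equal(fit$mu_gf, 2, tolerance = 0.05)
  expect_equal(fit$c_ef, 30, tolerance = 0.05 / 30)
  realized <- as.numeric(table(factor(d$comp,
                                      c("gf", "ef", "noise")))) / 2000
  expect_true(all(abs(fit$weights - realized) < 0.03))
})

test_that("a guiding-fixations-only sample collapses the entry cluster", {
  set.seed(11)
  x <- runif(600, 0, 15)
  y <- rnorm(600, 2, 0.3)
  fit <- grid_fit(x, y, default_init_grid(29))
  expect_lte(fit$weights[["ef"]], 0.02)
  expect_equal(fit$mu_gf, mean(y), tolerance = 0.02)
})

test_that("grid_fit returns the argmax and dominates bad single starts", {
  d <- sim_mixture_data(n = 1500, seed = 7)
  grid <- default_init_grid(29)
  fit <- grid_fit(d$x, d$y, grid)
  expect_true(all(fit$log_likelihood >= fit$candidate_loglik - 1e-8))
  # a one-point grid is exactly em_fit from that point
  single <- grid_fit(d$x, d$y, grid[2])
  direct <- em_fit(d$x, d$y, init = grid[[2]])
  expect_equal(single$log_likelihood, direct$log_likelihood)
  expect_equal(single$mu_gf, direct$mu_gf)
  # a deliberately bad start cannot beat the grid
  bad <- em_fit(d$x, d$y, init = mixture_init(mu_gf = 5, c_ef = 30))
  expect_gte(fit$log_likelihood, bad$log_likelihood - 1e-8)
  expect_error(grid_fit(d$x, d$y, list()), "empty")
})

test_that("sparse samples are refused", {
  expect_error(em_fit(1:10, rnorm(10, 2)), "at least 50")
})

test_that("fit summaries compose cluster means as documented", {
  # hand-computable example with hard 0/1 responsibilities
  fake <- structure(list(
    mu_gf = 2, sigma_gf = 0.3, c_ef = 12, sigma_ef = 0.3,
    weights = c(gf = 0.5, ef = 0.25, noise = 0.25),
    responsibilities = rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(0, 0, 1)),
    pruned = c(gf = FALSE, ef = FALSE)), class = "mixture_fit")
  s <- summarise_fit(fake, x = c(1, 2, 8, 3), y = c(1.8, 2.2, 4.0, 7.0))
  expect_equal(s$gf_mean_th, 2.0)       # mean of 1.8, 2.2
  expect_equal(s$ef_mean_th, 4.0)
  expect_equal(s$gf_weight, 2 / 3)      # 0.5 / (0.5 + 0.25)
  expect_equal(s$composed_mean_th, (2 / 3) * 2 + (1 / 3) * 4)
  expect_true(s$gf_ef_order_ok)
  # pure-GF fit: composed mean equals the GF mean
  d <- sim_mixture_data(n = 800, w = c(0.97, 0.005, 0.025), seed = 13)
  fit <- grid_fit(d$x, d$y, default_init_grid(29))
  s <- summarise_fit(fit, d$x, d$y)
  if (fit$pruned[["ef"]] || fit$weights[["ef"]] == 0)
    expect_equal(s$composed_mean_th, s$gf_mean_th)
  # standard fit: composed mean near the empirical non-noise mean
  d <- sim_mixture_data(n = 2000, seed = 17)
  fit <- grid_fit(d$x, d$y, default_init_grid(29))
  s <- summarise_fit(fit, d$x, d$y)
  expect_equal(s$composed_mean_th, mean(d$y[d$comp != "noise"]),
               tolerance = 0.05)
})

test_that("smoothed cluster weights sum to one and respect limits", {
  d <- sim_mixture_data(n = 1500, seed = 19)
  fit <- grid_fit(d$x, d$y, default_init_grid(29))
  w <- weights_along_track(fit, d$x, bandwidth_s = 0.5)
  expect_true(all(abs(rowSums(w[, c("gf", "ef", "noise")]) - 1) < 1e-6))
  # infinite bandwidth flattens every curve to the global weight
  winf <- weights_along_track(fit, d$x, bandwidth_s = 1e9)
  expect_lt(max(abs(winf$gf - mean(fit$responsibilities[, 1]))), 1e-6)
  expect_lt(diff(range(winf$ef)), 1e-9)
  # uniform responsibilities give flat thirds
  fake <- structure(list(responsibilities =
                           matrix(1 / 3, length(d$x), 3)),
                    class = "mixture_fit")
  wu <- weights_along_track(fake, d$x)
  expect_true(all(abs(wu$gf - 1 / 3) < 1e-12))
})

test_that("estimates are unbiased over repeated draws", {
  mus <- numeric(20); ces <- numeric(20)
  for (s in 1:20) {
    d <- sim_mixture_data(n = 2000, seed = 100 + s)
    fit <- grid_fit(d$x, d$y, default_init_grid(29))
    mus[s] <- fit$mu_gf; ces[s] <- fit$c_ef
  }
  expect_lt(abs(mean(mus) - 2), 0.02)
  expect_lt(abs(mean(ces) - 30), 0.02)
  expect_lt(sqrt(mean((mus - 2)^2)), 0.06)
  expect_lt(sqrt(mean((ces - 30)^2)), 0.06)
})

test_that("a between-condition shift in the GF mean is detected", {
  a <- sim_mixture_data(n = 2000, mu_gf = 2.0, seed = 23)
  b <- sim_mixture_data(n = 2000, mu_gf = 2.2, seed = 24)
  fa <- grid_fit(a$x, a$y, default_init_grid(29))
  fb <- grid_fit(b$x, b$y, default_init_grid(29))
  expect_equal(fb$mu_gf - fa$mu_gf, 0.2, tolerance = 0.05 / 0.2)
})
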