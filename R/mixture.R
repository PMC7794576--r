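#' Mixture specification for gaze headway decomposition
#'
#' The pooled gaze headway cloud, in (time into trial `x`, time headway `y`)
#' coordinates, is modelled as a weighted mixture of three regression
#' components with structurally fixed slopes:
#'
#' * **Guiding fixations (GF)** -- a region that moves with the observer:
#'   `y ~ Normal(mu_gf, sigma_gf^2)`, i.e. a regression line of slope 0.
#' * **Entry fixations (EF)** -- a fixed world point (the principal attractor
#'   just past the bend entry): `y ~ Normal(c_ef - x, sigma_ef^2)`, a
#'   regression line of slope -1 whose intercept `c_ef` is the attractor's
#'   time-along-midline.
#' * **Noise** -- a fixed uniform density on `[0, noise_max]` absorbing
#'   off-task samples; its parameters are never updated.
#'
#' Only `mu_gf`, `sigma_gf`, `c_ef`, `sigma_ef` are free (four parameters),
#' plus the mixing weights on the 3-simplex. Because the slopes are fixed and
#' distinct the components are not exchangeable and no label switching can
#' occur.
#'
#' @param noise_max Upper bound of the uniform noise density, seconds; by
#'   default the 8 s forward search window of the headway estimator.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(noise_max = 8) {
  stopifnot(noise_max > 0)
  structure(list(noise_max = noise_max), class = "mixture_spec")
}

#' Initial values for the EM algorithm
#'
#' @param mu_gf,c_ef,sigma_gf,sigma_ef,weights Starting parameter values;
#'   `weights` is a length-3 simplex vector `(GF, EF, noise)`.
#' @return A named list.
#' @export
mixture_init <- function(mu_gf = 2, c_ef = 6, sigma_gf = 0.5, sigma_ef = 0.5,
                         weights = c(0.6, 0.3, 0.1)) {
  stopifnot(length(weights) == 3, all(weights > 0))
  list(mu_gf = mu_gf, c_ef = c_ef, sigma_gf = sigma_gf, sigma_ef = sigma_ef,
       weights = weights / sum(weights))
}

# Component densities at (x, y) for current parameters; returns n x 3 matrix.
mixture_densities <- function(x, y, par, spec) {
  cbind(gf = dnorm(y, par$mu_gf, par$sigma_gf),
        ef = dnorm(y, par$c_ef - x, par$sigma_ef),
        noise = dunif(y, 0, spec$noise_max))
}

#' Fit the gaze headway mixture by expectation-maximisation
#'
#' E-step: responsibilities proportional to weight times component density.
#' M-step: `mu_gf` is the GF-responsibility-weighted mean of `y`; `c_ef` the
#' EF-weighted mean of `y + x` (the slope -1 line's intercept); the sigmas
#' the corresponding weighted standard deviations; the weights the mean
#' responsibilities. Iterates until the log-likelihood improves by less than
#' `tol` or `max_iter` is reached. A component whose sigma collapses below
#' `sigma_floor` is pruned to weight zero and flagged.
#'
#' @param x Time into trial, seconds.
#' @param y Gaze time headway, seconds.
#' @param init Initial values, see [mixture_init()].
#' @param spec A [mixture_spec()].
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param min_n Minimum number of samples; sparser data is refused since a
#'   small sample biases the fit.
#' @param sigma_floor Pruning threshold for component standard deviations,
#'   seconds.
#' @param weight_floor Pruning threshold for component weights: a free
#'   component whose weight collapses below this carries no information about
#'   its parameters (its sigma then tends to inflate without bound), so it is
#'   pruned and flagged.
#' @return An object of class `mixture_fit`: fitted parameters, `weights`,
#'   per-sample `responsibilities` (rows sum to 1), `log_likelihood` (final)
#'   and `loglik_trace`, `n_iter`, `converged`, `pruned`.
#' @export
em_fit <- function(x, y, init = mixture_init(), spec = mixture_spec(),
                   tol = 1e-6, max_iter = 500, min_n = 50,
                   sigma_floor = 0.01, weight_floor = 0.005) {
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < min_n)
    stop("em_fit: only ", n, " samples; at least ", min_n,
         " are required for a stable mixture fit", call. = FALSE)
  par <- init
  pruned <- c(gf = FALSE, ef = FALSE)
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- mixture_densities(x, y, par, spec)
    wd <- sweep(dens, 2, par$weights, "*")
    rowsum_wd <- rowSums(wd)
    rowsum_wd[rowsum_wd == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_wd))
    trace <- c(trace, ll)
    resp <- wd / rowsum_wd
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    # M-step
    nk <- colSums(resp)
    par$weights <- nk / n
    if (!pruned["gf"] && nk[[1]] > 0) {
      par$mu_gf <- sum(resp[, 1] * y) / nk[[1]]
      par$sigma_gf <- sqrt(sum(resp[, 1] * (y - par$mu_gf)^2) / nk[[1]])
      if (!is.finite(par$sigma_gf) || par$sigma_gf < sigma_floor ||
          par$weights[1] < weight_floor)
        pruned["gf"] <- TRUE
    }
    if (!pruned["ef"] && nk[[2]] > 0) {
      par$c_ef <- sum(resp[, 2] * (y + x)) / nk[[2]]
      par$sigma_ef <- sqrt(sum(resp[, 2] * (y - (par$c_ef - x))^2) / nk[[2]])
      if (!is.finite(par$sigma_ef) || par$sigma_ef < sigma_floor ||
          par$weights[2] < weight_floor)
        pruned["ef"] <- TRUE
    }
    if (pruned["gf"]) par$weights[1] <- 0
    if (pruned["ef"]) par$weights[2] <- 0
    par$weights <- par$weights / sum(par$weights)
  }
  structure(list(mu_gf = par$mu_gf, sigma_gf = par$sigma_gf,
                 c_ef = par$c_ef, sigma_ef = par$sigma_ef,
                 weights = setNames(par$weights, c("gf", "ef", "noise")),
                 responsibilities = resp,
                 log_likelihood = trace[length(trace)],
                 loglik_trace = trace,
                 n_iter = length(trace),
                 converged = length(trace) < max_iter,
                 pruned = pruned, spec = spec, init = init),
            class = "mixture_fit")
}

#' Default initialisation grid
#'
#' A sparse grid spanning the plausible guiding-fixation range and attractor
#' locations around one second past the bend entry.
#'
#' @param bend_entry_time_s Time into trial at which the vehicle crosses the
#'   bend entry, seconds.
#' @param mu_gf,c_ef_offset Grid values for the GF mean and for the attractor
#'   location relative to bend entry.
#' @return List of [mixture_init()] values.
#' @export
default_init_grid <- function(bend_entry_time_s, mu_gf = c(1.5, 2, 2.5),
                              c_ef_offset = c(0.5, 1, 1.5)) {
  grid <- expand.grid(mu = mu_gf, off = c_ef_offset)
  lapply(seq_len(nrow(grid)), function(i)
    mixture_init(mu_gf = grid$mu[i], c_ef = bend_entry_time_s + grid$off[i]))
}

#' Fit the mixture from a grid of initial values
#'
#' Runs [em_fit()] from every grid point and keeps the converged fit with the
#' highest log-likelihood. All candidate likelihoods are recorded for audit.
#'
#' @inheritParams em_fit
#' @param init_grid List of [mixture_init()] values.
#' @return The best `mixture_fit`, with `init_id` (index into the grid) and
#'   `candidate_loglik` attached.
#' @export
grid_fit <- function(x, y, init_grid, spec = mixture_spec(), ...) {
  if (length(init_grid) == 0) stop("grid_fit: empty init grid", call. = FALSE)
  fits <- vector("list", length(init_grid))
  errs <- character(length(init_grid))
  for (i in seq_along(init_grid)) {
    fits[[i]] <- tryCatch(em_fit(x, y, init = init_grid[[i]], spec = spec,
                                 ...),
                          error = function(e) {
                            errs[i] <<- conditionMessage(e)
                            NULL
                          })
  }
  ll <- vapply(fits, function(f) if (is.null(f)) -Inf else f$log_likelihood,
               numeric(1))
  if (all(!is.finite(ll)))
    stop("grid_fit: every initialisation failed:\n  ",
         paste(errs[errs != ""], collapse = "\n  "), call. = FALSE)
  best <- which.max(ll)
  fit <- fits[[best]]
  fit$init_id <- best
  fit$candidate_loglik <- ll
  fit
}

#' Summarise a fitted mixture
#'
#' Cluster headway means are responsibility-weighted means of the *observed*
#' headways; the composed mean is the weight-weighted average of the GF and EF
#' means with the noise component excluded and the GF/EF weights renormalised
#' accordingly.
#'
#' @param fit A [em_fit()] / [grid_fit()] result.
#' @param x,y The samples the fit was computed on.
#' @return Data frame with one row: `gf_mean_th`, `ef_mean_th`,
#'   `composed_mean_th`, `gf_weight`, `ef_weight` (noise-renormalised),
#'   `ef_point_time_s` (the attractor's time-along-midline, `c_ef`) and a
#'   `gf_ef_order_ok` flag (`EF mean > GF mean` in standard fits).
#' @export
summarise_fit <- function(fit, x, y) {
  r <- fit$responsibilities
  gf_mean <- if (sum(r[, 1]) > 0) sum(r[, 1] * y) / sum(r[, 1]) else NA_real_
  ef_mean <- if (sum(r[, 2]) > 0) sum(r[, 2] * y) / sum(r[, 2]) else NA_real_
  w <- fit$weights
  wsum <- w[["gf"]] + w[["ef"]]
  gf_w <- if (wsum > 0) w[["gf"]] / wsum else NA_real_
  ef_w <- if (wsum > 0) w[["ef"]] / wsum else NA_real_
  composed <- if (!is.na(gf_w) && !is.na(ef_mean) && ef_w > 0)
    gf_w * gf_mean + ef_w * ef_mean
  else gf_mean
  data.frame(gf_mean_th = gf_mean, ef_mean_th = ef_mean,
             composed_mean_th = composed,
             gf_weight = gf_w, ef_weight = ef_w,
             ef_point_time_s = fit$c_ef,
             gf_ef_order_ok = isTRUE(ef_mean > gf_mean))
}

#' Smoothed cluster weights along the track
#'
#' Kernel-smoothed (Nadaraya-Watson, Gaussian kernel) responsibility averages
#' as a function of time into trial. Because every responsibility vector sums
#' to one and all three curves share the same kernel weights, the curves sum
#' to one at every evaluation point.
#'
#' @param fit A fitted mixture.
#' @param x Time into trial of the fitted samples, seconds.
#' @param bandwidth_s Gaussian kernel standard deviation, seconds.
#' @param eval_at Evaluation grid; defaults to 100 points spanning `x`.
#' @return Data frame with `time_into_trial_s`, `gf`, `ef`, `noise`.
#' @export
weights_along_track <- function(fit, x, bandwidth_s = 0.5, eval_at = NULL) {
  if (is.null(eval_at))
    eval_at <- seq(min(x), max(x), length.out = 100)
  r <- fit$responsibilities
  out <- matrix(NA_real_, length(eval_at), 3)
  for (i in seq_along(eval_at)) {
    k <- dnorm(x, eval_at[i], bandwidth_s)
    ks <- sum(k)
    if (ks > 0) out[i, ] <- colSums(k * r) / ks
  }
  data.frame(time_into_trial_s = eval_at,
             gf = out[, 1], ef = out[, 2], noise = out[, 3])
}

#' Fit the mixture per participant and driving mode
#'
#' Pools the included headway samples per participant x mode across trials
#' and runs [grid_fit()] on each pool.
#'
#' @param th Tidy headway table from [estimate_th()] (all trials bound
#'   together); excluded samples are dropped here.
#' @param bend_entry_time_s Passed to [default_init_grid()].
#' @param spec A [mixture_spec()].
#' @param ... Further arguments to [em_fit()].
#' @return Data frame with one row per participant x mode: fitted parameters,
#'   weights, summary means and the sample count `n`.
#' @export
fit_all_mixtures <- function(th, bend_entry_time_s, spec = mixture_spec(),
                             ...) {
  inc <- th[!th$excluded, , drop = FALSE]
  grid <- default_init_grid(bend_entry_time_s)
  groups <- split(inc, list(inc$participant, inc$mode), drop = TRUE)
  rows <- lapply(groups, function(g) {
    fit <- grid_fit(g$time_into_trial_s, g$th_s, grid, spec = spec, ...)
    s <- summarise_fit(fit, g$time_into_trial_s, g$th_s)
    # a pruned component carries no parameter information
    if (fit$pruned[["ef"]]) {
      fit$c_ef <- NA_real_; fit$sigma_ef <- NA_real_
      s$ef_mean_th <- NA_real_; s$ef_point_time_s <- NA_real_
    }
    cbind(data.frame(participant = g$participant[1], mode = g$mode[1],
                     n = nrow(g), mu_gf = fit$mu_gf, sigma_gf = fit$sigma_gf,
                     c_ef = fit$c_ef, sigma_ef = fit$sigma_ef,
                     w_gf = fit$weights[["gf"]], w_ef = fit$weights[["ef"]],
                     w_noise = fit$weights[["noise"]],
                     gf_pruned = fit$pruned[["gf"]],
                     ef_pruned = fit$pruned[["ef"]],
                     log_likelihood = fit$log_likelihood,
                     n_iter = fit$n_iter, init_id = fit$init_id),
          s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, match(out$mode, MODE_LEVELS)), ]
}
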