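#' Per-participant summaries of a measure
#'
#' Pooled sample- or event-level measures are skewed, so the participant
#' summary entering the condition model is the median of each participant's
#' pooled values per driving mode. Participants with no data in a mode are
#' omitted with a warning.
#'
#' @param df Data frame with columns `participant`, `mode` and the measure.
#' @param value Name of the measure column.
#' @param measure Label stored in the output.
#' @return Data frame `participant`, `mode`, `measure`, `value` (one row per
#'   participant x mode present in the data).
#' @export
summarise_participants <- function(df, value, measure = value) {
  stopifnot(value %in% names(df))
  v <- df[[value]]
  keep <- !is.na(v)
  df <- df[keep, , drop = FALSE]
  agg <- stats::aggregate(df[[value]],
                          by = list(participant = df$participant,
                                    mode = df$mode),
                          FUN = median)
  names(agg)[3] <- "value"
  agg$measure <- measure
  # warn about participant x mode cells that exist for the participant in
  # other modes but are empty here
  full <- expand.grid(participant = unique(agg$participant),
                      mode = intersect(MODE_LEVELS, unique(df$mode)))
  miss <- !paste(full$participant, full$mode) %in%
    paste(agg$participant, agg$mode)
  if (any(miss))
    warning("no data for participant x mode: ",
            paste(full$participant[miss], full$mode[miss], collapse = "; "),
            call. = FALSE)
  agg[order(agg$participant, match(agg$mode, MODE_LEVELS)),
      c("participant", "mode", "measure", "value")]
}

condition_model_string <- function(per_condition_sigma = FALSE) {
  if (per_condition_sigma)
    "model {
      for (i in 1:N) { y[i] ~ dnorm(mu[cond[i]], tau[cond[i]]) }
      for (c in 1:C) {
        mu[c] ~ dnorm(center, 1)
        sigma[c] ~ dnorm(0, 1) T(0,)
        tau[c] <- pow(sigma[c], -2)
      }
    }"
  else
    "model {
      for (i in 1:N) { y[i] ~ dnorm(mu[cond[i]], tau) }
      for (c in 1:C) { mu[c] ~ dnorm(center, 1) }
      sigma ~ dnorm(0, 1) T(0,)
      tau <- pow(sigma, -2)
    }"
}

#' Highest-density interval of a sample
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval mass.
#' @return Length-2 numeric `(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  iv <- coda::HPDinterval(coda::as.mcmc(draws), prob = prob)
  c(lower = iv[1, "lower"], upper = iv[1, "upper"])
}

#' Bayesian condition model for one measure
#'
#' Hierarchical normal model for per-participant summaries: each value is
#' `Normal(mu[condition], sigma)` with weakly informative priors
#' `mu[c] ~ Normal(prior_center, 1)` and `sigma ~ HalfNormal(1)` (a shared
#' sigma by default; per-condition sigmas behind a flag). The posterior is
#' sampled with JAGS; pairwise contrasts are computed per draw, summarised by
#' posterior means, 95% highest-density intervals and the fraction of
#' posterior mass above zero.
#'
#' @param summaries From [summarise_participants()]: `participant`, `mode`,
#'   `value`.
#' @param prior_center Prior centre for the condition means (2 s is apt for
#'   headway measures, 0.4 s for durations, 0.5 for weights).
#' @param seed Integer seed; each chain gets a derived RNG seed so results
#'   are reproducible.
#' @param n_chains,n_iter,n_adapt,n_burn Sampler settings: chains, post-warmup
#'   draws per chain, adaptation steps and discarded burn-in steps.
#' @param per_condition_sigma Fit one sigma per condition instead of a shared
#'   one.
#' @param rhat_limit Convergence gate: the fit errors (with the diagnostics
#'   attached to the condition) if any split statistic exceeds this.
#' @param hdi_prob Mass of the reported highest-density intervals.
#' @return An object of class `posterior_summary`: data frames `conditions`
#'   (`mode`, `mean`, `hdi_lower`, `hdi_upper`, `n_participants`) and
#'   `contrasts` (`contrast`, `mean`, `hdi_lower`, `hdi_upper`,
#'   `mass_above_zero`), plus the raw `draws` matrix and `rhat`.
#' @export
fit_condition_model <- function(summaries, prior_center = 2, seed = 1,
                                n_chains = 4, n_iter = 2000, n_adapt = 500,
                                n_burn = 1000,
                                per_condition_sigma = FALSE,
                                rhat_limit = 1.01, hdi_prob = 0.95) {
  modes <- intersect(MODE_LEVELS, unique(summaries$mode))
  if (length(modes) < 2)
    stop("fit_condition_model: need at least two conditions", call. = FALSE)
  counts <- table(summaries$mode)[modes]
  if (any(counts < 2))
    stop("fit_condition_model: need >= 2 participants per condition",
         call. = FALSE)
  cond <- match(summaries$mode, modes)
  data <- list(y = summaries$value, cond = cond,
               N = nrow(summaries), C = length(modes),
               center = prior_center)
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 97L + ch) %% 2147483646L + 1L))
  jm <- rjags::jags.model(
    textConnection(condition_model_string(per_condition_sigma)),
    data = data, inits = inits, n.chains = n_chains, n.adapt = n_adapt,
    quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = n_iter,
                              progress.bar = "none")
  gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                              multivariate = FALSE), silent = TRUE)
  if (!inherits(gd, "try-error")) {
    rhat <- gd$psrf[, 1]
    if (any(is.finite(rhat) & rhat > rhat_limit)) {
      cond_err <- simpleError(paste0(
        "fit_condition_model: convergence gate failed (max R-hat = ",
        signif(max(rhat, na.rm = TRUE), 4), ")"))
      cond_err$diagnostics <- gd
      stop(cond_err)
    }
  } else rhat <- NA_real_
  draws <- do.call(rbind, lapply(samp, as.matrix))
  mu <- draws[, paste0("mu[", seq_along(modes), "]"), drop = FALSE]
  colnames(mu) <- modes

  cond_rows <- lapply(modes, function(m) {
    iv <- hdi(mu[, m], hdi_prob)
    data.frame(mode = m, mean = mean(mu[, m]),
               hdi_lower = iv[["lower"]], hdi_upper = iv[["upper"]],
               n_participants = as.integer(counts[[m]]))
  })
  pairs <- utils::combn(seq_along(modes), 2)
  con_rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[2, k]; b <- pairs[1, k]    # later mode minus earlier mode
    d <- mu[, a] - mu[, b]
    iv <- hdi(d, hdi_prob)
    data.frame(contrast = paste(modes[a], "-", modes[b]),
               mean = mean(d), hdi_lower = iv[["lower"]],
               hdi_upper = iv[["upper"]],
               mass_above_zero = mean(d > 0))
  })
  structure(list(conditions = do.call(rbind, cond_rows),
                 contrasts = do.call(rbind, con_rows),
                 draws = draws, rhat = rhat, modes = modes,
                 hdi_prob = hdi_prob, seed = seed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior condition means (", x$hdi_prob * 100, "% HDI):\n", sep = "")
  print(x$conditions, row.names = FALSE, digits = 3)
  cat("\nContrasts:\n")
  print(x$contrasts, row.names = FALSE, digits = 3)
  invisible(x)
}
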