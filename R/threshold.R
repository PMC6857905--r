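#' Specification of the coral-cover threshold model
#'
#' Settings for the Bayesian additive mixed model relating site net
#' carbonate production `G` to live coral cover:
#' \deqn{G = \beta_0 + f(cover) + habitat + a_{site} + \varepsilon}
#' where `f` is an O'Sullivan penalized spline, `habitat` a fixed effect and
#' `a_site` a random intercept. Priors are deliberately diffuse: Normal(0,
#' 10^2) on fixed effects, i.i.d. Normal(0, sigma_u^2) on the penalized
#' spline coefficients (the mixed-model form of the roughness penalty), and
#' half-Cauchy(5) on all standard deviations.
#'
#' @param n_knots interior spline knots (default 20).
#' @param chains MCMC chains (default 4).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param draws retained draws per chain (>= 1000 recommended for stable
#'   credible intervals; fewer triggers a warning at fit time).
#' @param thin thinning interval; the sampler runs `draws * thin`
#'   iterations and keeps every `thin`-th. The variance components mix
#'   slowly when sites contribute one observation each (site and residual
#'   variances are then separated only by their priors), so thinned longer
#'   chains are the default.
#' @param seed integer RNG seed controlling the samplers.
#' @return List of class `"threshold_model_spec"`.
#' @export
threshold_model_spec <- function(n_knots = 20, chains = 4, warmup = 3000,
                                 draws = 1000, thin = 10, seed = 1) {
  stopifnot(n_knots >= 3, chains >= 1, warmup >= 0, draws >= 1, thin >= 1)
  structure(list(n_knots = n_knots, chains = chains, warmup = warmup,
                 draws = draws, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "threshold_model_spec")
}

threshold_jags_model <- "
model {
  for (i in 1:n) {
    y[i] ~ dnorm(mu[i], tau_e)
    mu[i] <- inprod(X[i, ], beta) + inprod(Z[i, ], u) + b[site[i]]
  }
  for (k in 1:p) { beta[k] ~ dnorm(0, 0.01) }
  for (k in 1:q) { u[k] ~ dnorm(0, tau_u) }
  for (s in 1:S) { b[s] ~ dnorm(0, tau_s) }
  sigma_e ~ dt(0, 0.04, 1) T(0, )
  sigma_u ~ dt(0, 0.04, 1) T(0, )
  sigma_s ~ dt(0, 0.04, 1) T(0, )
  tau_e <- pow(sigma_e, -2)
  tau_u <- pow(sigma_u, -2)
  tau_s <- pow(sigma_s, -2)
}"

#' Fit the Bayesian penalized-spline threshold model
#'
#' Fits the additive mixed model of [threshold_model_spec()] with JAGS.
#' The spline enters in mixed-model form (see [build_spline_basis()]); the
#' linear trend in cover and the habitat contrasts are fixed effects; sites
#' get random intercepts. Split-Rhat is computed for the fixed effects and
#' standard deviations; values above 1.05 raise a warning (the fit is still
#' returned, never silently discarded).
#'
#' @param data `data.frame` with columns `net` (kg CaCO3 m-2 yr-1),
#'   `cover` (percent, 0-100), `habitat` (factor/character, >= 2 levels,
#'   >= 2 sites each) and `site` (identifier).
#' @param spec a [threshold_model_spec()].
#' @return Object of class `"threshold_fit"`: combined posterior `draws`
#'   matrix, the basis, design metadata, `rhat`, and the input data.
#' @seealso [extract_threshold()], [habitat_threshold_difference()]
#' @export
fit_threshold_model <- function(data, spec = threshold_model_spec()) {
  stopifnot(all(c("net", "cover", "habitat", "site") %in% names(data)))
  habs <- sort(unique(as.character(data$habitat)))
  if (length(habs) < 2) stop("need >= 2 habitats", call. = FALSE)
  sites_per_hab <- tapply(data$site, data$habitat,
                          function(s) length(unique(s)))
  if (any(sites_per_hab < 2)) {
    stop("need >= 2 sites per habitat", call. = FALSE)
  }
  if (spec$draws < 1000) {
    warning("fewer than 1000 draws per chain; credible intervals may be ",
            "unstable", call. = FALSE)
  }

  basis <- build_spline_basis(data$cover, n_knots = spec$n_knots)
  c_mean <- mean(data$cover)
  c_sd <- stats::sd(data$cover)
  hab_f <- factor(data$habitat, levels = habs)
  Xh <- if (length(habs) > 1) {
    stats::model.matrix(~hab_f)[, -1, drop = FALSE]
  } else NULL
  X <- cbind(intercept = 1, cover_std = (data$cover - c_mean) / c_sd, Xh)
  colnames(X) <- c("intercept", "cover_std", paste0("habitat_", habs[-1]))
  site_f <- factor(data$site)

  jd <- list(y = data$net, X = X, Z = basis$Z,
             site = as.integer(site_f),
             n = nrow(data), p = ncol(X), q = ncol(basis$Z),
             S = nlevels(site_f))
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (spec$seed %% 100000L) * 1000L + ch)
  })
  model <- rjags::jags.model(textConnection(threshold_jags_model),
                             data = jd, inits = inits,
                             n.chains = spec$chains,
                             n.adapt = max(100L, spec$warmup %/% 2L),
                             quiet = TRUE)
  stats::update(model, n.iter = max(0L, spec$warmup - spec$warmup %/% 2L),
                progress.bar = "none")
  samp <- rjags::coda.samples(
    model, c("beta", "u", "sigma_e", "sigma_u", "sigma_s"),
    n.iter = spec$draws * spec$thin, thin = spec$thin,
    progress.bar = "none")

  check_pars <- c(paste0("beta[", seq_len(ncol(X)), "]"),
                  "sigma_e", "sigma_u", "sigma_s")
  rhat <- if (spec$chains >= 2) {
    gd <- coda::gelman.diag(samp[, check_pars, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    stats::setNames(gd$psrf[, 1], check_pars)
  } else {
    stats::setNames(rep(NA_real_, length(check_pars)), check_pars)
  }
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warning("possible non-convergence: split-Rhat > 1.05 for ",
            paste(names(rhat)[which(rhat > 1.05)], collapse = ", "),
            call. = FALSE)
  }

  draws <- do.call(rbind, lapply(samp, as.matrix))
  structure(list(
    draws = draws,
    basis = basis,
    habitats = habs,
    cover_center = c_mean,
    cover_scale = c_sd,
    x_names = colnames(X),
    rhat = rhat,
    spec = spec,
    data = data
  ), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit> ", nrow(x$data), " observations, habitats: ",
      paste(x$habitats, collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$draws), " posterior draws (", x$spec$chains,
      " chains); max split-Rhat ",
      round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

# posterior expected net-production curves (random intercepts at zero):
# draws x grid matrix for one habitat
expected_curves <- function(fit, habitat, grid) {
  stopifnot(habitat %in% fit$habitats)
  d <- fit$draws
  p <- length(fit$x_names)
  beta <- d[, paste0("beta[", seq_len(p), "]"), drop = FALSE]
  u_cols <- grep("^u\\[", colnames(d), value = TRUE)
  u <- d[, u_cols[order(as.integer(gsub("\\D", "", u_cols)))], drop = FALSE]
  Zg <- fit$basis$predict(grid)
  Xg <- matrix(0, length(grid), p,
               dimnames = list(NULL, fit$x_names))
  Xg[, "intercept"] <- 1
  Xg[, "cover_std"] <- (grid - fit$cover_center) / fit$cover_scale
  hcol <- paste0("habitat_", habitat)
  if (hcol %in% fit$x_names) Xg[, hcol] <- 1
  beta %*% t(Xg) + u %*% t(Zg)
}

#' Live-coral-cover threshold for non-negative net production
#'
#' For each posterior draw, evaluates the expected (population-level;
#' random intercepts at zero) net-production curve for the habitat on a
#' fine cover grid and takes the smallest cover at which the curve reaches
#' zero from below, refining the crossing by linear interpolation between
#' bracketing grid points. Draws whose curve is non-negative already at
#' zero cover get threshold 0; draws whose curve never reaches zero are
#' censored at the upper boundary and counted in `censored_fraction`.
#'
#' @param fit a [fit_threshold_model()] result.
#' @param habitat habitat label present in the fit.
#' @param grid_by grid resolution on the cover axis (percent).
#' @return List of class `"threshold_estimate"`: `mean`, `lower`, `upper`
#'   (central 95% credible interval), `median`, `censored_fraction`,
#'   `draws` (per-draw thresholds), `habitat`.
#' @export
extract_threshold <- function(fit, habitat, grid_by = 0.1) {
  grid <- seq(fit$basis$boundary[1], fit$basis$boundary[2], by = grid_by)
  curves <- expected_curves(fit, habitat, grid)
  th <- apply(curves, 1, function(mu) {
    if (mu[1] >= 0) return(grid[1])
    nn <- which(mu >= 0)
    if (!length(nn)) return(NA_real_)  # censored
    i <- nn[1]
    # linear interpolation of the sign change between grid[i-1] and grid[i]
    grid[i - 1] + (0 - mu[i - 1]) / (mu[i] - mu[i - 1]) * grid_by
  })
  censored <- is.na(th)
  th[censored] <- fit$basis$boundary[2]
  structure(list(
    habitat = habitat,
    mean = mean(th),
    median = stats::median(th),
    lower = unname(stats::quantile(th, 0.025)),
    upper = unname(stats::quantile(th, 0.975)),
    censored_fraction = mean(censored),
    draws = th
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %s: %.1f%% LCC (95%% CrI %.1f-%.1f",
              x$habitat, x$mean, x$lower, x$upper))
  if (x$censored_fraction > 0) {
    cat(sprintf("; %.0f%% of draws censored", 100 * x$censored_fraction))
  }
  cat(")\n")
  invisible(x)
}

#' Posterior difference of two habitat thresholds
#'
#' Per-draw difference `threshold(habitat_a) - threshold(habitat_b)`,
#' summarised as posterior mean and central 95% credible interval; the
#' per-draw pairing propagates the full joint posterior.
#'
#' @param fit a [fit_threshold_model()] result.
#' @param habitat_a,habitat_b habitat labels in the fit.
#' @param grid_by grid resolution passed to [extract_threshold()].
#' @return List with `mean`, `lower`, `upper`, and the per-draw `draws`.
#' @export
habitat_threshold_difference <- function(fit, habitat_a, habitat_b,
                                         grid_by = 0.1) {
  ta <- extract_threshold(fit, habitat_a, grid_by)
  tb <- extract_threshold(fit, habitat_b, grid_by)
  d <- ta$draws - tb$draws
  list(mean = mean(d),
       lower = unname(stats::quantile(d, 0.025)),
       upper = unname(stats::quantile(d, 0.975)),
       draws = d)
}
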