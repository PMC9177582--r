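#' @useDynLib metaseed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate code with the global RNG state saved and restored.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Group a prepared cohort by (state, age bin) for fast likelihood sums.
# idx is the linear index of (state, bin) into the 16 x (nsteps+1) grid.
group_cohort <- function(cohort, dt) {
  if (!all(c("state_index", "tumor_age_years") %in% names(cohort)))
    stop("cohort is not prepared; run prepare_cohort() first")
  if (nrow(cohort) == 0L)
    return(list(states = integer(), bins = integer(), counts = integer(),
                idx = integer(), nsteps = 1L, horizon = dt))
  bins <- as.integer(round(cohort$tumor_age_years / dt))
  code <- bins * 16L + cohort$state_index
  tab <- table(code)
  code_u <- as.integer(names(tab))
  bins_u <- code_u %/% 16L
  states_u <- code_u - bins_u * 16L
  fix <- states_u == 0L  # state 16 wraps
  states_u[fix] <- 16L
  bins_u[fix] <- bins_u[fix] - 1L
  nsteps <- max(max(bins_u), 1L)
  list(states = states_u, bins = bins_u, counts = as.integer(tab),
       idx = bins_u * 16L + states_u, nsteps = nsteps,
       horizon = nsteps * dt)
}

nll_groups <- function(theta, groups, dt, method) {
  if (length(groups$counts) == 0L) return(0)
  Q <- build_generator(theta)
  A <- if (method == "euler") {
    qmax <- max(abs(diag(Q)))
    if (dt * qmax >= 0.1)
      stop(sprintf(
        "Euler step dt = %g is too coarse for these rates; need dt < %g",
        dt, 0.1 / qmax))
    diag(16) + dt * Q
  } else as.matrix(Matrix::expm(Q * dt))
  probs <- propagate_grid(A, c(1, rep(0, 15)), groups$nsteps)
  -sum(groups$counts * log(pmax(probs[groups$idx], 1e-300)))
}

#' Negative log-likelihood of a cohort
#'
#' The likelihood of a diagnosis-time cohort is the product over patients of
#' the probability of their observed state at their imputed tumor age,
#' \eqn{L(\theta) = \prod_j P_{s_j}(t_j, \theta)}, with probabilities read
#' from the master-equation grid (nearest column; ages binned to the grid
#' step). Patients sharing a (state, age-bin) pair are grouped with
#' multiplicities. Probabilities are floored at \code{1e-300} before logs.
#'
#' @param cohort A prepared [cohort].
#' @param theta A [rate_vector()].
#' @param dt Solver grid step, years (also the age-binning width).
#' @param method Solver scheme, \code{"euler"} or \code{"expm"}.
#' @return \eqn{-\log L(\theta)}; 0 for an empty cohort.
#' @export
negative_log_likelihood <- function(cohort, theta, dt = 1e-3,
                                    method = c("euler", "expm")) {
  method <- match.arg(method)
  theta <- as_rate_vector(theta)
  nll_groups(theta, group_cohort(cohort, dt), dt, method)
}

# fminsearchbnd-style box transform: theta = lo + (hi - lo) * sin(x)^2
box_forward <- function(x, lo, hi) lo + (hi - lo) * sin(x)^2
box_inverse <- function(theta, lo, hi) {
  frac <- pmin(pmax((theta - lo) / (hi - lo), 1e-12), 1 - 1e-12)
  asin(sqrt(frac))
}

#' Maximum-likelihood estimation of the six dissemination rates
#'
#' Bounded derivative-free minimization of the negative log-likelihood:
#' rates are mapped to an unconstrained scale by the sinusoidal box
#' transform \eqn{\theta = lo + (hi-lo)\sin^2 x} (the \code{fminsearchbnd}
#' construction) and optimized by Nelder--Mead. Optionally the best of
#' \code{n_starts} starting points is taken: the supplied \code{init} plus
#' log-uniform random draws.
#'
#' @inheritParams negative_log_likelihood
#' @param lower,upper Per-rate bounds, per year (recycled to length 6).
#' @param init Initial rates (recycled to length 6).
#' @param n_starts Number of starts (1 = deterministic from \code{init}).
#' @param seed Seed for the random starts (global RNG state is restored).
#' @param max_eval Maximum function evaluations per start.
#' @param reltol Relative convergence tolerance on the objective.
#' @return A \code{fit_result}: list with \code{theta_hat}
#'   ([rate_vector()]), \code{nll}, \code{converged}, \code{n_evaluations},
#'   \code{bounds}, \code{starts} (per-start summaries), and the solver
#'   settings.
#' @export
fit_mle <- function(cohort, lower = 0, upper = 10, init = 0.01,
                    n_starts = 5, dt = 1e-3, method = c("euler", "expm"),
                    seed = 1L, max_eval = 5000, reltol = 1e-8) {
  method <- match.arg(method)
  lo <- rep_len(lower, 6L); hi <- rep_len(upper, 6L)
  init <- rep_len(init, 6L)
  if (any(lo < 0) || any(lo >= hi)) stop("bounds must satisfy 0 <= lower < upper")
  if (any(init < lo) || any(init > hi)) stop("init outside bounds")
  groups <- group_cohort(cohort, dt)
  obj <- function(x) nll_groups(as_rate_vector(box_forward(x, lo, hi)),
                                groups, dt, method)
  starts <- matrix(init, nrow = 6L, ncol = 1L)
  if (n_starts > 1L) {
    extra <- with_seed(seed, matrix(
      exp(stats::runif(6L * (n_starts - 1L),
                       log(pmax(lo, 1e-4)), log(pmin(hi, 1)))),
      nrow = 6L))
    starts <- cbind(starts, extra)
  }
  runs <- lapply(seq_len(ncol(starts)), function(s) {
    opt <- stats::optim(box_inverse(starts[, s], lo, hi), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = reltol))
    list(par = opt$par, theta = as_rate_vector(box_forward(opt$par, lo, hi)),
         nll = opt$value, converged = opt$convergence == 0L,
         n_evaluations = unname(opt$counts[1]))
  })
  best <- which.min(vapply(runs, `[[`, numeric(1), "nll"))
  # Re-start the simplex at the incumbent optimum until it stops improving
  # (Nelder-Mead can stall with a collapsed simplex).
  for (r in 1:3) {
    opt <- stats::optim(runs[[best]]$par, obj, method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = reltol))
    improved <- runs[[best]]$nll - opt$value
    runs[[best]] <- list(par = opt$par,
                         theta = as_rate_vector(box_forward(opt$par, lo, hi)),
                         nll = opt$value, converged = opt$convergence == 0L,
                         n_evaluations = runs[[best]]$n_evaluations +
                           unname(opt$counts[1]))
    if (improved < 1e-6) break
  }
  structure(list(
    theta_hat = runs[[best]]$theta,
    nll = runs[[best]]$nll,
    converged = runs[[best]]$converged,
    n_evaluations = sum(vapply(runs, `[[`, numeric(1), "n_evaluations")),
    bounds = cbind(lower = lo, upper = hi),
    n_patients = sum(groups$counts),
    dt = dt, method = method, n_starts = n_starts,
    starts = lapply(runs, function(r)
      list(nll = r$nll, converged = r$converged)),
    ci_lower = NULL, ci_upper = NULL, bootstrap_samples = NULL
  ), class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat(sprintf("Dissemination-rate fit (n = %d patients, nll = %.4f, %s)\n",
              x$n_patients, x$nll,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(rate = names(x$theta_hat),
                    estimate = as.numeric(x$theta_hat))
  if (!is.null(x$ci_lower)) {
    tab$ci_2.5 <- x$ci_lower
    tab$ci_97.5 <- x$ci_upper
  }
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot rate estimates with their confidence intervals
#'
#' One point per dissemination rate on a log scale, with percentile
#' bootstrap intervals when present.
#'
#' @param x A \code{fit_result}.
#' @param ... Passed to [graphics::plot()].
#' @exportS3Method base::plot
plot.fit_result <- function(x, ...) {
  est <- as.numeric(x$theta_hat)
  k <- seq_along(est)
  lo <- if (!is.null(x$ci_lower)) x$ci_lower else est
  hi <- if (!is.null(x$ci_upper)) x$ci_upper else est
  ylim <- range(c(est, lo[lo > 0], hi), na.rm = TRUE)
  graphics::plot(k, est, log = "y", xaxt = "n", xlab = "",
                 ylab = "dissemination rate (per year)", pch = 19,
                 ylim = ylim, ...)
  graphics::axis(1, at = k, labels = names(x$theta_hat))
  if (!is.null(x$ci_lower))
    graphics::segments(k, pmax(lo, ylim[1]), k, hi)
  invisible(x)
}

#' Parametric-bootstrap confidence intervals
#'
#' Resamples the cohort's metastasis states from the fitted chain at the
#' patients' (fixed) imputed tumor ages, refits each resample starting from
#' the point estimate, and reports percentile 2.5/97.5 bounds per rate.
#' Resamples whose refit does not converge are excluded (the effective
#' number of samples is reported).
#'
#' @param fit A \code{fit_result} from [fit_mle()].
#' @param cohort The prepared [cohort] the fit used.
#' @param B Number of bootstrap resamples (default 50).
#' @param seed Seed; resample \code{b} uses \code{seed + b}.
#' @param n_starts Starts per refit (default 1, from the point estimate).
#' @param ... Passed to [fit_mle()] (e.g. \code{max_eval}).
#' @return The \code{fit_result} with \code{ci_lower}, \code{ci_upper},
#'   \code{bootstrap_samples} (matrix, one row per converged resample) and
#'   \code{B_effective} filled in.
#' @export
bootstrap_ci <- function(fit, cohort, B = 50, seed = 1L, n_starts = 1, ...) {
  stopifnot(inherits(fit, "fit_result"), B >= 1)
  if (B == 1) warning("B = 1 gives a degenerate confidence interval")
  ages <- cohort$tumor_age_years
  if (is.null(ages)) stop("cohort is not prepared")
  samples <- matrix(NA_real_, nrow = B, ncol = 6L,
                    dimnames = list(NULL, names(fit$theta_hat)))
  ok <- logical(B)
  for (b in seq_len(B)) {
    flags <- with_seed(seed + b,
                       simulate_patient_states(fit$theta_hat, ages))
    boot <- cohort
    boot$bone <- flags[, "bone"]; boot$lung <- flags[, "lung"]
    boot$liver <- flags[, "liver"]; boot$brain <- flags[, "brain"]
    boot$state_index <- state_index(flags[, "bone"], flags[, "lung"],
                                    flags[, "liver"], flags[, "brain"])
    refit <- fit_mle(boot, lower = fit$bounds[, "lower"],
                     upper = fit$bounds[, "upper"],
                     init = as.numeric(fit$theta_hat),
                     n_starts = n_starts, dt = fit$dt, method = fit$method,
                     ...)
    ok[b] <- refit$converged
    if (refit$converged) samples[b, ] <- as.numeric(refit$theta_hat)
  }
  if (!all(ok))
    message(sum(!ok), " bootstrap refit(s) did not converge and were excluded")
  kept <- samples[ok, , drop = FALSE]
  fit$bootstrap_samples <- kept
  fit$B_effective <- nrow(kept)
  fit$ci_lower <- apply(kept, 2L, stats::quantile, probs = 0.025,
                        names = FALSE)
  fit$ci_upper <- apply(kept, 2L, stats::quantile, probs = 0.975,
                        names = FALSE)
  fit
}

#' Write a fit report as JSON
#'
#' Point estimates, negative log-likelihood, bounds, solver settings, and
#' (when present) bootstrap confidence intervals.
#'
#' @param fit A \code{fit_result}.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    theta_hat = as.list(unclass(fit$theta_hat)),
    nll = fit$nll,
    converged = fit$converged,
    n_evaluations = fit$n_evaluations,
    n_patients = fit$n_patients,
    bounds = list(lower = fit$bounds[, "lower"],
                  upper = fit$bounds[, "upper"]),
    solver = list(dt = fit$dt, method = fit$method,
                  n_starts = fit$n_starts)
  )
  if (!is.null(fit$ci_lower)) {
    report$ci_lower <- stats::setNames(as.list(fit$ci_lower),
                                       names(fit$theta_hat))
    report$ci_upper <- stats::setNames(as.list(fit$ci_upper),
                                       names(fit$theta_hat))
    report$B_effective <- fit$B_effective
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
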