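#' Cumulative site-positive patient counts
#'
#' Data mode (\code{theta = NULL}): the number of patients with tumor age at
#' most \code{t} and a metastasis at \code{site}. Model mode: the expected
#' count, i.e. the sum over patients with age at most \code{t} of the
#' model's marginal probability that \code{site} is involved at their own
#' age. Both are non-decreasing in \code{t}.
#'
#' @param cohort A prepared [cohort] (the validation group).
#' @param site One of \code{"bone"}, \code{"lung"}, \code{"liver"},
#'   \code{"brain"}.
#' @param t_grid Evaluation times, years.
#' @param theta \code{NULL} for data mode, or a [rate_vector()] for model
#'   mode.
#' @param dt,method Solver settings for model mode.
#' @return Numeric vector along \code{t_grid}.
#' @export
cumulative_counts <- function(cohort, site, t_grid, theta = NULL,
                              dt = 1e-3, method = c("euler", "expm")) {
  site <- match.arg(site, .SITES)
  method <- match.arg(method)
  if (nrow(cohort) == 0L) {
    warning("empty validation group; returning zeros")
    return(numeric(length(t_grid)))
  }
  ages <- cohort$tumor_age_years
  if (is.null(ages)) stop("cohort is not prepared")
  if (is.null(theta)) {
    pos <- cohort[[site]] == 1
    vapply(t_grid, function(t) sum(pos & ages <= t), numeric(1))
  } else {
    theta <- as_rate_vector(theta)
    if (all(theta == 0)) return(numeric(length(t_grid)))
    grid <- solve_master(theta, horizon = max(ages) + dt, dt = dt,
                         method = method)
    psite <- site_probability(grid, site, ages)
    vapply(t_grid, function(t) sum(psite[ages <= t]), numeric(1))
  }
}

#' Mean absolute percentage error against model counts
#'
#' \deqn{\mathrm{MAPE} = \frac{100}{M}\sum_k \left|\frac{x^{data}_k -
#' x^{model}_k}{x^{model}_k}\right|}
#' Note the denominator is the \emph{model} value. Points where the model
#' count is zero are skipped (with a warning) and \eqn{M} reduced
#' accordingly.
#'
#' @param x_model,x_data Equal-length series of cumulative counts.
#' @return MAPE in percent; \code{NA} if no usable points remain.
#' @examples
#' mape(c(100, 200), c(110, 180)) # 10
#' @export
mape <- function(x_model, x_data) {
  stopifnot(length(x_model) == length(x_data), length(x_model) >= 1)
  keep <- x_model != 0
  if (!all(keep))
    warning(sum(!keep), " point(s) with a zero model count skipped")
  if (!any(keep)) return(NA_real_)
  100 / sum(keep) *
    sum(abs(x_data[keep] - x_model[keep]) / x_model[keep])
}

#' k-fold cross-validation of the seeding model
#'
#' Randomly partitions the cohort into \code{k} near-equal folds; for each
#' fold, fits the rates on the remaining data and compares model and data
#' cumulative site-positive counts on the held-out fold, by MAPE on a
#' time grid spanning the fold's age range in \code{grid_step} increments.
#'
#' @param cohort A prepared [cohort] with at least \code{2k} records.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param grid_step MAPE evaluation increment, years.
#' @param dt,method Solver settings.
#' @param ... Passed to [fit_mle()] (e.g. \code{n_starts}, \code{init}).
#' @return A \code{cv_report}: \code{fold} (assignment per patient),
#'   \code{theta} (k x 6 matrix of per-fold estimates), \code{mape}
#'   (k x 4 matrix, sites in columns; \code{NA} where the fold has no
#'   site-positive patients), \code{mean_mape} (per site) and
#'   \code{overall_mape}.
#' @export
cross_validate <- function(cohort, k = 10, seed = 1L, grid_step = 0.25,
                           dt = 1e-3, method = c("euler", "expm"), ...) {
  method <- match.arg(method)
  n <- nrow(cohort)
  if (n < 2 * k)
    stop("cohort too small for ", k, "-fold cross-validation (folds of size < 2)")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  theta_mat <- matrix(NA_real_, k, 6L,
                      dimnames = list(NULL, .RATE_NAMES))
  mape_mat <- matrix(NA_real_, k, 4L, dimnames = list(NULL, .SITES))
  for (f in seq_len(k)) {
    train <- cohort[fold != f, , drop = FALSE]
    test <- cohort[fold == f, , drop = FALSE]
    fit <- fit_mle(train, dt = dt, method = method, ...)
    theta_mat[f, ] <- as.numeric(fit$theta_hat)
    t_grid <- seq(grid_step, max(test$tumor_age_years) + grid_step,
                  by = grid_step)
    for (s in .SITES) {
      if (sum(test[[s]]) == 0) next  # MAPE undefined for this fold/site
      xm <- cumulative_counts(test, s, t_grid, theta = fit$theta_hat,
                              dt = dt, method = method)
      xd <- cumulative_counts(test, s, t_grid)
      mape_mat[f, s] <- suppressWarnings(mape(xm, xd))
    }
  }
  structure(list(fold = fold, k = k, seed = seed,
                 theta = theta_mat, mape = mape_mat,
                 mean_mape = colMeans(mape_mat, na.rm = TRUE),
                 overall_mape = mean(mape_mat, na.rm = TRUE)),
            class = "cv_report")
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat("mean MAPE per site (%):\n")
  print(round(x$mean_mape, 2))
  cat(sprintf("overall: %.2f%%\n", x$overall_mape))
  invisible(x)
}

#' Probability of metastasis at a given tumor age or diameter
#'
#' State-occupancy probabilities of the seeding chain at time \code{t}
#' (years since tumor initiation), or at the age imputed from a diameter.
#' The probability of having developed any metastasis is \eqn{1 - P_1(t)}.
#' Probabilities are computed with the matrix-exponential solution.
#'
#' @param theta A [rate_vector()].
#' @param t Tumor age(s), years. Exactly one of \code{t}, \code{diameter_mm}
#'   must be given.
#' @param diameter_mm Tumor diameter(s), mm, converted via the growth law.
#' @param growth A [gompertz_params()] (used with \code{diameter_mm}).
#' @return A data frame with \code{time_years}, (if applicable)
#'   \code{diameter_mm}, \code{P1}..\code{P16} and \code{p_any}.
#' @examples
#' metastasis_probability(default_theta_true(), t = c(2.4, 12.4))
#' @export
metastasis_probability <- function(theta, t = NULL, diameter_mm = NULL,
                                   growth = gompertz_params()) {
  theta <- as_rate_vector(theta)
  if (is.null(t) == is.null(diameter_mm))
    stop("give exactly one of t or diameter_mm")
  if (is.null(t)) t <- diameter_to_age(diameter_mm, growth)
  probs <- t(vapply(t, function(ti) exact_state_distribution(theta, ti),
                    numeric(16)))
  out <- data.frame(time_years = t)
  if (!is.null(diameter_mm)) out$diameter_mm <- diameter_mm
  out <- cbind(out, stats::setNames(as.data.frame(probs),
                                    paste0("P", 1:16)))
  out$p_any <- 1 - out$P1
  out
}

#' Quantities derived from the fitted rates
#'
#' Secondary-to-primary seeding ratios for liver (\code{luli/tuli}) and
#' brain (\code{lubr/tubr}); the relative colonizing ability of liver
#' versus brain, i.e. the secondary rates normalized by each organ's share
#' of cardiac output, \code{(luli/f_liver) / (lubr/f_brain)}; and the lung's
#' seeding influx (\code{tulu}) versus outflux (\code{luli + lubr}).
#'
#' @param theta A [rate_vector()].
#' @param f_liver,f_brain Fractions of cardiac output reaching liver and
#'   brain (defaults 6.5\% and 12\%).
#' @return Named list; ratios with a zero denominator are \code{NA} with a
#'   warning.
#' @examples
#' derived_ratios(default_theta_true())
#' @export
derived_ratios <- function(theta, f_liver = 0.065, f_brain = 0.12) {
  theta <- as_rate_vector(theta)
  stopifnot(f_liver > 0, f_brain > 0)
  safe_div <- function(a, b, what) {
    if (b == 0) {
      warning("zero denominator: ", what, " undefined")
      return(NA_real_)
    }
    a / b
  }
  list(
    secondary_primary_liver = safe_div(theta[["luli"]], theta[["tuli"]],
                                       "luli/tuli"),
    secondary_primary_brain = safe_div(theta[["lubr"]], theta[["tubr"]],
                                       "lubr/tubr"),
    colonizing_ability = safe_div(theta[["luli"]] / f_liver,
                                  theta[["lubr"]] / f_brain,
                                  "colonizing ability"),
    lung_influx = theta[["tulu"]],
    lung_outflux = theta[["luli"]] + theta[["lubr"]]
  )
}
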