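#' Gaussian log-likelihood of model parameters for a dataset
#'
#' Residuals are per-replicate differences between measured and predicted
#' log2 fold-changes; the common noise variance is profiled out, giving
#' `l = -(n/2) (ln(2 pi RSS/n) + 1)`. The RSS is floored at 1e-12 so a
#' perfect fit stays finite.
#'
#' @param params a `ModelParameters` object.
#' @param dataset a `PerturbationDataset`.
#' @param network the `SignalingNetwork` the parameters refer to.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, dataset, network) {
  if (!nrow(dataset$values)) stop("empty dataset")
  res <- model_residuals(network, params, dataset)
  ll_from_rss(sum(res^2), length(res))
}

#' Residuals of the steady-state model against a dataset
#'
#' @inheritParams log_likelihood
#' @return Numeric vector, one residual per measured value.
#' @export
model_residuals <- function(network, params, dataset) {
  keys <- condition_keys(dataset)
  uc <- unique(keys)
  conds <- row_conditions(dataset)[match(uc, keys)]
  pred <- vapply(conds, function(cond) {
    steady_state(network, params, cond)[colnames(dataset$values)]
  }, numeric(ncol(dataset$values)))
  pred_rows <- t(pred)[match(keys, uc), , drop = FALSE]
  as.vector(dataset$values - pred_rows)
}

#' Fit the steady-state model to one perturbation dataset
#'
#' Nonlinear least squares (Levenberg-Marquardt with an analytic residual
#' Jacobian) from `n_restarts` random initializations; edge strengths start
#' inside their declared sign, inhibitor and stimulus strengths start in
#' (0, 3). Parameter sets whose edge-strength matrix is unstable (spectral
#' radius >= 1) are rejected; the best stable restart is returned.
#'
#' @param network a `SignalingNetwork`.
#' @param dataset a `PerturbationDataset` of log2 fold-changes whose
#'   analytes are measured network nodes.
#' @param n_restarts number of random initializations (>= 1).
#' @param seed RNG seed; fits are deterministic given the seed.
#' @param maxiter Levenberg-Marquardt iteration cap per restart.
#' @param init optional `ModelParameters` used as the first start.
#' @return An object of class `FitResult`: fitted `params`, `rss`, `loglik`,
#'   `n_data`, `n_params`, `restart_rss`, `converged`, `seed`, plus the
#'   network/dataset needed by [profile_ci()].
#' @export
fit_model <- function(network, dataset, n_restarts = 100, seed = NULL,
                      maxiter = 150, init = NULL) {
  if (n_restarts < 1 && is.null(init)) stop("n_restarts must be >= 1")
  datasets <- list(line = dataset)
  linkmap <- all_shared_linkmap(network, names(datasets))
  obj <- build_objective(network, datasets, linkmap)
  if (obj$n_theta >= obj$n_data) {
    warning("model has as many parameters as data points (",
            obj$n_theta, " vs ", obj$n_data, ")")
  }
  inits <- if (is.null(init)) NULL else list(unname(unlist_params(init)))
  eng <- fit_engine(obj, n_restarts = n_restarts, seed = seed, inits = inits,
                    maxiter = maxiter)
  structure(list(
    params = obj$assemble(eng$theta)[[1]],
    theta = stats::setNames(eng$theta, obj$theta_names),
    rss = eng$rss,
    loglik = ll_from_rss(eng$rss, obj$n_data),
    n_data = obj$n_data, n_params = obj$n_theta,
    restart_rss = eng$restart_rss, converged = eng$converged,
    spectral_radius = eng$spectral_radius, seed = seed,
    network = network, datasets = datasets, linkmap = linkmap
  ), class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: RSS=%.6g, logLik=%.4f, %d params / %d data points%s\n",
              x$rss, x$loglik, x$n_params, x$n_data,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `D = 2 (l_free - l_shared)`, floored at zero, compared to a chi-square
#' with `df` degrees of freedom (the difference in free-parameter count).
#'
#' @param fit_free fit of the larger (free) model.
#' @param fit_shared fit of the nested (constrained) model on the same data.
#' @param df degrees of freedom; defaults to the parameter-count difference.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_free, fit_shared, df = NULL) {
  if (fit_free$n_data != fit_shared$n_data) {
    stop("fits are not nested: different data sizes")
  }
  diff_np <- fit_free$n_params - fit_shared$n_params
  if (diff_np < 1) stop("fits are not nested: free model must have more parameters")
  if (!is.null(fit_free$theta) && !is.null(fit_shared$theta)) {
    base_free <- unique(sub("@.*$", "", names(fit_free$theta)))
    base_shared <- unique(sub("@.*$", "", names(fit_shared$theta)))
    if (!setequal(base_free, base_shared)) {
      stop("fits are not nested: parameter sets differ")
    }
  }
  df <- df %||% diff_np
  if (df < 1) stop("df must be >= 1")
  D <- max(0, 2 * (fit_free$loglik - fit_shared$loglik))
  list(statistic = D, df = df,
       p_value = stats::pchisq(D, df, lower.tail = FALSE))
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Walks a grid outward from the fitted value, re-optimizing all other
#' parameters at each step (warm-started from the previous grid point), and
#' reports where twice the log-likelihood drop crosses the chi-square(1)
#' quantile at `level`. A bound that runs off the grid without crossing is
#' reported as infinite and flags the parameter non-identifiable.
#'
#' @param fit a `FitResult` from [fit_model()].
#' @param param_name name of the parameter to profile.
#' @param level confidence level (default 0.95, threshold 3.841 on 2 dl).
#' @param step grid step; defaults to `0.05 * (1 + |estimate|)`.
#' @param max_steps grid points per direction.
#' @return List with `lower`, `upper`, `identifiable`, `level`.
#' @export
profile_ci <- function(fit, param_name, level = 0.95, step = NULL,
                       max_steps = 40) {
  obj <- build_objective(fit$network, fit$datasets, fit$linkmap)
  ti <- match(param_name, obj$theta_names)
  if (is.na(ti)) stop("unknown parameter: ", param_name)
  theta_hat <- unname(fit$theta)
  val_hat <- theta_hat[ti]
  thr <- stats::qchisq(level, 1)
  n <- obj$n_data
  rss_hat <- max(fit$rss, 1e-12)
  step <- step %||% (0.05 * (1 + abs(val_hat)))

  profile_dir <- function(dir) {
    free <- theta_hat[-ti]
    d_prev <- 0
    v_prev <- val_hat
    for (s in seq_len(max_steps)) {
      v <- val_hat + dir * s * step
      fn_sub <- function(p) {
        full <- numeric(obj$n_theta)
        full[-ti] <- p
        full[ti] <- v
        obj$fn(full)
      }
      jac_sub <- function(p) {
        full <- numeric(obj$n_theta)
        full[-ti] <- p
        full[ti] <- v
        obj$jac(full)[, -ti, drop = FALSE]
      }
      f <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = free, fn = fn_sub, jac = jac_sub,
                             control = minpack.lm::nls.lm.control(maxiter = 100))),
        error = function(e) NULL)
      if (is.null(f)) break
      free <- f$par
      d <- n * log(max(f$deviance, 1e-12) / rss_hat)
      if (d >= thr) {
        frac <- (thr - d_prev) / (d - d_prev)
        return(v_prev + frac * (v - v_prev))
      }
      d_prev <- d
      v_prev <- v
    }
    dir * Inf
  }

  lower <- profile_dir(-1)
  upper <- profile_dir(1)
  list(lower = lower, upper = upper,
       identifiable = is.finite(lower) && is.finite(upper), level = level)
}
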