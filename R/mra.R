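#' Steady-state perturbation-response model
#'
#' The model is linear in log2 space, in the spirit of modular response
#' analysis: each node's log2 fold-change is the strength-weighted sum of the
#' *transmitted* activities of its upstream nodes plus any external stimulus,
#'
#'   x = R (x - beta o delta_inh) + p_stim,
#'
#' where `R[i, j]` is the strength of edge j -> i, `beta o delta_inh` is the
#' inhibitor attenuation applied to inhibited nodes, and `p_stim` holds
#' stimulus strengths at their entry nodes. Inhibitors act only on a node's
#' outgoing transmission, so the inhibited kinase's own phospho-level still
#' responds to upstream input — this is what lets phospho-MEK *rise* under
#' MEK inhibition when an ERK->RAF negative feedback is relieved.
#'
#' @name mra_model
NULL

node_index <- function(network) {
  stats::setNames(seq_along(network$nodes), network$nodes)
}

# Strength matrix R (target row, source column) from parameters.
response_matrix <- function(network, params) {
  idx <- node_index(network)
  n <- length(idx)
  R <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  R[cbind(idx[network$edges$to], idx[network$edges$from])] <- params$edges
  R
}

# Inhibitor attenuation vector b and stimulus input vector p for a condition.
condition_vectors <- function(network, params, condition) {
  idx <- node_index(network)
  b <- p <- numeric(length(idx))
  for (inh in condition$inhibitors %||% character()) {
    if (!inh %in% names(network$inhibitors)) stop("unknown inhibitor: ", inh)
    b[idx[network$inhibitors[inh]]] <- b[idx[network$inhibitors[inh]]] +
      params$inhibitors[inh]
  }
  for (st in condition$stimuli %||% character()) {
    if (!st %in% names(network$stimuli)) stop("unknown stimulus: ", st)
    p[idx[network$stimuli[st]]] <- p[idx[network$stimuli[st]]] +
      params$stimuli[st]
  }
  list(b = b, p = p)
}

#' Spectral-radius stability check
#'
#' The linear steady state is the limit of the signal-relay iteration only
#' when the spectral radius of the edge-strength matrix is below 1; larger
#' radii mean feedback loops amplify without bound.
#'
#' @param params a `ModelParameters` object.
#' @param network the matching `SignalingNetwork`.
#' @return List with `spectral_radius` and logical `ok`
#'   (`spectral_radius < 1 - 1e-9`).
#' @export
stability_check <- function(params, network) {
  R <- response_matrix(network, params)
  rho <- max(Mod(eigen(R, only.values = TRUE)$values))
  list(spectral_radius = rho, ok = rho < 1 - 1e-9)
}

#' Predict steady-state log2 fold-changes for one condition
#'
#' Solves the linear fixed point `x = R (x - b) + p` directly via
#' `(I - R) x = p - R b`. The unperturbed control returns the zero vector:
#' all responses are fold-changes relative to it.
#'
#' @param network a `SignalingNetwork`.
#' @param params a `ModelParameters` object (must be stable, see
#'   [stability_check()]).
#' @param condition list with character elements `stimuli` and `inhibitors`
#'   (either may be empty) naming applied treatments.
#' @return Named numeric vector of log2 fold-changes, one per network node.
#' @examples
#' net <- signaling_network(data.frame(from = "A", to = "B", sign = 1),
#'                          stimuli = c(S = "A"), measured = "B")
#' par <- model_parameters(net, edges = c("A->B" = 0.5), stimuli = c(S = 1))
#' steady_state(net, par, list(stimuli = "S"))  # A = 1, B = 0.5
#' @export
steady_state <- function(network, params, condition = list()) {
  st <- stability_check(params, network)
  if (!st$ok) {
    stop("unstable model: spectral radius ", format(st$spectral_radius, digits = 6))
  }
  R <- response_matrix(network, params)
  cv <- condition_vectors(network, params, condition)
  x <- solve(diag(nrow(R)) - R, cv$p - R %*% cv$b)
  stats::setNames(drop(x), network$nodes)
}

#' Brute-force fixed-point iteration (independent oracle)
#'
#' Iterates the signal-relay map `x <- R (x - b) + p` from zero until the
#' max-norm update falls below `tol`. Exists as an implementation-independent
#' cross-check of [steady_state()]; the two agree within ~10 * tol on any
#' stable model.
#'
#' @inheritParams steady_state
#' @param tol convergence tolerance on the max-norm update.
#' @param max_iter iteration cap; exceeding it (e.g. for an unstable model)
#'   is an error.
#' @return Named numeric vector of log2 fold-changes per node.
#' @export
fixed_point_oracle <- function(network, params, condition = list(),
                               tol = 1e-10, max_iter = 10000) {
  R <- response_matrix(network, params)
  cv <- condition_vectors(network, params, condition)
  x <- numeric(nrow(R))
  for (it in seq_len(max_iter)) {
    x_new <- drop(R %*% (x - cv$b)) + cv$p
    if (max(abs(x_new - x)) < tol) {
      return(stats::setNames(x_new, network$nodes))
    }
    x <- x_new
  }
  stop("fixed-point iteration did not converge in ", max_iter,
       " iterations (unstable model?)")
}

#' Simulate a noise-free perturbation dataset
#'
#' Runs [steady_state()] for every condition of a perturbation scheme and
#' collects the measured-node responses into a [perturbation_dataset()].
#'
#' @inheritParams steady_state
#' @param scheme list of conditions, each a list with `stimuli` and
#'   `inhibitors` character vectors; see [default_scheme()].
#' @return A `PerturbationDataset` with one row per condition (1 replicate),
#'   analytes = the network's measured nodes.
#' @export
simulate_dataset <- function(network, params, scheme = default_scheme(network)) {
  if (!length(scheme)) stop("empty perturbation scheme")
  vals <- vapply(scheme, function(cond) {
    steady_state(network, params, cond)[network$measured]
  }, numeric(length(network$measured)))
  vals <- t(matrix(vals, nrow = length(network$measured),
                   dimnames = list(network$measured, NULL)))
  all_tr <- unique(unlist(lapply(scheme, function(cond) {
    c(cond$stimuli, cond$inhibitors)
  }))) %||% character()
  all_tr <- c(
    intersect(names(network$stimuli), all_tr),
    intersect(names(network$inhibitors), all_tr)
  )
  tr <- as.data.frame(
    do.call(rbind, lapply(scheme, function(cond) {
      as.integer(all_tr %in% c(cond$stimuli, cond$inhibitors))
    }))
  )
  names(tr) <- all_tr
  kinds <- stats::setNames(
    ifelse(all_tr %in% names(network$stimuli), "stimulus", "inhibitor"), all_tr)
  perturbation_dataset(tr, vals, kinds = kinds)
}
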