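# Internal fitting engine: stacked residuals of the steady-state model over
# one or several cell lines, with parameters linked across lines by a
# link map, plus the analytic residual Jacobian obtained by implicit
# differentiation of (I - R) X = P - R B.

# A link map is a named list: parameter name -> list of character vectors
# (groups of lines sharing one value). Default: all lines in one group.
all_shared_linkmap <- function(network, lines) {
  nm <- c(edge_names(network), names(network$stimuli), names(network$inhibitors))
  stats::setNames(lapply(nm, function(p) list(lines)), nm)
}

# Precompute the per-dataset design: unique conditions, row membership,
# stimulus/inhibitor incidence matrices, measured-node indices.
prepare_dataset <- function(network, dataset) {
  idx <- node_index(network)
  keys <- condition_keys(dataset)
  uc <- unique(keys)
  row_cond <- match(keys, uc)
  rc <- row_conditions(dataset)
  conds <- rc[match(uc, keys)]
  sn <- names(network$stimuli)
  bn <- names(network$inhibitors)
  cond_stim <- matrix(0, length(sn), length(uc), dimnames = list(sn, uc))
  cond_inh <- matrix(0, length(bn), length(uc), dimnames = list(bn, uc))
  for (j in seq_along(conds)) {
    unknown <- setdiff(c(conds[[j]]$stimuli, conds[[j]]$inhibitors), c(sn, bn))
    if (length(unknown)) stop("treatment not in network: ", unknown[1])
    cond_stim[conds[[j]]$stimuli, j] <- 1
    cond_inh[conds[[j]]$inhibitors, j] <- 1
  }
  stim_entry <- matrix(0, length(idx), length(sn))
  if (length(sn)) stim_entry[cbind(idx[network$stimuli], seq_along(sn))] <- 1
  inh_target <- matrix(0, length(idx), length(bn))
  if (length(bn)) inh_target[cbind(idx[network$inhibitors], seq_along(bn))] <- 1
  meas_idx <- idx[colnames(dataset$values)]
  if (anyNA(meas_idx)) {
    stop("analyte not a network node: ",
         colnames(dataset$values)[which(is.na(meas_idx))[1]])
  }
  list(row_cond = row_cond, n_cond = length(uc),
       cond_stim = cond_stim, cond_inh = cond_inh,
       stim_entry = stim_entry, inh_target = inh_target,
       meas_idx = meas_idx, values_vec = as.vector(dataset$values),
       n_resid = length(dataset$values))
}

build_objective <- function(network, datasets, linkmap) {
  lines <- names(datasets)
  if (is.null(lines) || any(!nzchar(lines))) stop("datasets must be a named list")
  nn <- length(network$nodes)
  idx <- node_index(network)
  en <- edge_names(network)
  sn <- names(network$stimuli)
  bn <- names(network$inhibitors)
  local_names <- c(en, sn, bn)
  K <- length(local_names)
  class_of <- rep(c("edge", "stimulus", "inhibitor"),
                  c(length(en), length(sn), length(bn)))
  edge_lin <- (idx[network$edges$from] - 1L) * nn + idx[network$edges$to]
  edge_src <- idx[network$edges$from]
  edge_tgt <- idx[network$edges$to]
  stim_node <- idx[network$stimuli]
  inh_node <- idx[network$inhibitors]
  edge_sign <- network$edges$sign

  if (!setequal(names(linkmap), local_names)) {
    stop("link map must cover exactly the model parameters")
  }
  theta_names <- character(0)
  theta_class <- character(0)
  theta_sign <- numeric(0)
  tidx <- matrix(NA_integer_, K, length(lines),
                 dimnames = list(local_names, lines))
  for (k in seq_len(K)) {
    p <- local_names[k]
    groups <- linkmap[[p]]
    covered <- unlist(groups)
    if (!setequal(covered, lines) || anyDuplicated(covered)) {
      stop("groups for parameter ", p, " must partition the cell lines")
    }
    for (g in groups) {
      nm <- if (length(groups) == 1) p else paste0(p, "@", g[1])
      theta_names <- c(theta_names, nm)
      theta_class <- c(theta_class, class_of[k])
      theta_sign <- c(theta_sign,
                      if (class_of[k] == "edge") edge_sign[k] else NA_real_)
      tidx[k, g] <- length(theta_names)
    }
  }
  n_theta <- length(theta_names)

  prep <- lapply(datasets, function(d) prepare_dataset(network, d))
  n_resid <- vapply(prep, `[[`, numeric(1), "n_resid")
  offset <- c(0, cumsum(n_resid))
  total <- sum(n_resid)
  Imat <- diag(nn)
  Rtemplate <- matrix(0, nn, nn)
  E <- length(en); S <- length(sn); B <- length(bn)

  line_pieces <- function(theta, l) {
    loc <- theta[tidx[, l]]
    R <- Rtemplate
    R[edge_lin] <- loc[seq_len(E)]
    s <- loc[E + seq_len(S)]
    b <- loc[E + S + seq_len(B)]
    pr <- prep[[l]]
    Bmat <- pr$inh_target %*% (pr$cond_inh * b)
    Pmat <- pr$stim_entry %*% (pr$cond_stim * s)
    list(R = R, A = Imat - R, Smat = Pmat - R %*% Bmat, Bmat = Bmat, pr = pr)
  }

  fn <- function(theta) {
    res <- numeric(total)
    for (li in seq_along(lines)) {
      l <- lines[li]
      pc <- line_pieces(theta, l)
      rows <- (offset[li] + 1):offset[li + 1]
      X <- tryCatch(solve(pc$A, pc$Smat), error = function(e) NULL)
      if (is.null(X)) {
        res[rows] <- 1e6
      } else {
        pred <- t(X[pc$pr$meas_idx, pc$pr$row_cond, drop = FALSE])
        res[rows] <- pc$pr$values_vec - as.vector(pred)
      }
    }
    res
  }

  jac <- function(theta) {
    J <- matrix(0, total, n_theta)
    for (li in seq_along(lines)) {
      l <- lines[li]
      pc <- line_pieces(theta, l)
      pr <- pc$pr
      X <- tryCatch(solve(pc$A, pc$Smat), error = function(e) NULL)
      if (is.null(X)) next
      Xt <- X - pc$Bmat
      nc <- pr$n_cond
      bigM <- matrix(0, nn, K * nc)
      for (k in seq_len(K)) {
        cols <- (k - 1L) * nc + seq_len(nc)
        if (class_of[k] == "edge") {
          bigM[edge_tgt[k], cols] <- Xt[edge_src[k], ]
        } else if (class_of[k] == "stimulus") {
          j <- k - E
          bigM[stim_node[j], cols] <- pr$cond_stim[j, ]
        } else {
          j <- k - E - S
          bigM[, cols] <- -pc$R[, inh_node[j]] %o% pr$cond_inh[j, ]
        }
      }
      dX <- solve(pc$A, bigM)
      rows <- (offset[li] + 1):offset[li + 1]
      for (k in seq_len(K)) {
        cols <- (k - 1L) * nc + seq_len(nc)
        blk <- dX[pr$meas_idx, cols, drop = FALSE][, pr$row_cond, drop = FALSE]
        J[rows, tidx[k, li]] <- -as.vector(t(blk))
      }
    }
    J
  }

  assemble <- function(theta) {
    out <- lapply(lines, function(l) {
      loc <- theta[tidx[, l]]
      structure(list(
        edges = stats::setNames(loc[seq_len(E)], en),
        stimuli = stats::setNames(loc[E + seq_len(S)], sn),
        inhibitors = stats::setNames(loc[E + S + seq_len(B)], bn)
      ), class = "ModelParameters")
    })
    stats::setNames(out, lines)
  }

  max_rho <- function(theta) {
    max(vapply(seq_along(lines), function(li) {
      R <- Rtemplate
      R[edge_lin] <- theta[tidx[seq_len(E), li]]
      max(Mod(eigen(R, only.values = TRUE)$values))
    }, numeric(1)))
  }

  list(fn = fn, jac = jac, assemble = assemble, max_rho = max_rho,
       theta_names = theta_names, theta_class = theta_class,
       theta_sign = theta_sign, n_theta = n_theta, n_data = total,
       lines = lines, tidx = tidx, local_names = local_names,
       class_of = class_of)
}

# Random initialization: edge strengths respect declared signs, stimulus
# and inhibitor strengths start positive.
random_theta <- function(obj) {
  vapply(seq_len(obj$n_theta), function(j) {
    cls <- obj$theta_class[j]
    if (cls == "edge") {
      sg <- obj$theta_sign[j]
      if (is.na(sg)) stats::runif(1, -1, 1)
      else if (sg > 0) stats::runif(1, 0, 1)
      else stats::runif(1, -1, 0)
    } else {
      stats::runif(1, 0, 3)
    }
  }, numeric(1))
}

# Levenberg-Marquardt multistart over the objective. `inits` are tried
# first; `n_restarts` random starts follow. Unstable solutions (spectral
# radius >= 1) are rejected; the best stable solution wins.
fit_engine <- function(obj, n_restarts = 1, seed = NULL, inits = NULL,
                       maxiter = 150, use_jac = TRUE) {
  runs <- with_seed(seed, {
    starts <- c(inits %||% list(),
                lapply(seq_len(n_restarts), function(i) random_theta(obj)))
    if (!length(starts)) stop("need at least one start (inits or n_restarts >= 1)")
    lapply(starts, function(p0) {
      tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = p0, fn = obj$fn, jac = if (use_jac) obj$jac else NULL,
          control = minpack.lm::nls.lm.control(maxiter = maxiter))),
        error = function(e) NULL)
    })
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimizer restarts failed")
  restart_rss <- rep(NA_real_, length(runs))
  restart_rss[ok] <- vapply(runs[ok], `[[`, numeric(1), "deviance")
  rho <- rep(NA_real_, length(runs))
  rho[ok] <- vapply(runs[ok], function(r) obj$max_rho(r$par), numeric(1))
  stable <- ok & rho < 1 - 1e-9
  if (!any(stable)) {
    stop("no restart produced a stable parameter set (min spectral radius ",
         format(min(rho, na.rm = TRUE), digits = 4), ")")
  }
  best <- which(stable)[which.min(restart_rss[stable])]
  r <- runs[[best]]
  list(theta = r$par, rss = r$deviance, restart_rss = restart_rss,
       converged = r$info %in% 1:4, niter = r$niter,
       spectral_radius = rho[best])
}

# Gaussian log-likelihood with the common variance profiled out:
# l = -(n/2) (ln(2 pi RSS/n) + 1), RSS floored to keep the perfect-fit
# limit finite.
ll_from_rss <- function(rss, n) {
  rss <- max(rss, 1e-12)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}
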