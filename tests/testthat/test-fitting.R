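test_that("the profiled Gaussian log-likelihood follows its closed forms", {
  net <- mapk_network()
  par <- mapk_params(net)
  base <- simulate_dataset(net, par)
  n <- length(base$values)
  set.seed(3)
  r <- matrix(stats::rnorm(n, 0, 0.2), nrow(base$values))

  d1 <- perturbation_dataset(base$treatments, base$values + r, kinds = base$kinds)
  d2 <- perturbation_dataset(base$treatments, base$values + 2 * r, kinds = base$kinds)
  l1 <- log_likelihood(par, d1, net)
  l2 <- log_likelihood(par, d2, net)
  # RSS x 4  =>  delta l = -n ln 2
  expect_equal(l2 - l1, -n * log(2), tolerance = 1e-10)

  # equal RSS and n give equal likelihoods regardless of residual layout
  d3 <- perturbation_dataset(base$treatments, base$values + r[, c(2, 1, 3, 4)],
                             kinds = base$kinds)
  expect_equal(log_likelihood(par, d3, net), l1, tolerance = 1e-10)

  # perfect fit is guarded by the RSS floor, not infinite
  expect_true(is.finite(log_likelihood(par, base, net)))
  empty <- perturbation_dataset(base$treatments[0, , drop = FALSE],
                                base$values[0, , drop = FALSE])
  expect_error(log_likelihood(par, empty, net), "empty")
})

test_that("likelihood-ratio p-values match the chi-square oracle", {
  fit_at <- function(loglik, n_params) {
    list(loglik = loglik, n_params = n_params, n_data = 100)
  }
  expect_equal(lrt(fit_at(5, 3), fit_at(5, 2))$p_value, 1)
  expect_equal(lrt(fit_at(3.841 / 2, 3), fit_at(0, 2))$p_value,
               stats::pchisq(3.841, 1, lower.tail = FALSE))
  expect_equal(lrt(fit_at(3.841 / 2, 3), fit_at(0, 2))$p_value, 0.05,
               tolerance = 1e-3)
  expect_equal(lrt(fit_at(6.635 / 2, 3), fit_at(0, 2))$p_value, 0.01,
               tolerance = 1e-3)
  # a worse "free" likelihood is floored at D = 0
  expect_equal(lrt(fit_at(-1, 3), fit_at(0, 2))$statistic, 0)
  # non-nested inputs are refused
  bad <- fit_at(0, 2); bad$n_data <- 50
  expect_error(lrt(fit_at(0, 3), bad), "not nested")
  expect_error(lrt(fit_at(0, 2), fit_at(0, 2)), "not nested")
})

test_that("noise-free data from a fully measured network are recovered exactly", {
  net <- mapk_network()
  truth <- mapk_params(net)
  d <- generate_perturbation_data(net, truth, noise_sd = 0, n_replicates = 1,
                                  seed = 1)
  fit <- fit_model(net, d, n_restarts = 10, seed = 42)
  expect_lt(fit$rss, 1e-10)
  expect_equal(coef(fit$params), coef(truth), tolerance = 1e-4)
})

test_that("more restarts never worsen the best RSS under a shared seed", {
  net <- default_network()
  d <- generate_perturbation_data(net, default_true_params(net),
                                  noise_sd = 0.1, seed = 5)
  f1 <- fit_model(net, d, n_restarts = 1, seed = 7, maxiter = 60)
  f8 <- fit_model(net, d, n_restarts = 8, seed = 7, maxiter = 60)
  expect_lte(f8$rss, f1$rss + 1e-12)
  expect_equal(f8$restart_rss[1], f1$restart_rss[1])
})

test_that("the fit is invariant to the ordering of dataset rows", {
  net <- mapk_network()
  d <- generate_perturbation_data(net, mapk_params(net), noise_sd = 0.1,
                                  seed = 2)
  perm <- sample(nrow(d$values))
  d_perm <- perturbation_dataset(d$treatments[perm, , drop = FALSE],
                                 d$values[perm, , drop = FALSE],
                                 kinds = d$kinds,
                                 replicate = d$replicate[perm])
  f1 <- fit_model(net, d, n_restarts = 3, seed = 11)
  f2 <- fit_model(net, d_perm, n_restarts = 3, seed = 11)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-8)
})

test_that("analytic and finite-difference Jacobians of the objective agree", {
  net <- default_network()
  datasets <- list(
    a = generate_perturbation_data(net, default_true_params(net),
                                   noise_sd = 0.1, seed = 21),
    b = generate_perturbation_data(net, default_true_params(net, -0.3),
                                   noise_sd = 0.1, seed = 22))
  lm_map <- persignal:::all_shared_linkmap(net, names(datasets))
  lm_map[["ERK->RAF"]] <- list("a", "b")
  obj <- persignal:::build_objective(net, datasets, lm_map)
  set.seed(1)
  theta <- persignal:::random_theta(obj) * 0.5
  J <- obj$jac(theta)
  h <- 1e-6
  J_num <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, numeric(obj$n_data))
  expect_equal(J, J_num, tolerance = 1e-5)
})

test_that("profile likelihood flags flat directions and brackets the truth", {
  # an edge into an unmeasured leaf node cannot be identified
  net <- signaling_network(data.frame(from = "A", to = "B", sign = 1),
                           stimuli = c(S = "A"), measured = "A")
  d <- simulate_dataset(
    net,
    model_parameters(net, edges = c("A->B" = 0.7), stimuli = c(S = 1)),
    list(list(stimuli = character(), inhibitors = character()),
         list(stimuli = "S", inhibitors = character())))
  fit <- suppressWarnings(fit_model(net, d, n_restarts = 3, seed = 1))
  ci <- profile_ci(fit, "A->B", level = 0.95, max_steps = 10)
  expect_false(ci$identifiable)

  # identifiable parameters of the fully measured cascade bracket the truth
  net2 <- mapk_network()
  truth <- mapk_params(net2)
  d2 <- generate_perturbation_data(net2, truth, noise_sd = 0, n_replicates = 1,
                                   seed = 3)
  fit2 <- fit_model(net2, d2, n_restarts = 10, seed = 8)
  for (p in c("ERK->RAF", "MEKi")) {
    ci <- profile_ci(fit2, p, level = 0.95)
    expect_true(ci$identifiable)
    expect_gt(coef(truth)[p], ci$lower)
    expect_lt(coef(truth)[p], ci$upper)
  }
  expect_error(profile_ci(fit2, "NOPE"), "unknown parameter")
})

test_that("identical datasets for two lines leave all parameters linked", {
  net <- default_network()
  d <- generate_perturbation_data(net, default_true_params(net),
                                  noise_sd = 0.1, seed = 31)
  cmp <- comparative_fit(list(a = d, b = d), net, alpha = 0.05,
                         n_restarts = 4, seed = 2)
  expect_length(cmp$unlinked, 0)
  expect_equal(cmp$params_by_line$a, cmp$params_by_line$b)
})

test_that("a weakened feedback is localized to the right parameter", {
  net <- default_network()
  pair <- make_isogenic_pair(default_true_params(net), "ERK->RAF", 0.8)
  d_par <- generate_perturbation_data(net, pair$parental, noise_sd = 0.1,
                                      n_replicates = 3, seed = 41)
  d_ko <- generate_perturbation_data(net, pair$variant, noise_sd = 0.1,
                                     n_replicates = 3, seed = 42)
  cmp <- comparative_fit(list(parental = d_par, ko = d_ko), net,
                         alpha = 0.05, n_restarts = 5, seed = 3)
  expect_true("ERK->RAF" %in% cmp$unlinked)
  fb_par <- cmp$params_by_line$parental$edges["ERK->RAF"]
  fb_ko <- cmp$params_by_line$ko$edges["ERK->RAF"]
  expect_lt(fb_par, fb_ko)            # knockout feedback weaker (closer to 0)
  expect_lt(abs(fb_ko), abs(fb_par))
  # every accepted step improved the fit (nesting monotonicity)
  expect_true(all(cmp$steps$statistic >= 0))
  expect_true(all(cmp$steps$p_adj[cmp$steps$unlinked] < 0.05))

  # the scaled heatmap shows two same-sign values on the feedback row
  hm <- scaled_heatmap(cmp)
  expect_true(all(abs(hm) <= 1 + 1e-12))
  expect_equal(length(unique(hm["ERK->RAF", ])), 2)
  expect_true(all(hm["ERK->RAF", ] < 0))
  expect_setequal(attr(hm, "unlinked"), cmp$unlinked)
})

test_that("scaled heatmaps normalize each parameter class to unit maximum", {
  net <- mapk_network()
  fake <- structure(list(
    lines = "L",
    params_by_line = list(L = mapk_params(net)),
    unlinked = character(0)
  ), class = "ComparativeResult")
  hm <- scaled_heatmap(fake)
  expect_true(all(abs(hm) <= 1))
  cls <- list(edges = edge_names(net), stimuli = "EGF", inhibitors = "MEKi")
  for (rows in cls) expect_equal(max(abs(hm[rows, ])), 1)
  expect_equal(unname(hm["ERK->RAF", "L"]), -0.8 / 0.9)
  expect_error(scaled_heatmap(fake, groups = c(other = "g")), "every cell line")

  # two lines sharing everything produce identical columns
  d <- generate_perturbation_data(net, mapk_params(net), noise_sd = 0.05,
                                  seed = 51)
  cmp <- comparative_fit(list(a = d, b = d), net, n_restarts = 4, seed = 4)
  hm2 <- scaled_heatmap(cmp)
  expect_equal(hm2[, "a"], hm2[, "b"])
})
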