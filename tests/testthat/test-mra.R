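test_that("the unperturbed control maps to the zero vector", {
  net <- default_network()
  par <- default_true_params(net)
  expect_equal(unname(steady_state(net, par, list())),
               rep(0, length(net$nodes)))
})

test_that("a two-node chain propagates the stimulus linearly", {
  net <- signaling_network(data.frame(from = "A", to = "B", sign = 1),
                           stimuli = c(S = "A"), measured = "B")
  par <- model_parameters(net, edges = c("A->B" = 0.5), stimuli = c(S = 1))
  x <- steady_state(net, par, list(stimuli = "S"))
  expect_equal(unname(x[c("A", "B")]), c(1, 0.5))
})

test_that("MEK rises under MEK inhibition when the ERK->RAF feedback is negative", {
  # closed form for the 3-node loop: x_MEK = 2.6/1.8 with MEKi, 1/1.8 without
  net <- signaling_network(
    data.frame(from = c("RAF", "MEK", "ERK"), to = c("MEK", "ERK", "RAF"),
               sign = c(1, 1, -1)),
    stimuli = c(EGF = "RAF"), inhibitors = c(MEKi = "MEK"),
    measured = c("MEK", "ERK"))
  par <- model_parameters(
    net, edges = c("RAF->MEK" = 1, "MEK->ERK" = 1, "ERK->RAF" = -0.8),
    stimuli = c(EGF = 1), inhibitors = c(MEKi = 2))
  x_egf <- steady_state(net, par, list(stimuli = "EGF"))
  x_both <- steady_state(net, par, list(stimuli = "EGF", inhibitors = "MEKi"))
  expect_equal(unname(x_egf["MEK"]), 1 / 1.8)
  expect_equal(unname(x_both["MEK"]), 2.6 / 1.8)
  expect_gt(x_both["MEK"], x_egf["MEK"])
  # and the inhibited node's downstream target is still suppressed
  expect_lt(x_both["ERK"], x_egf["ERK"])
})

test_that("feedback relief is zero without feedback and grows with its strength", {
  net <- default_network()
  relief <- vapply(seq(0, -0.9, by = -0.1), function(f) {
    par <- default_true_params(net, feedback = f)
    x1 <- steady_state(net, par, list(stimuli = "EGF"))
    x2 <- steady_state(net, par, list(stimuli = "EGF", inhibitors = "MEKi"))
    unname(x2["MEK"] - x1["MEK"])
  }, numeric(1))
  expect_equal(relief[1], 0)
  expect_true(all(diff(relief) > 0))
})

test_that("direct solve and fixed-point iteration agree on random stable models", {
  for (seed in 1:100) {
    inst <- random_stable_instance(seed)
    x_direct <- steady_state(inst$network, inst$params, inst$condition)
    x_iter <- fixed_point_oracle(inst$network, inst$params, inst$condition,
                                 tol = 1e-10)
    expect_equal(x_direct, x_iter, tolerance = 1e-8)
  }
})

test_that("stimulus responses add linearly when no inhibitor is applied", {
  for (seed in 1:20) {
    inst <- random_stable_instance(seed)
    stims <- names(inst$network$stimuli)
    if (length(stims) < 2) next
    x_all <- steady_state(inst$network, inst$params, list(stimuli = stims))
    x_sum <- Reduce(`+`, lapply(stims, function(s) {
      steady_state(inst$network, inst$params, list(stimuli = s))
    }))
    expect_equal(x_all, x_sum, tolerance = 1e-10)
  }
})

test_that("spectral radius arithmetic matches closed forms", {
  net <- signaling_network(data.frame(from = "A", to = "B"), nodes = c("A", "B"))
  par <- structure(list(edges = c("A->B" = 0.5), stimuli = numeric(),
                        inhibitors = numeric()), class = "ModelParameters")
  st <- stability_check(par, net)
  expect_equal(st$spectral_radius, 0)
  expect_true(st$ok)

  two_cycle <- function(r1, r2) {
    net <- signaling_network(data.frame(from = c("A", "B"), to = c("B", "A")))
    par <- structure(list(edges = c("A->B" = r1, "B->A" = r2),
                          stimuli = numeric(), inhibitors = numeric()),
                     class = "ModelParameters")
    stability_check(par, net)
  }
  st <- two_cycle(0.9, 0.9)
  expect_equal(st$spectral_radius, 0.9)
  expect_true(st$ok)
  st <- two_cycle(1.1, 1.0)                 # radius sqrt(1.1 * 1.0)
  expect_equal(st$spectral_radius, sqrt(1.1), tolerance = 1e-12)
  expect_false(st$ok)
})

test_that("unstable models error in the solver and fail to converge in the oracle", {
  net <- signaling_network(data.frame(from = c("A", "B"), to = c("B", "A")),
                           stimuli = c(S = "A"))
  par <- structure(list(edges = c("A->B" = 1.2, "B->A" = 1.2),
                        stimuli = c(S = 1), inhibitors = numeric()),
                   class = "ModelParameters")
  expect_error(steady_state(net, par, list(stimuli = "S")), "spectral radius")
  expect_error(fixed_point_oracle(net, par, list(stimuli = "S"),
                                  max_iter = 200), "converge")
})

test_that("simulated datasets restrict to measured nodes and round-trip MIDAS", {
  net <- default_network()
  par <- default_true_params(net)
  d_ctrl <- simulate_dataset(net, par, list(list(stimuli = character(),
                                                 inhibitors = character())))
  expect_equal(nrow(d_ctrl$values), 1)
  expect_true(all(d_ctrl$values == 0))

  d <- simulate_dataset(net, par)
  expect_equal(colnames(d$values), net$measured)
  keys <- condition_keys(d)
  expect_lt(d$values[keys == "EGF+MEKi", "ERK"], d$values[keys == "EGF", "ERK"])

  p <- tempfile(fileext = ".csv")
  write_midas(d, p)
  d2 <- read_midas(p, values = "log2fc")
  expect_equal(d2$values, d$values, tolerance = 1e-9, ignore_attr = "dimnames")
  unlink(p)
})
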