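# Shared fixtures: tiny networks, random stable model instances, and
# random perturbation datasets, all built in code.

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Fully measured MAPK core with tunable ERK->RAF feedback: every parameter
# is structurally identifiable because every node is observed.
mapk_network <- function() {
  signaling_network(
    data.frame(from = c("RAS", "RAF", "MEK", "ERK"),
               to = c("RAF", "MEK", "ERK", "RAF"),
               sign = c(1, 1, 1, -1)),
    stimuli = c(EGF = "RAS"),
    inhibitors = c(MEKi = "MEK"),
    measured = c("RAS", "RAF", "MEK", "ERK")
  )
}

mapk_params <- function(network = mapk_network(), feedback = -0.8) {
  model_parameters(
    network,
    edges = c("RAS->RAF" = 0.9, "RAF->MEK" = 0.8, "MEK->ERK" = 0.9,
              "ERK->RAF" = feedback),
    stimuli = c(EGF = 1),
    inhibitors = c(MEKi = 2)
  )
}

# Random stable model instance (<= 10 nodes) plus a random condition.
random_stable_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:10, 1)
  nodes <- paste0("N", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- sample(seq(n - 1, min(nrow(pairs), 2 * n)), 1)
  edges <- pairs[sample(nrow(pairs), m), ]
  edges$sign <- NA
  strengths <- stats::runif(m, -1, 1)
  net0 <- signaling_network(edges, nodes = nodes)
  R <- matrix(0, n, n)
  R[cbind(match(edges$to, nodes), match(edges$from, nodes))] <- strengths
  rho <- max(Mod(eigen(R, only.values = TRUE)$values))
  if (rho > 0.9) strengths <- strengths * 0.9 / rho * stats::runif(1, 0.5, 1)

  stim_nodes <- sample(nodes, sample(1:2, 1))
  stimuli <- stats::setNames(stim_nodes, paste0("S", seq_along(stim_nodes)))
  inh_nodes <- sample(nodes, sample(1:2, 1))
  inhibitors <- stats::setNames(inh_nodes, paste0("X", seq_along(inh_nodes), "i"))
  measured <- sample(nodes, sample(2:n, 1))
  net <- signaling_network(edges, stimuli = stimuli, inhibitors = inhibitors,
                           measured = measured, nodes = nodes)
  params <- model_parameters(
    net,
    edges = stats::setNames(strengths, edge_names(net)),
    stimuli = stats::setNames(stats::runif(length(stimuli), 0.2, 2), names(stimuli)),
    inhibitors = stats::setNames(stats::runif(length(inhibitors), 0, 2), names(inhibitors))
  )
  condition <- list(
    stimuli = names(stimuli)[stats::runif(length(stimuli)) < 0.6],
    inhibitors = names(inhibitors)[stats::runif(length(inhibitors)) < 0.6]
  )
  list(network = net, params = params, condition = condition)
}

# Random dataset for MIDAS round-trip property tests.
random_dataset <- function(seed) {
  set.seed(seed)
  trnames <- c("EGF", "IGF1", "ALKi", "MEKi")[stats::runif(4) < 0.8]
  if (!length(trnames)) trnames <- "EGF"
  analytes <- paste0("A", seq_len(sample(1:4, 1)))
  n_cond <- sample(2:6, 1)
  n_rep <- sample(1:3, 1)
  tr <- matrix(stats::rbinom(n_cond * length(trnames), 1, 0.5), n_cond)
  colnames(tr) <- trnames
  tr <- tr[rep(seq_len(n_cond), each = n_rep), , drop = FALSE]
  vals <- matrix(stats::rnorm(nrow(tr) * length(analytes)), nrow(tr),
                 dimnames = list(NULL, analytes))
  perturbation_dataset(as.data.frame(tr), vals,
                       replicate = rep(seq_len(n_rep), n_cond))
}
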