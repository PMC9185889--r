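#' Canonical ALK-downstream signaling network fixture
#'
#' The package's default ground-truth topology: receptor inputs (EGF via
#' EGFR, IGF1 via IGF1R, constitutive ALK) feeding RAS-RAF-MEK-ERK and
#' PI3K-AKT-mTOR-S6K, with the ERK->RAF negative feedback that governs
#' phospho-MEK rebound under MEK inhibition. Measured nodes are the four
#' phospho-analytes of a multiplexed bead assay (P-MEK, P-ERK, P-AKT,
#' P-S6K); druggable nodes are ALK, MEK, PI3K and mTOR.
#'
#' @return A `SignalingNetwork`.
#' @export
default_network <- function() {
  edges <- data.frame(
    from = c("EGFR", "IGF1R", "IGF1R", "ALK", "ALK", "RAS", "RAF", "MEK",
             "ERK", "RAS", "PI3K", "AKT", "mTOR"),
    to   = c("RAS", "RAS", "PI3K", "RAS", "PI3K", "RAF", "MEK", "ERK",
             "RAF", "PI3K", "AKT", "mTOR", "S6K"),
    sign = c(1, 1, 1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 1)
  )
  signaling_network(
    edges,
    stimuli = c(EGF = "EGFR", IGF1 = "IGF1R"),
    inhibitors = c(ALKi = "ALK", MEKi = "MEK", PI3Ki = "PI3K", mTORi = "mTOR"),
    measured = c("MEK", "ERK", "AKT", "S6K")
  )
}

#' Ground-truth parameters for the default network
#'
#' Stable, biologically plausible strengths: strong MAPK core, moderate
#' PI3K arm, and an ERK->RAF negative feedback of tunable strength (default
#' -0.9, the "parental" phenotype; weakening it toward 0 emulates the
#' feedback loss of a RAS-GAP knockout clone).
#'
#' @param network the [default_network()] (or one sharing its edge set).
#' @param feedback strength of the ERK->RAF edge (<= 0).
#' @return A `ModelParameters` object.
#' @export
default_true_params <- function(network = default_network(), feedback = -0.9) {
  edges <- c(
    "EGFR->RAS" = 0.9, "IGF1R->RAS" = 0.5, "IGF1R->PI3K" = 0.8,
    "ALK->RAS" = 0.7, "ALK->PI3K" = 0.5, "RAS->RAF" = 0.9,
    "RAF->MEK" = 0.8, "MEK->ERK" = 0.9, "ERK->RAF" = feedback,
    "RAS->PI3K" = 0.4, "PI3K->AKT" = 0.8, "AKT->mTOR" = 0.7,
    "mTOR->S6K" = 0.9
  )
  model_parameters(
    network, edges,
    stimuli = c(EGF = 1, IGF1 = 1),
    inhibitors = c(ALKi = 1.5, MEKi = 2, PI3Ki = 1.8, mTORi = 1.2)
  )
}

#' Full-factorial perturbation scheme
#'
#' Every combination of one-or-no inhibitor with one-or-no stimulus,
#' including the unperturbed control — the design of a stimulus x inhibitor
#' perturbation panel (growth-factor stimulation on top of targeted kinase
#' inhibition).
#'
#' @param network a `SignalingNetwork`.
#' @return List of conditions (`list(stimuli =, inhibitors =)`), the first
#'   being the control.
#' @export
default_scheme <- function(network) {
  out <- list()
  for (inh in c(list(character()), as.list(names(network$inhibitors)))) {
    for (st in c(list(character()), as.list(names(network$stimuli)))) {
      out[[length(out) + 1]] <- list(stimuli = st, inhibitors = inh)
    }
  }
  out
}

#' Simulate a pooled CRISPR knockout screen
#'
#' Generates negative-binomial sgRNA counts for a baseline (t0) sample,
#' vehicle-control replicates and drug-treated replicates. Guide means are
#' equal across samples except for guides of effect genes, whose treated
#' means are multiplied by `2^effect` — the count-level signature of
#' enrichment (resistance genes) or depletion under treatment. Defaults
#' mirror a genome-wide screen at 4 guides/gene, ~500 reads/guide coverage
#' and two technical replicates per arm.
#'
#' @param n_genes number of genes in the library.
#' @param guides_per_gene guides per gene.
#' @param library_size total guide count; defaults to
#'   `n_genes * guides_per_gene`. Supplying any other value is an error
#'   unless `allow_uneven = TRUE`, in which case guides are spread as evenly
#'   as possible across genes.
#' @param baseline_mean typical reads per guide: the geometric mean of the
#'   per-guide abundance distribution.
#' @param abundance_sdlog log-scale standard deviation of the per-guide
#'   baseline abundance (drawn once per screen and shared across samples).
#'   The default 2.0 spreads guides over roughly three orders of magnitude,
#'   as in a pooled library after two weeks of selection, and is what makes
#'   technical replicates of the same screen highly correlated per guide.
#'   Set to 0 for an idealized equi-abundant library.
#' @param dispersion NB overdispersion `alpha` (variance `mu + alpha mu^2`).
#' @param resistance_genes named numeric vector: gene name -> log2 enrichment
#'   effect under treatment (positive enriches).
#' @param depletion_genes named numeric vector: gene name -> log2 depletion
#'   magnitude under treatment (applied with negative sign).
#' @param n_replicates technical replicates per arm.
#' @param seed RNG seed; identical seeds give identical matrices.
#' @param allow_uneven allow `library_size != n_genes * guides_per_gene`.
#' @return A [screen_counts()] object with samples `t0`, `control_1..n`,
#'   `treated_1..n` and matching `roles`.
#' @export
generate_screen_counts <- function(n_genes = 1000, guides_per_gene = 4,
                                   library_size = NULL, baseline_mean = 500,
                                   abundance_sdlog = 2.0, dispersion = 0.2,
                                   resistance_genes = numeric(),
                                   depletion_genes = numeric(),
                                   n_replicates = 2, seed = NULL,
                                   allow_uneven = FALSE) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, baseline_mean > 0,
            dispersion > 0, n_replicates >= 1)
  full <- n_genes * guides_per_gene
  library_size <- library_size %||% full
  if (library_size != full && !allow_uneven) {
    stop("library_size (", library_size, ") != n_genes * guides_per_gene (",
         full, "); pass allow_uneven = TRUE to distribute guides unevenly")
  }
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  per_gene <- rep(library_size %/% n_genes, n_genes)
  extra <- library_size %% n_genes
  if (extra) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
  gene_of <- rep(genes, per_gene)
  guides <- paste0(gene_of, "_g", unlist(lapply(per_gene, seq_len)))

  effect <- stats::setNames(numeric(length(guides)), guides)
  for (g in names(resistance_genes)) {
    effect[gene_of == g] <- resistance_genes[[g]]
  }
  for (g in names(depletion_genes)) {
    effect[gene_of == g] <- -abs(depletion_genes[[g]])
  }

  size <- 1 / dispersion
  samples <- c("t0", paste0("control_", seq_len(n_replicates)),
               paste0("treated_", seq_len(n_replicates)))
  roles <- stats::setNames(
    c("t0", rep("control", n_replicates), rep("treated", n_replicates)),
    samples)
  with_seed(seed, {
    # per-guide library abundance, shared by all samples; baseline_mean is
    # the geometric mean so the typical guide sits at the stated coverage
    base_mu <- baseline_mean *
      exp(stats::rnorm(length(guides), 0, abundance_sdlog))
    counts <- vapply(samples, function(s) {
      mu <- if (roles[s] == "treated") base_mu * 2^effect else base_mu
      stats::rnbinom(length(guides), size = size, mu = mu)
    }, numeric(length(guides)))
  })
  rownames(counts) <- guides
  screen_counts(counts, stats::setNames(gene_of, guides), roles = roles)
}

#' Simulate dose-response viability data
#'
#' Samples viability values from a known four-parameter logistic curve with
#' multiplicative lognormal noise of a given coefficient of variation.
#'
#' @param true_curve a [curve_4pl()] object (the ground truth).
#' @param concentrations positive drug concentrations (nM).
#' @param cv coefficient of variation of the multiplicative noise (0 = exact).
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @return Data frame with columns `concentration_nM`, `replicate`, `value`.
#' @export
generate_dose_response <- function(true_curve, concentrations, cv = 0.05,
                                   n_replicates = 3, seed = NULL) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (cv < 0) stop("cv must be >= 0")
  df <- expand.grid(concentration_nM = concentrations,
                    replicate = seq_len(n_replicates))
  mu <- predict_4pl(true_curve, df$concentration_nM)
  # lognormal with exact CV: sdlog^2 = log(1 + cv^2), mean preserved
  sdlog <- sqrt(log(1 + cv^2))
  noise <- if (cv == 0) rep(1, nrow(df)) else with_seed(seed, {
    exp(stats::rnorm(nrow(df), -sdlog^2 / 2, sdlog))
  })
  df$value <- mu * noise
  df[order(df$concentration_nM, df$replicate), , drop = FALSE]
}

#' Simulate a perturbation-response dataset
#'
#' Per replicate and condition, measured-node log2 fold-changes are the
#' model steady state plus additive Gaussian noise — the generative model of
#' a stimulus/inhibitor phospho-panel experiment. The control condition has
#' expectation zero.
#'
#' @inheritParams simulate_dataset
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param n_replicates biological replicates.
#' @param seed RNG seed.
#' @return A `PerturbationDataset` with `n_replicates` rows per condition.
#' @export
generate_perturbation_data <- function(network, params,
                                       scheme = default_scheme(network),
                                       noise_sd = 0.15, n_replicates = 3,
                                       seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  has_ctrl <- any(vapply(scheme, function(cond) {
    !length(cond$stimuli) && !length(cond$inhibitors)
  }, logical(1)))
  if (!has_ctrl) stop("scheme must include the unperturbed control condition")
  base <- simulate_dataset(network, params, scheme)
  n_cond <- nrow(base$values)
  tr <- base$treatments[rep(seq_len(n_cond), times = n_replicates), , drop = FALSE]
  vals <- base$values[rep(seq_len(n_cond), times = n_replicates), , drop = FALSE]
  noise <- with_seed(seed, stats::rnorm(length(vals), 0, noise_sd))
  vals <- vals + matrix(noise, nrow(vals), ncol(vals))
  rownames(tr) <- rownames(vals) <- NULL
  perturbation_dataset(tr, vals, kinds = base$kinds,
                       replicate = rep(seq_len(n_replicates), each = n_cond))
}
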