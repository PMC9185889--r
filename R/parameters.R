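#' Model parameters for a signaling network
#'
#' Parameters of the steady-state perturbation-response model: one strength
#' per network edge (the log2 response of the target per unit log2 change of
#' the source; negative for inhibitory feedback), one strength per stimulus
#' (the log2 input delivered at its entry node), and one strength per
#' inhibitor (the log2 attenuation of the target node's *transmitted*
#' activity; must be non-negative).
#'
#' @param network a [signaling_network()].
#' @param edges named numeric vector of edge strengths, names `"SRC->TGT"`
#'   matching [edge_names()]. Order is normalized to the network's.
#' @param stimuli named numeric vector, one value per network stimulus.
#' @param inhibitors named numeric vector (>= 0), one value per inhibitor.
#' @return An object of class `ModelParameters`.
#' @export
model_parameters <- function(network, edges, stimuli = numeric(), inhibitors = numeric()) {
  en <- edge_names(network)
  if (!setequal(names(edges), en)) {
    stop("edge strengths must cover exactly the network edges; missing: ",
         paste(setdiff(en, names(edges)), collapse = ", "))
  }
  if (!setequal(names(stimuli), names(network$stimuli))) {
    stop("stimulus strengths must cover exactly the network stimuli")
  }
  if (!setequal(names(inhibitors), names(network$inhibitors))) {
    stop("inhibitor strengths must cover exactly the network inhibitors")
  }
  if (any(inhibitors < 0)) stop("inhibitor strengths must be >= 0")
  structure(
    list(edges = edges[en],
         stimuli = stimuli[names(network$stimuli)],
         inhibitors = inhibitors[names(network$inhibitors)]),
    class = "ModelParameters"
  )
}

#' @export
print.ModelParameters <- function(x, ...) {
  cat("ModelParameters:", length(x$edges), "edges,", length(x$stimuli),
      "stimuli,", length(x$inhibitors), "inhibitors\n")
  print(round(unlist_params(x), 4))
  invisible(x)
}

# Flatten to a single named vector; names are unique across blocks
# (edge names contain "->", inhibitors end in "i", stimuli are bare).
unlist_params <- function(params) {
  c(params$edges, params$stimuli, params$inhibitors)
}

#' @describeIn model_parameters Flattened named coefficient vector (edges,
#'   then stimuli, then inhibitors).
#' @param object,... method arguments.
#' @export
coef.ModelParameters <- function(object, ...) unlist_params(object)

#' Names of all free parameters
#'
#' @param params a `ModelParameters` object.
#' @return Character vector: edge names, then stimuli, then inhibitors.
#' @export
param_names <- function(params) names(unlist_params(params))

# Locate a parameter by name; returns list(block, name) or errors.
locate_param <- function(params, param_name) {
  for (block in c("edges", "stimuli", "inhibitors")) {
    if (param_name %in% names(params[[block]])) {
      return(list(block = block, name = param_name))
    }
  }
  stop("unknown parameter: ", param_name)
}

#' Shift one parameter to create an isogenic pair
#'
#' Returns the ground truth for divergence-detection experiments: two
#' parameter sets that are identical except for one named parameter shifted
#' by `delta` in the second. This emulates an isogenic knockout clone whose
#' only quantitative rewiring is, e.g., a weakened ERK->RAF negative
#' feedback.
#'
#' @param base a `ModelParameters` object (the "parental" line).
#' @param param_name name of the parameter to shift (an edge `"SRC->TGT"`,
#'   a stimulus, or an inhibitor name).
#' @param delta additive shift applied in the second set.
#' @return A list of two `ModelParameters`: `parental` (= `base`) and
#'   `variant`.
#' @examples
#' net <- default_network()
#' pair <- make_isogenic_pair(default_true_params(net), "ERK->RAF", 0.8)
#' pair$variant$edges["ERK->RAF"]  # weakened feedback, -0.1
#' @export
make_isogenic_pair <- function(base, param_name, delta) {
  loc <- locate_param(base, param_name)
  variant <- base
  variant[[loc$block]][param_name] <- variant[[loc$block]][param_name] + delta
  list(parental = base, variant = variant)
}
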