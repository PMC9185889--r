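#' Construct a signaling network
#'
#' A `SignalingNetwork` is a signed directed graph of signaling modules
#' together with the experimental handles on it: which nodes receive external
#' stimuli (growth factors), which nodes are targeted by small-molecule
#' inhibitors, and which nodes are measured (phospho-readouts).
#'
#' @param edges data frame with columns `from`, `to` and optionally `sign`
#'   (`+1`, `-1`, or `NA` for a free/unconstrained sign). Self-loops and
#'   duplicate edges are rejected.
#' @param stimuli named character vector mapping stimulus name to its entry
#'   node, e.g. `c(EGF = "EGFR")`.
#' @param inhibitors named character vector mapping inhibitor name to its
#'   target node, e.g. `c(MEKi = "MEK")`. By the MIDAS dialect used here,
#'   inhibitor names end in a lowercase `"i"`.
#' @param measured character vector of measured node names.
#' @param nodes optional character vector of all node names; defaults to the
#'   union of edge endpoints and role nodes.
#'
#' @return An object of class `SignalingNetwork`: a list with elements
#'   `nodes`, `edges`, `stimuli`, `inhibitors`, `measured`.
#' @seealso [read_network()], [default_network()]
#' @export
signaling_network <- function(edges, stimuli = character(), inhibitors = character(),
                              measured = character(), nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns 'from' and 'to'")
  }
  if (is.null(edges$sign)) edges$sign <- NA_real_
  edges$sign <- as.numeric(edges$sign)
  bad_sign <- !is.na(edges$sign) & !edges$sign %in% c(-1, 1)
  if (any(bad_sign)) stop("edge sign must be +1, -1 or NA (free)")
  if (any(!nzchar(edges$from)) || any(!nzchar(edges$to))) {
    stop("node names must be non-empty")
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    stop("self-loop not allowed: ", edges$from[which(loops)[1]])
  }
  key <- paste(edges$from, edges$to, sep = "->")
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", key[duplicated(key)][1])
  }
  rownames(edges) <- key

  all_nodes <- unique(c(nodes, edges$from, edges$to))
  for (role in list(stimuli = stimuli, inhibitors = inhibitors)) {
    if (length(role) && (is.null(names(role)) || any(!nzchar(names(role))))) {
      stop("stimuli and inhibitors must be named vectors (name -> node)")
    }
  }
  missing_role <- setdiff(c(unname(stimuli), unname(inhibitors), measured),
                          all_nodes)
  if (length(missing_role)) stop("unknown role node: ", missing_role[1])

  structure(
    list(nodes = all_nodes, edges = edges,
         stimuli = stimuli, inhibitors = inhibitors,
         measured = unique(measured)),
    class = "SignalingNetwork"
  )
}

#' @export
print.SignalingNetwork <- function(x, ...) {
  cat("SignalingNetwork:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  neg <- sum(x$edges$sign %in% -1)
  if (neg) cat("  negative (feedback) edges:", neg, "\n")
  if (length(x$stimuli)) {
    cat("  stimuli:", paste0(names(x$stimuli), "->", x$stimuli, collapse = ", "), "\n")
  }
  if (length(x$inhibitors)) {
    cat("  inhibitors:", paste0(names(x$inhibitors), "->", x$inhibitors, collapse = ", "), "\n")
  }
  cat("  measured:", paste(x$measured, collapse = ", "), "\n")
  invisible(x)
}

#' Edge names of a network
#'
#' @param network a [signaling_network()].
#' @return Character vector `"SRC->TGT"` in file/row order.
#' @export
edge_names <- function(network) rownames(network$edges)

#' Read a signed network edge list
#'
#' Parses a SIF-like tab-separated file with rows `source <TAB> target` and an
#' optional third column holding the interaction sign (`+1`/`-1`; absent or
#' `free` means unconstrained). Node roles (stimuli, inhibitors, measured) are
#' attached either from arguments or from a companion YAML-like key file (see
#' Details).
#'
#' @details The optional `config` file is plain text with lines
#'   `stimulus <TAB> name <TAB> node`, `inhibitor <TAB> name <TAB> node`,
#'   `measured <TAB> node`. Arguments override the config file.
#'
#' @param path path to the edge-list TSV.
#' @param stimuli,inhibitors,measured as in [signaling_network()].
#' @param config optional path to a role config file.
#' @return A `SignalingNetwork`.
#' @export
read_network <- function(path, stimuli = NULL, inhibitors = NULL,
                         measured = NULL, config = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty network file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col < 2)) stop("network rows need at least source and target")
  sign <- vapply(parts, function(p) {
    if (length(p) < 3 || p[3] %in% c("", "free")) NA_real_ else as.numeric(p[3])
  }, numeric(1))
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    sign = sign, stringsAsFactors = FALSE
  )
  roles <- list(stimuli = character(), inhibitors = character(),
                measured = character())
  if (!is.null(config)) {
    cl <- readLines(config)
    cl <- cl[nzchar(trimws(cl)) & !startsWith(trimws(cl), "#")]
    for (ln in cl) {
      p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (p[1] == "stimulus" && length(p) == 3) {
        roles$stimuli[p[2]] <- p[3]
      } else if (p[1] == "inhibitor" && length(p) == 3) {
        roles$inhibitors[p[2]] <- p[3]
      } else if (p[1] == "measured" && length(p) == 2) {
        roles$measured <- c(roles$measured, p[2])
      } else {
        stop("unrecognized role line: ", ln)
      }
    }
  }
  signaling_network(
    edges,
    stimuli = stimuli %||% roles$stimuli,
    inhibitors = inhibitors %||% roles$inhibitors,
    measured = measured %||% roles$measured
  )
}

#' Write a network edge list
#'
#' Inverse of [read_network()] for the edge list itself (roles are not
#' serialized).
#'
#' @param network a `SignalingNetwork`.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  sign <- ifelse(is.na(network$edges$sign), "free",
                 sprintf("%+d", as.integer(network$edges$sign)))
  writeLines(paste(network$edges$from, network$edges$to, sign, sep = "\t"), path)
  invisible(path)
}
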