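#' Perturbation-response dataset
#'
#' Holds per-condition, per-replicate log2 fold-changes of measured
#' phospho-analytes relative to the unperturbed control, the quantity the
#' steady-state model predicts. Rows are condition x replicate; a condition
#' is the set of applied treatments (stimuli and inhibitors).
#'
#' @param treatments data frame of 0/1 applied flags, one column per
#'   treatment name; rows align with `values`.
#' @param values numeric matrix of log2 fold-changes, one column per analyte.
#' @param kinds named character vector mapping each treatment name to
#'   `"stimulus"` or `"inhibitor"`. Defaults to the MIDAS dialect rule:
#'   names ending in lowercase `"i"` are inhibitors.
#' @param replicate integer replicate ids, one per row (default all 1).
#' @return An object of class `PerturbationDataset` with elements
#'   `treatments`, `values`, `kinds`, `replicate`.
#' @export
perturbation_dataset <- function(treatments, values, kinds = NULL, replicate = NULL) {
  treatments <- as.data.frame(treatments)
  values <- as.matrix(values)
  if (nrow(treatments) != nrow(values)) {
    stop("treatments and values must have the same number of rows")
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    stop("value columns must be named after analytes")
  }
  for (cn in names(treatments)) {
    if (!all(treatments[[cn]] %in% c(0, 1))) {
      stop("treatment flags must be 0 or 1 (column ", cn, ")")
    }
  }
  if (is.null(kinds)) {
    kinds <- ifelse(grepl("i$", names(treatments)), "inhibitor", "stimulus")
    names(kinds) <- names(treatments)
  }
  if (!setequal(names(kinds), names(treatments)) ||
      !all(kinds %in% c("stimulus", "inhibitor"))) {
    stop("`kinds` must map every treatment to 'stimulus' or 'inhibitor'")
  }
  replicate <- replicate %||% rep(1L, nrow(values))
  structure(
    list(treatments = treatments, values = values,
         kinds = kinds[names(treatments)], replicate = as.integer(replicate)),
    class = "PerturbationDataset"
  )
}

#' @export
print.PerturbationDataset <- function(x, ...) {
  keys <- condition_keys(x)
  cat("PerturbationDataset:", length(unique(keys)), "conditions x",
      max(x$replicate), "replicate(s),", ncol(x$values), "analytes (",
      paste(colnames(x$values), collapse = ", "), ")\n")
  invisible(x)
}

#' Condition key per row
#'
#' @param dataset a `PerturbationDataset`.
#' @return Character vector: sorted applied treatments joined by `"+"`;
#'   `"control"` for the all-zero condition.
#' @export
condition_keys <- function(dataset) {
  tr <- as.matrix(dataset$treatments)
  if (ncol(tr) == 0) return(rep("control", nrow(dataset$values)))
  apply(tr, 1, function(fl) {
    on <- sort(colnames(tr)[fl == 1])
    if (!length(on)) "control" else paste(on, collapse = "+")
  })
}

# Per-row list of list(stimuli=, inhibitors=) for the model.
row_conditions <- function(dataset) {
  tr <- as.matrix(dataset$treatments)
  kinds <- dataset$kinds
  lapply(seq_len(nrow(tr)), function(i) {
    on <- colnames(tr)[tr[i, ] == 1]
    list(stimuli = on[kinds[on] == "stimulus"],
         inhibitors = on[kinds[on] == "inhibitor"])
  })
}

#' Condition-wise mean log2 fold-changes
#'
#' @param dataset a `PerturbationDataset`.
#' @return Matrix condition x analyte of replicate means; rownames are
#'   condition keys.
#' @export
condition_means <- function(dataset) {
  keys <- condition_keys(dataset)
  uk <- unique(keys)
  out <- vapply(uk, function(k) {
    colMeans(dataset$values[keys == k, , drop = FALSE])
  }, numeric(ncol(dataset$values)))
  out <- matrix(out, nrow = ncol(dataset$values),
                dimnames = list(colnames(dataset$values), uk))
  t(out)
}

#' Read a MIDAS-formatted perturbation file
#'
#' MIDAS is the CSV dialect for perturbation-biology data: `TR:` columns are
#' 0/1 treatment flags (names ending in lowercase `"i"` denote inhibitors; a
#' `TR:Replicate` column, if present, gives replicate blocks), `DA:` columns
#' carry acquisition times, and `DV:` columns carry measurements.
#'
#' Raw (non-log) measurements are converted to log2 fold-changes against the
#' all-treatments-zero control row(s) of the same replicate block. Without a
#' `TR:Replicate` column, each control row opens a new block in row order.
#'
#' @param path path to the MIDAS CSV.
#' @param values `"raw"` (default) to convert to log2 fold-change against the
#'   matching control, or `"log2fc"` if the file already stores fold-changes.
#' @return A [perturbation_dataset()]. Control rows are retained (their
#'   log2 fold-change is 0 by construction when `values = "raw"`).
#' @export
read_midas <- function(path, values = c("raw", "log2fc")) {
  values <- match.arg(values)
  if (!file.exists(path)) stop("MIDAS file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty MIDAS file: ", path)
  cn <- names(df)
  pref <- sub(":.*$", "", cn)
  known <- pref %in% c("TR", "DA", "DV") | cn %in% c("ID", "id")
  if (any(!known)) stop("unknown column prefix in MIDAS header: ", cn[!known][1])

  tr_cols <- cn[pref == "TR"]
  dv_cols <- cn[pref == "DV"]
  if (!length(dv_cols)) stop("MIDAS file has no DV: columns")
  rep_col <- tr_cols[sub("^TR:", "", tr_cols) == "Replicate"]
  tr_cols <- setdiff(tr_cols, rep_col)
  tr_names <- sub("^TR:", "", tr_cols)

  dv <- as.matrix(df[, dv_cols, drop = FALSE])
  if (!is.numeric(dv)) {
    bad <- which(!vapply(df[, dv_cols, drop = FALSE], is.numeric, logical(1)))
    col <- dv_cols[bad[1]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    stop("non-numeric DV value in column ", col, ", row ", row %||% 1)
  }
  if (anyNA(dv)) {
    stop("non-numeric DV value at row ", which(rowSums(is.na(dv)) > 0)[1])
  }
  colnames(dv) <- sub("^DV:", "", dv_cols)

  tr <- as.data.frame(df[, tr_cols, drop = FALSE])
  names(tr) <- tr_names
  for (j in seq_along(tr)) {
    if (!all(tr[[j]] %in% c(0, 1))) {
      stop("treatment flags must be 0/1 in column TR:", tr_names[j])
    }
  }

  is_ctrl <- if (length(tr_cols)) rowSums(tr) == 0 else rep(TRUE, nrow(df))
  if (length(rep_col)) {
    block <- as.integer(df[[rep_col]])
  } else {
    # each control row opens a new replicate block, in row order
    block <- cumsum(is_ctrl)
    if (values == "log2fc") block[block == 0] <- 1L
  }

  if (values == "raw") {
    if (any(dv < 0)) stop("raw MIDAS values must be non-negative")
    keys <- apply(as.matrix(tr), 1, function(fl) {
      on <- sort(tr_names[fl == 1])
      if (!length(on)) "control" else paste(on, collapse = "+")
    })
    out <- dv
    for (b in unique(block)) {
      in_b <- block == b
      ctrl <- in_b & is_ctrl
      if (!any(ctrl)) {
        stop("no control row for condition '", keys[which(in_b)[1]],
             "' (replicate block ", b, ")")
      }
      ref <- colMeans(dv[ctrl, , drop = FALSE])
      if (any(ref <= 0)) stop("control values must be positive to form fold-changes")
      out[in_b, ] <- log2(sweep(dv[in_b, , drop = FALSE], 2, ref, "/"))
    }
    dv <- out
  }

  perturbation_dataset(tr, dv, replicate = match(block, unique(block)))
}

#' Write a perturbation dataset as MIDAS
#'
#' Serializes log2 fold-change values with `TR:` treatment flags (inhibitor
#' names must end in lowercase `"i"` so the kind survives the round trip), a
#' `TR:Replicate` block column and a single `DA:ALL` time column.
#' `read_midas(path, values = "log2fc")` reproduces the dataset.
#'
#' @param dataset a non-empty `PerturbationDataset`.
#' @param path output path.
#' @param time acquisition time written to `DA:ALL` (minutes, default 30).
#' @export
write_midas <- function(dataset, path, time = 30) {
  if (!inherits(dataset, "PerturbationDataset") || nrow(dataset$values) == 0) {
    stop("cannot write an empty perturbation dataset")
  }
  bad <- names(dataset$kinds)[dataset$kinds == "inhibitor" &
                                !grepl("i$", names(dataset$kinds))]
  if (length(bad)) {
    stop("inhibitor names must end in lowercase 'i' for MIDAS export: ", bad[1])
  }
  out <- data.frame(ID = seq_len(nrow(dataset$values)))
  for (tn in names(dataset$treatments)) {
    out[[paste0("TR:", tn)]] <- dataset$treatments[[tn]]
  }
  out[["TR:Replicate"]] <- dataset$replicate
  out[["DA:ALL"]] <- time
  for (an in colnames(dataset$values)) {
    out[[paste0("DV:", an)]] <- dataset$values[, an]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
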