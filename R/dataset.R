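#' Rectangular data set with an explicit missingness mask
#'
#' The central data container: a numeric matrix of covariates plus one outcome
#' column (the last column), a logical mask of the same shape (`TRUE` =
#' observed), and a per-column variable type tag (`"continuous"` or
#' `"binary"`). Unobserved cells hold `NA` in `values`; when a data set is
#' produced by [apply_mcar()] the pre-deletion values are retained in the
#' `complete` attribute so that simulation truth remains available.
#'
#' @param values numeric matrix (or data frame) with column names; the last
#'   column is the outcome. `NA` cells are taken as unobserved.
#' @param var_types character vector, one of `"continuous"`/`"binary"` per
#'   column. Defaults to `"binary"` for observed columns containing only
#'   0/1, `"continuous"` otherwise.
#' @param mask optional logical matrix, `TRUE` = observed. Must agree with the
#'   `NA` pattern of `values`.
#' @param outcome name of the outcome column; defaults to the last column.
#' @return An object of class `mi_dataset`.
#' @export
mi_dataset <- function(values, var_types = NULL, mask = NULL, outcome = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- c(paste0("x", seq_len(ncol(values) - 1L)), "y")
  }
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  dimnames(mask) <- dimnames(values)
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values must have identical dimensions")
  }
  if (any(is.na(values) & mask)) {
    stop("mask marks NA cells as observed")
  }
  if (is.null(outcome)) outcome <- colnames(values)[ncol(values)]
  if (is.null(var_types)) {
    var_types <- vapply(seq_len(ncol(values)), function(j) {
      v <- values[mask[, j], j]
      if (length(v) && all(v %in% c(0, 1)) && colnames(values)[j] != outcome) {
        "binary"
      } else {
        "continuous"
      }
    }, character(1))
  }
  var_types <- rep_len(var_types, ncol(values))
  names(var_types) <- colnames(values)
  bad <- vapply(seq_len(ncol(values)), function(j) {
    var_types[j] == "binary" && !all(values[mask[, j], j] %in% c(0, 1))
  }, logical(1))
  if (any(bad)) {
    stop("binary column(s) with values outside {0,1}: ",
         paste(colnames(values)[bad], collapse = ", "))
  }
  structure(
    list(values = values, mask = mask, var_types = var_types,
         outcome = outcome),
    class = "mi_dataset"
  )
}

#' @export
print.mi_dataset <- function(x, ...) {
  nmis <- sum(!x$mask)
  cat(sprintf("mi_dataset: %d rows, %d covariates + outcome '%s'\n",
              nrow(x$values), ncol(x$values) - 1L, x$outcome))
  cat(sprintf("  binary: %d, continuous: %d, missing cells: %d (%.1f%%)\n",
              sum(x$var_types == "binary"),
              sum(x$var_types == "continuous") - 1L,
              nmis, 100 * nmis / length(x$mask)))
  invisible(x)
}

#' @export
dim.mi_dataset <- function(x) dim(x$values)

# covariate matrix / outcome accessors ---------------------------------------

#' Extract the covariate matrix of a data set
#' @param data an `mi_dataset` (or a plain numeric matrix, returned as is).
#' @return numeric matrix of covariates (outcome column dropped).
#' @export
covariates <- function(data) {
  if (is.matrix(data)) return(data)
  data$values[, setdiff(colnames(data$values), data$outcome), drop = FALSE]
}

#' Extract the outcome vector of a data set
#' @param data an `mi_dataset`.
#' @return numeric vector.
#' @export
outcome_of <- function(data) data$values[, data$outcome]

#' Subset the rows of a data set
#'
#' Used by the bootstrap machinery; keeps mask and (if present) the retained
#' complete-values attribute aligned with the resampled rows.
#' @param data an `mi_dataset`.
#' @param idx integer row indices (repeats allowed).
#' @return an `mi_dataset` with `length(idx)` rows.
#' @export
subset_rows <- function(data, idx) {
  out <- data
  out$values <- data$values[idx, , drop = FALSE]
  out$mask <- data$mask[idx, , drop = FALSE]
  cm <- attr(data, "complete")
  if (!is.null(cm)) attr(out, "complete") <- cm[idx, , drop = FALSE]
  out
}

# file interchange ------------------------------------------------------------

#' Write a data set to CSV with a JSON sidecar
#'
#' The CSV holds one header row and empty cells for unobserved values; the
#' sidecar (same path with extension `.json`) records the variable types and,
#' when present, the generating simulation configuration.
#'
#' @param data an `mi_dataset`.
#' @param path CSV file path.
#' @param sidecar path of the JSON sidecar; default swaps the extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]*$", "", path)
  if (!grepl("\\.json$", sidecar)) sidecar <- paste0(sidecar, ".json")
  vals <- data$values
  vals[!data$mask] <- NA
  # %.17g guarantees a bit-exact double round trip through text
  chr <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  chr[is.na(vals)] <- ""
  utils::write.table(chr, path, sep = ",", quote = FALSE,
                     row.names = FALSE,
                     col.names = colnames(vals))
  meta <- list(var_types = as.list(data$var_types), outcome = data$outcome)
  cfg <- attr(data, "sim_config")
  if (!is.null(cfg)) meta$sim_config <- unclass(cfg)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a data set from CSV (+ optional JSON sidecar with variable types)
#'
#' Empty cells and `NA` are read as unobserved. Binary columns are checked to
#' contain only 0/1 where observed.
#'
#' @param path CSV file path.
#' @param types_path optional JSON file with a `var_types` map; defaults to
#'   the sidecar written by [write_dataset()] if it exists, else types are
#'   inferred from the observed values.
#' @return an `mi_dataset`.
#' @export
read_dataset <- function(path, types_path = NULL) {
  vals <- as.matrix(utils::read.csv(path, na.strings = c("NA", "")))
  var_types <- NULL
  outcome <- NULL
  if (is.null(types_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), ".json")
    if (file.exists(cand)) types_path <- cand
  }
  if (!is.null(types_path)) {
    meta <- jsonlite::read_json(types_path)
    var_types <- unlist(meta$var_types)[colnames(vals)]
    outcome <- meta$outcome
  }
  mi_dataset(vals, var_types = var_types, outcome = outcome)
}
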