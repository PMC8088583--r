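# Key-value parameter file parsing for the workflow driver.

config_schema <- function() {
  list(
    input_dir = list(type = "character", required = TRUE),
    reference = list(type = "character", required = TRUE),
    out_dir = list(type = "character", required = TRUE),
    subsets = list(type = "character", default = "alpha_carbon"),
    residue_numbers = list(type = "integer_vector", default = NULL),
    models = list(type = "character", default = "Q"),
    top_k = list(type = "integer", default = 5L),
    floor = list(type = "numeric", default = 1e-6),
    res_shrink = list(type = "logical", default = FALSE),
    res_threshold = list(type = "numeric", default = 1.96),
    res_center = list(type = "character", default = "mean"),
    acs_shrink = list(type = "logical", default = FALSE),
    hierarchical = list(type = "logical", default = FALSE),
    hierarchical_h = list(type = "integer", default = 3L),
    coupling = list(type = "logical", default = FALSE),
    coupling_h = list(type = "integer", default = 12L),
    sigma = list(type = "numeric", default = 0.25),
    sparsify_threshold = list(type = "numeric", default = NA_real_),
    kernel = list(type = "character", default = NA_character_),
    fes = list(type = "logical", default = FALSE),
    fes_smoothing = list(type = "numeric", default = 1),
    grid_size = list(type = "integer", default = 50L),
    downsample_stride = list(type = "integer", default = 1L),
    do_output_coordinates = list(type = "logical", default = FALSE),
    verbose = list(type = "logical", default = FALSE)
  )
}

#' Parse a key-value workflow parameter file
#'
#' One `key = value` pair per line; `#` starts a comment; blank lines are
#' ignored. Unknown keys, duplicate keys, malformed values and missing
#' mandatory keys are hard errors naming the line. Defaults fill any absent
#' optional key: 3 eigenresidues for hierarchical PCA, `h = 12` and
#' `sigma = 0.25` for coupling, eigenvalue floor `1e-6`, z threshold 1.96.
#' The covariance model `Q` is always computed; `models` may add `R` and/or
#' `P` (comma separated).
#'
#' @param path parameter file path.
#' @return an object of class `run_config` (named list of validated values).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  schema <- config_schema()
  lines <- readLines(path)
  values <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("line ", i, ": expected key = value, got '", lines[i], "'")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!(key %in% names(schema))) {
      stop("line ", i, ": unknown key '", key, "'")
    }
    if (key %in% names(values)) {
      stop("line ", i, ": duplicate key '", key, "'")
    }
    values[[key]] <- parse_config_value(val, schema[[key]]$type, key, i)
  }
  for (key in names(schema)) {
    entry <- schema[[key]]
    if (!(key %in% names(values))) {
      if (isTRUE(entry$required)) stop("missing mandatory key '", key, "'")
      values[key] <- list(entry$default)
    }
  }
  models <- toupper(trimws(strsplit(values$models, ",")[[1L]]))
  bad <- setdiff(models, c("Q", "R", "P"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  values$models <- union("Q", models)  # Q is always computed
  values$subsets <- trimws(strsplit(values$subsets, ",")[[1L]])
  ok_res <- c("all_atom", "heavy_atom", "backbone", "alpha_carbon")
  bad <- setdiff(values$subsets, ok_res)
  if (length(bad)) {
    stop("workflow subsets must be resolutions among ",
         paste(ok_res, collapse = ", "), "; got ", paste(bad, collapse = ", "))
  }
  if (!is.na(values$kernel)) {
    values$kernel <- match.arg(values$kernel, kernel_registry())
  }
  structure(values, class = "run_config")
}

parse_config_value <- function(val, type, key, line) {
  fail <- function() {
    stop("line ", line, ": malformed ", type, " value for '", key, "': '",
         val, "'")
  }
  switch(type,
    character = val,
    logical = {
      v <- tolower(val)
      if (v %in% c("true", "yes", "1")) TRUE
      else if (v %in% c("false", "no", "0")) FALSE
      else fail()
    },
    numeric = {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) fail() else v
    },
    integer = {
      v <- suppressWarnings(as.integer(val))
      if (is.na(v)) fail() else v
    },
    integer_vector = {
      v <- suppressWarnings(as.integer(strsplit(val, ",")[[1L]]))
      if (anyNA(v)) fail() else v
    },
    fail()
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat("  ", k, " = ", paste(format(x[[k]]), collapse = ","), "\n", sep = "")
  }
  invisible(x)
}
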