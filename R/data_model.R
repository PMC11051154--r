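#' Construct a test dataset of accuracy and response-time matrices
#'
#' The canonical container used by every model in the package: a person x item
#' matrix of dichotomous item scores, a matching matrix of response times in
#' seconds, and optional person- and item-level covariate tables (e.g., an
#' external criterion score per person, or cognitive-complexity features per
#' item).
#'
#' Missing entries (`NA`) are allowed and propagate as "not observed" into all
#' likelihoods downstream; trimming of erratic responses is implemented as
#' induced missingness. The accuracy and response-time matrices must have the
#' same shape; unless a trim has been applied they are expected to share a
#' missingness pattern.
#'
#' @param responses person x item matrix with entries in \{0, 1, NA\}.
#' @param response_times person x item matrix of positive response times in
#'   seconds (NA allowed). May be `NULL` for accuracy-only analyses.
#' @param person_covariates optional `data.frame` with a `person` id column.
#' @param item_covariates optional `data.frame` with an `item` id column;
#'   conventional columns are `memory_load`, `unique_elements`, `position`
#'   (1-based serial order; must be a permutation of `1:n_items` if present).
#' @param person_ids,item_ids identifier vectors; default to dimnames or
#'   `p1..pJ` / `i1..iI`.
#'
#' @return An object of class `test_dataset` with elements `responses`,
#'   `response_times`, `person_covariates`, `item_covariates`, `person_ids`,
#'   `item_ids`.
#' @export
test_dataset <- function(responses, response_times = NULL,
                         person_covariates = NULL, item_covariates = NULL,
                         person_ids = NULL, item_ids = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  bad <- responses[!is.na(responses)]
  if (length(bad) && !all(bad %in% c(0, 1)))
    stop("responses must contain only 0, 1 or NA")
  J <- nrow(responses); I <- ncol(responses)
  if (is.null(person_ids))
    person_ids <- if (!is.null(rownames(responses))) rownames(responses) else paste0("p", seq_len(J))
  if (is.null(item_ids))
    item_ids <- if (!is.null(colnames(responses))) colnames(responses) else paste0("i", seq_len(I))
  if (length(person_ids) != J) stop("person_ids length must match nrow(responses)")
  if (length(item_ids) != I) stop("item_ids length must match ncol(responses)")
  dimnames(responses) <- list(person_ids, item_ids)

  if (!is.null(response_times)) {
    response_times <- as.matrix(response_times)
    storage.mode(response_times) <- "double"
    if (!all(dim(response_times) == dim(responses)))
      stop(sprintf("shape mismatch: responses are %d x %d but response_times are %d x %d",
                   J, I, nrow(response_times), ncol(response_times)))
    off <- which(!is.na(response_times) & response_times <= 0, arr.ind = TRUE)
    if (nrow(off))
      stop(sprintf("non-positive response time at person '%s', item '%s' (%.4g s)",
                   person_ids[off[1, 1]], item_ids[off[1, 2]],
                   response_times[off[1, 1], off[1, 2]]))
    dimnames(response_times) <- dimnames(responses)
  }

  if (!is.null(person_covariates)) {
    person_covariates <- as.data.frame(person_covariates)
    if (!"person" %in% names(person_covariates))
      stop("person_covariates must have a 'person' column")
    unknown <- setdiff(as.character(person_covariates$person), as.character(person_ids))
    if (length(unknown))
      stop("unknown person id(s) in person_covariates: ", paste(unknown, collapse = ", "))
    person_covariates <- person_covariates[match(person_ids, person_covariates$person), , drop = FALSE]
    person_covariates$person <- person_ids
    rownames(person_covariates) <- NULL
  }
  if (!is.null(item_covariates)) {
    item_covariates <- as.data.frame(item_covariates)
    if (!"item" %in% names(item_covariates))
      stop("item_covariates must have an 'item' column")
    unknown <- setdiff(as.character(item_covariates$item), as.character(item_ids))
    if (length(unknown))
      stop("unknown item id(s) in item_covariates: ", paste(unknown, collapse = ", "))
    item_covariates <- item_covariates[match(item_ids, item_covariates$item), , drop = FALSE]
    item_covariates$item <- item_ids
    rownames(item_covariates) <- NULL
    if ("position" %in% names(item_covariates)) {
      pos <- item_covariates$position
      if (anyNA(pos) || !setequal(pos, seq_len(I)))
        stop("item covariate 'position' must be a permutation of 1..n_items")
    }
  }

  structure(
    list(responses = responses, response_times = response_times,
         person_covariates = person_covariates, item_covariates = item_covariates,
         person_ids = person_ids, item_ids = item_ids),
    class = "test_dataset")
}

#' @export
print.test_dataset <- function(x, ...) {
  cat(sprintf("<test_dataset> %d persons x %d items\n",
              nrow(x$responses), ncol(x$responses)))
  cat(sprintf("  responses observed: %d/%d",
              sum(!is.na(x$responses)), length(x$responses)))
  if (!is.null(x$response_times))
    cat(sprintf("; response times observed: %d/%d",
                sum(!is.na(x$response_times)), length(x$response_times)))
  cat("\n")
  if (!is.null(x$person_covariates))
    cat("  person covariates:", paste(setdiff(names(x$person_covariates), "person"),
                                      collapse = ", "), "\n")
  if (!is.null(x$item_covariates))
    cat("  item covariates:", paste(setdiff(names(x$item_covariates), "item"),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.test_dataset <- function(x) dim(x$responses)

.read_wide <- function(path, colnames_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a test dataset from CSV files
#'
#' Wide layout: first column holds person ids, remaining columns one per item
#' (item ids in the header). Long layout: one record per observed response with
#' columns `person,item,response,rt` (names overridable via `columns`).
#' Duplicate (person, item) records in long layout are rejected.
#'
#' @param responses_path CSV of item scores (wide) or of all records (long; in
#'   that case `rts_path` is ignored and may be `NULL`).
#' @param rts_path CSV of response times in seconds, wide layout only.
#' @param person_covariates_path,item_covariates_path optional CSV paths; the
#'   first column must be named `person` / `item` respectively.
#' @param layout `"wide"` or `"long"`.
#' @param columns optional named list (or YAML/JSON file path) overriding long
#'   column names, with entries `person`, `item`, `response`, `rt`.
#' @return a [test_dataset()].
#' @export
load_dataset <- function(responses_path, rts_path = NULL,
                         person_covariates_path = NULL,
                         item_covariates_path = NULL,
                         layout = c("wide", "long"),
                         columns = NULL) {
  layout <- match.arg(layout)
  for (p in c(responses_path, rts_path, person_covariates_path, item_covariates_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  if (is.character(columns) && length(columns) == 1L && file.exists(columns))
    columns <- yaml::read_yaml(columns)
  cols <- utils::modifyList(list(person = "person", item = "item",
                                 response = "response", rt = "rt"),
                            as.list(columns %||% list()))

  if (layout == "wide") {
    resp <- .read_wide(responses_path)
    rts <- if (!is.null(rts_path)) .read_wide(rts_path) else NULL
    if (!is.null(rts)) {
      if (!identical(dim(rts), dim(resp)))
        stop("shape mismatch between response and response-time files")
      if (!identical(rownames(rts), rownames(resp)) ||
          !identical(colnames(rts), colnames(resp)))
        stop("person/item ids differ between response and response-time files")
    }
  } else {
    df <- utils::read.csv(responses_path, stringsAsFactors = FALSE)
    need <- c(cols$person, cols$item, cols$response)
    if (!all(need %in% names(df)))
      stop("long file must have columns: ", paste(need, collapse = ", "))
    key <- paste(df[[cols$person]], df[[cols$item]], sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate record for person '%s', item '%s'",
                   d[[cols$person]], d[[cols$item]]))
    }
    pids <- unique(as.character(df[[cols$person]]))
    iids <- unique(as.character(df[[cols$item]]))
    resp <- matrix(NA_real_, length(pids), length(iids), dimnames = list(pids, iids))
    resp[cbind(match(df[[cols$person]], pids), match(df[[cols$item]], iids))] <-
      df[[cols$response]]
    rts <- NULL
    if (cols$rt %in% names(df)) {
      rts <- matrix(NA_real_, length(pids), length(iids), dimnames = list(pids, iids))
      rts[cbind(match(df[[cols$person]], pids), match(df[[cols$item]], iids))] <-
        df[[cols$rt]]
    }
  }

  pcov <- if (!is.null(person_covariates_path))
    utils::read.csv(person_covariates_path, stringsAsFactors = FALSE) else NULL
  icov <- if (!is.null(item_covariates_path))
    utils::read.csv(item_covariates_path, stringsAsFactors = FALSE) else NULL
  test_dataset(resp, rts, person_covariates = pcov, item_covariates = icov)
}

#' Write a test dataset to CSV files
#'
#' Inverse of [load_dataset()] for the wide layout; `load_dataset()` on the
#' written files reproduces the matrices exactly.
#'
#' @param dataset a [test_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the named vector of paths written.
#' @export
write_dataset <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "test_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(responses = file.path(dir, paste0(prefix, "_responses.csv")))
  wide <- function(m) data.frame(person = rownames(m), m, check.names = FALSE)
  utils::write.csv(wide(dataset$responses), paths[["responses"]], row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$response_times)) {
    paths[["rts"]] <- file.path(dir, paste0(prefix, "_rts.csv"))
    utils::write.csv(wide(dataset$response_times), paths[["rts"]], row.names = FALSE, quote = FALSE)
  }
  if (!is.null(dataset$person_covariates)) {
    paths[["person_covariates"]] <- file.path(dir, paste0(prefix, "_persons.csv"))
    utils::write.csv(dataset$person_covariates, paths[["person_covariates"]],
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(dataset$item_covariates)) {
    paths[["item_covariates"]] <- file.path(dir, paste0(prefix, "_items.csv"))
    utils::write.csv(dataset$item_covariates, paths[["item_covariates"]],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Natural-log transform of a response-time matrix
#'
#' Response-time distributions have a floor at zero and a long right tail; the
#' models in this package work on the natural log scale throughout, so that,
#' e.g., a mean log response time of 3.038 corresponds to 20.860 s.
#'
#' @param rt_matrix matrix of positive response times in seconds (NA allowed),
#'   or a [test_dataset()] (its `response_times` element is used).
#' @return matrix of natural-log response times, class `log_rt_matrix`;
#'   missingness is preserved.
#' @export
log_transform <- function(rt_matrix) {
  if (inherits(rt_matrix, "test_dataset")) {
    if (is.null(rt_matrix$response_times)) stop("dataset has no response times")
    rt_matrix <- rt_matrix$response_times
  }
  rt_matrix <- as.matrix(rt_matrix)
  off <- which(!is.na(rt_matrix) & rt_matrix <= 0, arr.ind = TRUE)
  if (nrow(off)) {
    rn <- rownames(rt_matrix) %||% as.character(seq_len(nrow(rt_matrix)))
    cn <- colnames(rt_matrix) %||% as.character(seq_len(ncol(rt_matrix)))
    stop(sprintf("cannot log-transform non-positive RT at person '%s', item '%s'",
                 rn[off[1, 1]], cn[off[1, 2]]))
  }
  structure(log(rt_matrix), class = c("log_rt_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
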