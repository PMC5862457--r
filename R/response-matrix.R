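#' Construct a response matrix of ordinal scores
#'
#' The raw data object of the package: a persons-by-items matrix of ordinal
#' scores coded internally as 0..K (where K + 1 is the number of response
#' categories), with `NA` marking missing responses. External Likert codes
#' 1..K+1 are shifted to this 0-based coding by [read_responses()]; Rasch
#' category formulas index categories from 0.
#'
#' @param responses Numeric matrix of scores in `0:(n_categories - 1)` or
#'   `NA`; rows are persons, columns are items.
#' @param person_ids,item_ids Unique identifiers; default to existing
#'   dimnames or generated labels.
#' @param n_categories Number of response categories K + 1.
#' @return An object of class `response_matrix`: a list with elements
#'   `responses` (integer matrix with dimnames), `person_ids`, `item_ids`,
#'   `n_categories`.
#' @export
response_matrix <- function(responses, person_ids = rownames(responses),
                            item_ids = colnames(responses), n_categories = 5L) {
  responses <- as.matrix(responses)
  n_categories <- as.integer(n_categories)
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(responses)))
  if (is.null(item_ids)) item_ids <- paste0("i", seq_len(ncol(responses)))
  person_ids <- as.character(person_ids)
  item_ids <- as.character(item_ids)
  if (length(person_ids) != nrow(responses) ||
      length(item_ids) != ncol(responses)) {
    stop("id lengths must match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(person_ids)) stop("duplicate person ids", call. = FALSE)
  if (anyDuplicated(item_ids)) stop("duplicate item ids", call. = FALSE)
  vals <- responses[!is.na(responses)]
  if (length(vals) && (any(vals != round(vals)) || any(vals < 0) ||
                       any(vals > n_categories - 1L))) {
    stop("non-missing scores must be integers in [0, ", n_categories - 1L,
         "]", call. = FALSE)
  }
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(person_ids, item_ids)
  structure(
    list(responses = responses, person_ids = person_ids, item_ids = item_ids,
         n_categories = n_categories),
    class = "response_matrix"
  )
}

#' Read ordinal responses from a delimited text file
#'
#' Expects a header row with a person-id column followed by one column per
#' item, and one row per person. Cells hold external Likert codes
#' `1..n_categories` or a missing code; scores are shifted to the internal
#' 0-based coding.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param missing_codes Character vector of cell values treated as missing.
#' @param n_categories Number of response categories.
#' @param sep Field separator; `","` or `"\t"`.
#' @param id_column Name or index of the person-id column (default first).
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, missing_codes = c("", "NA"),
                           n_categories = 5L, sep = ",", id_column = 1L) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          comment.char = "", strip.white = TRUE)
  if (ncol(df) < 3L) stop("need an id column and at least 2 items: ", path,
                          call. = FALSE)
  person_ids <- df[[id_column]]
  item_ids <- colnames(df)[-id_column]  # before subsetting: `[.data.frame`
  dat <- df[, -id_column, drop = FALSE] # would silently de-duplicate names
  if (anyDuplicated(person_ids)) {
    stop("duplicate person ids in ", path, ": ",
         paste(unique(person_ids[duplicated(person_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(item_ids)) {
    stop("duplicate item ids in ", path, ": ",
         paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(NA_integer_, nrow(dat), ncol(dat))
  for (j in seq_len(ncol(dat))) {
    cell <- dat[[j]]
    miss <- cell %in% missing_codes
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & (is.na(num) | num != round(num) | num < 1 |
                      num > n_categories)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("invalid cell '", cell[i], "' at row ", i, " (person '",
           person_ids[i], "'), column '", item_ids[j],
           "': expected an integer in [1, ", n_categories,
           "] or a missing code", call. = FALSE)
    }
    m[!miss, j] <- as.integer(num[!miss]) - 1L  # shift 1..K+1 -> 0..K
  }
  response_matrix(m, person_ids, item_ids, n_categories)
}

#' Write a response matrix to a delimited text file
#'
#' Inverse of [read_responses()]: internal 0-based scores are written as
#' external codes `1..n_categories`, missing entries as empty cells.
#'
#' @param rm A [response_matrix()].
#' @param path Output file path.
#' @param sep Field separator.
#' @param id_header Header of the person-id column.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path, sep = ",", id_header = "person_id") {
  stopifnot(inherits(rm, "response_matrix"))
  ext <- rm$responses + 1L
  out <- cbind(rm$person_ids, apply(ext, 2L, function(x) {
    y <- as.character(x); y[is.na(x)] <- ""; y
  }))
  colnames(out) <- c(id_header, rm$item_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reflect reverse-keyed items
#'
#' Recodes every reverse-keyed item of the scale as `x -> K - x` (so that
#' higher internal scores always mean more of the trait); other items and
#' missing entries are untouched. Applying the operation twice restores the
#' original matrix.
#'
#' @param rm A [response_matrix()].
#' @param scale A [scale_definition()] whose `reverse_keyed` items all exist
#'   in `rm`.
#' @return A recoded [response_matrix()].
#' @export
apply_reverse_keying <- function(rm, scale) {
  stopifnot(inherits(rm, "response_matrix"),
            inherits(scale, "scale_definition"))
  rev_ids <- scale$reverse_keyed
  if (!length(rev_ids)) return(rm)
  unknown <- setdiff(rev_ids, rm$item_ids)
  if (length(unknown)) {
    stop("reverse-keyed items not present in the response matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  K <- rm$n_categories - 1L
  m <- rm$responses
  cols <- match(rev_ids, rm$item_ids)
  m[, cols] <- K - m[, cols]
  response_matrix(m, rm$person_ids, rm$item_ids, rm$n_categories)
}

#' Exclude persons with excessive missing data
#'
#' Removes every person whose fraction of missing responses is strictly
#' greater than `max_missing_fraction` ("more than 20%" by default). The
#' threshold is evaluated over all items present in `rm`, i.e. over the
#' administered instrument, before any dimension subsetting.
#'
#' @param rm A [response_matrix()].
#' @param max_missing_fraction Exclusion threshold in `[0, 1)`; a person at
#'   exactly the threshold is retained.
#' @return A list with elements `retained` (the filtered
#'   [response_matrix()]) and `excluded` (character vector of removed person
#'   ids). Retained plus excluded persons partition the input.
#' @export
filter_missing_persons <- function(rm, max_missing_fraction = 0.20) {
  stopifnot(inherits(rm, "response_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction >= 1) {
    stop("`max_missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  frac <- rowMeans(is.na(rm$responses))
  drop <- frac > max_missing_fraction
  if (all(drop)) {
    stop("all persons exceed the missing-data threshold; no data left",
         call. = FALSE)
  }
  retained <- response_matrix(rm$responses[!drop, , drop = FALSE],
                              rm$person_ids[!drop], rm$item_ids,
                              rm$n_categories)
  list(retained = retained, excluded = rm$person_ids[drop])
}

#' Restrict a response matrix to one dimension of a scale
#'
#' Keeps only the columns belonging to the requested dimension, in the order
#' given by the scale definition, for either the full item set or the
#' short-form subset. Persons are unchanged.
#'
#' @param rm A [response_matrix()].
#' @param scale A [scale_definition()].
#' @param dimension Dimension name.
#' @param version `"full"` or `"short"`.
#' @return A [response_matrix()] restricted to the dimension's items.
#' @export
subset_dimension <- function(rm, scale, dimension,
                             version = c("full", "short")) {
  stopifnot(inherits(rm, "response_matrix"),
            inherits(scale, "scale_definition"))
  version <- match.arg(version)
  if (!dimension %in% names(scale$dimensions)) {
    stop("unknown dimension '", dimension, "'; available: ",
         paste(names(scale$dimensions), collapse = ", "), call. = FALSE)
  }
  ids <- if (version == "full") {
    scale$dimensions[[dimension]]
  } else {
    if (!dimension %in% names(scale$short_form)) {
      stop("no short form defined for dimension '", dimension, "'",
           call. = FALSE)
    }
    scale$short_form[[dimension]]
  }
  missing_items <- setdiff(ids, rm$item_ids)
  if (length(missing_items)) {
    stop("items of dimension '", dimension, "' absent from data: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  cols <- match(ids, rm$item_ids)
  response_matrix(rm$responses[, cols, drop = FALSE], rm$person_ids, ids,
                  rm$n_categories)
}

#' @export
print.response_matrix <- function(x, ...) {
  miss <- mean(is.na(x$responses))
  cat("Response matrix:", length(x$person_ids), "persons x",
      length(x$item_ids), "items,", x$n_categories, "categories",
      sprintf("(%.1f%% missing)\n", 100 * miss))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)
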