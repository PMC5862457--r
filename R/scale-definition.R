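#' Define a multidimensional scale with optional short-form subsets
#'
#' A scale definition maps each dimension of an instrument to an ordered list
#' of item identifiers, optionally marks a subset of each dimension as the
#' short-form items, lists reverse-keyed items, and records the number of
#' response categories shared by all items.
#'
#' @param dimensions Named list; each element is a character vector of item
#'   ids belonging to that dimension, in presentation order. Dimensions must
#'   be pairwise disjoint and contain at least 4 items each.
#' @param short_form Named list (names a subset of `names(dimensions)`); each
#'   element is the character vector of short-form item ids for that
#'   dimension. Every short-form item must belong to the dimension's full
#'   item list, and each short form needs at least 2 items.
#' @param reverse_keyed Character vector of item ids whose raw scores are to
#'   be reflected before analysis. Default none.
#' @param n_categories Number of response categories (e.g. 5 for a 1-5
#'   Likert format).
#'
#' @return An object of class `scale_definition`.
#' @seealso [read_scale_definition()], [upps_scale_definition()],
#'   [subset_dimension()]
#' @export
scale_definition <- function(dimensions, short_form = list(),
                             reverse_keyed = character(), n_categories = 5L) {
  if (!is.list(dimensions) || is.null(names(dimensions)) ||
      any(!nzchar(names(dimensions)))) {
    stop("`dimensions` must be a named list of item-id vectors", call. = FALSE)
  }
  dimensions <- lapply(dimensions, as.character)
  short_form <- lapply(short_form, as.character)
  reverse_keyed <- as.character(reverse_keyed)
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("`n_categories` must be at least 2", call. = FALSE)

  all_items <- unlist(dimensions, use.names = FALSE)
  if (anyDuplicated(all_items)) {
    stop("dimensions must be pairwise disjoint in item ids; duplicated: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "),
         call. = FALSE)
  }
  short <- lengths(dimensions) < 4L
  if (any(short)) {
    stop("each dimension needs at least 4 items; too small: ",
         paste(names(dimensions)[short], collapse = ", "), call. = FALSE)
  }
  if (length(short_form)) {
    if (is.null(names(short_form)) ||
        !all(names(short_form) %in% names(dimensions))) {
      stop("short_form names must match dimension names", call. = FALSE)
    }
    for (d in names(short_form)) {
      if (length(short_form[[d]]) < 2L) {
        stop("short form of '", d, "' needs at least 2 items", call. = FALSE)
      }
      bad <- setdiff(short_form[[d]], dimensions[[d]])
      if (length(bad)) {
        stop("short-form items not in dimension '", d, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  bad_rev <- setdiff(reverse_keyed, all_items)
  if (length(bad_rev)) {
    stop("reverse_keyed items not in any dimension: ",
         paste(bad_rev, collapse = ", "), call. = FALSE)
  }
  structure(
    list(dimensions = dimensions, short_form = short_form,
         reverse_keyed = reverse_keyed, n_categories = n_categories),
    class = "scale_definition"
  )
}

#' Read a scale definition from a JSON or YAML file
#'
#' The document must contain the keys `dimensions` (mapping dimension name to
#' item-id list), and may contain `short_form`, `reverse_keyed` and
#' `n_categories` (default 5).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [scale_definition()] object.
#' @export
read_scale_definition <- function(path) {
  if (!file.exists(path)) {
    stop("scale definition file not found: ", path, call. = FALSE)
  }
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(doc$dimensions)) {
    stop("scale definition must contain a 'dimensions' key: ", path,
         call. = FALSE)
  }
  scale_definition(
    dimensions = lapply(doc$dimensions, as.character),
    short_form = if (is.null(doc$short_form)) list() else
      lapply(doc$short_form, as.character),
    reverse_keyed = if (is.null(doc$reverse_keyed)) character() else
      as.character(doc$reverse_keyed),
    n_categories = if (is.null(doc$n_categories)) 5L else doc$n_categories
  )
}

#' Built-in UPPS-P / SUPPS-P scale definition
#'
#' Returns the item structure of the 59-item UPPS-P impulsive behaviour
#' scale: five dimensions (Negative Urgency 12 items, Lack of Premeditation
#' 11, Lack of Perseverance 10, Sensation Seeking 12, Positive Urgency 14)
#' with the four-item short-form (SUPPS-P) subsets. Items use the
#' questionnaire's item numbers as ids ("i1".."i59"). The reverse-keyed set
#' defaults to empty and can be overridden.
#'
#' @param reverse_keyed Character vector of reverse-keyed item ids.
#' @return A [scale_definition()] object with `n_categories = 5`.
#' @export
upps_scale_definition <- function(reverse_keyed = character()) {
  it <- function(x) paste0("i", x)
  scale_definition(
    dimensions = list(
      negative_urgency     = it(c(2, 7, 12, 17, 22, 29, 34, 39, 44, 50, 53, 58)),
      lack_of_premeditation = it(c(1, 6, 11, 16, 21, 28, 33, 38, 43, 48, 55)),
      lack_of_perseverance = it(c(4, 9, 14, 19, 24, 27, 32, 37, 42, 47)),
      sensation_seeking    = it(c(3, 8, 13, 18, 23, 26, 31, 36, 41, 46, 51, 56)),
      positive_urgency     = it(c(5, 10, 15, 20, 25, 30, 35, 40, 45, 49, 52, 54, 57, 59))
    ),
    short_form = list(
      negative_urgency     = it(c(29, 34, 44, 50)),
      lack_of_premeditation = it(c(6, 33, 43, 48)),
      lack_of_perseverance = it(c(4, 27, 37, 42)),
      sensation_seeking    = it(c(3, 23, 31, 41)),
      positive_urgency     = it(c(40, 45, 49, 52))
    ),
    reverse_keyed = reverse_keyed,
    n_categories = 5L
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("Scale definition:", length(x$dimensions), "dimensions,",
      length(unlist(x$dimensions)), "items,",
      x$n_categories, "response categories\n")
  for (d in names(x$dimensions)) {
    sf <- if (d %in% names(x$short_form)) {
      paste0(" (short form: ", length(x$short_form[[d]]), " items)")
    } else ""
    cat("  ", d, ": ", length(x$dimensions[[d]]), " items", sf, "\n", sep = "")
  }
  if (length(x$reverse_keyed)) {
    cat("  reverse-keyed:", paste(x$reverse_keyed, collapse = ", "), "\n")
  }
  invisible(x)
}
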