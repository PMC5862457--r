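#' Run the full measurement and concordance pipeline
#'
#' Executes, for each requested dimension of the scale: reverse-keying and
#' missing-data exclusion (once, on the whole instrument), independent
#' Rating Scale Model calibrations of the full and short versions, fit
#' diagnostics (item and person mean-squares, separation, information
#' curves, item maps) and the full-vs-short concordance analysis.
#'
#' @param responses A [response_matrix()] or a path to a delimited response
#'   file (see [read_responses()]).
#' @param scale A [scale_definition()] or a path to a JSON/YAML definition.
#' @param dimensions Dimension names to analyze; default all dimensions that
#'   have a short form.
#' @param max_missing_fraction Person exclusion threshold; see
#'   [filter_missing_persons()].
#' @param theta_grid Grid for information curves.
#' @param out_dir Optional directory: when given, tables are written there
#'   via [render_tables()] (created if absent).
#' @param format Output format(s) for `out_dir`: `"tsv"`, `"json"` or both.
#' @param ... Estimation settings passed to [fit_rsm()].
#' @return An object of class `pipeline_bundle`: a list with `excluded`
#'   (person ids removed for missingness), `n_analyzed`, and `dimensions`, a
#'   named list holding per dimension: `fit_full`, `fit_short`, `item_table_full`,
#'   `item_table_short`, `person_fit_full`, `person_fit_short`,
#'   `separation` (data frame, margin x version), `information` (data frame
#'   with a `version` column), `map_full`, `map_short`, `concordance`.
#' @export
run_pipeline <- function(responses, scale, dimensions = NULL,
                         max_missing_fraction = 0.20,
                         theta_grid = seq(-6, 6, by = 0.1),
                         out_dir = NULL, format = "tsv", ...) {
  if (is.character(responses)) responses <- read_responses(responses)
  if (is.character(scale)) scale <- read_scale_definition(scale)
  stopifnot(inherits(responses, "response_matrix"),
            inherits(scale, "scale_definition"))
  if (is.null(dimensions)) dimensions <- names(scale$short_form)
  unknown <- setdiff(dimensions, names(scale$dimensions))
  if (length(unknown)) {
    stop("unknown dimension(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  rm <- apply_reverse_keying(responses, scale)
  filt <- filter_missing_persons(rm, max_missing_fraction)
  rm <- filt$retained

  results <- list()
  for (d in dimensions) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", what, "' failed for dimension '", d, "': ",
             conditionMessage(e), call. = FALSE)
      })
    }
    rm_full <- stage("subset", subset_dimension(rm, scale, d, "full"))
    rm_short <- stage("subset", subset_dimension(rm, scale, d, "short"))
    fit_full <- stage("fit-full", fit_rsm(rm_full, ...))
    fit_short <- stage("fit-short", fit_rsm(rm_short, ...))

    sep <- do.call(rbind, lapply(
      list(c("full", "persons"), c("full", "items"),
           c("short", "persons"), c("short", "items")),
      function(vm) {
        s <- separation(if (vm[1L] == "full") fit_full else fit_short, vm[2L])
        data.frame(version = vm[1L], margin = vm[2L], n = s$n,
                   observed_sd = s$observed_sd, rmse = s$rmse,
                   adjusted_sd = s$adjusted_sd, reliability = s$reliability,
                   separation_index = s$separation_index, strata = s$strata,
                   verdict = s$verdict)
      }))

    info <- rbind(
      cbind(version = "full",
            as.data.frame(information_function(fit_full, theta_grid))),
      cbind(version = "short",
            as.data.frame(information_function(fit_short, theta_grid)))
    )

    results[[d]] <- list(
      fit_full = fit_full, fit_short = fit_short,
      item_table_full = item_table(fit_full),
      item_table_short = item_table(fit_short),
      person_fit_full = infit_outfit(fit_full, "persons"),
      person_fit_short = infit_outfit(fit_short, "persons"),
      separation = sep, information = info,
      map_full = item_map(fit_full), map_short = item_map(fit_short),
      concordance = stage("concordance",
                          concordance_report(fit_full, fit_short, d))
    )
  }

  bundle <- structure(
    list(excluded = filt$excluded, n_analyzed = nrow(rm$responses),
         dimensions = results),
    class = "pipeline_bundle"
  )
  if (!is.null(out_dir)) render_tables(bundle, out_dir, format)
  bundle
}

#' Write pipeline tables to disk
#'
#' Serializes a [run_pipeline()] bundle: per dimension, an item calibration
#' table (measure, error, INFIT/OUTFIT, item-total correlation, per
#' version), a separation table, the information curves, item maps and the
#' concordance report. TSV files round logits to 4 decimals and indices to
#' 3; JSON keeps full precision.
#'
#' @param bundle A `pipeline_bundle`.
#' @param out_dir Output directory (created if absent).
#' @param format `"tsv"`, `"json"` or both.
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(bundle, out_dir, format = "tsv") {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  format <- match.arg(format, c("tsv", "json"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  round_df <- function(df) {
    for (nm in names(df)) {
      if (is.numeric(df[[nm]])) {
        digits <- if (nm %in% c("reliability", "r", "r_squared", "riu",
                                "efficiency", "infit_mnsq", "outfit_mnsq",
                                "item_total_r", "item_total_correlation"))
          3L else 4L
        df[[nm]] <- round(df[[nm]], digits)
      }
    }
    df
  }
  emit <- function(obj, stem) {
    if ("tsv" %in% format && is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(stem, ".tsv"))
      utils::write.table(round_df(obj), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <<- c(written, f)
    }
    if ("json" %in% format) {
      f <- file.path(out_dir, paste0(stem, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
      written <<- c(written, f)
    }
  }

  for (d in names(bundle$dimensions)) {
    res <- bundle$dimensions[[d]]
    items <- rbind(cbind(version = "full", res$item_table_full),
                   cbind(version = "short", res$item_table_short))
    emit(items, paste0(d, "_items"))
    emit(res$separation, paste0(d, "_separation"))
    emit(res$information, paste0(d, "_information"))
    emit(rbind(cbind(version = "full", res$map_full),
               cbind(version = "short", res$map_short)),
         paste0(d, "_item_map"))
    conc <- res$concordance
    conc_df <- data.frame(dimension = conc$dimension, n_pairs = conc$n_pairs,
                          slope = conc$slope, intercept = conc$intercept,
                          r = conc$r, r_squared = conc$r_squared,
                          riu = conc$riu, riu_verdict = conc$riu_verdict,
                          efficiency = conc$efficiency,
                          efficiency_verdict = conc$efficiency_verdict,
                          order_tau = conc$order_tau,
                          n_short = conc$n_short, n_full = conc$n_full)
    emit(conc_df, paste0(d, "_concordance"))
  }

  summary <- data.frame(
    dimension = names(bundle$dimensions),
    n_persons = bundle$n_analyzed,
    n_excluded = length(bundle$excluded),
    slope = vapply(bundle$dimensions, function(r) r$concordance$slope, 0),
    r = vapply(bundle$dimensions, function(r) r$concordance$r, 0),
    riu = vapply(bundle$dimensions, function(r) r$concordance$riu, 0),
    efficiency = vapply(bundle$dimensions,
                        function(r) r$concordance$efficiency, 0),
    row.names = NULL)
  emit(summary, "concordance_summary")
  invisible(written)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline bundle:", length(x$dimensions), "dimension(s),",
      x$n_analyzed, "persons analyzed,", length(x$excluded),
      "excluded for missing data\n")
  for (d in names(x$dimensions)) print(x$dimensions[[d]]$concordance)
  invisible(x)
}
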