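# Per-column application to tables: eligible numeric columns (at least
# min_unique_column distinct values) are cleaned independently; flagged
# cells become NA rather than dropping rows, so one column's outliers never
# destroy another column's data.

read_table_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  tryCatch(
    read.csv(path, sep = sep, check.names = FALSE,
             na.strings = c("", "NA", "na", "NaN")),
    error = function(e) stop("clean_table: cannot read '", path, "': ",
                             conditionMessage(e)))
}

model_params_row <- function(model) {
  if (inherits(model, "tgh_params")) {
    data.frame(A = model$A, B = model$B, g = model$g, h = model$h)
  } else if (inherits(model, "mixture_model")) {
    p1 <- model$components[[1]]
    data.frame(A = p1$A, B = p1$B, g = p1$g, h = p1$h)
  } else if (is.list(model) && !is.null(model$upper_side)) {
    p <- model$upper_side
    data.frame(A = p$A, B = p$B, g = p$g, h = p$h)
  } else {
    data.frame(A = NA_real_, B = NA_real_, g = NA_real_, h = NA_real_)
  }
}

#' Remove outliers from every eligible column of a table
#'
#' Columns that are numeric with at least `min_unique_column` distinct
#' finite values are run through [detect_outliers()]; flagged cells are
#' replaced by `NA`. Other columns pass through untouched and are reported
#' as ineligible.
#'
#' @param table a data frame, or the path of a CSV/TSV file (delimiter
#'   guessed from the extension).
#' @param config a [detector_config()]; per-column seeds are derived from
#'   `config$seed` so results are reproducible and column-order independent.
#' @param index optional name of an identifier column to pass through.
#' @return a list of class `"clean_table"`: `cleaned` (the table with
#'   flagged cells set to `NA`), `report` (one row per column: shape, model
#'   parameters, cuts, counts, fraction removed, and a skip reason where
#'   applicable), and `results` (the per-column `"outlier_result"` objects).
#' @export
#' @examples
#' set.seed(4)
#' tab <- data.frame(a = rnorm(500), b = c(rnorm(499), 25))
#' ct <- clean_table(tab, detector_config(seed = 4))
#' ct$report[, c("column", "status", "n_flagged")]
clean_table <- function(table, config = detector_config(), index = NULL) {
  df <- if (is.character(table)) read_table_auto(table) else as.data.frame(table)
  cfg <- config
  report <- list()
  results <- list()
  for (j in seq_along(df)) {
    nm <- names(df)[j]
    col <- df[[j]]
    base <- data.frame(column = nm, status = "skipped", shape = NA_character_,
                       A = NA_real_, B = NA_real_, g = NA_real_, h = NA_real_,
                       lower_cut = NA_real_, upper_cut = NA_real_,
                       n = sum(is.finite(suppressWarnings(as.numeric(col)))),
                       n_flagged = 0L, fraction_removed = NA_real_,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(index) && nm == index) {
      base$reason <- "index column"
      report[[j]] <- base
      next
    }
    if (!is.numeric(col)) {
      base$reason <- "not numeric"
      report[[j]] <- base
      next
    }
    nu <- length(unique(col[is.finite(col)]))
    if (nu < cfg$min_unique_column) {
      base$reason <- sprintf("fewer than %d unique values (%d)",
                             cfg$min_unique_column, nu)
      report[[j]] <- base
      next
    }
    col_cfg <- cfg
    if (!is.null(cfg$seed)) col_cfg$seed <- cfg$seed + 1000L * j
    res <- tryCatch(detect_outliers(col, col_cfg),
                    ghoutliers_degenerate = function(e) e)
    if (inherits(res, "error")) {
      base$reason <- conditionMessage(res)
      report[[j]] <- base
      next
    }
    df[[j]][res$mask] <- NA
    pars <- model_params_row(res$model)
    base$status <- "cleaned"
    base$shape <- res$shape$label
    base[, c("A", "B", "g", "h")] <- pars
    base$lower_cut <- res$lower_cut
    base$upper_cut <- res$upper_cut
    base$n <- res$n
    base$n_flagged <- sum(res$mask)
    base$fraction_removed <- res$fraction_removed
    report[[j]] <- base
    results[[nm]] <- res
  }
  structure(list(cleaned = df, report = do.call(rbind, report),
                 results = results),
            class = "clean_table")
}

#' @export
print.clean_table <- function(x, ...) {
  ncl <- sum(x$report$status == "cleaned")
  cat(sprintf("clean_table: %d of %d columns cleaned, %d cells flagged\n",
              ncl, nrow(x$report), sum(x$report$n_flagged)))
  print(x$report[, c("column", "status", "shape", "n", "n_flagged",
                     "fraction_removed")], row.names = FALSE)
  invisible(x)
}

#' Clean a delimited file and write the results
#'
#' File-level wrapper around [clean_table()]: writes the cleaned table (same
#' shape, flagged cells as NA), a TSV report (one row per column) and a JSON
#' sidecar with the fitted model parameters.
#'
#' @param input path of the CSV/TSV input (header row expected).
#' @param output path for the cleaned table (same delimiter as input).
#' @param report path for the TSV per-column report.
#' @param json optional path for the JSON parameter sidecar.
#' @param config a [detector_config()].
#' @param index optional identifier column name.
#' @return the [clean_table()] result, invisibly.
#' @export
clean_file <- function(input, output, report, json = NULL,
                       config = detector_config(), index = NULL) {
  ct <- clean_table(input, config = config, index = index)
  sep <- if (grepl("\\.tsv$|\\.txt$", input, ignore.case = TRUE)) "\t" else ","
  write.table(ct$cleaned, output, sep = sep, row.names = FALSE, na = "NA",
              quote = FALSE)
  write.table(ct$report, report, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json)) {
    params <- lapply(ct$results, function(r) {
      mod <- r$model
      if (inherits(mod, "tgh_params")) {
        list(kind = "single", A = mod$A, B = mod$B, g = mod$g, h = mod$h)
      } else if (inherits(mod, "mixture_model")) {
        list(kind = "mixture", weights = mod$weights,
             components = lapply(mod$components, function(p)
               list(A = p$A, B = p$B, g = p$g, h = p$h)))
      } else {
        list(kind = "two_sided",
             lower_side = with(mod$lower_side, list(A = A, B = B, g = g, h = h)),
             upper_side = with(mod$upper_side, list(A = A, B = B, g = g, h = h)))
      }
    })
    jsonlite::write_json(params, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(ct)
}
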