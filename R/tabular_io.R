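#' Read a luminescence CSV table
#'
#' The expected layout has a header row and columns `Luc` (firefly
#' luminescence, RLU), `Ren` (Renilla luminescence, RLU), `Construct`
#' (reporter construct label), followed by one column per experimental
#' condition (e.g. `OHT`, `Cytokine`). Condition labels that parse as numbers
#' are treated as categorical levels, never as quantities.
#'
#' @param path Path to a CSV file (comma delimiter, `.` decimal, UTF-8,
#'   quoted fields allowed).
#' @return A `data.frame` of class `luminescence_table` with columns in file
#'   order; `Luc` and `Ren` numeric, all other columns character.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Luc,Ren,Construct,OHT,Cytokine",
#'              "120,10,Cebpa0,no,IL3", "150,12,Cebpa0,no,IL3"), f)
#' read_luminescence_csv(f)
#' @export
read_luminescence_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_luminescence_table(df, where = path)
}

validate_luminescence_table <- function(df, where = "input") {
  nm <- names(df)
  if (length(nm) < 3L || nm[1] != "Luc" || nm[2] != "Ren" || nm[3] != "Construct") {
    stop(sprintf(paste0("%s: the first three columns must be named 'Luc', 'Ren', ",
                        "'Construct' (found: %s)"),
                 where, paste(utils::head(nm, 3), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("%s: duplicated column names", where), call. = FALSE)
  }
  for (col in c("Luc", "Ren")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("%s: non-numeric '%s' value in data row %d",
                     where, col, bad[1]), call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v) || !all(is.finite(v))) {
      stop(sprintf("%s: missing or non-finite '%s' value in data row %d",
                   where, col, which(!is.finite(v))[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  # grouping labels are categorical even when they look numeric
  for (col in setdiff(nm, c("Luc", "Ren"))) {
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("luminescence_table", "data.frame")
  df
}

#' Grouped activity estimation over a luminescence table
#'
#' Partitions the table rows by every distinct observed combination of the
#' grouping columns (all columns not in `ignore`), runs the chosen estimator
#' on each group with `Ren` as R and `Luc` as F, and (optionally) attaches a
#' bootstrap confidence interval. Groups on which the estimator fails — too
#' few replicates, zero Renilla readings for the ratio method — are reported
#' with `NA` slope and the failure message, never silently dropped. Output
#' rows follow the file-appearance order of each group's first member.
#'
#' @param table A `luminescence_table` from [read_luminescence_csv()], or any
#'   data.frame in the same layout.
#' @param alpha Significance threshold for the confidence interval; 0.05
#'   yields 95% intervals.
#' @param method Estimator: `"ratio"`, `"ols"`, `"eiv"`, or `"reiv"`
#'   (default).
#' @param ci_method `"boot"` (basic bootstrap), `"boot-positive"` (basic with
#'   the lower bound clamped at 0; default), or `"none"`.
#' @param ignore Character vector of column names that are not grouping
#'   conditions; must contain at least `"Luc"` and `"Ren"`. Add annotation
#'   columns here.
#' @param n_boot Bootstrap resamples (default 999).
#' @param seed Optional integer seed making bootstrap intervals reproducible.
#' @param reference_construct Optional construct label; when given, an extra
#'   column `relative_slope` reports each group's slope divided by the slope
#'   of the matching group (same condition levels) of the reference construct.
#'   No interval is propagated to the ratio.
#' @return A `data.frame` of class `result_table`: the grouping columns, then
#'   `slope`, `ci_lower`, `ci_upper`, `n_replicates`, `method`, `converged`,
#'   and `error` (NA for successful groups).
#' @examples
#' df <- data.frame(Luc = c(40, 80, 10, 20), Ren = c(10, 20, 10, 20),
#'                  Construct = c("a", "a", "b", "b"))
#' calc_slopes_cis(df, method = "ols", ci_method = "none")
#' @export
calc_slopes_cis <- function(table, alpha = 0.05, method = "reiv",
                            ci_method = c("boot-positive", "boot", "none"),
                            ignore = c("Luc", "Ren"), n_boot = 999L,
                            seed = NULL, reference_construct = NULL) {
  if (!inherits(table, "luminescence_table")) {
    table <- validate_luminescence_table(as.data.frame(table))
  }
  method <- match.arg(method, c("ratio", "ols", "eiv", "reiv"))
  ci_method <- match.arg(ci_method)
  if (!all(c("Luc", "Ren") %in% ignore)) {
    stop("'ignore' must contain at least \"Luc\" and \"Ren\"", call. = FALSE)
  }
  group_cols <- setdiff(names(table), ignore)
  if (length(group_cols) == 0L) {
    stop("no grouping columns remain after applying 'ignore'", call. = FALSE)
  }

  if (nrow(table) == 0L) {
    out <- table[, group_cols, drop = FALSE]
    out$slope <- numeric(0); out$ci_lower <- numeric(0); out$ci_upper <- numeric(0)
    out$n_replicates <- integer(0); out$method <- character(0)
    out$converged <- logical(0); out$error <- character(0)
    class(out) <- c("result_table", "data.frame")
    return(out)
  }

  key <- do.call(paste, c(table[group_cols], sep = "\r"))
  first_seen <- !duplicated(key)
  levels_in_order <- key[first_seen]
  groups <- split(seq_len(nrow(table)), factor(key, levels = levels_in_order))

  est_fun <- get_estimator(method)
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    keyrow <- table[idx[1], group_cols, drop = FALSE]
    res <- tryCatch({
      rs <- replicate_set(renilla = table$Ren[idx], firefly = table$Luc[idx])
      if (ci_method == "none") {
        est <- est_fun(rs)
      } else {
        spec <- bootstrap_spec(
          n_boot = n_boot, alpha = alpha,
          method = if (ci_method == "boot-positive") "basic_positive" else "basic",
          seed = if (is.null(seed)) NULL else seed + g
        )
        est <- bootstrap_ci(rs, est_fun, spec)$estimate
      }
      cbind(keyrow,
            data.frame(slope = est$activity, ci_lower = est$ci_lower,
                       ci_upper = est$ci_upper, n_replicates = length(idx),
                       method = method, converged = isTRUE(est$converged),
                       error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(keyrow,
            data.frame(slope = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, n_replicates = length(idx),
                       method = method, converged = FALSE,
                       error = conditionMessage(e), stringsAsFactors = FALSE))
    })
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (!is.null(reference_construct)) {
    out <- add_reference_normalization(out, group_cols, reference_construct)
  }
  class(out) <- c("result_table", "data.frame")
  out
}

# divide each group's slope by the reference construct's slope at the same
# condition levels; no CI propagation
add_reference_normalization <- function(out, group_cols, reference_construct) {
  if (!"Construct" %in% group_cols) {
    stop("reference normalization requires 'Construct' among the grouping columns",
         call. = FALSE)
  }
  cond_cols <- setdiff(group_cols, "Construct")
  ref_rows <- out[out$Construct == reference_construct, , drop = FALSE]
  if (nrow(ref_rows) == 0L) {
    stop(sprintf("reference construct '%s' not found", reference_construct),
         call. = FALSE)
  }
  ref_key <- if (length(cond_cols) > 0L) {
    do.call(paste, c(ref_rows[cond_cols], sep = "\r"))
  } else rep("", nrow(ref_rows))
  all_key <- if (length(cond_cols) > 0L) {
    do.call(paste, c(out[cond_cols], sep = "\r"))
  } else rep("", nrow(out))
  out$relative_slope <- out$slope / ref_rows$slope[match(all_key, ref_key)]
  out
}

#' Write a result table to CSV
#'
#' Serializes slopes and interval bounds at full decimal precision (15
#' significant digits), so a write-then-read round trip preserves them.
#'
#' @param results A `result_table` from [calc_slopes_cis()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results_csv <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 15, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a replicate set as a luminescence CSV
#'
#' Emits the standard `Luc,Ren,Construct,...` layout so simulated data flow
#' through the same I/O path as measured data.
#'
#' @param data A [replicate_set()].
#' @param path Output file path.
#' @param construct Construct label for the `Construct` column.
#' @param conditions Optional named character vector of condition levels,
#'   one output column per entry.
#' @return The path, invisibly.
#' @export
write_luminescence_csv <- function(data, path, construct = "sim",
                                   conditions = NULL) {
  data <- as_replicate_set(data)
  df <- data.frame(Luc = formatC(data$firefly, digits = 15, format = "g"),
                   Ren = formatC(data$renilla, digits = 15, format = "g"),
                   Construct = construct, stringsAsFactors = FALSE)
  if (!is.null(conditions)) {
    for (nm in names(conditions)) df[[nm]] <- conditions[[nm]]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
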