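#' Compare per-trial variable tables from two measurement methods
#'
#' Takes two per-trial variable tables (as produced by stacking
#' [as.data.frame.cmj_variables()] rows, one row per trial and side) from a
#' reference method (`a`) and a comparison method (`b`), matches rows by
#' `trial_id` and `side`, and computes per variable: Bland--Altman
#' bias/LoA with CIs, RMSE, Pearson r with CI, ICC(3,1) with CI per side,
#' the two-way within-within ANOVA (method x side, case = trial), and
#' Cohen's d (harmonic-SD form) per side.
#'
#' @param a,b Data frames with columns `trial_id`, `side`, and one column
#'   per variable.
#' @param variables Variable columns to compare (default: all shared
#'   numeric columns other than the keys).
#' @param aggregation `"trial"` (default) or `"subject-mean"`; for
#'   `"subject-mean"` rows are first averaged within `subject_id` (which
#'   must then be a column).
#' @return An object of class `method_comparison`: a long data frame
#'   `report` (one row per variable x side) plus `anova` (named list of
#'   [rm_anova_2way()] results per variable).
#' @export
compare_methods <- function(a, b, variables = NULL,
                            aggregation = c("trial", "subject-mean")) {
  aggregation <- match.arg(aggregation)
  for (tb in list(a, b))
    if (!all(c("trial_id", "side") %in% names(tb)))
      stop("tables need `trial_id` and `side` columns", call. = FALSE)
  if (aggregation == "subject-mean") {
    agg <- function(tb) {
      if (!"subject_id" %in% names(tb))
        stop("subject-mean aggregation needs a `subject_id` column",
             call. = FALSE)
      num <- vapply(tb, is.numeric, logical(1))
      out <- stats::aggregate(tb[num], by = list(subject_id = tb$subject_id,
                                                 side = tb$side), mean)
      out$trial_id <- paste(out$subject_id, "mean", sep = "_")
      out
    }
    a <- agg(a); b <- agg(b)
  }
  key <- function(tb) paste(tb$trial_id, tb$side, sep = "|")
  ka <- key(a); kb <- key(b)
  orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(orphans))
    stop("unmatched trial keys: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  b <- b[match(ka, kb), , drop = FALSE]

  if (is.null(variables)) {
    num_a <- names(a)[vapply(a, is.numeric, logical(1))]
    variables <- setdiff(intersect(num_a, names(b)),
                         c("trial_id", "side", "subject_id"))
  }
  sides <- sort(unique(a$side))
  rows <- list()
  anovas <- list()
  for (v in variables) {
    long <- rbind(
      data.frame(value = a[[v]], case = a$trial_id, method = "a",
                 side = a$side, stringsAsFactors = FALSE),
      data.frame(value = b[[v]], case = b$trial_id, method = "b",
                 side = b$side, stringsAsFactors = FALSE))
    anovas[[v]] <- tryCatch(rm_anova_2way(long), error = function(e) NULL)
    for (s in sides) {
      xi <- a[[v]][a$side == s]
      yi <- b[[v]][b$side == s]
      ba <- bland_altman(xi, yi)
      pr <- tryCatch(pearson_r(xi, yi), error = function(e) NULL)
      ic <- icc_3_1(cbind(xi, yi))
      cd <- tryCatch(cohens_d_harmonic(xi, yi), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, side = s, n = length(xi),
        bias = ba$bias, bias_lo = ba$bias_ci[1], bias_hi = ba$bias_ci[2],
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        rmse = ba$rmse,
        r = if (is.null(pr)) NA else pr$r,
        r_lo = if (is.null(pr)) NA else pr$ci[1],
        r_hi = if (is.null(pr)) NA else pr$ci[2],
        r_label = if (is.null(pr)) NA else pr$label,
        icc = ic$icc, icc_lo = ic$ci[1], icc_hi = ic$ci[2],
        d = if (is.null(cd)) NA else cd$d,
        d_lo = if (is.null(cd)) NA else cd$ci[1],
        d_hi = if (is.null(cd)) NA else cd$ci[2],
        d_magnitude = if (is.null(cd)) NA else cd$magnitude,
        d_clearness = if (is.null(cd)) NA else cd$clearness,
        F_method = if (is.null(anovas[[v]])) NA else anovas[[v]]$table$F[1],
        F_side = if (is.null(anovas[[v]])) NA else anovas[[v]]$table$F[2],
        F_interaction = if (is.null(anovas[[v]]))
          NA else anovas[[v]]$table$F[3],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(report = do.call(rbind, rows), anova = anovas,
                 aggregation = aggregation),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d variables x sides (%s level)\n",
              nrow(x$report), x$aggregation))
  print(utils::head(x$report[, c("variable", "side", "bias", "loa_lower",
                                 "loa_upper", "rmse", "r", "icc", "d")],
                    20), digits = 4)
  if (nrow(x$report) > 20) cat("  ...\n")
  invisible(x)
}

#' Write a method-comparison report as TSV
#'
#' @param x A [compare_methods()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "method_comparison"))
  utils::write.table(x$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
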