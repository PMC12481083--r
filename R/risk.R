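#' Assign a NICE breast-cancer risk category
#'
#' Lifetime risk: near-population below 17 %, moderate from 17 % up to (but
#' not including) 30 %, high at 30 % and above. Ten-year risk:
#' near-population below 3 %, moderate from 3 % to 8 % inclusive, high
#' above 8 %. The two horizons place their upper boundary differently —
#' lifetime 30 % is already high, ten-year 8 % is still moderate — matching
#' the guideline wording "between 3 % and 8 %" versus ">= 17 % and < 30 %".
#'
#' @param risk_percent risk as a percentage, >= 0 (vectorized)
#' @param horizon "lifetime" or "ten_year"
#' @return character vector in \{"near_population","moderate","high"\}
#' @export
assign_risk_category <- function(risk_percent, horizon = c("lifetime", "ten_year")) {
  horizon <- match.arg(horizon)
  if (any(is.na(risk_percent)) || any(risk_percent < 0)) {
    stop("risk_percent must be non-negative")
  }
  if (horizon == "lifetime") {
    ifelse(risk_percent < 17, "near_population",
           ifelse(risk_percent < 30, "moderate", "high"))
  } else {
    ifelse(risk_percent < 3, "near_population",
           ifelse(risk_percent <= 8, "moderate", "high"))
  }
}

#' Read a risk table (TSV)
#'
#' Columns: `subject_id`, optional `scenario_id`, `horizon`
#' ("lifetime"/"ten_year"), `risk_percent`. A `category` column is
#' (re)derived from the thresholds.
#'
#' @param path TSV path
#' @return data.frame with a validated `category` column
#' @export
read_risk_table <- function(path) {
  if (!file.exists(path)) stop("risk file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("subject_id", "horizon", "risk_percent")
  if (!all(required %in% names(tab))) {
    stop("risk table needs columns: ", paste(required, collapse = ", "))
  }
  if (!"scenario_id" %in% names(tab)) tab$scenario_id <- ""
  tab$risk_percent <- as.numeric(tab$risk_percent)
  tab$category <- NA_character_
  for (h in unique(tab$horizon)) {
    idx <- tab$horizon == h
    tab$category[idx] <- assign_risk_category(tab$risk_percent[idx], h)
  }
  tab
}

#' Tabulate risk-category changes between two methods
#'
#' Records are matched by (subject_id, scenario_id, horizon); the cross-tab
#' counts pairs by (reference category, test category), the change count is
#' its off-diagonal sum, and the percentage is reported both at one decimal
#' and at integer display rounding.
#'
#' @param ref,test data.frames with columns `subject_id`, `scenario_id`
#'   (optional), `horizon`, `risk_percent` and/or `category`; categories
#'   are derived from `risk_percent` when absent
#' @return list of class `category_change`: `n_pairs`, `n_changed`,
#'   `pct_changed` (1-decimal), `pct_changed_display` (integer),
#'   `crosstab` (reference categories in rows, test in columns)
#' @export
category_change_table <- function(ref, test) {
  prep <- function(x) {
    x <- as.data.frame(x)
    if (!"scenario_id" %in% names(x)) x$scenario_id <- ""
    x$scenario_id[is.na(x$scenario_id)] <- ""
    if (!"category" %in% names(x)) {
      x$category <- NA_character_
      for (h in unique(x$horizon)) {
        idx <- x$horizon == h
        x$category[idx] <- assign_risk_category(x$risk_percent[idx], h)
      }
    }
    x$key <- paste(x$subject_id, x$scenario_id, x$horizon, sep = "\r")
    if (anyDuplicated(x$key)) stop("duplicate (subject, scenario, horizon) keys")
    x
  }
  r <- prep(ref); t <- prep(test)
  only_ref <- setdiff(r$key, t$key)
  only_test <- setdiff(t$key, r$key)
  if (length(only_ref) > 0 || length(only_test) > 0) {
    stop("unmatched records: ",
         paste(gsub("\r", "/", c(only_ref, only_test)), collapse = "; "))
  }
  t <- t[match(r$key, t$key), ]
  levels <- c("near_population", "moderate", "high")
  crosstab <- table(factor(r$category, levels = levels),
                    factor(t$category, levels = levels),
                    dnn = c("reference", "test"))
  n_pairs <- nrow(r)
  n_changed <- sum(r$category != t$category)
  structure(list(n_pairs = n_pairs, n_changed = n_changed,
                 pct_changed = round_half_up(n_changed * 100 / n_pairs, 1),
                 pct_changed_display = round_half_up(n_changed * 100 / n_pairs, 0),
                 crosstab = crosstab),
            class = "category_change")
}

#' @export
print.category_change <- function(x, ...) {
  cat(sprintf("%d of %d pairs changed risk category (%.1f %%, displayed %d %%)\n",
              x$n_changed, x$n_pairs, x$pct_changed, as.integer(x$pct_changed_display)))
  print(x$crosstab)
  invisible(x)
}
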