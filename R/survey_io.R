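#' Respondent response tables
#'
#' A data frame with a `respondent_id` column, one ordinal rating column per
#' third-level indicator, and covariate columns prefixed `meta_` (gender,
#' years-of-work band, job nature, major, certificates, exercise habit,
#' training/drill participation, ...).
#'
#' @param df Data frame holding `respondent_id`, the leaf columns and any
#'   covariates.
#' @param leaf_ids Character vector naming the rating columns.
#' @param axis Declared rating range; ratings outside it are an error (missing
#'   values are allowed and handled by [filter_valid]).
#' @return Object of class `response_table` (a data frame with attributes
#'   `leaf_ids` and `axis`).
#' @export
response_table <- function(df, leaf_ids, axis = c(1, 5)) {
  stopifnot(is.data.frame(df))
  if (!("respondent_id" %in% names(df)))
    stop("response table must have a 'respondent_id' column")
  missing_cols <- setdiff(leaf_ids, names(df))
  if (length(missing_cols))
    stop("missing leaf column(s): ", paste(missing_cols, collapse = ", "))
  for (lf in leaf_ids) {
    v <- df[[lf]]
    if (!is.numeric(v)) stop("leaf column '", lf, "' is not numeric")
    bad <- which(!is.na(v) & (v < axis[1] | v > axis[2]))
    if (length(bad))
      stop(sprintf("rating outside [%g, %g] in column '%s', row(s) %s",
                   axis[1], axis[2], lf, paste(bad, collapse = ", ")))
  }
  structure(df, leaf_ids = as.character(leaf_ids), axis = as.numeric(axis),
            class = c("response_table", "data.frame"))
}

#' Covariate column names of a response table
#' @param table A [response_table].
#' @return Character vector of `meta_`-prefixed columns.
#' @export
covariate_names <- function(table) {
  grep("^meta_", names(table), value = TRUE)
}

#' Read a respondent CSV
#'
#' Expects a `respondent_id` column, one column per leaf id of `tree` and
#' covariates prefixed `meta_`. Unknown columns are preserved as covariates
#' with a warning.
#'
#' @param path CSV path.
#' @param tree An [indicator_tree] whose leaves define the rating columns.
#' @param axis Declared rating range.
#' @return A [response_table].
#' @export
load_responses <- function(path, tree, axis = c(1, 5)) {
  stopifnot(inherits(tree, "indicator_tree"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- ifelse(grepl("^(respondent_id|meta_)", names(df)),
                      names(df), tolower(names(df)))
  leaves <- leaf_ids(tree)
  unknown <- setdiff(names(df), c("respondent_id", leaves))
  unknown <- unknown[!grepl("^meta_", unknown)]
  if (length(unknown))
    warning("unknown column(s) kept as covariates: ",
            paste(unknown, collapse = ", "))
  response_table(df, leaf_ids = leaves, axis = axis)
}

#' Validity rules for questionnaire records
#'
#' @param max_missing_fraction Largest tolerated fraction of missing leaf
#'   ratings per respondent (default 0: complete cases only).
#' @param straightline_max_run Longest allowed run of identical consecutive
#'   answers; a run longer than this flags straight-lining. Default disables
#'   the check (run may span all leaves).
#' @param require_consent If `TRUE`, rows need `meta_consent` equal to
#'   `"yes"`/`TRUE`/1.
#' @return Object of class `validity_rule`.
#' @export
validity_rule <- function(max_missing_fraction = 0,
                          straightline_max_run = Inf,
                          require_consent = FALSE) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]")
  if (straightline_max_run < 1) stop("straightline_max_run must be >= 1")
  structure(list(max_missing_fraction = max_missing_fraction,
                 straightline_max_run = straightline_max_run,
                 require_consent = isTRUE(require_consent)),
            class = "validity_rule")
}

.max_run <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(length(v))
  max(rle(v)$lengths)
}

#' Filter invalid questionnaire records
#'
#' Partitions a response table into valid and excluded rows; every excluded
#' row carries a reason code (`missing`, `straightline`, `no_consent`).
#'
#' @param table A [response_table].
#' @param rule A [validity_rule].
#' @return List with `valid` (a [response_table]), `excluded_count`, and
#'   `reasons`, a data frame of excluded `respondent_id`s and their codes.
#'   An empty valid set is allowed but raised as a warning.
#' @export
filter_valid <- function(table, rule = validity_rule()) {
  stopifnot(inherits(table, "response_table"), inherits(rule, "validity_rule"))
  leaves <- attr(table, "leaf_ids")
  x <- as.data.frame(table)[, leaves, drop = FALSE]
  reasons <- character(nrow(table))
  miss_frac <- rowMeans(is.na(x))
  reasons[miss_frac > rule$max_missing_fraction] <- "missing"
  if (is.finite(rule$straightline_max_run)) {
    runs <- apply(x, 1L, .max_run)
    reasons[reasons == "" & runs > rule$straightline_max_run] <- "straightline"
  }
  if (rule$require_consent) {
    consent <- table[["meta_consent"]]
    if (is.null(consent)) stop("rule requires consent but 'meta_consent' is absent")
    ok <- consent %in% c("yes", "TRUE", TRUE, 1)
    reasons[reasons == "" & !ok] <- "no_consent"
  }
  excl <- reasons != ""
  if (all(excl)) warning("no valid records remain after filtering")
  valid_df <- as.data.frame(table)[!excl, , drop = FALSE]
  rownames(valid_df) <- NULL
  list(valid = response_table(valid_df, leaf_ids = leaves,
                              axis = attr(table, "axis")),
       excluded_count = sum(excl),
       reasons = data.frame(respondent_id = table$respondent_id[excl],
                            reason = reasons[excl], row.names = NULL))
}

#' Questionnaire recovery rate
#'
#' `100 * valid / distributed`, rounded half-up to one decimal — e.g. 417
#' questionnaires distributed and 347 effectively recovered give 83.2.
#'
#' @param distributed Number of questionnaires distributed (> 0).
#' @param valid Number effectively recovered (0 <= valid <= distributed).
#' @return Percentage with one decimal.
#' @export
recovery_rate <- function(distributed, valid) {
  if (!(distributed > 0)) stop("distributed must be > 0")
  if (valid < 0 || valid > distributed)
    stop("valid must lie between 0 and distributed")
  floor(1000 * valid / distributed + 0.5) / 10
}
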