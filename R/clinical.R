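#' Score the AASE temptation items
#'
#' The 20 temptation ratings of the Alcohol Abstinence Self-Efficacy scale
#' yield a total score and two 5-item craving subscores with fixed, disjoint,
#' 1-based item sets: reward craving = items 4, 8, 15, 17, 20; relief craving
#' = items 3, 6, 12, 16, 18.
#'
#' @param items Numeric vector of exactly 20 item ratings.
#' @param scale Legal per-item range (default `c(1, 5)`).
#' @return List with `items`, `total`, `reward_craving`, `relief_craving`.
#' @export
#' @examples
#' aase_scores(1:20)$reward_craving  # 4 + 8 + 15 + 17 + 20 = 64
aase_scores <- function(items, scale = c(1, 5)) {
  if (length(items) != 20L) stop_("exactly 20 AASE items are required")
  items <- as.numeric(items)
  if (anyNA(items) || any(items < scale[1] | items > scale[2]))
    stop_("item ratings must lie in [", scale[1], ", ", scale[2], "]")
  list(items = items,
       total = sum(items),
       reward_craving = sum(items[c(4L, 8L, 15L, 17L, 20L)]),
       relief_craving = sum(items[c(3L, 6L, 12L, 16L, 18L)]))
}

#' AASE scores for every subject of a cohort
#'
#' @param cohort A `cohort_table` with columns `AASE_item_1..20`.
#' @param scale Legal per-item range (default `c(1, 5)`).
#' @return Data frame with `subject_id`, `aase_total`, `reward_craving`,
#'   `relief_craving`.
#' @export
cohort_aase <- function(cohort, scale = c(1, 5)) {
  cols <- paste0("AASE_item_", 1:20)
  if (!all(cols %in% names(cohort))) stop_("cohort lacks AASE item columns")
  m <- as.matrix(cohort[, cols])
  sc <- t(apply(m, 1L, function(v) {
    s <- aase_scores(v, scale)
    c(s$total, s$reward_craving, s$relief_craving)
  }))
  data.frame(subject_id = cohort$subject_id, aase_total = sc[, 1L],
             reward_craving = sc[, 2L], relief_craving = sc[, 3L],
             stringsAsFactors = FALSE)
}

#' Correlate a region's DVR with a clinical variable
#'
#' Pearson, or Spearman computed as Pearson on mid-ranks (ties averaged) with
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` for the p-value.
#' For Spearman with n <= 10 and no ties, `exact = TRUE` switches to the
#' exact null distribution. The derived variables `aase_total`,
#' `reward_craving` and `relief_craving` are computed from the AASE item
#' columns on the fly.
#'
#' @param cohort A `cohort_table`.
#' @param region Region label.
#' @param variable Clinical column name or one of `"aase_total"`,
#'   `"reward_craving"`, `"relief_craving"`.
#' @param method `"pearson"` or `"spearman"`.
#' @param group Optional group restriction (`"patient"` or `"control"`).
#' @param exact Use the exact Spearman null distribution when n <= 10
#'   (default `FALSE`).
#' @return List with `estimate`, `p`, `n`, `method`.
#' @export
correlate_region_clinical <- function(cohort, region, variable,
                                      method = c("pearson", "spearman"),
                                      group = NULL, exact = FALSE) {
  method <- match.arg(method)
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  if (!region %in% names(cohort)) stop_("unknown region: ", region)
  x <- cohort[[region]]
  y <- if (variable %in% c("aase_total", "reward_craving", "relief_craving"))
    cohort_aase(cohort)[[variable]] else cohort[[variable]]
  if (is.null(y)) stop_("unknown clinical variable: ", variable)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("constant variable; correlation undefined")
  if (method == "spearman") {
    if (exact && n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)) {
      ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
      return(list(estimate = unname(ct$estimate), p = ct$p.value, n = n,
                  method = "spearman (exact)"))
    }
    x <- rank(x); y <- rank(y)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(estimate = r, p = p, n = n, method = method)
}

#' Imipramine dose equivalents
#'
#' Standardises a subject's antidepressant regimen to a single imipramine-
#' equivalent dose: the sum of `daily dose x conversion factor` over all
#' drugs. Subjects taking no antidepressants score 0. Factors come from a
#' user-editable conversion table (`drug`, `factor_mg_per_mg`); the shipped
#' default (see [default_conversion_table()]) holds a small set of
#' approximate literature-based factors and should be replaced when exact
#' local conventions matter.
#'
#' @param meds Data frame with columns `drug` and `dose` (mg/day); may have
#'   zero rows.
#' @param table Conversion table (`drug`, `factor_mg_per_mg`); default
#'   [default_conversion_table()].
#' @return Total imipramine-equivalent dose in mg.
#' @export
#' @examples
#' imipramine_equivalent(data.frame(drug = c("a", "b"), dose = c(50, 30)),
#'                       table = data.frame(drug = c("a", "b"),
#'                                          factor_mg_per_mg = c(2, 1.5)))
imipramine_equivalent <- function(meds, table = default_conversion_table()) {
  if (is.null(meds) || nrow(meds) == 0L) return(0)
  if (!all(c("drug", "dose") %in% names(meds)))
    stop_("meds needs columns 'drug' and 'dose'")
  if (any(meds$dose < 0)) stop_("doses must be >= 0")
  idx <- match(meds$drug, table$drug)
  if (anyNA(idx))
    stop_("unknown drug(s) in conversion table: ",
          paste(unique(meds$drug[is.na(idx)]), collapse = ", "))
  sum(meds$dose * table$factor_mg_per_mg[idx])
}

#' Default antidepressant conversion table
#'
#' Reads the editable CSV shipped with the package
#' (`extdata/imipramine_factors.csv`): approximate mg-to-mg factors relative
#' to imipramine for a handful of common antidepressants, intended as a
#' starting point only.
#'
#' @return Data frame with `drug`, `factor_mg_per_mg`.
#' @export
default_conversion_table <- function() {
  path <- system.file("extdata", "imipramine_factors.csv",
                      package = "petcovnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Welch comparison of a target variable across a within-cohort split
#'
#' Splits the cohort (optionally one group of it) by a boolean variable, e.g.
#' antidepressant use or relapse, and runs [welch_test()] on a target
#' variable such as a regional DVR or `imipramine_eq`. Accommodates small
#' subgroups (each n >= 2).
#'
#' @param cohort A `cohort_table`.
#' @param grouping Name of a logical column (rows with `NA` are dropped).
#' @param target Name of the numeric target column.
#' @param group Optional group restriction (`"patient"` or `"control"`).
#' @param tail Passed to [welch_test()]; the first sample is
#'   `grouping == TRUE`.
#' @return A `welch_result`.
#' @export
subgroup_welch <- function(cohort, grouping, target, group = NULL,
                           tail = "two_sided") {
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  g <- cohort[[grouping]]
  y <- cohort[[target]]
  if (is.null(g) || is.null(y)) stop_("unknown grouping or target column")
  ok <- !is.na(g) & !is.na(y)
  welch_test(y[ok & g], y[ok & !g], tail = tail)
}
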