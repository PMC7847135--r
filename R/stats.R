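#' Nonparametric descriptive statistics
#'
#' Median, quartiles and range, matching the descriptive protocol used for
#' skewed morphometric variables. Quartiles use linear interpolation
#' (quantile type 7). Missing values are dropped (count reported).
#'
#' @param values numeric vector.
#' @return list: median, q1, q3, min, max, n, n_missing.
#' @export
descriptives <- function(values) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(v), max = max(v),
       n = length(v), n_missing = n_missing)
}

#' Kruskal-Wallis comparison
#'
#' Rank-based k-sample test with tie correction; p-value from the chi-square
#' upper tail with k - 1 degrees of freedom (the standard large-sample
#' reference). When all pooled values are identical the statistic is defined
#' as 0.
#'
#' @param groups list of numeric vectors (one per group), each non-empty
#'   after removing missing values.
#' @param feature optional feature name carried into the result.
#' @return list: H (tie-corrected), df, p, group_ns, feature.
#' @export
kruskal_wallis <- function(groups, feature = NA_character_) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(x) < 3L) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1,
                group_ns = vapply(groups, length, integer(1)),
                feature = feature))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, group_ns = vapply(groups, length, integer(1)),
       feature = feature)
}

#' Group comparisons for every feature
#'
#' Runs [descriptives()] per group and [kruskal_wallis()] across groups for
#' every numeric feature of a feature table. No multiple-testing correction
#' is applied by default (per-feature raw tests); set `p_adjust = "holm"` to
#' add adjusted p-values.
#'
#' @param features data.frame from [build_feature_table()].
#' @param group_col name of the group label column.
#' @param columns feature columns to test; defaults to [feature_columns()].
#' @param p_adjust "none" (default) or a method for [stats::p.adjust()].
#' @return list with `descriptives` and `tests` data.frames.
#' @export
compare_groups <- function(features, group_col = "group",
                           columns = intersect(feature_columns(),
                                               names(features)),
                           p_adjust = "none") {
  g <- features[[group_col]]
  if (is.null(g)) stop("group column '", group_col, "' not found")
  desc <- do.call(rbind, lapply(columns, function(col) {
    sp <- split(features[[col]], g)
    do.call(rbind, lapply(names(sp), function(gn) {
      v <- sp[[gn]]
      if (all(is.na(v))) return(NULL)
      d <- descriptives(v)
      data.frame(feature = col, group = gn,
                 median = d$median, q1 = d$q1, q3 = d$q3,
                 min = d$min, max = d$max, n = d$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(columns, function(col) {
    kw <- kruskal_wallis(split(features[[col]], g), feature = col)
    data.frame(feature = col, H = kw$H, df = kw$df, p = kw$p,
               n = sum(kw$group_ns), stringsAsFactors = FALSE)
  }))
  if (p_adjust != "none") tests$p_adj <- stats::p.adjust(tests$p, p_adjust)
  list(descriptives = desc, tests = tests)
}
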