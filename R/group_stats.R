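#' Ryan-adjusted significance level
#'
#' Step-down per-comparison alpha for pairwise contrasts among `k` ordered
#' conditions: a pair spanning `m` conditions is tested at
#' `alpha' = 2 * alpha / (k * (m - 1))`.
#'
#' @param alpha nominal familywise level.
#' @param k_conditions number of conditions compared.
#' @param span_m span of the pair in the ordered conditions
#'   (`2 <= span_m <= k_conditions`; adjacent conditions span 2).
#' @return adjusted per-comparison alpha.
#' @export
ryan_adjusted_alpha <- function(alpha, k_conditions, span_m) {
  stopifnot(alpha > 0, alpha < 1, k_conditions >= 2,
            span_m >= 2, span_m <= k_conditions)
  2 * alpha / (k_conditions * (span_m - 1))
}

#' Effect-size class for Pearson's R
#'
#' Bins an effect size into the conventional classes: null
#' (`0 <= R < 0.1`), small (`0.1 <= R < 0.3`), medium (`0.3 <= R < 0.5`),
#' large (`0.5 <= R <= 1`).
#'
#' @param R effect size in `[0, 1]`.
#' @return character class (vectorised).
#' @export
effect_size_class <- function(R) {
  if (any(!is.na(R) & (R < 0 | R > 1))) stop("R must lie in [0, 1]")
  as.character(cut(R, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
                   labels = c("null", "small", "medium", "large"),
                   right = FALSE))
}

# Pearson's R effect size from a standard-normal statistic
effect_r <- function(z, n) min(1, abs(z) / sqrt(n))

comparison_row <- function(feature, test, statistic, df, p, alpha_adj, R,
                           note = "") {
  data.frame(
    feature = feature, test = test, statistic = statistic, df = df,
    p_value = p, adjusted_alpha = alpha_adj,
    significant = !is.na(p) & p < alpha_adj,
    effect_R = R,
    effect_class = ifelse(is.na(R), NA_character_, effect_size_class(R)),
    note = note, stringsAsFactors = FALSE
  )
}

# Mann-Whitney with a normal-approximation Z for the effect size
mw_pair <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  n1 <- length(x)
  n2 <- length(y)
  z <- (wt$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       R = effect_r(z, n1 + n2))
}

# paired sign test on differences; ties dropped
sign_pair <- function(diffs) {
  d <- diffs[diffs != 0 & !is.na(diffs)]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p = NA_real_, R = NA_real_, n = 0L))
  }
  np <- sum(d > 0)
  p <- stats::binom.test(np, n, 0.5)$p.value
  z <- (2 * np - n) / sqrt(n)
  list(statistic = np, p = p, R = effect_r(z, n), n = n)
}

#' Between-group comparison of a feature, per day
#'
#' Kruskal-Wallis omnibus test of a per-trial (or per-subject-day) feature
#' between groups within each day, followed, when significant, by pairwise
#' Mann-Whitney tests at the Ryan-adjusted level.  Rows with missing
#' feature values (e.g. undefined network features from degenerate
#' networks) are excluded pairwise and counted.
#'
#' @param table data.frame with the feature, a group column and a day
#'   column.
#' @param feature name of the numeric feature column.
#' @param group_col,day_col column names (defaults `"entry"`, `"day"`).
#' @param alpha familywise significance level.
#' @return list with `omnibus` (one row per day) and `pairwise`
#'   (follow-up rows; empty when no omnibus test is significant).
#' @export
between_group_per_day <- function(table, feature, group_col = "entry",
                                  day_col = "day", alpha = 0.05) {
  stopifnot(all(c(feature, group_col, day_col) %in% names(table)))
  omnibus <- list()
  pairwise <- list()
  for (d in sort(unique(table[[day_col]]))) {
    sub <- table[table[[day_col]] == d & !is.na(table[[feature]]), ]
    groups <- split(sub[[feature]], sub[[group_col]], drop = TRUE)
    n_excl <- sum(table[[day_col]] == d & is.na(table[[feature]]))
    if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2)) {
      omnibus[[length(omnibus) + 1L]] <- cbind(
        comparison_row(feature, "kruskal-wallis", NA_real_, NA_real_,
                       NA_real_, alpha, NA_real_,
                       note = "insufficient data"),
        data.frame(day = d, n_excluded = n_excl)
      )
      next
    }
    kw <- stats::kruskal.test(groups)
    row <- cbind(
      comparison_row(feature, "kruskal-wallis", unname(kw$statistic),
                     unname(kw$parameter), kw$p.value, alpha, NA_real_),
      data.frame(day = d, n_excluded = n_excl)
    )
    omnibus[[length(omnibus) + 1L]] <- row
    if (!is.na(kw$p.value) && kw$p.value < alpha) {
      med <- vapply(groups, stats::median, numeric(1))
      rank_order <- rank(-med, ties.method = "first")
      gn <- names(groups)
      k <- length(gn)
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          span <- abs(rank_order[a] - rank_order[b]) + 1
          a_adj <- ryan_adjusted_alpha(alpha, k, max(2, span))
          mw <- mw_pair(groups[[a]], groups[[b]])
          pairwise[[length(pairwise) + 1L]] <- cbind(
            comparison_row(feature, "mann-whitney", mw$statistic, NA_real_,
                           mw$p, a_adj, mw$R),
            data.frame(day = d, pair = paste(gn[a], gn[b], sep = " vs "))
          )
        }
      }
    }
  }
  list(
    omnibus = do.call(rbind, omnibus),
    pairwise = if (length(pairwise) > 0) do.call(rbind, pairwise) else NULL
  )
}

#' Within-group comparison of a feature across days
#'
#' Friedman test over complete subject-by-day blocks (subjects missing any
#' day are dropped and reported), followed, when significant, by pairwise
#' sign tests between days at the Ryan-adjusted level.
#'
#' @param table data.frame with the feature, a subject column and a day
#'   column (one value per subject-day; average trials first, e.g. with
#'   [daily_average()]).
#' @param feature name of the numeric feature column.
#' @param subject_col,day_col column names.
#' @param alpha familywise significance level.
#' @return list with `omnibus` (one row), `pairwise` (day-pair rows or
#'   `NULL`) and `n_subjects_dropped`.
#' @export
within_group_across_days <- function(table, feature,
                                     subject_col = "subject_id",
                                     day_col = "day", alpha = 0.05) {
  stopifnot(all(c(feature, subject_col, day_col) %in% names(table)))
  days <- sort(unique(table[[day_col]]))
  if (length(days) < 2) stop("need at least 2 days")
  wide <- stats::reshape(
    table[c(subject_col, day_col, feature)],
    direction = "wide", idvar = subject_col, timevar = day_col
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(mat)
  dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 complete subjects")
  fr <- stats::friedman.test(mat)
  omnibus <- comparison_row(feature, "friedman", unname(fr$statistic),
                            unname(fr$parameter), fr$p.value, alpha,
                            NA_real_)
  pairwise <- NULL
  if (!is.na(fr$p.value) && fr$p.value < alpha) {
    med <- apply(mat, 2, stats::median)
    rank_order <- rank(-med, ties.method = "first")
    k <- ncol(mat)
    rows <- list()
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        span <- abs(rank_order[a] - rank_order[b]) + 1
        a_adj <- ryan_adjusted_alpha(alpha, k, max(2, span))
        st <- sign_pair(mat[, a] - mat[, b])
        rows[[length(rows) + 1L]] <- cbind(
          comparison_row(feature, "sign", st$statistic, NA_real_, st$p,
                         a_adj, st$R),
          data.frame(pair = paste("day", days[a], "vs day", days[b]))
        )
      }
    }
    pairwise <- do.call(rbind, rows)
  }
  list(omnibus = omnibus, pairwise = pairwise,
       n_subjects_dropped = dropped)
}
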