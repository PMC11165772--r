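# Cohort statistics: normality screening, sex comparisons, anterior-vs-
# posterior aspect-ratio contrasts, left-right symmetry, and post-hoc power.
#
# The unit of analysis is the sinus (side), matching a design in which both
# sides of every subject enter the comparison; subject-level aggregation is
# available behind a flag. Tests are two-sided at alpha = 0.05 with no
# multiple-testing correction by default (a Holm option is provided).

interior_fractions <- seq(10, 90, by = 10)

# one value per sinus for a parameter at a fraction (or length)
param_values <- function(table, parameter, fraction = NULL) {
  check_profile_schema(table)
  if (parameter == "length") {
    u <- unique(table[c("subject", "side", "sex", "length_mm")])
    data.frame(sex = u$sex, subject = u$subject, side = u$side,
               value = u$length_mm)
  } else {
    col <- switch(parameter, W = "W_mm", H = "H_mm", AR = "AR",
                  stop("unknown parameter '", parameter, "'"))
    sel <- table$fraction == fraction
    data.frame(sex = table$sex[sel], subject = table$subject[sel],
               side = table$side[sel], value = table[[col]][sel])
  }
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of each group against a normal with the group's
#' sample mean and SD (parameters estimated from the data, uncorrected, as
#' in common SPSS usage; set `lilliefors = TRUE` for a Monte-Carlo
#' corrected p-value).
#'
#' @param values numeric vector.
#' @param group optional grouping factor (one test per group).
#' @param lilliefors use a Monte-Carlo Lilliefors correction.
#' @param B Monte-Carlo replicates for the correction.
#' @return data.frame: `group`, `n`, `mean`, `sd`, `D`, `p`, `normal`
#'   (flagging `p > 0.05`).
#' @export
check_normality <- function(values, group = NULL, lilliefors = FALSE, B = 2000) {
  if (is.null(group)) group <- rep("all", length(values))
  out <- lapply(split(values, group), function(x) {
    n <- length(x)
    if (n < 5) stop("need n >= 5 per group for the normality screen")
    if (stats::sd(x) == 0) stop("zero variance group in normality screen")
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    p <- ks$p.value
    if (lilliefors) {
      d0 <- ks$statistic
      dsim <- replicate(B, {
        z <- stats::rnorm(n)
        suppressWarnings(stats::ks.test(z, "pnorm", mean(z), stats::sd(z))$statistic)
      })
      p <- mean(dsim >= d0)
    }
    data.frame(n = n, mean = mean(x), sd = stats::sd(x),
               D = unname(ks$statistic), p = p, normal = p > 0.05)
  })
  cbind(data.frame(group = names(out)), do.call(rbind, out), row.names = NULL)
}

two_sample_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  if (var_equal) {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      d <- mean(x) - mean(y)
      return(list(t = if (d == 0) 0 else sign(d) * Inf,
                  df = n1 + n2 - 2, p = if (d == 0) 1 else 0))
    }
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
    tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Sex comparison of a morphometric parameter
#'
#' Independent two-sample t-test (pooled variance by default; Welch behind
#' a flag) of male vs female values, per fraction for sectional parameters.
#'
#' @param table a long cohort table (see [profiles_to_table]).
#' @param parameter one of `"length"`, `"W"`, `"H"`, `"AR"`.
#' @param fractions fractions to test for sectional parameters; defaults to
#'   the interior sections present in the table (endpoints excluded).
#' @param var_equal pooled-variance (Student) t if `TRUE`, Welch otherwise.
#' @param holm apply a Holm correction across the returned rows.
#' @param subject_level average both sides within subject before testing.
#' @return data.frame of class `stat_report`: one row per fraction (or a
#'   single row for length) with group summaries, `t`, `df`, `p`,
#'   `significant`. Degenerate groups (n < 2) yield `NA` entries.
#' @export
compare_sexes <- function(table, parameter, fractions = NULL,
                          var_equal = TRUE, holm = FALSE,
                          subject_level = FALSE) {
  check_profile_schema(table)
  if (!all(c("male", "female") %in% table$sex))
    stop("both sexes must be present in the cohort table")
  if (is.null(fractions))
    fractions <- setdiff(sort(unique(table$fraction)), c(0, 100))
  fr_list <- if (parameter == "length") list(NULL) else as.list(fractions)
  rows <- lapply(fr_list, function(fr) {
    v <- param_values(table, parameter, fr)
    if (subject_level)
      v <- do.call(rbind, lapply(split(v, list(v$subject, v$sex), drop = TRUE),
                                 function(g) data.frame(sex = g$sex[1],
                                                        value = mean(g$value))))
    x <- v$value[v$sex == "male"]; y <- v$value[v$sex == "female"]
    tt <- two_sample_t(x, y, var_equal)
    data.frame(parameter = parameter,
               fraction = if (is.null(fr)) NA_real_ else fr,
               n_male = length(x), mean_male = mean(x), sd_male = stats::sd(x),
               n_female = length(y), mean_female = mean(y),
               sd_female = stats::sd(y),
               test = if (var_equal) "pooled t" else "Welch t",
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p <- stats::p.adjust(out$p, "holm")
  out$significant <- !is.na(out$p) & out$p < 0.05
  if (any(is.na(out$p)))
    warning("degenerate group sizes: some comparisons reported as NA")
  class(out) <- c("stat_report", "data.frame")
  out
}

#' Anterior vs posterior aspect-ratio contrast
#'
#' Paired t-tests of the mirrored fraction pairs (10 vs 90, 20 vs 80,
#' 30 vs 70, 40 vs 60) across sinuses, plus the anterior (10-40%) and
#' posterior (60-90%) mean AR and their percent difference
#' `(1 - anterior/posterior) * 100`. The 50% section is the divide and
#' belongs to neither mean (the labels "AR_10-AR_50" / "AR_50-AR_90" overlap
#' at the midpoint; the mirrored-pair structure excludes it).
#'
#' @param table a long cohort table with complete AR profiles.
#' @param sex optionally restrict to one sex.
#' @return list: `pairs` (data.frame anterior/posterior fraction, mean
#'   difference, `t`, `df`, `p`, `significant`), `anterior_mean`,
#'   `posterior_mean`, `percent_difference`.
#' @export
ap_contrast <- function(table, sex = NULL) {
  check_profile_schema(table)
  if (!is.null(sex)) table <- table[table$sex == sex, ]
  need <- interior_fractions
  have <- sort(unique(table$fraction))
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing AR fractions: ", paste(missing, collapse = ", "))
  key <- paste(table$subject, table$side)
  wide <- stats::reshape(
    data.frame(key = key, fraction = table$fraction, AR = table$AR),
    idvar = "key", timevar = "fraction", direction = "wide")
  arcol <- function(f) wide[[paste0("AR.", f)]]
  if (anyNA(wide[paste0("AR.", need)]))
    stop("incomplete AR profiles: some sinuses lack interior fractions")
  pairs <- do.call(rbind, lapply(list(c(10, 90), c(20, 80), c(30, 70), c(40, 60)),
    function(pr) {
      d <- arcol(pr[1]) - arcol(pr[2])
      n <- length(d)
      if (n < 2) stop("need at least two complete profiles for paired contrasts")
      tt <- if (stats::sd(d) == 0) {
        list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
             p = if (mean(d) == 0) 1 else 0)
      } else {
        t0 <- mean(d) / (stats::sd(d) / sqrt(n))
        list(t = t0, p = 2 * stats::pt(-abs(t0), n - 1))
      }
      data.frame(anterior = pr[1], posterior = pr[2], mean_diff = mean(d),
                 t = tt$t, df = n - 1, p = tt$p, significant = tt$p < 0.05)
    }))
  ant <- mean(unlist(lapply(c(10, 20, 30, 40), arcol)))
  post <- mean(unlist(lapply(c(60, 70, 80, 90), arcol)))
  list(pairs = pairs, anterior_mean = ant, posterior_mean = post,
       percent_difference = (1 - ant / post) * 100)
}

#' Left-right symmetry contrast
#'
#' Paired t-test of per-subject mean AR (over interior fractions), left vs
#' right. Subjects lacking either side are dropped.
#'
#' @param table a long cohort table.
#' @return list: `n_pairs`, `mean_left`, `mean_right`, `mean_diff`, `t`,
#'   `df`, `p`, `significant`.
#' @export
symmetry_contrast <- function(table) {
  check_profile_schema(table)
  sel <- table$fraction %in% interior_fractions
  agg <- stats::aggregate(AR ~ subject + side, data = table[sel, ], FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "side",
                         direction = "wide")
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2)
    stop("need at least two subjects with both sides for the symmetry contrast")
  d <- wide$AR.left - wide$AR.right
  n <- length(d)
  if (stats::sd(d) == 0) {
    t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t0 <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(t0), n - 1)
  }
  list(n_pairs = n, mean_left = mean(wide$AR.left),
       mean_right = mean(wide$AR.right), mean_diff = mean(d),
       t = t0, df = n - 1, p = p, significant = p < 0.05)
}

#' Post-hoc power of a two-sample t-test
#'
#' Exact two-sided power via the noncentral t distribution, for the
#' realized group means, pooled SD and sample sizes.
#'
#' @param mean1,mean2 group means.
#' @param sd_pooled pooled SD (> 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level in (0, 1).
#' @return power in \[0, 1\].
#' @export
posthoc_power <- function(mean1, mean2, sd_pooled, n1, n2, alpha = 0.05) {
  stopifnot_scalar(sd_pooled, "sd_pooled", positive = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  d <- (mean1 - mean2) / sd_pooled
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Table-1-style summary of the cohort
#'
#' Sex summaries and p-values for length and every sectional parameter,
#' mirroring the layout `parameter, M mean+/-SD, F mean+/-SD, p`.
#'
#' @param table a long cohort table.
#' @param ... passed to [compare_sexes].
#' @return a `stat_report` data.frame over all parameters.
#' @export
cohort_report <- function(table, ...) {
  out <- rbind(compare_sexes(table, "length", ...),
               compare_sexes(table, "W", ...),
               compare_sexes(table, "H", ...),
               compare_sexes(table, "AR", ...))
  class(out) <- c("stat_report", "data.frame")
  out
}
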