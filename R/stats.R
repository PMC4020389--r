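#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS statistic of the sample against a normal distribution with mean and SD
#' estimated from the sample; because the parameters are estimated, the
#' classical KS null is wrong and the p value is taken from a seeded
#' Monte-Carlo simulation of the Lilliefors null (default 10^4 replicates,
#' cached per sample size within a session). Following the convention of
#' statistical packages, p values above 0.2 are reported as the lower bound
#' `p >= 0.200` via the `p_censored` flag.
#'
#' @param x numeric sample, `n >= 4`.
#' @param n_sim Monte-Carlo replicates for the null distribution.
#' @param seed seed for the null simulation (cached per `(n, n_sim, seed)`).
#' @return a one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `p_censored`, `n`.
#' @export
lilliefors_ks <- function(x, n_sim = 10000, seed = 771) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined", call. = FALSE)
  D <- lilliefors_statistic(x)
  null <- lilliefors_null(n, n_sim, seed)
  p <- (sum(null >= D) + 1) / (length(null) + 1)
  censored <- p > 0.2
  tibble::tibble(test = "lilliefors_ks", statistic = D, df = n,
                 p_value = if (censored) 0.2 else p,
                 p_censored = censored, n = n)
}

# max |ECDF - Phi((x - xbar)/s)| over both one-sided deviations
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

# memoized Monte-Carlo null of the Lilliefors statistic
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, n_sim, seed) {
  key <- paste(n, n_sim, seed, sep = "_")
  if (!is.null(.lilliefors_cache[[key]])) return(.lilliefors_cache[[key]])
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed + n)
  null <- vapply(seq_len(n_sim),
                 function(i) lilliefors_statistic(stats::rnorm(n)),
                 numeric(1))
  .lilliefors_cache[[key]] <- null
  null
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W statistic and p value, in the same tibble shape
#' as the other tests of the battery.
#'
#' @param x numeric sample, `3 <= n <= 5000`.
#' @return a one-row tibble: `test`, `statistic`, `df`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined", call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(test = "shapiro_wilk", statistic = unname(sw$statistic),
                 df = length(x), p_value = sw$p.value, p_censored = FALSE,
                 n = length(x))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Ties receive midranks.
#' When `n * m <= exact_limit` the two-sided p value is computed by exact
#' enumeration of all group assignments of the pooled sample (valid under
#' ties); otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit use exact enumeration when `length(x) * length(y)` is
#'   at most this (default 64).
#' @return a one-row tibble: `test`, `statistic` (U for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, exact_limit = 64) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n * m <= exact_limit) {
    p <- mw_exact_p(pooled, n, U)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tie_term)
    mu <- n * m / 2
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(test = "mann_whitney", statistic = U, p_value = p,
                 method = method, n1 = n, n2 = m)
}

# exact two-sided p by enumeration of all C(n+m, n) group assignments
mw_exact_p <- function(pooled, n, U_obs) {
  r <- rank(pooled)
  N <- length(pooled)
  combs <- utils::combn(N, n)
  U_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
  mu <- n * (N - n) / 2
  # two-sided: assignments at least as extreme (in |U - mu|) as observed
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

#' Paired comparison via one-sample t on differences
#'
#' One-sample Student's t of `second - first` against zero; algebraically
#' identical to the two-sample paired t-test.
#'
#' @param first,second numeric vectors of equal length (`n >= 2`).
#' @return a one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `mean_difference`, `n`.
#' @export
paired_t <- function(first, second) {
  if (length(first) != length(second))
    stop("paired samples must have equal length", call. = FALSE)
  d <- second - first
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 paired differences", call. = FALSE)
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  tt <- stats::t.test(d, mu = 0)
  tibble::tibble(test = "paired_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_difference = mean(d), n = length(d))
}

#' Group comparison of the TDCH variables
#'
#' The full battery applied to a cohort table: per variable, Lilliefors and
#' Shapiro-Wilk normality tests per group, then (when routing is enabled) a
#' Mann-Whitney U test if any group departs from normality at the 5% level,
#' otherwise a Welch two-sample t-test. Summaries follow the reporting
#' convention of each route: median (IQR) for the nonparametric route,
#' mean (SD) for the parametric one. A variable that is constant within both
#' groups is reported as a test error without affecting the others. No
#' multiple-testing correction is applied by default (`p_adjust = "none"`).
#'
#' @param cohort data frame with a `group` column (exactly two levels) and
#'   the variable columns.
#' @param variables character vector of variable columns (default V1..V7).
#' @param route_by_normality route to Mann-Whitney vs t by the normality
#'   tests (default `TRUE`); `FALSE` forces Mann-Whitney.
#' @param alpha significance level used only for the routing decision.
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @param n_sim_lilliefors Monte-Carlo replicates for the Lilliefors null.
#' @return a `group_comparison`: tibble with one row per variable (test
#'   used, statistic, p, per-group summaries) and the normality block as
#'   attribute `normality`.
#' @export
group_compare <- function(cohort, variables = paste0("V", 1:7),
                          route_by_normality = TRUE, alpha = 0.05,
                          p_adjust = "none", n_sim_lilliefors = 10000) {
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column", call. = FALSE)
  groups <- sort(unique(as.character(cohort$group)))
  if (length(groups) != 2)
    stop("exactly two groups are required, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars))
    stop("variables not in cohort: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  normality <- list()
  rows <- purrr::map(variables, function(v) {
    x <- cohort[[v]][cohort$group == groups[1]]
    y <- cohort[[v]][cohort$group == groups[2]]
    norm_v <- purrr::map2_dfr(list(x, y), groups, function(s, g) {
      res <- tryCatch(
        dplyr::bind_rows(
          lilliefors_ks(s, n_sim = n_sim_lilliefors),
          shapiro_wilk(s)
        ),
        error = function(e) tibble::tibble(
          test = c("lilliefors_ks", "shapiro_wilk"), statistic = NA_real_,
          df = length(s), p_value = NA_real_, p_censored = FALSE, n = length(s))
      )
      dplyr::mutate(res, variable = v, group = g, .before = 1)
    })
    normality[[v]] <<- norm_v
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble::tibble(
        variable = v, test = "error", statistic = NA_real_, p_value = NA_real_,
        note = "constant in both groups",
        summary_1 = summary_median_iqr(x), summary_2 = summary_median_iqr(y)))
    }
    all_normal <- route_by_normality &&
      all(norm_v$p_value > alpha, na.rm = TRUE) && !any(is.na(norm_v$p_value))
    if (all_normal) {
      tt <- stats::t.test(x, y)
      tibble::tibble(
        variable = v, test = "welch_t", statistic = unname(tt$statistic),
        p_value = tt$p.value, note = NA_character_,
        summary_1 = summary_mean_sd(x), summary_2 = summary_mean_sd(y))
    } else {
      mw <- mann_whitney(x, y)
      tibble::tibble(
        variable = v, test = "mann_whitney", statistic = mw$statistic,
        p_value = mw$p_value, note = NA_character_,
        summary_1 = summary_median_iqr(x), summary_2 = summary_median_iqr(y))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  names(out)[names(out) == "summary_1"] <- paste0(groups[1], " (n = ", sum(cohort$group == groups[1]), ")")
  names(out)[names(out) == "summary_2"] <- paste0(groups[2], " (n = ", sum(cohort$group == groups[2]), ")")
  structure(out, normality = dplyr::bind_rows(normality), groups = groups,
            class = c("group_comparison", class(out)))
}

summary_median_iqr <- function(x) {
  sprintf("%.3f (%.3f)", stats::median(x), stats::IQR(x))
}

summary_mean_sd <- function(x) {
  sprintf("%.3f (%.3f)", mean(x), stats::sd(x))
}

#' Paired comparison of the TDCH variables across two visits
#'
#' For each variable, a one-sample t on the within-subject difference
#' (second visit minus first). Rows are matched by `subject_id`.
#'
#' @param cohort data frame with `subject_id`, `visit` (`"first"`/`"second"`)
#'   and the variable columns.
#' @param variables character vector of variable columns.
#' @return a tibble with one row per variable (`statistic`, `p_value`,
#'   mean (SD) summaries per visit).
#' @export
paired_compare <- function(cohort, variables = paste0("V", 1:7)) {
  w <- cohort |>
    dplyr::select(dplyr::all_of(c("subject_id", "visit", variables))) |>
    tidyr::pivot_wider(names_from = "visit", values_from = dplyr::all_of(variables),
                       names_sep = "...")
  purrr::map_dfr(variables, function(v) {
    f <- w[[paste0(v, "...first")]]
    s <- w[[paste0(v, "...second")]]
    keep <- is.finite(f) & is.finite(s)
    res <- tryCatch(paired_t(f[keep], s[keep]), error = function(e)
      tibble::tibble(test = "error", statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, mean_difference = NA_real_,
                     n = sum(keep)))
    tibble::tibble(variable = v, statistic = res$statistic, df = res$df,
                   p_value = res$p_value, mean_difference = res$mean_difference,
                   first = summary_mean_sd(f[keep]),
                   second = summary_mean_sd(s[keep]), n = res$n)
  })
}

#' Plot a group comparison
#'
#' Boxplots of each variable by group with the comparison p value in the
#' strip label.
#'
#' @param object a `group_comparison`.
#' @param cohort the cohort the comparison was computed from.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, cohort, ...) {
  vars <- object$variable
  long <- cohort |>
    dplyr::select(dplyr::all_of(c("group", vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable")
  labs <- stats::setNames(
    sprintf("%s (p = %.3f)", object$variable, object$p_value), object$variable)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y",
                        labeller = ggplot2::labeller(variable = labs)) +
    ggplot2::labs(x = NULL, y = "proportion of tongue area") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
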