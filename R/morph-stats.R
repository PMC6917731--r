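#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees
#' of freedom and a 95% confidence interval for the mean difference
#' (x minus y), the statistic used for all morph-physiology
#' comparisons. Computed via [stats::t.test()]; the degenerate case of
#' two identical constant groups returns t = 0, p = 1 by convention.
#'
#' @param x,y numeric vectors, each with at least two finite values.
#' @param conf_level confidence level (default 0.95, matching every
#'   reported interval).
#' @return An object of class `welch_result`: `t`, `df`, `p`, `ci`,
#'   `mean_x`, `mean_y`, `n_x`, `n_y`, `var_x`, `var_y`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (sum(is.finite(x)) < 2L || sum(is.finite(y)) < 2L) {
    stop_("both groups need at least two finite observations")
  }
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (var(x) + var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(
        t = 0, df = length(x) + length(y) - 2L, p = 1, ci = c(0, 0),
        mean_x = mean(x), mean_y = mean(y),
        n_x = length(x), n_y = length(y), var_x = 0, var_y = 0,
        conf_level = conf_level
      )
      class(res) <- "welch_result"
      return(res)
    }
    stop_("zero variance in both groups with unequal means: t undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  res <- list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    ci = as.numeric(tt$conf.int),
    mean_x = mean(x), mean_y = mean(y),
    n_x = length(x), n_y = length(y),
    var_x = var(x), var_y = var(y),
    conf_level = conf_level
  )
  class(res) <- "welch_result"
  res
}

#' @export
print.welch_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Welch two-sample t-test: t(%.*g) = %.*g, p = %.*g\n%g%% CI of difference: [%.*g, %.*g]; means %.*g vs %.*g (n = %d, %d)\n",
    digits, x$df, digits, x$t, digits, x$p, 100 * x$conf_level,
    digits, x$ci[1], digits, x$ci[2], digits, x$mean_x, digits, x$mean_y,
    x$n_x, x$n_y
  ))
  invisible(x)
}

#' Reconstruct group samples from a reported Welch tuple
#'
#' Given group sizes, group means and a reported Welch t statistic and
#' Satterthwaite df, solves for the pair of group variances consistent
#' with them and returns deterministic moment-matched samples (via
#' [moment_matched_groups()]). Running [welch_t()] on the result
#' reproduces the full tuple (t, df, p, CI), so a published summary can
#' be round-tripped through the package's own computations. Fails when
#' no non-negative variance pair is compatible (an internally
#' inconsistent tuple, e.g. a df exceeding `n1 + n2 - 2`).
#'
#' @param n1,n2 group sizes.
#' @param mean1,mean2 group means.
#' @param t reported Welch t statistic (sign taken as group1 - group2).
#' @param df reported Welch-Satterthwaite degrees of freedom.
#' @return List with samples `x`, `y` and the solved standard
#'   deviations `sd1`, `sd2`.
#' @examples
#' g <- welch_groups_from_summary(5, 5, 32.2, 106.6, t = -10.78, df = 5.45)
#' welch_t(g$x, g$y)
#' @export
welch_groups_from_summary <- function(n1, n2, mean1, mean2, t, df) {
  stopifnot(n1 >= 2, n2 >= 2, is.finite(t), t != 0, df > 0)
  if (df > n1 + n2 - 2) {
    stop_("df = %g exceeds n1 + n2 - 2 = %d: tuple is internally inconsistent",
      df, n1 + n2 - 2L)
  }
  se2 <- ((mean1 - mean2) / t)^2 # u + v, with u = s1^2/n1, v = s2^2/n2
  # Welch-Satterthwaite: se2^2 / df = u^2/(n1-1) + v^2/(n2-1)
  c2 <- se2^2 / df
  # substitute v = se2 - u -> quadratic a u^2 + b u + c = 0
  a <- 1 / (n1 - 1) + 1 / (n2 - 1)
  b <- -2 * se2 / (n2 - 1)
  cc <- se2^2 / (n2 - 1) - c2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    stop_("no variance pair is compatible with this (t, df) tuple")
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  ok <- roots >= 0 & (se2 - roots) >= 0
  if (!any(ok)) stop_("no non-negative variance pair is compatible with this tuple")
  u <- min(roots[ok]) # deterministic choice between the two valid pairs
  v <- se2 - u
  sd1 <- sqrt(u * n1)
  sd2 <- sqrt(v * n2)
  list(
    x = moment_matched_groups(n1, mean1, sd1),
    y = moment_matched_groups(n2, mean2, sd2),
    sd1 = sd1, sd2 = sd2
  )
}

#' Quantify a lipid class against its standard
#'
#' `pmol_sample = (area_sample / area_standard) * pmol_standard`.
#'
#' @param area_sample integrated peak area of the sample (>= 0).
#' @param area_standard integrated peak area of the standard (> 0).
#' @param pmol_standard amount of the standard in pmol.
#' @return Amount of the sample in pmol.
#' @examples
#' quantify_class(200, 100, 100) # 200 pmol
#' @export
quantify_class <- function(area_sample, area_standard, pmol_standard) {
  stopifnot(all(area_sample >= 0), pmol_standard >= 0)
  if (any(area_standard <= 0)) stop_("standard peak area must be positive")
  area_sample / area_standard * pmol_standard
}

#' Total neutral lipid per individual
#'
#' Sums the quantified amounts of the four neutral lipid classes
#' (diacylglycerols, triacylglycerols, cholesterol, cholesterol esters)
#' from a lipid measurement table (see [simulate_lipid_table()]) and
#' converts pmol to nmol.
#'
#' @param lipids data frame with `area_*` class columns,
#'   `area_standard` and `pmol_standard`.
#' @return Numeric vector of total lipid in nmol per row.
#' @export
total_lipid <- function(lipids) {
  area_cols <- grep("^area_", names(lipids), value = TRUE)
  area_cols <- setdiff(area_cols, "area_standard")
  if (length(area_cols) == 0L) stop_("no area_* class columns found")
  pmol <- sapply(area_cols, function(cl) {
    quantify_class(lipids[[cl]], lipids$area_standard, lipids$pmol_standard)
  })
  if (is.null(dim(pmol))) pmol <- matrix(pmol, nrow = 1L)
  rowSums(pmol) / 1000
}

#' Mass-corrected trait values via standardized residuals
#'
#' Ordinary least squares of the trait on body mass; residuals divided
#' by the residual standard deviation give a size-corrected trait with
#' mean ~0 and SD ~1. `type = "internally_studentized"` uses
#' leverage-adjusted studentized residuals instead of the simple
#' standardization.
#'
#' @param trait numeric trait values (e.g. total lipid, nmol).
#' @param mass body (abdomen) mass, same length, not constant.
#' @param type `"simple"` (residual / residual SD, default) or
#'   `"internally_studentized"`.
#' @return Numeric vector of standardized residuals.
#' @examples
#' mass_correct(c(10, 12, 15, 13), c(50, 55, 62, 56))
#' @export
mass_correct <- function(trait, mass,
                         type = c("simple", "internally_studentized")) {
  type <- match.arg(type)
  stopifnot(length(trait) == length(mass))
  if (length(trait) < 3L) stop_("need at least 3 individuals")
  if (sd(mass) == 0) stop_("mass is constant; regression undefined")
  fit <- stats::lm(trait ~ mass)
  if (type == "internally_studentized") {
    return(as.numeric(stats::rstandard(fit)))
  }
  r <- stats::resid(fit)
  s <- sqrt(sum(r^2) / fit$df.residual)
  if (s <= 1e-10 * max(abs(trait), 1)) {
    # numerically perfect fit: residuals are all zero
    return(rep(0, length(r)))
  }
  as.numeric(r / s)
}

#' Average granule counts over counting squares
#'
#' The phenotype unit of the electron-microscopy comparisons: the
#' arithmetic mean of the pigment-granule counts of the (typically
#' three) 4 um^2 squares placed on one individual's scale image.
#' Counts must be non-negative integers.
#'
#' @param counts integer vector of per-square counts (length >= 1).
#' @return The mean count.
#' @examples
#' aggregate_squares(c(60, 70, 80))
#' @export
aggregate_squares <- function(counts) {
  if (length(counts) == 0L) stop_("no square counts supplied")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_("granule counts must be non-negative integers")
  }
  mean(counts)
}
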