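#' Simulate per-square pigment-granule counts
#'
#' Emulates scanning-electron-microscopy granule counting: for each
#' individual, `squares_per_individual` randomly placed 4 um^2 squares
#' are counted, with counts negative-binomial around the individual's
#' group mean. Group means default to typical white (Alba) and orange
#' scale densities.
#'
#' @param group_means named numeric vector of expected counts per square,
#'   one entry per group.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson); `Inf` gives Poisson counts, `0` is rejected.
#' @param n_per_group individuals per group (>= 2).
#' @param squares_per_individual counting squares per individual.
#' @param seed integer seed or `NULL`.
#' @return Data frame with `group`, `individual`, `square`, `count`.
#' @examples
#' g <- simulate_morph_measurements(c(alba = 67, orange = 127), seed = 1)
#' aggregate(count ~ group, g, mean)
#' @export
simulate_morph_measurements <- function(group_means = c(alba = 66.9, orange = 126.9),
                                        dispersion = 30,
                                        n_per_group = 3L,
                                        squares_per_individual = 3L,
                                        seed = NULL) {
  stopifnot(
    length(group_means) >= 2, !is.null(names(group_means)),
    all(group_means > 0), dispersion > 0,
    n_per_group >= 2, squares_per_individual >= 1
  )
  with_seed(seed, {
    rows <- lapply(names(group_means), function(g) {
      mu <- group_means[[g]]
      n <- n_per_group * squares_per_individual
      counts <- if (is.infinite(dispersion)) {
        rpois(n, mu)
      } else {
        rnbinom(n, size = dispersion, mu = mu)
      }
      data.frame(
        group = g,
        individual = sprintf("%s_%d", g, rep(seq_len(n_per_group),
          each = squares_per_individual)),
        square = rep(seq_len(squares_per_individual), n_per_group),
        count = counts,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate an abdominal-lipid measurement table
#'
#' Emulates the HPTLC quantification input: per individual, a total
#' neutral-lipid amount linear in abdomen mass plus a morph effect plus
#' Gaussian noise, split across the four neutral lipid classes
#' (diacylglycerols, triacylglycerols, cholesterol, cholesterol esters)
#' and back-converted to peak areas against a known standard, so that
#' [quantify_class()] and summation recover the simulated totals.
#'
#' @param n_per_group individuals per morph (>= 2).
#' @param mass_mean,mass_sd abdomen mass distribution (mg).
#' @param intercept,slope total lipid (nmol) = `intercept + slope * mass`.
#' @param morph_effect additive lipid increase (nmol) in Alba females.
#' @param resid_sd residual SD of total lipid (nmol).
#' @param class_props expected proportions of the four lipid classes.
#' @param area_standard,pmol_standard peak area and amount of the
#'   quantification standard.
#' @param seed integer seed or `NULL`.
#' @return Data frame with `individual`, `morph`, `abdomen_mass_mg`,
#'   one `area_*` column per lipid class, `area_standard`,
#'   `pmol_standard`, and the latent `true_total_nmol`.
#' @export
simulate_lipid_table <- function(n_per_group = 16L, mass_mean = 60,
                                 mass_sd = 8, intercept = 5, slope = 0.5,
                                 morph_effect = 6, resid_sd = 3,
                                 class_props = c(
                                   dag = 0.1, tag = 0.6,
                                   chol = 0.2, ce = 0.1
                                 ),
                                 area_standard = 1000, pmol_standard = 500,
                                 seed = NULL) {
  stopifnot(
    n_per_group >= 2, mass_mean > 0, mass_sd >= 0, resid_sd >= 0,
    length(class_props) == 4, all(class_props > 0),
    area_standard > 0, pmol_standard > 0
  )
  class_props <- class_props / sum(class_props)
  with_seed(seed, {
    n <- 2L * n_per_group
    morph <- rep(c("alba", "orange"), each = n_per_group)
    mass <- pmax(1, rnorm(n, mass_mean, mass_sd))
    total_nmol <- pmax(
      0.1,
      intercept + slope * mass + morph_effect * (morph == "alba") +
        rnorm(n, 0, resid_sd)
    )
    # jitter the class split per individual, keep proportions positive
    props <- vapply(seq_len(n), function(i) {
      p <- pmax(0.01, class_props * exp(rnorm(4, 0, 0.2)))
      p / sum(p)
    }, numeric(4))
    pmol_class <- t(props) * total_nmol * 1000 # nmol -> pmol
    areas <- pmol_class / pmol_standard * area_standard
    out <- data.frame(
      individual = sprintf("%s_%02d", morph, c(
        seq_len(n_per_group), seq_len(n_per_group)
      )),
      morph = morph,
      abdomen_mass_mg = round(mass, 2),
      stringsAsFactors = FALSE
    )
    out[paste0("area_", names(class_props))] <- round(areas, 3)
    out$area_standard <- area_standard
    out$pmol_standard <- pmol_standard
    out$true_total_nmol <- total_nmol
    out
  })
}

#' Deterministic sample with exact mean and standard deviation
#'
#' Builds a numeric vector of length `n` whose sample mean and sample
#' standard deviation (n - 1 denominator) equal the given values exactly,
#' by affinely rescaling an equally spaced template. Useful for
#' reconstructing group data compatible with published summary
#' statistics.
#'
#' @param n sample size (>= 2).
#' @param mean target sample mean.
#' @param sd target sample standard deviation (>= 0).
#' @return Numeric vector of length `n`.
#' @examples
#' x <- moment_matched_groups(5, 10, 2)
#' c(mean(x), sd(x))
#' @export
moment_matched_groups <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
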