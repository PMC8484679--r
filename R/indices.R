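#' Log coefficient-of-variation ratio (lnCVR) between the sexes
#'
#' Effect size contrasting the variability of a success measure between males
#' and females: the natural log of the ratio of the male to the female
#' coefficient of variation. Applied to reproductive success it contrasts the
#' opportunity for selection between the sexes; applied to mating success it
#' contrasts the opportunity for sexual selection. Positive values indicate
#' more intense (more variable) selection in males.
#'
#' With `small_sample_correction = TRUE` (the default) the additive
#' correction `1/(2(n_m - 1)) - 1/(2(n_f - 1))` is included; it vanishes when
#' the two sample sizes are equal.
#'
#' @param mean_m,sd_m,n_m Male mean, standard deviation and sample size.
#' @param mean_f,sd_f,n_f Female mean, standard deviation and sample size.
#' @param small_sample_correction Apply the small-sample bias correction?
#' @return The lnCVR effect size (log units).
#' @examples
#' ln_cvr(10, 4, 20, 10, 2, 20)  # male CV twice the female CV: log(2)
#' @export
ln_cvr <- function(mean_m, sd_m, n_m, mean_f, sd_f, n_f,
                   small_sample_correction = TRUE) {
  if (any(c(mean_m, mean_f) <= 0) || any(!is.finite(c(mean_m, mean_f)))) {
    stop("means must be positive: coefficient of variation undefined", call. = FALSE)
  }
  if (any(c(sd_m, sd_f) <= 0) || any(!is.finite(c(sd_m, sd_f)))) {
    stop("standard deviations must be positive (degenerate input)", call. = FALSE)
  }
  if (any(c(n_m, n_f) < 2)) stop("need n >= 2 per sex", call. = FALSE)
  out <- log((sd_m / mean_m) / (sd_f / mean_f))
  if (small_sample_correction) {
    out <- out + 1 / (2 * (n_m - 1)) - 1 / (2 * (n_f - 1))
  }
  out
}

#' Hedges' d standardized mean difference (male minus female)
#'
#' Standardized difference of male and female means in pooled-SD units, with
#' the small-sample bias correction factor
#' `J = 1 - 3 / (4(n_m + n_f - 2) - 1)`. Used to contrast Bateman gradients
#' between the sexes; positive values indicate a steeper male gradient.
#'
#' @inheritParams ln_cvr
#' @return Hedges' d (pooled-SD units).
#' @examples
#' hedges_d(2, 1, 10, 1, 1, 10)
#' @export
hedges_d <- function(mean_m, sd_m, n_m, mean_f, sd_f, n_f) {
  if (any(c(sd_m, sd_f) < 0) || (sd_m == 0 && sd_f == 0)) {
    stop("SDs must be non-negative and not both zero (degenerate input)", call. = FALSE)
  }
  if (any(c(n_m, n_f) < 2)) stop("need n >= 2 per sex", call. = FALSE)
  s_pooled <- sqrt(((n_m - 1) * sd_m^2 + (n_f - 1) * sd_f^2) / (n_m + n_f - 2))
  j <- 1 - 3 / (4 * (n_m + n_f - 2) - 1)
  (mean_m - mean_f) / s_pooled * j
}

#' Opportunity for selection
#'
#' The standardized variance of a success measure across individuals:
#' `var(x) / mean(x)^2`. Computed on reproductive success this is the
#' opportunity for selection I; on mating success, the opportunity for
#' sexual selection I_s. The sample (n - 1) variance convention is used.
#'
#' @param success Numeric vector of per-individual success values (>= 2).
#' @return The standardized variance (dimensionless, >= 0).
#' @examples
#' opportunity_for_selection(c(0, 2))  # sample variance 2, mean 1 -> 2
#' @export
opportunity_for_selection <- function(success) {
  if (length(success) < 2L || any(!is.finite(success))) {
    stop("need >= 2 finite success values", call. = FALSE)
  }
  m <- mean(success)
  if (m <= 0) stop("mean success must be positive", call. = FALSE)
  stats::var(success) / m^2
}

#' Bateman gradient
#'
#' Ordinary least-squares slope of reproductive success on mating success
#' within one sex; a steeper slope means a larger fitness payoff to
#' additional matings.
#'
#' @param mating_success,reproductive_success Equal-length numeric vectors
#'   (>= 3 individuals); mating success must not be constant.
#' @return The OLS slope (offspring per additional mate).
#' @examples
#' bateman_gradient(c(1, 2, 3), c(2, 4, 6))
#' @export
bateman_gradient <- function(mating_success, reproductive_success) {
  if (length(mating_success) != length(reproductive_success)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(mating_success) < 3L) stop("need >= 3 individuals", call. = FALSE)
  if (stats::var(mating_success) == 0) {
    stop("mating success is constant: slope undefined (singular fit)", call. = FALSE)
  }
  stats::cov(mating_success, reproductive_success) / stats::var(mating_success)
}

#' Sexual size dimorphism (SSD)
#'
#' Natural log of the male/female size ratio. Positive values mean males are
#' the larger sex. Sizes may be weights or linear lengths; lengths are
#' converted through the cubic weight-length relationship
#' `weight = c * length^3` (the shape constant c is assumed shared by the
#' sexes and cancels), so for lengths SSD is `3 * log(male/female)`.
#'
#' @param male_size,female_size Strictly positive sizes, both in the same
#'   dimension.
#' @param dimension Either `"weight"` or `"length"`.
#' @return SSD in log units.
#' @examples
#' ssd(10, 1)                      # log(10)
#' ssd(2, 1, dimension = "length") # 3 * log(2)
#' @export
ssd <- function(male_size, female_size, dimension = c("weight", "length")) {
  dimension <- match.arg(dimension)
  check_positive(c(male_size, female_size), "size")
  k <- if (dimension == "length") 3 else 1
  k * log(male_size / female_size)
}

#' Gamete size bias between the sexes
#'
#' Natural log of the ratio of mass-relative gamete sizes:
#' `log((male_gamete_size / male_mass) / (female_gamete_size / female_mass))`.
#' Zero corresponds to relative isogamy; the sign follows the algebra of the
#' ratio, so positive values mean the male gamete is larger relative to male
#' body mass than the female gamete is relative to female body mass.
#'
#' @param male_gamete_size,male_mass,female_gamete_size,female_mass Strictly
#'   positive; gamete size and body mass in consistent units within each sex.
#' @return Log-ratio bias (log units).
#' @export
gamete_size_bias <- function(male_gamete_size, male_mass,
                             female_gamete_size, female_mass) {
  check_positive(c(male_gamete_size, male_mass, female_gamete_size, female_mass),
                 "gamete size / mass inputs")
  log((male_gamete_size / male_mass) / (female_gamete_size / female_mass))
}

#' Gametic investment bias between the sexes
#'
#' Natural log of relative total gametic investment:
#' `log((testis_mass / male_mass) /
#'      (female_gamete_mass * clutch_size / female_mass))`.
#' The male side uses testis mass as a proxy for total sperm investment; the
#' female side multiplies per-egg mass by clutch size.
#'
#' @param testis_mass,male_mass,female_gamete_mass,clutch_size,female_mass
#'   Strictly positive.
#' @return Log-ratio bias (log units).
#' @export
gametic_investment_bias <- function(testis_mass, male_mass,
                                    female_gamete_mass, clutch_size,
                                    female_mass) {
  check_positive(c(testis_mass, male_mass, female_gamete_mass, clutch_size,
                   female_mass), "investment inputs")
  log((testis_mass / male_mass) / (female_gamete_mass * clutch_size / female_mass))
}

#' Five-level parental-care bias score
#'
#' Scores the division of care between the sexes on the 0-4 scale used in
#' comparative care studies: 0 = female-only care (exactly 0% male care),
#' 1 = 1-33% male care, 2 = 34-66%, 3 = 67-99%, 4 = male-only care (exactly
#' 100%). The two interior bin edges (33 1/3 and 66 2/3 percent) belong to
#' the lower bin. Species without any parental care are not scored: pass
#' `has_care = FALSE` (or the label `"no_care"`) to obtain `NA`.
#'
#' Qualitative labels are accepted in place of a percentage:
#' `"female_only"` (0), `"mostly_female"` (1), `"biparental"` (2),
#' `"mostly_male"` (3), `"male_only"` (4), `"no_care"` (NA).
#'
#' @param percent_male_care Percentage of care provided by males, in
#'   \[0, 100\], or one of the labels above. Vectorized.
#' @param has_care Logical (recycled): does the species provide any care at
#'   all? `FALSE` yields `NA` regardless of `percent_male_care`.
#' @return Integer score in 0..4, `NA` for no-care species.
#' @examples
#' care_score(c(0, 50, 100))
#' care_score("mostly_male")
#' @export
care_score <- function(percent_male_care, has_care = TRUE) {
  labels <- c(female_only = 0L, mostly_female = 1L, biparental = 2L,
              mostly_male = 3L, male_only = 4L)
  if (is.character(percent_male_care)) {
    unknown <- setdiff(percent_male_care, c(names(labels), "no_care"))
    if (length(unknown)) {
      stop("unrecognized care label: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out <- ifelse(percent_male_care == "no_care", NA_integer_,
                  labels[percent_male_care])
    has_care <- rep_len(has_care, length(out)) & percent_male_care != "no_care"
    out[!has_care] <- NA_integer_
    return(as.integer(out))
  }
  p <- percent_male_care
  if (any(!is.na(p) & (p < 0 | p > 100))) {
    stop("percent_male_care must lie in [0, 100]", call. = FALSE)
  }
  lo <- 100 / 3
  hi <- 200 / 3
  score <- ifelse(p == 0, 0L,
           ifelse(p == 100, 4L,
           ifelse(p <= lo, 1L,
           ifelse(p <= hi, 2L, 3L))))
  has_care <- rep_len(has_care, length(score))
  score[!has_care] <- NA_integer_
  score[is.na(p) & has_care] <- NA_integer_
  as.integer(score)
}

#' Column dictionary for raw species trait tables
#'
#' The raw table consumed by [derive_indices()] is one row per species, keyed
#' by a `species` column matching the tree's tip labels. This function
#' documents every recognized column.
#'
#' @return A data frame with columns `column`, `description`, `units`.
#' @export
trait_columns <- function() {
  data.frame(
    column = c("species",
               "male_mass_g", "female_mass_g",
               "male_gamete_size", "female_gamete_size",
               "testis_mass_g", "clutch_size",
               "percent_male_care", "has_care",
               "rs_mean_m", "rs_sd_m", "rs_n_m",
               "rs_mean_f", "rs_sd_f", "rs_n_f",
               "ms_mean_m", "ms_sd_m", "ms_n_m",
               "ms_mean_f", "ms_sd_f", "ms_n_f",
               "bg_mean_m", "bg_sd_m", "bg_n_m",
               "bg_mean_f", "bg_sd_f", "bg_n_f",
               "delta_I", "delta_I_s", "delta_beta_ss"),
    description = c("species name, must match tree tip labels",
                    "male body mass", "female body mass",
                    "male gamete (sperm) size", "female gamete (egg) mass",
                    "combined testis mass", "eggs per breeding event",
                    "% of care provided by males (no-care species: NA)",
                    "does the species provide any parental care?",
                    "male reproductive-success mean", "male RS SD", "male RS sample size",
                    "female reproductive-success mean", "female RS SD", "female RS sample size",
                    "male mating-success mean", "male MS SD", "male MS sample size",
                    "female mating-success mean", "female MS SD", "female MS sample size",
                    "male Bateman-gradient mean", "male gradient SD", "male gradient n",
                    "female Bateman-gradient mean", "female gradient SD", "female gradient n",
                    "pre-computed lnCVR of reproductive success (optional)",
                    "pre-computed lnCVR of mating success (optional)",
                    "pre-computed Hedges' d of Bateman gradients (optional)"),
    units = c("-", "g", "g", "volume or length", "g", "g", "count",
              "%", "logical",
              "offspring", "offspring", "individuals",
              "offspring", "offspring", "individuals",
              "mates", "mates", "individuals",
              "mates", "mates", "individuals",
              "offspring/mate", "offspring/mate", "estimates",
              "offspring/mate", "offspring/mate", "estimates",
              "log units", "log units", "SD units"),
    stringsAsFactors = FALSE
  )
}
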