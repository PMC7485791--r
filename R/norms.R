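#' Age-stratified LF reference table
#'
#' The LF deviation score standardises `ln(LF / RRI_average)` against an
#' age-stratified reference distribution with per-bin mean `mu_lf` and
#' standard deviation `sigma_lf` (both on the natural-log scale). The
#' published normative distribution for this score is not publicly
#' available, so the package ships a *synthetic* reference table built
#' from the same reference population that the cohort generator draws
#' from: LF power declines mildly with age while its log-scale spread
#' stays constant. Any conclusions about real drivers require a
#' user-supplied table (see [read_norm_table()]).
#'
#' @param age_lo,age_hi lower/upper edges of the covered age range (years);
#'   bins are 5 years wide.
#' @param mu_at_45 mean of `ln(LF / RRI_average)` at age 45.
#' @param mu_slope change in the log-scale mean per year of age.
#' @param sigma log-scale standard deviation (constant across bins).
#' @return A `norm_table`: a tibble with columns `age_lo`, `age_hi`,
#'   `mu_lf`, `sigma_lf`.
#' @examples
#' default_norm_table()
#' @export
default_norm_table <- function(age_lo = 20, age_hi = 70,
                               mu_at_45 = -0.5, mu_slope = -0.02,
                               sigma = 0.5) {
  lo <- seq(age_lo, age_hi - 5, by = 5)
  mid <- lo + 2.5
  norms <- tibble(
    age_lo = lo,
    age_hi = lo + 5,
    mu_lf = mu_at_45 + mu_slope * (mid - 45),
    sigma_lf = sigma
  )
  validate_norm_table(norms)
}

#' Read an age-stratified LF reference table from CSV
#'
#' Expects columns `age_lo`, `age_hi`, `mu_lf`, `sigma_lf`, one row per
#' age bin, bins contiguous and `sigma_lf > 0`.
#'
#' @param path CSV file path.
#' @return A validated `norm_table` tibble.
#' @export
read_norm_table <- function(path) {
  norms <- readr::read_csv(path, col_types = readr::cols(
    age_lo = readr::col_double(), age_hi = readr::col_double(),
    mu_lf = readr::col_double(), sigma_lf = readr::col_double()
  ))
  validate_norm_table(norms)
}

validate_norm_table <- function(norms) {
  need <- c("age_lo", "age_hi", "mu_lf", "sigma_lf")
  miss <- setdiff(need, names(norms))
  if (length(miss) > 0) stop_("norm table missing column(s): %s", paste(miss, collapse = ", "))
  norms <- arrange(as_tibble(norms), .data$age_lo)
  if (any(norms$sigma_lf <= 0)) stop_("norm table sigma_lf must be > 0 in every bin")
  if (nrow(norms) > 1 && any(abs(norms$age_hi[-nrow(norms)] - norms$age_lo[-1]) > 1e-9))
    stop_("norm table age bins must be contiguous (no gaps or overlaps)")
  class(norms) <- c("norm_table", class(norms))
  norms
}

# interpolate (mu, sigma) at an age: linear between bin midpoints,
# constant beyond the outermost midpoints; age must be covered by the bins
norm_lookup <- function(norms, age) {
  if (any(age < min(norms$age_lo) | age > max(norms$age_hi)))
    stop_("age %s outside the reference table coverage [%g, %g]",
          paste(age[age < min(norms$age_lo) | age > max(norms$age_hi)], collapse = ", "),
          min(norms$age_lo), max(norms$age_hi))
  mid <- (norms$age_lo + norms$age_hi) / 2
  if (nrow(norms) == 1) {
    return(list(mu = rep(norms$mu_lf, length(age)),
                sigma = rep(norms$sigma_lf, length(age))))
  }
  list(
    mu = approx(mid, norms$mu_lf, xout = age, rule = 2)$y,
    sigma = approx(mid, norms$sigma_lf, xout = age, rule = 2)$y
  )
}

#' LF deviation score
#'
#' Standardised sympathetic index for one recording:
#' \deqn{LF_{score} = \frac{\ln(LF / RRI_{average}) - \mu_{LF}(age)}{\sigma_{LF}(age)/10} + 50}
#' i.e. `ln(LF / RRI_average)` z-scored against the age-stratified
#' reference and rescaled to mean 50, SD 10. Heart-rate dependence is
#' absorbed by dividing LF power by the mean beat interval before taking
#' the log; age dependence by the age-binned reference moments.
#'
#' @param lf_power LF band power (ms^2), must be > 0.
#' @param rri_average mean beat interval (ms), must be > 0.
#' @param age driver age in years; must lie inside the reference coverage.
#' @param norms a `norm_table`, e.g. [default_norm_table()].
#' @return Numeric score (dimensionless deviation-score units).
#' @examples
#' nt <- default_norm_table()
#' lf_score(exp(-0.5) * 800, 800, 45, nt) # at the age-45 reference mean: 50
#' @export
lf_score <- function(lf_power, rri_average, age, norms) {
  if (any(lf_power <= 0)) stop_("lf_power must be > 0 (log of LF/RRI_average is undefined)")
  if (any(rri_average <= 0)) stop_("rri_average must be > 0")
  ns <- norm_lookup(norms, age)
  x <- log(lf_power / rri_average)
  (x - ns$mu) / (ns$sigma / 10) + 50
}

#' LF/HF sympathovagal balance ratio
#'
#' @param lf_power,hf_power band powers in ms^2; `hf_power` must be > 0.
#' @return `lf_power / hf_power`.
#' @export
lf_hf <- function(lf_power, hf_power) {
  if (any(hf_power <= 0)) stop_("hf_power must be > 0: LF/HF ratio undefined")
  if (any(lf_power < 0)) stop_("lf_power must be >= 0")
  lf_power / hf_power
}
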