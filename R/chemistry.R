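#' Free ammonia and free nitrous acid equilibria
#'
#' Unionized fractions of the total ammonia and nitrite pools, after
#' Anthonisen's classical acid-base equilibrium expressions. Free
#' ammonia (NH3) rises with pH and temperature,
#' \deqn{FA = \frac{17}{14}\,\frac{TAN \cdot 10^{pH}}
#'   {\exp(6344/(273+T)) + 10^{pH}},}
#' and free nitrous acid (HNO2) falls tenfold per pH unit,
#' \deqn{FNA = \frac{46}{14}\,\frac{NO_2\mbox{-}N}
#'   {\exp(-2300/(273+T)) \cdot 10^{pH}}.}
#' Concentrations are as N (mg N/L) in, as the free species (mg NH3/L,
#' mg HNO2/L) out.
#'
#' @param TAN total ammonia nitrogen (mg N/L), >= 0.
#' @param NO2N nitrite nitrogen (mg N/L), >= 0.
#' @param pH in (0, 14).
#' @param T_C temperature (deg C) in (-5, 60).
#' @return numeric vector of concentrations (mg/L).
#' @examples
#' free_ammonia(TAN = 280, pH = 7.5, T_C = 20)
#' free_nitrous_acid(NO2N = 50, pH = 6.08, T_C = 20)
#' @export
free_ammonia <- function(TAN, pH, T_C) {
  check_chem(TAN, pH, T_C, "TAN")
  (17 / 14) * TAN * 10^pH / (exp(6344 / (273 + T_C)) + 10^pH)
}

#' @rdname free_ammonia
#' @export
free_nitrous_acid <- function(NO2N, pH, T_C) {
  check_chem(NO2N, pH, T_C, "NO2N")
  (46 / 14) * NO2N / (exp(-2300 / (273 + T_C)) * 10^pH)
}

check_chem <- function(conc, pH, T_C, what) {
  if (any(conc < 0)) stop(what, " must be >= 0")
  if (any(pH <= 0 | pH >= 14)) stop("pH must lie in (0, 14)")
  if (any(T_C <= -5 | T_C >= 60)) stop("temperature must lie in (-5, 60) degC")
  invisible(TRUE)
}
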