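#' Equilibrium survivors at supply points (graphical classifier)
#'
#' Predicts the steady-state community at one or many supply points from
#' the graphical resource-ratio construction, without integrating ODEs.
#' For two essential resources, at most two species can coexist at a
#' point. Candidate equilibria are (i) single front species whose
#' resident equilibrium on their own ZNGI is uninvadable by every other
#' species, and (ii) adjacent pairs along the trade-off front whose
#' ZNGIs cross, where the supply point lies inside the cone spanned by
#' the two consumption vectors at the crossing and the coexistence
#' equilibrium is stable (each species consumes relatively more of the
#' resource limiting it). Species whose ZNGI corner is dominated
#' componentwise by another's can never persist and are excluded up
#' front. In founder-controlled (bistable) regions both alternative
#' residents are reported, since either may occupy the patch.
#'
#' The classification agrees with [chemostat_outcome()] away from region
#' boundaries; the ODE route remains the reference for single points and
#' is used to cross-validate this classifier in the test-suite.
#'
#' @param pool a \code{species_pool}.
#' @param S_N,S_O numeric vectors of supply concentrations (mg/L).
#' @param D loss/dilution rate applied to every species (1/d).
#' @return logical matrix, points in rows, species in columns (named by
#'   id): \code{TRUE} where the species persists at that supply point.
#'   Attribute \code{"unresolved"} counts points (generically boundary
#'   cases) where no candidate equilibrium qualified; these rows are all
#'   \code{FALSE}.
#' @export
equilibrium_survivors <- function(pool, S_N, S_O, D) {
  if (length(S_N) != length(S_O)) stop("S_N and S_O must have equal length")
  if (any(S_N < 0) || any(S_O < 0)) stop("supply must be non-negative")
  np <- length(S_N)
  ns <- nrow(pool)
  out <- matrix(FALSE, np, ns, dimnames = list(NULL, pool$id))

  ok <- pool$mu_max > D
  if (!any(ok) || np == 0L) { attr(out, "unresolved") <- 0L; return(out) }
  RN <- rep(Inf, ns); RO <- rep(Inf, ns)
  RN[ok] <- pool$K_N[ok] * D / (pool$mu_max[ok] - D)
  RO[ok] <- pool$K_O[ok] * D / (pool$mu_max[ok] - D)

  # trade-off front: sort by R*_N, keep strictly decreasing R*_O;
  # dominated corners can never persist (always invadable)
  ord <- order(RN, RO)
  front <- integer(0)
  best_RO <- Inf
  for (i in ord) {
    if (!ok[i]) next
    if (RO[i] < best_RO - 1e-15) { front <- c(front, i); best_RO <- RO[i] }
  }
  cN <- pool$c_N; cO <- pool$c_O
  tol <- 1e-12

  # single-species resident equilibria (front members only)
  for (i in front) {
    tN <- (S_N - RN[i]) / cN[i]
    tO <- (S_O - RO[i]) / cO[i]
    feas <- tN > 0 & tO > 0
    if (!any(feas)) next
    B <- pmin(tN, tO)
    ReqN <- S_N - B * cN[i]
    ReqO <- S_O - B * cO[i]
    inv <- rep(FALSE, np)
    for (j in seq_len(ns)) {
      if (j == i || !ok[j]) next
      inv <- inv | (ReqN > RN[j] + tol & ReqO > RO[j] + tol)
    }
    out[feas & !inv, i] <- TRUE
  }

  # adjacent-pair coexistence cones
  if (length(front) >= 2) {
    for (k in seq_len(length(front) - 1L)) {
      i <- front[k]; j <- front[k + 1L]       # i: lower R*_N, O-limited at X
      stable <- (cO[i] / cN[i]) > (cO[j] / cN[j])
      if (!stable) next                        # founder control: singles above
      Xn <- RN[j]; Xo <- RO[i]
      det <- cN[i] * cO[j] - cO[i] * cN[j]
      if (abs(det) < tol) next
      vN <- S_N - Xn; vO <- S_O - Xo
      a <- (cO[j] * vN - cN[j] * vO) / det
      b <- (-cO[i] * vN + cN[i] * vO) / det
      inside <- a > 0 & b > 0
      out[inside, i] <- TRUE
      out[inside, j] <- TRUE
    }
  }

  viable_any <- rep(FALSE, np)
  for (j in seq_len(ns)) if (ok[j])
    viable_any <- viable_any | (S_N > RN[j] & S_O > RO[j])
  unresolved <- sum(viable_any & rowSums(out) == 0L)
  attr(out, "unresolved") <- unresolved
  out
}
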