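#' Chemostat competition outcome by ODE integration
#'
#' Integrates the classical two-resource chemostat
#' \deqn{dR_j/dt = D (S_j - R_j) - \sum_i c_{ij}\, \mu_i(R)\, B_i, \qquad
#'       dB_i/dt = (\mu_i(R) - D)\, B_i}
#' from small equal inocula to steady state and reports the surviving
#' species, the ambient resource concentrations and the per-species
#' biomasses. The loss rate of every species is the dilution rate
#' \code{D}. Steady state is declared when the largest relative rate of
#' change falls below \code{tol}; if that does not happen by
#' \code{t_end} the outcome is returned with \code{converged = FALSE}.
#'
#' @param community a \code{species_pool}.
#' @param supply a single-row supply point (see [supply_point()]), or a
#'   numeric length-2 vector \code{c(S_N, S_O)}.
#' @param D dilution rate (1/d), must be > 0.
#' @param t_end maximum integration time (d).
#' @param extinction_threshold biomass (mg/L) below which a species is
#'   scored extinct at steady state.
#' @param B0 initial biomass of every species (mg/L).
#' @param tol relative steady-state tolerance (1/d).
#' @return a list of class \code{"competition_outcome"} with elements
#'   \code{survivors} (character), \code{equilibrium_R} (named numeric,
#'   \code{R_N}, \code{R_O}), \code{biomasses} (named numeric),
#'   \code{converged} (logical) and \code{t_used}.
#' @examples
#' sp <- species_pool(c("a", "b"), mu_max = 1, K_N = c(0.5, 1),
#'                    K_O = 0.2, m = 0.2, c_N = 7, c_O = 25)
#' out <- chemostat_outcome(sp, supply_point(20, 50), D = 0.2)
#' out$survivors  # lower R*_N species wins when ammonia limits
#' @export
chemostat_outcome <- function(community, supply, D, t_end = 1e4,
                              extinction_threshold = 1e-6, B0 = 1e-3,
                              tol = 1e-8) {
  if (D <= 0) stop("dilution rate D must be > 0")
  if (nrow(community) < 1) stop("community must contain at least one species")
  S <- as_supply_vec(supply)
  n <- nrow(community)
  mu_max <- community$mu_max; K_N <- community$K_N; K_O <- community$K_O
  c_N <- community$c_N; c_O <- community$c_O

  deriv <- function(t, y, parms) {
    R_N <- max(y[1], 0); R_O <- max(y[2], 0); B <- pmax(y[-(1:2)], 0)
    mu <- mu_max * pmin(R_N / (K_N + R_N), R_O / (K_O + R_O))
    up <- mu * B
    list(c(D * (S[1] - y[1]) - sum(c_N * up),
           D * (S[2] - y[2]) - sum(c_O * up),
           (mu - D) * B))
  }

  y <- c(S[1], S[2], rep(B0, n))
  t_used <- 0
  chunk <- min(200, t_end)
  converged <- FALSE
  while (t_used < t_end) {
    t1 <- min(t_used + chunk, t_end)
    sol <- deSolve::lsoda(y, c(t_used, t1), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    y <- sol[nrow(sol), -1]
    t_used <- t1
    dy <- unlist(deriv(t_used, y, NULL))
    rel <- abs(dy) / pmax(abs(y), extinction_threshold)
    # species already below the extinction threshold and still declining
    # are sealed losers: their slow exponential decay does not keep the
    # live system from being scored at equilibrium
    gone <- c(FALSE, FALSE, y[-(1:2)] < extinction_threshold & dy[-(1:2)] <= 0)
    if (max(rel[!gone], 0) < tol) { converged <- TRUE; break }
    chunk <- min(chunk * 2, 2000)
  }

  B <- pmax(y[-(1:2)], 0)
  names(B) <- community$id
  alive <- B > extinction_threshold
  structure(list(survivors = community$id[alive],
                 equilibrium_R = c(R_N = unname(max(y[1], 0)),
                                   R_O = unname(max(y[2], 0))),
                 biomasses = B,
                 converged = converged,
                 t_used = t_used),
            class = "competition_outcome")
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat("Chemostat outcome:",
      if (length(x$survivors)) paste(x$survivors, collapse = ", ") else
        "washout (no survivors)", "\n")
  cat(sprintf("  R_N = %.4g, R_O = %.4g mg/L%s\n",
              x$equilibrium_R["R_N"], x$equilibrium_R["R_O"],
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

as_supply_vec <- function(supply) {
  if (is.data.frame(supply)) {
    if (nrow(supply) != 1) stop("supply must be a single point")
    supply <- c(supply$S_N, supply$S_O)
  }
  supply <- as.numeric(supply)
  if (length(supply) != 2 || any(supply < 0))
    stop("supply must be two non-negative concentrations")
  supply
}

#' Two-species coexistence wedge
#'
#' Graphical resource-ratio construction for two species at a common
#' loss rate: if the right-angled ZNGIs cross, the crossing point is the
#' componentwise maximum of the two corners, and the supply points at
#' which both species coexist form a wedge bounded by rays from the
#' crossing in the directions of the two consumption vectors.
#'
#' @param a,b single-row \code{species_pool} objects.
#' @param m common loss rate; defaults to \code{a$m}.
#' @return a list of class \code{"coexistence_wedge"}: either
#'   \code{crossing = FALSE} (one ZNGI nested in the other or identical
#'   corners), or the crossing point, the two bounding consumption-vector
#'   rays, the limiting-resource assignment at the crossing, and
#'   \code{stable}, the mutual-invasibility condition that each species
#'   consumes relatively more of the resource limiting it there.
#' @seealso [classify_supply()] for the induced partition of supply space.
#' @export
coexistence_wedge <- function(a, b, m = NULL) {
  if (is.null(m)) m <- a$m[1]
  two <- rbind(as.data.frame(a), as.data.frame(b))
  two$id <- make.unique(two$id)
  z <- zngi(validate_species_pool(two), m = m)
  dN <- z$R_N_star[1] - z$R_N_star[2]
  dO <- z$R_O_star[1] - z$R_O_star[2]
  if (dN == 0 && dO == 0)
    return(structure(list(crossing = FALSE, reason = "identical ZNGIs"),
                     class = "coexistence_wedge"))
  if (dN * dO >= 0) {
    dom <- if (dN <= 0 && dO <= 0) z$id[1] else z$id[2]
    return(structure(list(crossing = FALSE, reason = "nested ZNGIs",
                          dominant = dom),
                     class = "coexistence_wedge"))
  }
  cross <- c(R_N = max(z$R_N_star), R_O = max(z$R_O_star))
  # species whose corner supplies the N coordinate of the crossing is
  # N-limited there; the other is O-limited
  n_lim <- z$id[which.max(z$R_N_star)]
  o_lim <- z$id[which.max(z$R_O_star)]
  cons <- rbind(c(two$c_N[1], two$c_O[1]), c(two$c_N[2], two$c_O[2]))
  rownames(cons) <- z$id
  stable <- (cons[o_lim, 2] / cons[o_lim, 1]) >
            (cons[n_lim, 2] / cons[n_lim, 1])
  structure(list(crossing = TRUE, point = cross, rays = cons,
                 n_limited = n_lim, o_limited = o_lim,
                 corners = z, m = m, stable = stable),
            class = "coexistence_wedge")
}

#' Classify a supply point against a two-species wedge
#'
#' Predicts the equilibrium community at each supply point from the
#' graphical construction alone: \code{"none"} below both ZNGIs, the
#' winning species' id in single-species regions, \code{"coexist"}
#' inside a stable wedge, and \code{"bistable"} inside an unstable one
#' (founder control; either species may win).
#'
#' @param wedge result of [coexistence_wedge()].
#' @param supply a supply-point data frame (any number of rows).
#' @return character vector, one label per supply point.
#' @export
classify_supply <- function(wedge, supply) {
  z <- wedge$corners
  if (is.null(z)) stop("classify_supply needs a crossing wedge; got ",
                       wedge$reason)
  corners <- as.matrix(z[, c("R_N_star", "R_O_star")])
  rownames(corners) <- z$id
  cls <- classify_points_graphical(corners, wedge$rays, supply$S_N, supply$S_O,
                                   stable = wedge$stable)
  cls
}

# Shared graphical classifier for an arbitrary set of species given their
# ZNGI corners (rows) and consumption vectors (rows, cols c_N, c_O).
# Returns per-point labels for the 2-species case; the multi-species pool
# path lives in equilibrium_survivors().
classify_points_graphical <- function(corners, cons, S_N, S_O, stable = TRUE) {
  ids <- rownames(corners)
  n <- length(S_N)
  out <- character(n)
  cross <- c(max(corners[, 1]), max(corners[, 2]))
  n_lim <- ids[which.max(corners[, 1])]
  o_lim <- ids[which.max(corners[, 2])]
  for (p in seq_len(n)) {
    S <- c(S_N[p], S_O[p])
    viable <- S[1] > corners[, 1] & S[2] > corners[, 2]
    if (!any(viable)) { out[p] <- "none"; next }
    v <- S - cross
    M <- t(cons[c(n_lim, o_lim), ])   # columns: consumption vectors
    ab <- tryCatch(solve(M, v), error = function(e) c(-1, -1))
    if (all(viable) && all(ab > 0)) {
      out[p] <- if (stable) "coexist" else "bistable"
      next
    }
    # single-species: survivor is the viable species whose single-species
    # equilibrium on its own ZNGI is uninvadable by the other
    winner <- NA_character_
    for (i in which(viable)) {
      tN <- (S[1] - corners[i, 1]) / cons[i, 1]
      tO <- (S[2] - corners[i, 2]) / cons[i, 2]
      B <- min(tN, tO)
      Req <- S - B * cons[i, ]
      j <- setdiff(seq_along(ids), i)
      invadable <- Req[1] > corners[j, 1] + 1e-12 &
                   Req[2] > corners[j, 2] + 1e-12
      if (!invadable) { winner <- ids[i]; break }
    }
    out[p] <- if (is.na(winner)) "coexist" else winner
  }
  out
}
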