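#' Monod kinetic parameters for a pool of ammonia oxidizers
#'
#' A species pool is a data frame with one row per taxon and the columns
#' \code{id}, \code{mu_max} (maximum specific growth rate, 1/d),
#' \code{K_N} (ammonia half-saturation, mg N/L), \code{K_O} (oxygen
#' half-saturation, mg O2/L), \code{m} (loss/dilution rate at which
#' persistence is evaluated, 1/d), and \code{c_N}, \code{c_O}
#' (resource consumed per unit biomass produced, mg resource per mg
#' biomass). All parameters must be strictly positive; \code{m <
#' mu_max} is required only when an equilibrium is actually evaluated.
#'
#' @param id character vector of taxon labels (unique).
#' @param mu_max,K_N,K_O,m,c_N,c_O numeric vectors recycled to the
#'   length of \code{id}.
#' @return a data frame of class \code{"species_pool"}.
#' @examples
#' sp <- species_pool("A", mu_max = 1, K_N = 1, K_O = 0.5, m = 0.2,
#'                    c_N = 7, c_O = 25)
#' r_star(sp, "N")
#' @export
species_pool <- function(id, mu_max, K_N, K_O, m, c_N, c_O) {
  pool <- data.frame(id = as.character(id), mu_max = mu_max, K_N = K_N,
                     K_O = K_O, m = m, c_N = c_N, c_O = c_O,
                     stringsAsFactors = FALSE)
  validate_species_pool(pool)
}

validate_species_pool <- function(pool) {
  need <- c("id", "mu_max", "K_N", "K_O", "m", "c_N", "c_O")
  missing <- setdiff(need, names(pool))
  if (length(missing))
    stop("species table lacks column(s): ", paste(missing, collapse = ", "))
  num <- pool[setdiff(need, "id")]
  if (any(!vapply(num, is.numeric, logical(1))))
    stop("species kinetic parameters must be numeric")
  if (any(is.na(as.matrix(num))))
    stop("species table contains missing values")
  if (any(as.matrix(num) <= 0))
    stop("all kinetic parameters must be strictly positive")
  if (anyDuplicated(pool$id))
    stop("duplicated species id(s)")
  pool <- pool[need]
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' Read or write a species kinetic-parameter table
#'
#' CSV with header \code{id,mu_max,K_N,K_O,m,c_N,c_O}. Parsing is strict:
#' missing columns, missing values or non-positive parameters are errors.
#'
#' @param path file path.
#' @return \code{read_species_table} returns a \code{species_pool};
#'   \code{write_species_table} returns \code{path} invisibly.
#' @export
read_species_table <- function(path) {
  pool <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_species_pool(pool)
}

#' @rdname read_species_table
#' @param pool a \code{species_pool}.
#' @export
write_species_table <- function(pool, path) {
  pool <- validate_species_pool(as.data.frame(pool))
  utils::write.csv(pool, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("Species pool: %d taxa\n", nrow(x)))
  NextMethod()
  invisible(x)
}

#' Liebig growth rate on two essential resources
#'
#' Specific growth rate under Monod kinetics for two essential
#' resources, combined by Liebig's law of the minimum:
#' \deqn{\mu(R_N, R_O) = \mu_{max} \min\!\left(\frac{R_N}{K_N + R_N},
#'   \frac{R_O}{K_O + R_O}\right).}
#'
#' @param sp a \code{species_pool} (one or more rows).
#' @param R_N,R_O ambient ammonia (mg N/L) and oxygen (mg O2/L)
#'   concentrations; vectors are recycled against each other.
#' @return matrix of rates (1/d), species in rows, concentration pairs in
#'   columns; dropped to a vector when \code{sp} has a single row.
#' @export
growth_rate <- function(sp, R_N, R_O) {
  if (any(R_N < 0) || any(R_O < 0))
    stop("resource concentrations must be non-negative")
  n <- max(length(R_N), length(R_O))
  R_N <- rep_len(R_N, n); R_O <- rep_len(R_O, n)
  fN <- sweep(matrix(R_N, nrow(sp), n, byrow = TRUE), 1, sp$K_N, function(r, k) r / (k + r))
  fO <- sweep(matrix(R_O, nrow(sp), n, byrow = TRUE), 1, sp$K_O, function(r, k) r / (k + r))
  mu <- sp$mu_max * pmin(fN, fO)
  if (nrow(sp) == 1L) drop(mu) else mu
}

#' Break-even resource concentration R*
#'
#' The lowest concentration of the named resource at which a species can
#' persist at its loss rate \code{m}: \eqn{R^* = K m / (\mu_{max} - m)}.
#' Species with \code{m >= mu_max} wash out at any concentration.
#'
#' @param sp a \code{species_pool}.
#' @param resource \code{"N"} (ammonia) or \code{"O"} (oxygen).
#' @param m optional loss rate overriding the pool's \code{m} column.
#' @return numeric vector of R* values (mg/L), one per species.
#' @export
r_star <- function(sp, resource = c("N", "O"), m = NULL) {
  resource <- match.arg(resource)
  if (is.null(m)) m <- sp$m
  m <- rep_len(m, nrow(sp))
  if (any(m >= sp$mu_max))
    stop("no equilibrium: loss rate m >= mu_max for species ",
         paste(sp$id[m >= sp$mu_max], collapse = ", "))
  K <- if (resource == "N") sp$K_N else sp$K_O
  K * m / (sp$mu_max - m)
}

#' Zero-net-growth isocline corner
#'
#' For two essential resources the ZNGI is a right angle cornered at
#' \code{(R*_N, R*_O)}: a species grows faster than its loss rate exactly
#' when both ambient concentrations strictly exceed the corner.
#'
#' @inheritParams r_star
#' @return data frame with columns \code{id}, \code{R_N_star},
#'   \code{R_O_star}.
#' @export
zngi <- function(sp, m = NULL) {
  data.frame(id = sp$id,
             R_N_star = r_star(sp, "N", m),
             R_O_star = r_star(sp, "O", m),
             stringsAsFactors = FALSE)
}

#' Supply point constructor
#'
#' @param S_N,S_O non-negative ammonia / oxygen supply concentrations
#'   (mg/L); vectors of equal length allowed.
#' @return data frame with columns \code{S_N}, \code{S_O}.
#' @export
supply_point <- function(S_N, S_O) {
  if (any(S_N < 0) || any(S_O < 0)) stop("supply concentrations must be >= 0")
  if (length(S_N) != length(S_O)) stop("S_N and S_O must have equal length")
  data.frame(S_N = as.numeric(S_N), S_O = as.numeric(S_O))
}
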