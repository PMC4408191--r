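#' Specification of a synthetic AOB species pool
#'
#' Defaults describe a 23-taxon ammonia-oxidizer guild with
#' literature-plausible kinetic ranges at around 20 deg C: maximum
#' growth rates near 1 per day (a kinetically similar guild, so
#' competitive differences come mainly from affinities), ammonia
#' half-saturations 0.5-4 mg N/L, oxygen half-saturations 0.15-1.2 mg
#' O2/L, and a loss rate of 0.2 per
#' day (a 5-day solids retention time). A negative rank correlation
#' between the two half-saturations imposes the gleaner-opportunist
#' trade-off that resource-ratio coexistence requires: no taxon is the
#' best competitor for both resources.
#'
#' @param n_species number of taxa (default 23).
#' @param mu_max_range,K_N_range,K_O_range positive (lo, hi) ranges for
#'   log-uniform draws.
#' @param tradeoff_rho Spearman rank correlation between K_N and K_O
#'   across species, in [-1, 1] (default -0.8).
#' @param m common loss rate column written into the pool (1/d).
#' @param seed integer seed.
#' @return a list of class \code{"pool_spec"}.
#' @export
pool_spec <- function(n_species = 23, mu_max_range = c(0.9, 1.1),
                      K_N_range = c(0.5, 4), K_O_range = c(0.15, 1.2),
                      tradeoff_rho = -0.9, m = 0.2, seed = 1) {
  for (rg in list(mu_max_range, K_N_range, K_O_range))
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2])
      stop("ranges must be positive (lo, hi) pairs with lo <= hi")
  if (abs(tradeoff_rho) > 1) stop("|tradeoff_rho| must be <= 1")
  if (n_species < 1) stop("n_species must be >= 1")
  structure(list(n_species = n_species, mu_max_range = mu_max_range,
                 K_N_range = K_N_range, K_O_range = K_O_range,
                 tradeoff_rho = tradeoff_rho, m = m, seed = seed),
            class = "pool_spec")
}

#' Generate a synthetic species pool
#'
#' Kinetic parameters are drawn log-uniformly within the spec ranges.
#' The affinity trade-off is induced by a Gaussian copula whose
#' parameter is chosen so the rank (Spearman) correlation between
#' \code{K_N} and \code{K_O} equals \code{tradeoff_rho}
#' (\eqn{\rho_{gauss} = 2\sin(\pi\rho_s/6)}); at \code{tradeoff_rho =
#' -1} the ranks are exactly reversed. Consumption coefficients scale
#' with the square root of each half-saturation relative to the
#' mid-range value, anchored at 7 mg N and 25 mg O2 per mg biomass —
#' ammonia-oxidizer stoichiometry (yield about 0.14 mg biomass per mg N;
#' about 3.5 mg O2 per mg N oxidized) — so that taxa consume relatively
#' more of the resource they compete poorly for, the configuration in
#' which two-species coexistence equilibria are stable.
#'
#' @param spec a [pool_spec()].
#' @return a \code{species_pool} of \code{n_species} rows; deterministic
#'   given \code{spec$seed}.
#' @export
gen_species_pool <- function(spec) {
  stopifnot(inherits(spec, "pool_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  qlogunif <- function(u, rg) exp(log(rg[1]) + u * (log(rg[2]) - log(rg[1])))
  u_mu <- stats::runif(n)
  u1 <- stats::runif(n)
  rho_s <- spec$tradeoff_rho
  if (abs(rho_s) == 1) {
    u2 <- if (rho_s == 1) u1 else 1 - u1
  } else {
    r_g <- 2 * sin(pi * rho_s / 6)
    z1 <- stats::qnorm(u1)
    z2 <- r_g * z1 + sqrt(1 - r_g^2) * stats::rnorm(n)
    u2 <- stats::pnorm(z2)
  }
  K_N <- qlogunif(u1, spec$K_N_range)
  K_O <- qlogunif(u2, spec$K_O_range)
  gm <- function(rg) sqrt(rg[1] * rg[2])
  species_pool(id = sprintf("sp%02d", seq_len(n)),
               mu_max = qlogunif(u_mu, spec$mu_max_range),
               K_N = K_N, K_O = K_O, m = spec$m,
               c_N = 7 * sqrt(K_N / gm(spec$K_N_range)),
               c_O = 25 * sqrt(K_O / gm(spec$K_O_range)))
}

#' Specification of a synthetic fingerprint time series
#'
#' Emulates a 2 x 2 treatment design (high/low ammonia x high/low
#' oxygen, one reactor each) fingerprinted on nine sampling days. All
#' reactors start from a common inoculum profile; before
#' \code{convergence_day} profiles drift neutrally (presence swaps that
#' conserve richness), and afterwards each reactor is pulled toward a
#' treatment-specific attractor subset of the band registry, so late
#' samples cluster by reactor while early samples resemble the inoculum.
#' Attractor sizes default to the 5-12 band range typical of such gels.
#'
#' @param treatments four treatment labels.
#' @param days strictly increasing sampling days.
#' @param pool size of the band registry.
#' @param attractor_sizes richness of each treatment's attractor.
#' @param convergence_day day after which treatment selection acts.
#' @param turnover_rate per-interval probability that a present band is
#'   swapped during neutral drift, in [0, 1].
#' @param attractor_pull per-interval probability a band is reset to its
#'   attractor state after convergence, in [0, 1].
#' @param noise_rate per-interval toggle probability after convergence.
#' @param inoculum_richness bands present at day one.
#' @param seed integer seed.
#' @return a list of class \code{"gel_spec"}.
#' @export
gel_spec <- function(treatments = c("R1_LN_HO", "R2_LN_LO",
                                    "R3_HN_HO", "R4_HN_LO"),
                     days = c(1, 10, 19, 28, 37, 46, 55, 64, 73),
                     pool = 36, attractor_sizes = c(9, 7, 12, 6),
                     convergence_day = 28, turnover_rate = 0.15,
                     attractor_pull = 0.6, noise_rate = 0.05,
                     inoculum_richness = 10, seed = 1) {
  if (length(treatments) != 4) stop("need four treatment labels (2 x 2 design)")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  probs <- c(turnover_rate, attractor_pull, noise_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  if (max(attractor_sizes) > pool)
    stop("band pool smaller than an attractor richness")
  if (inoculum_richness > pool) stop("inoculum richness exceeds pool")
  structure(list(treatments = treatments, days = days, pool = pool,
                 attractor_sizes = attractor_sizes,
                 convergence_day = convergence_day,
                 turnover_rate = turnover_rate,
                 attractor_pull = attractor_pull, noise_rate = noise_rate,
                 inoculum_richness = inoculum_richness, seed = seed),
            class = "gel_spec")
}

#' Generate a synthetic presence/absence band matrix
#'
#' @param spec a [gel_spec()].
#' @return a \code{"band_matrix"} with one sample per treatment x day;
#'   deterministic given \code{spec$seed}.
#' @export
gen_band_matrix <- function(spec) {
  stopifnot(inherits(spec, "gel_spec"))
  set.seed(spec$seed)
  P <- spec$pool
  inoc <- logical(P)
  inoc[sample.int(P, spec$inoculum_richness)] <- TRUE
  # disjointly biased attractors: prefer bands no other treatment uses
  unused <- seq_len(P)
  attractors <- lapply(spec$attractor_sizes, function(sz) {
    take <- unused[sample.int(length(unused), min(sz, length(unused)))]
    if (length(take) < sz) {
      extra <- setdiff(seq_len(P), take)
      take <- c(take, extra[sample.int(length(extra), sz - length(take))])
    }
    unused <<- setdiff(unused, take)
    a <- logical(P); a[take] <- TRUE; a
  })
  profiles <- list(); reactor <- character(); day <- numeric()
  state <- rep(list(inoc), 4)
  for (d in seq_along(spec$days)) {
    if (d > 1) {
      for (tr in 1:4) {
        s <- state[[tr]]
        if (spec$days[d] <= spec$convergence_day) {
          # neutral drift: swap present bands for absent ones
          pres <- which(s); abs_ <- which(!s)
          nswap <- stats::rbinom(1, length(pres), spec$turnover_rate)
          nswap <- min(nswap, length(abs_))
          if (nswap > 0) {
            s[pres[sample.int(length(pres), nswap)]] <- FALSE
            s[abs_[sample.int(length(abs_), nswap)]] <- TRUE
          }
        } else {
          pull <- stats::runif(P) < spec$attractor_pull
          s[pull] <- attractors[[tr]][pull]
          flip <- stats::runif(P) < spec$noise_rate
          s[flip] <- !s[flip]
        }
        state[[tr]] <- s
      }
    }
    for (tr in 1:4) {
      profiles[[length(profiles) + 1]] <- as.integer(state[[tr]])
      reactor <- c(reactor, spec$treatments[tr])
      day <- c(day, spec$days[d])
    }
  }
  ord <- order(match(reactor, spec$treatments), day)
  m <- do.call(rbind, profiles)[ord, , drop = FALSE]
  colnames(m) <- sprintf("band%02d", seq_len(P))
  suppressWarnings(band_matrix(m, reactor[ord], day[ord]))
}

#' Generate synthetic clone-library OTU counts
#'
#' Per sample, a clone count is drawn uniformly from
#' \code{n_clones_range} and clones are assigned to taxa by a
#' multinomial draw over a geometric rank-abundance series
#' \eqn{p_i \propto k(1-k)^{i-1}} — the simplest skewed abundance model
#' that produces the singleton/doubleton tail the nonparametric richness
#' estimators rely on. The mapping of abundance ranks to OTU labels is
#' permuted independently per sample, so different samples have
#' different dominant taxa.
#'
#' @param n_samples number of clone libraries (default 4).
#' @param n_clones_range integer (lo, hi) clones per library
#'   (default 37-42).
#' @param k geometric-series parameter in (0, 1) (default 0.3, which at
#'   37-42 clones yields libraries of 7-11 observed taxa with a
#'   singleton tail, the structure of typical AOB clone libraries).
#' @param pool number of OTU labels (default 25).
#' @param seed integer seed.
#' @return integer matrix of class \code{"otu_counts"}, OTUs in rows,
#'   samples in columns.
#' @export
gen_otu_counts <- function(n_samples = 4, n_clones_range = c(37, 42),
                           k = 0.3, pool = 25, seed = 1) {
  if (k <= 0 || k >= 1) stop("k must lie strictly in (0, 1)")
  if (n_samples < 1 || pool < 1) stop("n_samples and pool must be >= 1")
  set.seed(seed)
  p <- k * (1 - k)^(seq_len(pool) - 1)
  p <- p / sum(p)
  m <- matrix(0L, pool, n_samples,
              dimnames = list(sprintf("OTU%02d", seq_len(pool)),
                              sprintf("sample%d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    n <- sample(seq(n_clones_range[1], n_clones_range[2]), 1)
    ranks <- sample.int(pool)   # which OTU holds each abundance rank
    m[ranks, s] <- as.integer(stats::rmultinom(1, n, p))
  }
  class(m) <- c("otu_counts", class(m))
  m
}

#' Read / write an OTU count table (rows OTUs, columns samples)
#' @param path file path (CSV; first column OTU id).
#' @return integer matrix of class \code{"otu_counts"}.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0) || any(m != round(m))) stop("OTU counts must be non-negative integers")
  storage.mode(m) <- "integer"
  class(m) <- c("otu_counts", class(m))
  m
}

#' @rdname read_otu_table
#' @param counts an \code{"otu_counts"} matrix.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(otu = rownames(counts), unclass(counts),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
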