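#' Presence/absence band matrix
#'
#' Community fingerprints (e.g. DGGE profiles): a binary samples x bands
#' matrix plus sample metadata (reactor, day). Band columns observed in
#' no sample are dropped with a warning, since they carry no information
#' for the closed-pool null model.
#'
#' @param presence binary matrix, samples in rows, bands in columns.
#' @param reactor,day vectors of sample metadata, one entry per row.
#' @return a list of class \code{"band_matrix"} with elements
#'   \code{presence} and \code{samples}.
#' @export
band_matrix <- function(presence, reactor, day) {
  presence <- as.matrix(presence)
  if (!all(presence %in% c(0, 1))) stop("presence entries must be 0/1")
  storage.mode(presence) <- "integer"
  if (length(reactor) == 1L) reactor <- rep_len(reactor, nrow(presence))
  if (length(day) == 1L) day <- rep_len(day, nrow(presence))
  if (length(reactor) != nrow(presence) || length(day) != nrow(presence))
    stop("reactor/day metadata must match the number of rows")
  empty <- colSums(presence) == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero band column(s) dropped")
    presence <- presence[, !empty, drop = FALSE]
  }
  if (is.null(colnames(presence)))
    colnames(presence) <- sprintf("band%02d", seq_len(ncol(presence)))
  rownames(presence) <- paste(reactor, day, sep = ":")
  structure(list(presence = presence,
                 samples = data.frame(sample = rownames(presence),
                                      reactor = as.character(reactor),
                                      day = as.numeric(day),
                                      stringsAsFactors = FALSE)),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("Band matrix: %d samples x %d bands, %d reactor(s)\n",
              nrow(x$presence), ncol(x$presence),
              length(unique(x$samples$reactor))))
  invisible(x)
}

#' Read / write a band matrix
#'
#' CSV/TSV with first column the sample id formatted \code{reactor:day}
#' and remaining columns 0/1 per band.
#'
#' @param path file path; delimiter inferred from the extension
#'   (\code{.tsv} = tab, otherwise comma).
#' @return a \code{"band_matrix"}.
#' @export
read_band_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("sample ids must be formatted reactor:day")
  m <- as.matrix(df[, -1, drop = FALSE])
  band_matrix(m, vapply(parts, `[`, "", 1),
              as.numeric(vapply(parts, `[`, "", 2)))
}

#' @rdname read_band_matrix
#' @param bm a \code{"band_matrix"}.
#' @export
write_band_matrix <- function(bm, path) {
  df <- data.frame(sample = rownames(bm$presence), bm$presence,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Raup-Crick similarity by Monte-Carlo null model
#'
#' Null-model similarity between two presence/absence profiles: the two
#' observed richness values are kept fixed and taxa are redrawn
#' uniformly without replacement from a closed pool, so the number of
#' shared taxa under the null is distributed hypergeometrically. The
#' index is oriented so that large values mean the observed overlap
#' exceeds the null:
#' \deqn{S_{RC} = \big[\#\{\text{null} < \text{obs}\} +
#'   \tfrac12\#\{\text{null} = \text{obs}\}\big] / n_{null},}
#' i.e. a mid-P probability. Values above 0.95 indicate significant
#' similarity and below 0.05 significant dissimilarity.
#'
#' @param profile_a,profile_b binary vectors of equal length (the band
#'   registry), or — with \code{pool_size} given — their presence
#'   vectors over any common labelling.
#' @param pool_size size of the closed taxon pool; defaults to the
#'   profile length.
#' @param n_null number of null draws (>= 999; default 9999).
#' @param seed optional integer seed.
#' @return scalar similarity in [0, 1].
#' @seealso [raup_crick_exact()] for the closed form.
#' @export
raup_crick <- function(profile_a, profile_b, pool_size = NULL,
                       n_null = 9999, seed = NULL) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  if (!all(c(profile_a, profile_b) %in% c(0, 1)))
    stop("profiles must be binary")
  if (is.null(pool_size)) pool_size <- length(profile_a)
  n_a <- sum(profile_a); n_b <- sum(profile_b)
  if (n_a > pool_size || n_b > pool_size)
    stop("profile richness exceeds pool size")
  if (n_null < 999) stop("n_null must be >= 999")
  obs <- sum(profile_a == 1 & profile_b == 1)
  if (!is.null(seed)) set.seed(seed)
  memb <- logical(pool_size)
  shared <- integer(n_null)
  for (k in seq_len(n_null)) {
    ia <- sample.int(pool_size, n_a)
    ib <- sample.int(pool_size, n_b)
    memb[ia] <- TRUE
    shared[k] <- sum(memb[ib])
    memb[ia] <- FALSE
  }
  (sum(shared < obs) + 0.5 * sum(shared == obs)) / n_null
}

#' Raup-Crick similarity, exact hypergeometric form
#'
#' Closed form of the equal-likelihood null: the shared-taxon count is
#' \eqn{X \sim} Hypergeometric(pool, n_a, n_b) and
#' \eqn{S_{RC} = P(X < s_{obs}) + \frac12 P(X = s_{obs})}.
#'
#' @param n_a,n_b observed richness of the two profiles.
#' @param pool_size closed pool size.
#' @param shared_obs observed number of shared taxa.
#' @return scalar similarity in [0, 1].
#' @export
raup_crick_exact <- function(n_a, n_b, pool_size, shared_obs) {
  if (n_a > pool_size || n_b > pool_size)
    stop("richness exceeds pool size")
  if (shared_obs > min(n_a, n_b) || shared_obs < 0)
    stop("infeasible shared_obs")
  stats::phyper(shared_obs - 1, n_a, pool_size - n_a, n_b) +
    0.5 * stats::dhyper(shared_obs, n_a, pool_size - n_a, n_b)
}

# deterministic per-pair seed from unordered sample labels, so pairwise
# values are invariant to sample ordering
pair_seed <- function(seed, label_a, label_b) {
  s <- paste(sort(c(label_a, label_b)), collapse = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 268435456L
  (as.integer(seed) + as.integer(h)) %% .Machine$integer.max
}

#' Pairwise Raup-Crick similarity matrix
#'
#' @param bm a \code{"band_matrix"} with >= 2 samples.
#' @param n_null null draws per pair.
#' @param seed integer seed; each unordered sample pair gets a seed
#'   derived from it and the pair's labels, so the matrix is symmetric,
#'   reproducible, and invariant to sample reordering.
#' @param pool_size closed pool size (default: number of band columns).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
pairwise_src <- function(bm, n_null = 9999, seed = 1, pool_size = NULL) {
  stopifnot(inherits(bm, "band_matrix"))
  m <- bm$presence
  n <- nrow(m)
  if (is.null(pool_size)) pool_size <- ncol(m)
  S <- diag(1, n)
  dimnames(S) <- list(rownames(m), rownames(m))
  if (n < 2) return(S)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- raup_crick(m[i, ], m[j, ], pool_size, n_null,
                                     seed = pair_seed(seed, rownames(m)[i],
                                                      rownames(m)[j]))
  }
  S
}

#' Single-linkage clustering of a similarity matrix
#'
#' Agglomerates on distance \code{1 - S} with single linkage.
#'
#' @param S symmetric similarity matrix with unit diagonal.
#' @return an [stats::hclust] object.
#' @export
single_linkage_cluster <- function(S) {
  if (!isSymmetric(unname(S))) stop("similarity matrix must be symmetric")
  if (any(abs(diag(S) - 1) > 1e-12)) stop("similarity diagonal must be 1")
  stats::hclust(stats::as.dist(1 - S), method = "single")
}

#' Export a dendrogram as a Newick string
#' @param hc an [stats::hclust] object.
#' @return Newick string over the sample labels (branch lengths from the
#'   merge heights).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Moving-window community drift
#'
#' For each reactor, the Raup-Crick similarity between the profile of
#' each sampling day and the previous sampling day. Pairs with
#' \eqn{S_{RC} < 0.05} are flagged \code{"shift"} (significant change),
#' \eqn{> 0.95} \code{"stable"} (significant persistence), and values
#' between are \code{"random"} — no stronger association than random
#' band co-occurrence.
#'
#' @param bm a \code{"band_matrix"}; within each reactor the samples
#'   must appear in strictly increasing day order.
#' @param n_null,seed,pool_size as in [pairwise_src()].
#' @return data frame: \code{reactor, day_from, day_to, S_RC, flag}.
#' @export
moving_window <- function(bm, n_null = 9999, seed = 1, pool_size = NULL) {
  stopifnot(inherits(bm, "band_matrix"))
  if (is.null(pool_size)) pool_size <- ncol(bm$presence)
  out <- list()
  for (rx in unique(bm$samples$reactor)) {
    idx <- which(bm$samples$reactor == rx)
    if (length(idx) < 2) stop("reactor ", rx, " has fewer than 2 time points")
    days <- bm$samples$day[idx]
    if (any(diff(days) <= 0)) stop("days must be strictly increasing within reactor ", rx)
    for (k in 2:length(idx)) {
      i <- idx[k - 1]; j <- idx[k]
      s <- raup_crick(bm$presence[i, ], bm$presence[j, ], pool_size, n_null,
                      seed = pair_seed(seed, rownames(bm$presence)[i],
                                       rownames(bm$presence)[j]))
      out[[length(out) + 1]] <- data.frame(
        reactor = rx, day_from = days[k - 1], day_to = days[k], S_RC = s,
        flag = if (s < 0.05) "shift" else if (s > 0.95) "stable" else "random",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Chao1 richness estimator
#'
#' Nonparametric richness from singleton/doubleton counts. The
#' bias-corrected form \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} is the
#' default (always defined); the classic form
#' \eqn{S_{obs} + F_1^2/(2F_2)} is available for comparison with
#' literature values. Standard errors use the usual variance formulas
#' for the chosen form.
#'
#' @param counts non-negative integer abundance vector (zeros allowed).
#' @param bias_corrected logical (default \code{TRUE}).
#' @return list: \code{estimate}, \code{se}, \code{S_obs}, \code{F1},
#'   \code{F2}, \code{form}.
#' @examples
#' chao1(c(1, 1, 2, 3, 4), bias_corrected = FALSE)$estimate  # 7
#' chao1(c(1, 1, 2, 3, 4))$estimate                          # 5.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  S_obs <- sum(counts > 0)
  F1 <- sum(counts == 1); F2 <- sum(counts == 2)
  if (bias_corrected) {
    est <- S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))
    v <- F1 * (F1 - 1) / (2 * (F2 + 1)) +
      F1 * (2 * F1 - 1)^2 / (4 * (F2 + 1)^2) +
      F1^2 * F2 * (F1 - 1)^2 / (4 * (F2 + 1)^4)
    form <- "bias-corrected"
  } else if (F2 > 0) {
    G <- F1 / F2
    est <- S_obs + F1^2 / (2 * F2)
    v <- F2 * (G^2 / 2 + G^3 + G^4 / 4)
    form <- "classic"
  } else {
    est <- S_obs + F1 * (F1 - 1) / 2
    v <- F1 * (F1 - 1) / 2 + F1 * (2 * F1 - 1)^2 / 4 -
      if (est > 0) F1^4 / (4 * est) else 0
    form <- "classic (F2 = 0)"
  }
  list(estimate = est, se = sqrt(max(v, 0)), S_obs = S_obs,
       F1 = F1, F2 = F2, form = form)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator: species are split at
#' \code{rare_cutoff} into rare and abundant classes; the rare-class
#' sample coverage \eqn{C_{ACE} = 1 - F_1/N_{rare}} and a
#' coefficient-of-variation correction (floored at zero) give
#' \deqn{S_{ACE} = S_{abund} + S_{rare}/C_{ACE} +
#'   (F_1/C_{ACE})\,\gamma^2.}
#' When every rare taxon is a singleton the coverage is zero and the
#' estimator falls back to bias-corrected Chao1 with a warning. The
#' standard error comes from the delta method over the rare frequency
#' counts \eqn{F_k} with multinomial-type covariances
#' \eqn{cov(F_j, F_k) = F_j(\delta_{jk} - F_k/S_{ACE})}.
#'
#' @param counts non-negative integer abundance vector.
#' @param rare_cutoff largest count still considered rare (default 10).
#' @return list: \code{estimate}, \code{se}, \code{S_obs}, plus the
#'   rare-class summaries.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_counts(counts)
  S_obs <- sum(counts > 0)
  rare <- counts[counts > 0 & counts <= rare_cutoff]
  S_abund <- sum(counts > rare_cutoff)
  S_rare <- length(rare)
  if (S_rare == 0)
    return(list(estimate = S_obs, se = 0, S_obs = S_obs, S_rare = 0,
                S_abund = S_abund, C_ace = 1, gamma2 = 0))
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  if (F1 == N_rare) {
    warning("ACE undefined (all rare taxa are singletons); falling back to Chao1")
    ch <- chao1(counts)
    return(list(estimate = ch$estimate, se = ch$se, S_obs = S_obs,
                S_rare = S_rare, S_abund = S_abund, C_ace = 0,
                gamma2 = NA_real_, fallback = "chao1"))
  }
  Fk <- vapply(seq_len(rare_cutoff), function(k) sum(rare == k), numeric(1))
  est_from_F <- function(Fk) {
    Nr <- sum(seq_along(Fk) * Fk)
    Sr <- sum(Fk)
    C <- 1 - Fk[1] / Nr
    g2 <- max(Sr / C * sum(seq_along(Fk) * (seq_along(Fk) - 1) * Fk) /
                (Nr * (Nr - 1)) - 1, 0)
    S_abund + Sr / C + Fk[1] / C * g2
  }
  est <- est_from_F(Fk)
  # delta-method SE: numeric gradient in the rare frequency counts
  grad <- vapply(seq_len(rare_cutoff), function(k) {
    hstep <- 1e-4
    Fp <- Fk; Fp[k] <- Fp[k] + hstep
    Fm <- Fk; Fm[k] <- max(Fm[k] - hstep, 0)
    (est_from_F(Fp) - est_from_F(Fm)) / (Fp[k] - Fm[k])
  }, numeric(1))
  covF <- -outer(Fk, Fk) / est
  diag(covF) <- diag(covF) + Fk
  v <- drop(t(grad) %*% covF %*% grad)
  C_ace <- 1 - F1 / N_rare
  g2 <- max(S_rare / C_ace * sum(seq_len(rare_cutoff) *
                                 (seq_len(rare_cutoff) - 1) * Fk) /
              (N_rare * (N_rare - 1)) - 1, 0)
  list(estimate = est, se = sqrt(max(v, 0)), S_obs = S_obs,
       S_rare = S_rare, S_abund = S_abund, C_ace = C_ace, gamma2 = g2)
}

check_counts <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0)
    stop("counts must contain at least one positive entry")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

#' Individual-based rarefaction
#'
#' Expected species count in random subsamples of fixed sizes, by the
#' exact hypergeometric formula
#' \eqn{E[S_n] = \sum_i [1 - \binom{N-N_i}{n}/\binom{N}{n}]}
#' (computed via \code{vegan::rarefy}).
#'
#' @param counts non-negative integer abundance vector.
#' @param depths subsample sizes, each between 1 and \code{sum(counts)}.
#' @return data frame: \code{depth}, \code{expected_species}, \code{se}.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (any(depths > N)) stop("rarefaction depth exceeds the sample total")
  if (any(depths < 1)) stop("depths must be >= 1")
  r <- suppressWarnings(vegan::rarefy(counts, sample = depths, se = TRUE))
  data.frame(depth = depths,
             expected_species = as.numeric(r[1, ]),
             se = as.numeric(r[2, ]))
}

#' Band-count richness over the final sampling days
#'
#' Per reactor, the number of bands present on each of the last
#' \code{last_k_days} sampling days, summarized as mean and sample SD.
#'
#' @param bm a \code{"band_matrix"}.
#' @param last_k_days how many trailing days to use (default 4).
#' @return data frame: \code{reactor, mean_bands, sd_bands, n_days}.
#' @export
band_richness <- function(bm, last_k_days = 4) {
  stopifnot(inherits(bm, "band_matrix"))
  out <- lapply(unique(bm$samples$reactor), function(rx) {
    idx <- which(bm$samples$reactor == rx)
    if (length(idx) < last_k_days)
      stop("reactor ", rx, " has fewer than ", last_k_days, " time points")
    idx <- idx[order(bm$samples$day[idx])]
    tail_idx <- utils::tail(idx, last_k_days)
    nb <- rowSums(bm$presence[tail_idx, , drop = FALSE])
    data.frame(reactor = rx, mean_bands = mean(nb),
               sd_bands = stats::sd(nb), n_days = last_k_days,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
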