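#' Default run configuration
#'
#' A nested list with every knob of the two analysis arms. The
#' simulation arm realizes the richness-enrichment simulation (gradient
#' endpoints spanning the feed range of the 2 x 2 reactor design,
#' 20 positions, 50 replicate microhabitats of 100 supply points, loss
#' rate 0.2/d); the analysis arm runs the fingerprint and clone-library
#' statistics on supplied or synthetic community data.
#'
#' @param seed global integer seed (mandatory for any run).
#' @param out_dir output directory.
#' @return a list of class \code{"run_config"}.
#' @export
default_config <- function(seed = 1, out_dir = "results") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    paths = list(species_table = NULL, band_matrix = NULL, otu_table = NULL),
    simulation = list(
      gradient_min = c(0.05, 0.025),
      gradient_max = c(6, 3),
      n_steps = 20,
      sigma_mode = "diffusion",
      n_replicates = 50,
      n_points = 100,
      D = 0.2,
      radius_factor = 2.58,
      floc_N = NULL,    # optional lists of floc_spec() arguments;
      floc_O = NULL),   # NULL = default_floc_specs()
    null_model = list(n_null = 9999, pool_size = NULL),
    synthetic = list(pool = list(), gel = list(), clones = list())
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override [default_config()]; all validation
#' problems are collected and reported in a single error.
#'
#' @param path YAML file.
#' @return a validated \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- modify_list_deep(default_config(), raw)
  validate_run_config(cfg)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  errs <- character()
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    errs <- c(errs, "seed is mandatory and must be numeric")
  sim <- cfg$simulation
  if (length(sim$gradient_min) != 2 || length(sim$gradient_max) != 2 ||
      any(sim$gradient_min < 0) || any(sim$gradient_max < sim$gradient_min))
    errs <- c(errs, "gradient endpoints must be 0 <= min <= max, two components")
  if (!sim$sigma_mode %in% c("diffusion", "min_all_species"))
    errs <- c(errs, "sigma_mode must be 'diffusion' or 'min_all_species'")
  for (nm in c("n_steps", "n_replicates", "n_points"))
    if (sim[[nm]] < 1) errs <- c(errs, paste(nm, "must be >= 1"))
  if (sim$D <= 0) errs <- c(errs, "D must be > 0")
  if (cfg$null_model$n_null < 999) errs <- c(errs, "n_null must be >= 999")
  for (p in Filter(Negate(is.null), cfg$paths))
    if (!file.exists(p)) errs <- c(errs, paste("missing input file:", p))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg)[order(names(unclass(cfg)))], f)
  unname(tools::md5sum(f))
}

write_manifest <- function(cfg, extra, path) {
  man <- c(list(config_hash = config_hash(cfg), seed = cfg$seed,
                package_version = as.character(utils::packageVersion("flocrrt")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Run the simulation arm
#'
#' Builds (or loads) the species pool, runs [richness_curve()] over the
#' configured gradient, and writes the curve CSV, a mean +/- SD figure
#' and a run manifest (config hash, seed, sigma values, versions) into
#' \code{out_dir}. Reruns with an identical configuration produce
#' identical CSVs.
#'
#' @param cfg a \code{"run_config"}.
#' @return the \code{"richness_curve"}, invisibly; artifact paths in
#'   attribute \code{"artifacts"}.
#' @export
run_simulation_arm <- function(cfg) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- if (!is.null(cfg$paths$species_table))
    read_species_table(cfg$paths$species_table)
  else
    gen_species_pool(do.call(pool_spec,
                             c(cfg$synthetic$pool,
                               list(seed = cfg$seed)[is.null(cfg$synthetic$pool$seed)])))
  sim <- cfg$simulation
  grad <- build_gradient(sim$gradient_min, sim$gradient_max, sim$n_steps)
  fl_N <- if (!is.null(sim$floc_N)) do.call(floc_spec, sim$floc_N)
  fl_O <- if (!is.null(sim$floc_O)) do.call(floc_spec, sim$floc_O)
  curve <- richness_curve(grad, pool, sigma_mode = sim$sigma_mode,
                          n_replicates = sim$n_replicates,
                          n_points = sim$n_points, D = sim$D,
                          seed = cfg$seed, radius_factor = sim$radius_factor,
                          floc_N = fl_N, floc_O = fl_O)
  paths <- file.path(cfg$out_dir,
                     c(curve = "richness_curve.csv",
                       fig = "richness_curve.pdf",
                       manifest = "simulation_manifest.yaml",
                       pool = "species_pool.csv"))
  names(paths) <- c("curve", "fig", "manifest", "pool")
  utils::write.csv(as.data.frame(curve)[c("position", "S_N", "S_O",
                                          "mean_richness", "sd_richness",
                                          "n_replicates")],
                   paths["curve"], row.names = FALSE, quote = FALSE)
  write_species_table(pool, paths["pool"])
  grDevices::pdf(paths["fig"], width = 6, height = 4)
  plot(curve, main = sprintf("Simulated AOB richness (%s sigma)", sim$sigma_mode))
  grDevices::dev.off()
  write_manifest(cfg, list(arm = "simulation", sigma = as.list(curve$sigma),
                           pool_size = nrow(pool)), paths["manifest"])
  attr(curve, "artifacts") <- paths
  invisible(curve)
}

#' Run the analysis arm
#'
#' Loads (or generates) a band matrix and OTU count table, then writes
#' the pairwise Raup-Crick similarity matrix, a single-linkage
#' dendrogram in Newick form, the moving-window drift series, the
#' trailing band-count summary, the per-sample richness-estimate report
#' (observed, Chao1 and ACE with standard errors) and per-sample
#' rarefaction curves, plus a manifest, into \code{out_dir}.
#'
#' @param cfg a \code{"run_config"}.
#' @return list of the computed objects, invisibly; artifact paths in
#'   attribute \code{"artifacts"}.
#' @export
run_analysis_arm <- function(cfg) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bm <- if (!is.null(cfg$paths$band_matrix))
    read_band_matrix(cfg$paths$band_matrix)
  else
    gen_band_matrix(do.call(gel_spec,
                            c(cfg$synthetic$gel,
                              list(seed = cfg$seed)[is.null(cfg$synthetic$gel$seed)])))
  otus <- if (!is.null(cfg$paths$otu_table))
    read_otu_table(cfg$paths$otu_table)
  else
    gen_otu_counts(seed = cfg$seed + 1)

  nn <- cfg$null_model$n_null
  S <- pairwise_src(bm, n_null = nn, seed = cfg$seed,
                    pool_size = cfg$null_model$pool_size)
  hc <- single_linkage_cluster(S)
  mw <- moving_window(bm, n_null = nn, seed = cfg$seed,
                      pool_size = cfg$null_model$pool_size)
  br <- band_richness(bm)

  rich <- do.call(rbind, lapply(colnames(otus), function(s) {
    x <- otus[, s]
    ch <- chao1(x); ac <- ace(x)
    data.frame(sample = s, n_clones = sum(x), S_obs = ch$S_obs,
               chao1 = ch$estimate, chao1_se = ch$se,
               ACE = ac$estimate, ACE_se = ac$se)
  }))
  rare <- do.call(rbind, lapply(colnames(otus), function(s) {
    x <- otus[, s]
    cbind(sample = s, rarefaction_curve(x, seq_len(sum(x))))
  }))

  paths <- file.path(cfg$out_dir,
                     c("similarity_matrix.csv", "dendrogram.nwk",
                       "moving_window.csv", "band_richness.csv",
                       "richness_estimates.csv", "rarefaction.csv",
                       "analysis_manifest.yaml"))
  names(paths) <- c("similarity", "dendrogram", "moving_window",
                    "band_richness", "richness", "rarefaction", "manifest")
  utils::write.csv(S, paths["similarity"], quote = FALSE)
  writeLines(dendrogram_newick(hc), paths["dendrogram"])
  utils::write.csv(mw, paths["moving_window"], row.names = FALSE, quote = FALSE)
  utils::write.csv(br, paths["band_richness"], row.names = FALSE, quote = FALSE)
  utils::write.csv(rich, paths["richness"], row.names = FALSE, quote = FALSE)
  utils::write.csv(rare, paths["rarefaction"], row.names = FALSE, quote = FALSE)
  write_manifest(cfg, list(arm = "analysis", n_null = nn,
                           n_samples = nrow(bm$presence)), paths["manifest"])
  out <- list(similarity = S, cluster = hc, moving_window = mw,
              band_richness = br, richness = rich, rarefaction = rare,
              band_matrix = bm, otu_counts = otus)
  attr(out, "artifacts") <- paths
  invisible(out)
}

#' ZNGI diagram for a species pool
#'
#' Plots the right-angled zero-net-growth isocline corners of every
#' species at loss rate \code{D}, highlighting the trade-off front.
#'
#' @param pool a \code{species_pool}.
#' @param D loss rate (1/d).
#' @param ... passed to [plot()].
#' @export
plot_zngi <- function(pool, D, ...) {
  z <- zngi(pool, m = D)
  graphics::plot(z$R_N_star, z$R_O_star, pch = 16, log = "xy",
                 xlab = "R*_N (mg N/L)", ylab = "R*_O (mg O2/L)", ...)
  ord <- order(z$R_N_star)
  keep <- ord[!duplicated(cummin(z$R_O_star[ord]))]
  graphics::lines(z$R_N_star[keep], z$R_O_star[keep], col = "grey50", lty = 2)
  invisible(z)
}
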