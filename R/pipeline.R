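#' Default ground-truth kinetic constants per ligand condition
#'
#' The stock rate table used by the synthetic kinetics stage: flipping
#' rates, association/dissociation rate constants and uptake potencies for
#' the serotonin alkyl-chain series. The cumulative dissociation rate of
#' serotonin itself is not separately resolved by the steady-state-recovery
#' protocol and defaults to its outward-facing K_off.
#'
#' @return named list of [transport_rates()]
#' @export
default_transport_rates <- function() {
  list(
    `5HT` = transport_rates(k_flip = 104.30, K_on = 6.3, K_off = 0.55,
                            K_off_cumulative = 0.55, IC50 = 4.49,
                            Km = 1.3, Vmax = 100),
    M5HT = transport_rates(k_flip = 32.06, K_on = 1.2, K_off = 3.16,
                           K_off_cumulative = 0.24, IC50 = 79.35,
                           Km = 1.3, Vmax = 100),
    P5HT = transport_rates(k_flip = 72.30, K_on = 26.1, K_off = 0.31,
                           K_off_cumulative = 0.04, IC50 = 0.59,
                           Km = 1.3, Vmax = 100),
    B5HT = transport_rates(k_flip = 50.05, K_on = 20.7, K_off = 0.15,
                           K_off_cumulative = 0.03, IC50 = 0.27,
                           Km = 1.3, Vmax = 100)
  )
}

#' Pipeline configuration
#'
#' Collects every knob of the synthetic end-to-end study. Validation
#' happens up front: lag times must be positive multiples of the frame
#' stride, sizes positive, and the output directory creatable.
#'
#' @param seed master seed; every random draw in the run derives from it
#' @param outdir output directory
#' @param profiles named list of [ligand_profile()]s (default: the six
#'   stock conditions)
#' @param n_replicas,n_steps ensemble size per condition
#' @param dt_ns,diffusion integrator settings
#' @param noise_sigma emission noise (nm)
#' @param tica_lag_ns,msm_lag_ns analysis lag times, ns
#' @param k number of microstate cluster centres
#' @param n_bins free-energy surface bins per axis
#' @param n_boot bootstrap replicates for the surface (0 = skip)
#' @param rates named list of [transport_rates()] for the kinetics stage
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, outdir = file.path(tempdir(), "gatekin_run"),
                       profiles = default_ligand_profiles(),
                       n_replicas = 10L, n_steps = 20000L, dt_ns = 0.5,
                       diffusion = 0.01, noise_sigma = 0.02,
                       tica_lag_ns = 5, msm_lag_ns = 25, k = 100L,
                       n_bins = 50L, n_boot = 0L,
                       rates = default_transport_rates()) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  lag_to_steps(cfg$tica_lag_ns, cfg$dt_ns)   # errors if not a multiple
  lag_to_steps(cfg$msm_lag_ns, cfg$dt_ns)
  if (cfg$n_replicas < 1L || cfg$n_steps < 2L) stopf("ensemble sizes must be positive")
  if (cfg$k < 2L) stopf("k must be >= 2")
  if (!length(cfg$profiles)) stopf("need at least one ligand profile")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [run_config()] arguments; ligand
#' profiles may be given as `profiles: {NAME: {oo_depth: .., oc_depth: ..}}`.
#'
#' @param path YAML file
#' @param seed optional seed override
#' @param outdir optional outdir override
#' @return run_config
#' @export
read_run_config <- function(path, seed = NULL, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$profiles))
    raw$profiles <- lapply(stats::setNames(names(raw$profiles), names(raw$profiles)),
                           function(nm) do.call(ligand_profile,
                                                c(list(name = nm), raw$profiles[[nm]])))
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(outdir)) raw$outdir <- outdir
  keep <- intersect(names(raw), names(formals(run_config)))
  do.call(run_config, raw[keep])
}

stage_hash <- function(cfg, stage) {
  c2 <- unclass(cfg)
  c2$outdir <- NULL
  object_hash(list(stage = stage, cfg = c2))
}

# run one cached stage: reuse the stored result when the config hash of the
# stage (and everything upstream, via the chained inputs hash) matches
run_stage <- function(state, stage, cfg, resume, fun) {
  cache_dir <- file.path(cfg$outdir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  h <- object_hash(list(stage_hash(cfg, stage), state$hash))
  cache_file <- file.path(cache_dir, paste0(stage, ".rds"))
  hash_file <- file.path(cache_dir, paste0(stage, ".hash"))
  t0 <- proc.time()[["elapsed"]]
  cached <- resume && file.exists(cache_file) && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE), h)
  warns <- character()
  if (cached) {
    out <- readRDS(cache_file)
  } else {
    out <- withCallingHandlers(fun(state$results), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    saveRDS(out, cache_file)
    writeLines(h, hash_file)
  }
  state$results[[stage]] <- out
  state$hash <- h
  state$reports[[stage]] <- list(
    stage = stage, inputs_hash = h, cached = cached,
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
    warnings = warns,
    key_outputs = names(out) %||% character())
  message(sprintf("[gatekin] stage %-10s seed %d  %6.2fs%s", stage, cfg$seed,
                  state$reports[[stage]]$wall_time_s,
                  if (cached) "  (cached)" else ""))
  state
}

#' Run the full synthetic occlusion study
#'
#' Executes, in dependency order: ensemble generation for every ligand
#' condition, occlusion labelling and interaction splitting, PCA + FMA,
#' the shared-basis tICA / k-means / MSM / free-energy chain with
#' implied-timescale and Chapman-Kolmogorov checks, the synthetic kinetics
#' fits, and the summary report. Reruns with the same config and seed are
#' deterministic; with `resume = TRUE` completed stages are reloaded from
#' the per-stage cache when their input hashes match.
#'
#' @param cfg run_config
#' @param stages which stages to run (subset of the defaults, in order)
#' @param resume reuse cached stage results when hashes match
#' @return list with `results` (per-stage outputs), `reports` (stage
#'   reports) and `config`
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "featurize", "modes",
                                         "msm", "kinetics", "report"),
                         resume = FALSE) {
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "featurize", "modes", "msm", "kinetics", "report")
  stages <- all_stages[all_stages %in% stages]
  state <- list(results = list(), reports = list(), hash = "root")

  for (stage in stages) {
    fun <- switch(stage,
      simulate = function(res) stage_simulate(cfg),
      featurize = function(res) stage_featurize(cfg, need(res, "simulate")),
      modes = function(res) stage_modes(cfg, need(res, "simulate")),
      msm = function(res) stage_msm(cfg, need(res, "simulate")),
      kinetics = function(res) stage_kinetics(cfg),
      report = function(res) stage_report(cfg, res))
    state <- tryCatch(run_stage(state, stage, cfg, resume, fun),
                      error = function(e)
                        stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  invisible(list(results = state$results, reports = state$reports,
                 config = cfg))
}

need <- function(res, stage) {
  if (is.null(res[[stage]]))
    stopf("required upstream stage '%s' has not been run", stage)
  res[[stage]]
}

stage_simulate <- function(cfg) {
  tab_dir <- file.path(cfg$outdir, "tables")
  dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)
  ensembles <- list()
  for (i in seq_along(cfg$profiles)) {
    nm <- names(cfg$profiles)[i]
    ens <- make_ligand_ensemble(cfg$profiles[[i]], n_replicas = cfg$n_replicas,
                                n_steps = cfg$n_steps,
                                seed = derive_seed(cfg$seed, i),
                                dt = cfg$dt_ns, diffusion = cfg$diffusion,
                                noise_sigma = cfg$noise_sigma)
    for (r in seq_along(ens))
      write_feature_table(ens[[r]], file.path(tab_dir, paste0(names(ens)[r], ".tsv")))
    attr(ens, "latent") <- NULL
    ensembles[[nm]] <- ens
  }
  ensembles
}

stage_featurize <- function(cfg, ensembles) {
  ep <- cfg$profiles[[1]]$emission_means$tm6a_tm9up_nm
  ref <- gate_reference(OO = ep[["oo"]], OC = ep[["oc"]])
  per_cond <- lapply(ensembles, function(ens) {
    pooled <- do.call(rbind, lapply(ens, as.data.frame))
    labels <- label_occlusion(pooled$tm6a_tm9up_nm, ref)
    split <- split_by_interaction(ens)
    list(label_fractions = prop.table(table(labels$labels)),
         n_strong = nrow(split$strong), n_weak = nrow(split$weak),
         mean_dist_strong = mean(split$strong$tm6a_tm9up_nm),
         mean_dist_weak = mean(split$weak$tm6a_tm9up_nm))
  })
  summary <- data.frame(
    condition = names(per_cond),
    frac_full = vapply(per_cond, function(x) unname(x$label_fractions["full"]), 1.0),
    frac_none = vapply(per_cond, function(x) unname(x$label_fractions["none"]), 1.0),
    n_strong = vapply(per_cond, function(x) x$n_strong, 1.0),
    mean_dist_strong = vapply(per_cond, function(x) x$mean_dist_strong, 1.0),
    mean_dist_weak = vapply(per_cond, function(x) x$mean_dist_weak, 1.0))
  utils::write.table(summary, file.path(cfg$outdir, "occlusion_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(reference = ref, per_condition = per_cond, summary = summary)
}

stage_modes <- function(cfg, ensembles) {
  all_tables <- unlist(ensembles, recursive = FALSE)
  pca <- fit_pca(all_tables)
  pooled <- pool_rows(all_tables)
  query <- pooled[, "e_f335_kjmol"]
  fma <- fit_fma(pooled, query, n_components = min(10L, ncol(pooled)))
  rmsf <- filtered_rmsf(fma, pooled)
  list(pca = pca, fma = fma, rmsf = rmsf,
       variance_explained = pca$values / sum(pca$values))
}

stage_msm <- function(cfg, ensembles) {
  all_tables <- unlist(ensembles, recursive = FALSE)
  tica <- fit_tica(all_tables, lag_ns = cfg$tica_lag_ns, dt_ns = cfg$dt_ns)
  proj_all <- tica_project(tica, all_tables)
  disc <- discretize(proj_all, k = cfg$k, seed = derive_seed(cfg$seed, 777L))
  grid <- default_grid(disc$centers, cfg$n_bins)
  ep <- cfg$profiles[[1]]$emission_means$tm6a_tm9up_nm
  midpoint <- mean(c(ep[["oo"]], ep[["oc"]]))

  # per-microstate mean gate distance (over all conditions) for occupancy
  pooled_dist <- unlist(lapply(all_tables, function(tb) tb$tm6a_tm9up_nm))
  pooled_states <- unlist(disc$dtrajs) + 1L
  state_dist <- tapply(pooled_dist, pooled_states, mean)
  state_mean_dist <- rep(NA_real_, cfg$k)
  state_mean_dist[as.integer(names(state_dist))] <- state_dist

  cond_of <- rep(names(ensembles), vapply(ensembles, length, 1L))
  idx <- split(seq_along(all_tables),
               factor(cond_of, levels = names(ensembles)))
  per_cond <- list()
  for (nm in names(ensembles)) {
    dt_cond <- disc$dtrajs[idx[[nm]]]
    pr_cond <- disc$projections[idx[[nm]]]
    m <- estimate_msm(dt_cond, lag_ns = cfg$msm_lag_ns, dt_ns = cfg$dt_ns)
    fes <- free_energy_surface(m, disc, grid = grid,
                               projections = pr_cond, dtrajs = dt_cond)
    occ_states <- which(state_mean_dist[m$active + 1L] <= midpoint)
    occupancy <- sum(m$pi[occ_states])
    dG <- -fes$kT * log(occupancy / max(1 - occupancy, 1e-12))
    write_analysis_table(fes, file.path(cfg$outdir, paste0("fes_", nm, ".tsv")),
                         meta = list(condition = nm, lag_ns = cfg$msm_lag_ns,
                                     k = cfg$k, seed = cfg$seed,
                                     tica_hash = tica$hash))
    boot <- NULL
    if (cfg$n_boot >= 2L && length(dt_cond) >= 2L) {
      disc_cond <- structure(list(centers = disc$centers, dtrajs = dt_cond,
                                  projections = pr_cond,
                                  k = disc$k, seed = disc$seed),
                             class = "discretization")
      boot <- bootstrap_surface(disc_cond, lag_ns = cfg$msm_lag_ns,
                                dt_ns = cfg$dt_ns, grid = grid,
                                n_boot = cfg$n_boot,
                                seed = derive_seed(cfg$seed, 888L))
    }
    per_cond[[nm]] <- list(msm = m, fes = fes, occupancy = occupancy,
                           dG_oo_oc = dG, bootstrap = boot)
  }
  # validation on the pooled dataset
  lags <- cfg$dt_ns * unique(pmax(1, round(c(2, 10, 25, 50) / cfg$dt_ns / 2) * 2))
  lags <- lags[lags * 2 < cfg$n_steps * cfg$dt_ns]
  its <- implied_timescales(disc$dtrajs, lags_ns = lags, dt_ns = cfg$dt_ns)
  write_analysis_table(its, file.path(cfg$outdir, "its.tsv"),
                       meta = list(seed = cfg$seed, tica_hash = tica$hash))
  pooled_msm <- estimate_msm(disc$dtrajs, lag_ns = cfg$msm_lag_ns,
                             dt_ns = cfg$dt_ns)
  ck <- ck_test(pooled_msm, disc$dtrajs, n_boot = 10L,
                seed = derive_seed(cfg$seed, 999L))
  write_analysis_table(ck, file.path(cfg$outdir, "ck.tsv"),
                       meta = list(lag_ns = cfg$msm_lag_ns, seed = cfg$seed))
  list(tica = tica, tica_hash = tica$hash, disc = disc, per_condition = per_cond,
       its = its, ck = ck, midpoint_nm = midpoint)
}

stage_kinetics <- function(cfg) {
  out <- list()
  for (nm in names(cfg$rates)) {
    rates <- cfg$rates[[nm]]
    sd_k <- derive_seed(cfg$seed, 100L + match(nm, names(cfg$rates)))
    trace <- simulate_patch_clamp(rates,
                                  patch_protocol(mode = "peak_0mV",
                                                 concentration_uM = 1000,
                                                 compound = nm),
                                  noise_sigma = 0.02, seed = sd_k)
    peak <- fit_peak_relaxation(trace)
    conc <- c(1, 3, 10, 30, 100, 300)
    kobs <- vapply(conc, function(cc)
      rates$k_flip * (1 - exp(-(rates$K_on / rates$k_flip) * cc)), 1.0)
    kobs <- kobs * (1 + with_seed(sd_k + 1L, rnorm(length(conc), sd = 0.03)))
    dose <- fit_flipping_dose_curve(conc, kobs)
    # wash times spanning ~0.05 to ~5 characteristic dissociation times
    wash <- signif(10^seq(log10(0.05 / rates$K_off), log10(5 / rates$K_off),
                          length.out = 8L), 3)
    rec <- fit_recovery(wash, pmin(1.2, pmax(0, simulate_recovery_amplitudes(
      rates$K_off, wash, noise_sigma = 0.05, seed = sd_k + 2L))))
    cc <- rates$IC50 * 10^seq(-2, 2, length.out = 9)
    resp <- 100 / (1 + cc / rates$IC50)
    resp <- resp + with_seed(sd_k + 3L, rnorm(length(cc), sd = 3))
    ic50 <- fit_ic50(cc, resp)
    out[[nm]] <- list(flipping_rate = unname(peak$K), K_on = dose$K_on,
                      K_off = unname(rec$K), IC50 = ic50$IC50,
                      fits = list(peak = peak, dose = dose, recovery = rec,
                                  ic50 = ic50))
    write_fit_report(peak, file.path(cfg$outdir, paste0("kinetics_", nm, "_peak.yml")))
  }
  out
}

stage_report <- function(cfg, res) {
  path <- file.path(cfg$outdir, "report.md")
  lines <- c("# Synthetic occlusion study report",
             sprintf("seed: %d | conditions: %s", cfg$seed,
                     paste(names(cfg$profiles), collapse = ", ")), "")
  if (!is.null(res$msm)) {
    lines <- c(lines, "## Occlusion energetics", "",
               "| condition | occluded occupancy | dG(OO->OC) kJ/mol |",
               "|---|---|---|")
    for (nm in names(res$msm$per_condition)) {
      pc <- res$msm$per_condition[[nm]]
      lines <- c(lines, sprintf("| %s | %.3f | %.2f |", nm, pc$occupancy,
                                pc$dG_oo_oc))
    }
    lines <- c(lines, "")
  }
  if (!is.null(res$kinetics)) {
    lines <- c(lines, "## Kinetic constants (fitted from synthetic traces)", "",
               "| condition | flipping rate 1/s | K_on 1/(uM s) | K_off 1/s | IC50 uM |",
               "|---|---|---|---|---|")
    for (nm in names(res$kinetics)) {
      k <- res$kinetics[[nm]]
      lines <- c(lines, sprintf("| %s | %.2f | %.2f | %.3f | %.3g |", nm,
                                k$flipping_rate, k$K_on, k$K_off, k$IC50))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  list(path = path, n_lines = length(lines))
}

#' Command-line entry point
#'
#' Subcommand-style interface over [run_pipeline()]:
#' `gatekin_cli(c("all", "--seed", "7", "--outdir", "out"))`. Subcommands
#' are stage names (or `all`); flags: `--config PATH` (YAML),
#' `--seed INT`, `--outdir PATH`, `--stages a,b`, `--resume`.
#'
#' @param args character vector of CLI arguments
#' @return the [run_pipeline()] result, invisibly
#' @export
gatekin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_flag <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  sub <- if (length(args) && !startsWith(args[1], "--")) args[1] else "all"
  stages <- get_flag("--stages")
  stages <- if (!is.null(stages)) strsplit(stages, ",")[[1]]
  else if (sub == "all") c("simulate", "featurize", "modes", "msm",
                           "kinetics", "report")
  else sub
  if ("simulate" %in% stages || length(setdiff(stages, "simulate")))
    stages <- union("simulate", stages)  # downstream stages need the ensembles
  seed <- get_flag("--seed")
  outdir <- get_flag("--outdir")
  cfg_path <- get_flag("--config")
  cfg <- if (!is.null(cfg_path))
    read_run_config(cfg_path, seed = if (!is.null(seed)) as.integer(seed),
                    outdir = outdir)
  else do.call(run_config, Filter(Negate(is.null),
                                  list(seed = if (!is.null(seed)) as.integer(seed),
                                       outdir = outdir)))
  invisible(run_pipeline(cfg, stages = stages, resume = "--resume" %in% args))
}
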