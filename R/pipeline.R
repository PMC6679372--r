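#' Run configuration for the toy free-energy pipeline
#'
#' @param temperature Temperature in K (default 300).
#' @param lambda_schedule Coupling schedule in \[0, 1\]; default 11
#'   equidistant points.
#' @param target_sigma Acceptable propagated TI error in kJ/mol (default 1).
#' @param seed Integer master seed for all sampling.
#' @param n_samples Stored snapshots per lambda point.
#' @param endstate_factor The end states are prolonged by this factor for
#'   the one-step-perturbation and decomposition series (default 5, echoing
#'   the practice of extending 1 ns production windows to 5 ns).
#' @param stride Monte Carlo sweeps between stored snapshots.
#' @param out_dir Output directory for tables and series files.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(temperature = 300,
                       lambda_schedule = seq(0, 1, length.out = 11),
                       target_sigma = 1, seed = 1L,
                       n_samples = 400L, endstate_factor = 5L,
                       stride = 5L, out_dir = tempfile("alchemr_run_")) {
  stopifnot(temperature > 0, target_sigma > 0, n_samples >= 16L,
            endstate_factor >= 1L, stride >= 1L)
  ls <- sort(unique(as.numeric(lambda_schedule)))
  if (!isTRUE(all.equal(min(ls), 0)) || !isTRUE(all.equal(max(ls), 1)) ||
      any(ls < 0 | ls > 1))
    stop("lambda schedule must be unique values spanning [0, 1]")
  structure(list(temperature = temperature, lambda_schedule = ls,
                 target_sigma = target_sigma, seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 endstate_factor = as.integer(endstate_factor),
                 stride = as.integer(stride), out_dir = out_dir),
            class = "run_config")
}

#' Simulate a TI profile for a toy system over a lambda schedule
#'
#' Samples one trajectory per lambda point and assembles the mean
#' dH/dlambda profile with block-averaged errors.
#'
#' @param spec A \code{\link{toy_system_spec}}.
#' @param lambda_schedule Numeric vector of lambda values.
#' @return A \code{\link{ti_profile}}.
#' @export
simulate_ti_profile <- function(spec, lambda_schedule = seq(0, 1, length.out = 11)) {
  series <- lapply(lambda_schedule, function(lam)
    dhdl_series(sample_lambda(spec, lam)))
  ti_profile(series)
}

.stage_log <- function(stage, t0, verbose, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s (%.1f s)", stage, sprintf(fmt, ...),
                    as.numeric(Sys.time()) - t0))
}

#' Run the toy free-energy pipeline end to end
#'
#' Exercises every layer of the package on a simulated charging system:
#' (1) \emph{simulate} -- Metropolis ensembles of the lambda-coupled charge
#' transformation A > B in a loose-bath ("water") and a stiff-bath
#' ("protein") environment, plus prolonged end states; series are written
#' as TSV; (2) \emph{ti} -- trapezoidal integration per environment, with
#' schedule-refinement proposals logged when the error target is missed;
#' (3) \emph{osp} -- one-step perturbation from the end states to the
#' charge variants A* and B*; (4) \emph{cycle} -- relative binding free
#' energy and its charge-variant composite; (5) \emph{decompose} --
#' ligand--surrounding energy/entropy split per environment and
#' bound-minus-unbound differences; (6) \emph{scan} -- MAE/correlation
#' statistics of the packaged affinity table. Results are written as TSV
#' plus a machine-readable JSON summary; the whole run is a deterministic
#' function of the config.
#'
#' @param config A \code{\link{run_config}}.
#' @param verbose Log stage progress and timings to stderr.
#' @return Invisibly, the summary list (also written to
#'   \code{summary.json} in \code{config$out_dir}).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  envs <- list(water = 200, protein = 800)  # bath tether constants
  dq <- -0.1  # charge-variant offset probed by OSP

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## --- simulate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sims <- run_stage("simulate", {
    lapply(names(envs), function(env) {
      spec <- toy_system_spec("charging", k_A = envs[[env]], k_B = envs[[env]],
                              temperature = config$temperature,
                              seed = config$seed + match(env, names(envs)),
                              n_samples = config$n_samples,
                              stride = config$stride)
      trajs <- lapply(config$lambda_schedule, function(lam) sample_lambda(spec, lam))
      long_spec <- spec
      long_spec$n_samples <- spec$n_samples * config$endstate_factor
      ends <- list(A = sample_lambda(long_spec, 0), B = sample_lambda(long_spec, 1))
      files <- sprintf("dhdl_%s_%02d.tsv", env, seq_along(trajs))
      for (i in seq_along(trajs))
        write_dhdl(dhdl_series(trajs[[i]]), file.path(config$out_dir, files[i]),
                   seed = spec$seed)
      write_lambda_manifest(config$lambda_schedule, files,
                            file.path(config$out_dir, sprintf("manifest_%s.tsv", env)))
      for (st in names(ends))
        write_energy_series(endstate_energy_series(ends[[st]], environment = env),
                            file.path(config$out_dir,
                                      sprintf("endstate_%s_%s.tsv", env, st)),
                            seed = spec$seed)
      list(env = env, spec = spec, trajs = trajs, ends = ends)
    })
  })
  names(sims) <- names(envs)
  .stage_log("simulate", t0, verbose, "2 environments x %d lambda points, seed %d",
             length(config$lambda_schedule), config$seed)

  ## --- ti ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ti <- run_stage("ti", {
    lapply(sims, function(s) {
      prof <- ti_profile(lapply(s$trajs, dhdl_series))
      fe <- ti_integrate(prof)
      prop <- refine_schedule(prof, config$target_sigma)
      if (length(prop) && verbose)
        message(sprintf("[ti] %s: sigma %.3g above target %.3g; proposed lambda: %s",
                        s$env, fe$sigma, config$target_sigma,
                        paste(format(prop, digits = 3), collapse = ", ")))
      list(profile = prof, fe = fe, proposals = prop)
    })
  })
  .stage_log("ti", t0, verbose, "dG water %.3f, protein %.3f kJ/mol",
             ti$water$fe$value, ti$protein$fe$value)

  ## --- osp --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  osp <- run_stage("osp", {
    lapply(sims, function(s) {
      vary <- function(spec, dqA, dqB) {
        sp <- spec; sp$q_A <- spec$q_A + dqA; sp$q_B <- spec$q_B + dqB; sp
      }
      star <- vary(s$spec, dq, dq)
      long_spec <- s$spec; long_spec$n_samples <- s$spec$n_samples * config$endstate_factor
      star$n_samples <- long_spec$n_samples
      fa <- osp_zwanzig(perturbed_energy_series(s$ends$A, star, environment = s$env),
                        config$temperature, direction = c("A", "A*"))
      fb <- osp_zwanzig(perturbed_energy_series(s$ends$B, star, environment = s$env),
                        config$temperature, direction = c("B", "B*"))
      list(flank_A = fa, flank_B = fb)
    })
  })
  .stage_log("osp", t0, verbose, "flank legs done (dq = %g e)", dq)

  ## --- cycle ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cyc <- run_stage("cycle", {
    cycle <- thermo_cycle(unbound_leg = ti$water$fe, bound_leg = ti$protein$fe,
                          flank_A = list(water = osp$water$flank_A,
                                         protein = osp$protein$flank_A),
                          flank_B = list(water = osp$water$flank_B,
                                         protein = osp$protein$flank_B),
                          label = "toy charging A>B")
    ddG <- relative_binding_dG(cycle)
    ddG_star <- apply_charge_flanks(cycle)
    tab <- data.frame(label = c("A>B", "A*>B*"),
                      ddG = c(ddG$value, ddG_star$value),
                      sigma = c(ddG$sigma, ddG_star$sigma))
    utils::write.table(tab, file.path(config$out_dir, "cycle_ddG.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(cycle = cycle, ddG = ddG, ddG_star = ddG_star)
  })
  .stage_log("cycle", t0, verbose, "ddG %.3f +/- %.3f kJ/mol",
             cyc$ddG$value, cyc$ddG$sigma)

  ## --- decompose --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dec <- run_stage("decompose", {
    per_env <- lapply(sims, function(s) {
      eA <- endstate_energy_series(s$ends$A, environment = s$env)
      eB <- endstate_energy_series(s$ends$B, environment = s$env)
      de <- delta_E(eA, eB)
      dG_env <- ti[[s$env]]$fe$value
      thermo_decomposition(s$env, de$dE, de$sigma_dE,
                           entropy_from(de$dE, dG_env), "toy A>B")
    })
    diff <- bound_minus_unbound(per_env$water, per_env$protein, cyc$ddG$value)
    tab <- data.frame(compound = "toy A>B",
                      dE_water = per_env$water$dE, sigma_water = per_env$water$sigma_dE,
                      TdS_water = per_env$water$TdS,
                      dE_protein = per_env$protein$dE,
                      sigma_protein = per_env$protein$sigma_dE,
                      TdS_protein = per_env$protein$TdS,
                      ddE = diff$ddE, sigma_ddE = diff$sigma_ddE, TddS = diff$TddS)
    utils::write.table(tab, file.path(config$out_dir, "decomposition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(per_env = per_env, diff = diff)
  })
  .stage_log("decompose", t0, verbose, "ddE %.3f, TddS %.3f kJ/mol",
             dec$diff$ddE, dec$diff$TddS)

  ## --- scan -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  scan <- run_stage("scan", {
    tab <- a3_affinity_table()
    stats <- scan_statistics(tab)
    utils::write.table(stats, file.path(config$out_dir, "charge_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats
  })
  .stage_log("scan", t0, verbose, "%d charges scanned", nrow(scan))

  summary <- list(
    seed = config$seed,
    temperature = config$temperature,
    lambda_schedule = config$lambda_schedule,
    ti = lapply(ti, function(t)
      list(value = t$fe$value, sigma = t$fe$sigma,
           refinement_proposals = t$proposals)),
    osp = lapply(osp, function(o)
      list(flank_A = list(value = o$flank_A$value, sigma = o$flank_A$sigma),
           flank_B = list(value = o$flank_B$value, sigma = o$flank_B$sigma))),
    ddG = list(value = cyc$ddG$value, sigma = cyc$ddG$sigma),
    ddG_charge_variant = list(value = cyc$ddG_star$value, sigma = cyc$ddG_star$sigma),
    decomposition = list(ddE = dec$diff$ddE, sigma_ddE = dec$diff$sigma_ddE,
                         TddS = dec$diff$TddS),
    charge_scan = scan)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
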