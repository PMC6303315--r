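# End-to-end orchestration: simulate (or ingest) -> normalize/correct ->
# estimate -> compare, with delimited-table outputs and a run log. These
# functions back the numbered driver scripts under analysis/.

output_header <- function(seed = NA_integer_) {
  pkg <- utils::packageVersion("emuflux")
  c(sprintf("emuflux %s", pkg),
    sprintf("seed: %s", seed),
    sprintf("generated: deterministic given seed"))
}

#' Validate a network file and report
#'
#' @param path Path to a reaction file.
#' @return List with `valid`, `violations`, `n_reactions`,
#'   `n_metabolites`.
#' @export
validate_network <- function(path) {
  net <- tryCatch(parse_network_file(path), error = function(e) e)
  if (inherits(net, "error")) {
    return(list(valid = FALSE, violations = conditionMessage(net),
                n_reactions = NA_integer_, n_metabolites = NA_integer_))
  }
  viol <- validate_atom_balance(net)
  list(valid = length(viol) == 0L, violations = viol,
       n_reactions = length(net$reaction_ids),
       n_metabolites = nrow(net$pools))
}

#' Flux-estimate table in the output dialect
#' @keywords internal
flux_estimate_table <- function(est) {
  rep_rows <- do.call(rbind, lapply(names(est$per_replicate), function(r) {
    v <- unclass(est$per_replicate[[r]])
    data.frame(condition = est$condition, statistic = paste0("replicate_", r),
               flux = names(v), value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  rbind(rep_rows,
        data.frame(condition = est$condition, statistic = "mean",
                   flux = names(est$mean), value = as.numeric(est$mean),
                   stringsAsFactors = FALSE),
        data.frame(condition = est$condition, statistic = "sd",
                   flux = names(est$sd), value = as.numeric(est$sd),
                   stringsAsFactors = FALSE))
}

#' Run the full steady-state MFA pipeline on synthetic scenarios
#'
#' Simulates control and treated datasets, estimates growth-rate-relative
#' fluxes per replicate, compares conditions, and writes the flux table,
#' branch-ratio table and comparison table plus a run log to `out_dir`.
#' Measured-data runs use the same estimation path via
#' [read_mid_table()] + [estimate_fluxes()].
#'
#' @param control,treated `mfa_scenario` objects (treated may be `NULL`
#'   for a single-condition run).
#' @param out_dir Output directory (created if needed).
#' @param tracer A [tracer_spec()].
#' @return Invisible list with `estimates`, `comparison`, `files`.
#' @export
run_mfa <- function(control, treated = NULL, out_dir, tracer = tracer_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "mfa_run.log")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cat(paste0("# ", output_header(control$seed), collapse = "\n"), "\n",
      sep = "", file = log_path)

  scenarios <- Filter(Negate(is.null), list(control, treated))
  estimates <- list()
  ratio_rows <- list()
  for (sc in scenarios) {
    logf("simulating condition '%s' (noise sd %g, %d replicates)",
         sc$name, sc$noise_sd, sc$n_replicates)
    ds <- simulate_mid_dataset(sc, tracer)
    est <- withCallingHandlers(
      estimate_fluxes(ds, sc$network, tracer, sc$name),
      warning = function(w) {
        logf("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    logf("condition '%s': %d usable replicates, %d excluded",
         sc$name, est$n, length(est$excluded))
    estimates[[sc$name]] <- est
    for (r in names(est$per_replicate)) {
      shares <- ratios_from_fluxes(sc$network, est$per_replicate[[r]])
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        condition = sc$name, replicate = r, branch = names(shares),
        share = as.numeric(shares), stringsAsFactors = FALSE)
    }
  }

  files <- character(0)
  flux_tab <- do.call(rbind, lapply(estimates, flux_estimate_table))
  f <- file.path(out_dir, "flux_estimates.csv")
  writeLines(paste0("# ", output_header(control$seed)), f)
  suppressWarnings(utils::write.table(flux_tab, f, append = TRUE, sep = ",",
                                      row.names = FALSE, qmethod = "double"))
  files <- c(files, f)

  f <- file.path(out_dir, "branch_ratios.csv")
  writeLines(paste0("# ", output_header(control$seed)), f)
  suppressWarnings(utils::write.table(do.call(rbind, ratio_rows), f,
                                      append = TRUE, sep = ",",
                                      row.names = FALSE, qmethod = "double"))
  files <- c(files, f)

  comparison <- NULL
  if (length(estimates) == 2L) {
    comparison <- compare_conditions(estimates[[1L]], estimates[[2L]])
    f <- file.path(out_dir, "condition_comparison.csv")
    writeLines(paste0("# ", output_header(control$seed)), f)
    suppressWarnings(utils::write.table(comparison, f, append = TRUE,
                                        sep = ",", row.names = FALSE,
                                        qmethod = "double"))
    files <- c(files, f)
    logf("comparison written for %d fluxes", nrow(comparison))
  }
  invisible(list(estimates = estimates, comparison = comparison,
                 files = c(files, log_path)))
}

#' Run the kinetic flux profiling pipeline on synthetic scenarios
#'
#' Simulates labeling time courses for both conditions, fits the
#' first-order model per reporter, computes relative turnover changes, and
#' writes the kinetic-fit and trajectory tables.
#'
#' @inheritParams run_mfa
#' @param noise_sd Time-course measurement noise.
#' @return Invisible list with `fits`, `trajectories`, `turnover`,
#'   `files`.
#' @export
run_kfp <- function(control, treated = NULL, out_dir, noise_sd = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenarios <- Filter(Negate(is.null), list(control, treated))
  tcs <- do.call(rbind, lapply(scenarios, simulate_timecourse_dataset,
                               noise_sd = noise_sd))
  fits <- fit_timecourse_table(tcs)
  traj <- trajectory_table(tcs)

  turnover <- NULL
  if (length(scenarios) == 2L) {
    rows <- lapply(unique(fits$metabolite), function(met) {
      fc <- fits[fits$metabolite == met & fits$condition ==
                   scenarios[[1L]]$name, ]
      ft <- fits[fits$metabolite == met & fits$condition ==
                   scenarios[[2L]]$name, ]
      ratio <- if (fc$status == "ok" && ft$status == "ok")
        ft$k / fc$k else NA_real_
      data.frame(metabolite = met, k_control = fc$k, k_treated = ft$k,
                 turnover_ratio = ratio, stringsAsFactors = FALSE)
    })
    turnover <- do.call(rbind, rows)
  }

  files <- character(0)
  for (nm in c("kinetic_fits", "trajectories", "turnover_ratios")) {
    obj <- switch(nm, kinetic_fits = fits, trajectories = traj,
                  turnover_ratios = turnover)
    if (is.null(obj)) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    writeLines(paste0("# ", output_header(control$seed)), f)
    suppressWarnings(utils::write.table(obj, f, append = TRUE, sep = ",",
                                        row.names = FALSE,
                                        qmethod = "double"))
    files <- c(files, f)
  }
  invisible(list(fits = fits, trajectories = traj, turnover = turnover,
                 files = files))
}
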