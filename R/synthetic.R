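# Ground-truth flux scenarios and noisy synthetic datasets emulating the
# study design: steady-state MIDs under [U-13C]glucose with replicate
# noise, and first-order labeling time courses.

control_ratios <- function() {
  # branch shares defining the control ground truth (rationale in vignette):
  # de novo serine is a small share of serine supply; glycine is split
  # between serine cleavage and uptake; most aspartate and most nucleotide
  # synthesis is de novo in proliferating cells; pyruvate carboxylase takes
  # the larger share at the OAA convergence in this anabolic sub-network.
  c(SER = 0.10, GLY = 0.50, ASP = 0.70, OAA = 0.60, IMP = 0.85, UMP = 0.80)
}

#' Default measured metabolite panel
#'
#' The pools whose MIDs the emulated LC-HRMS experiment reports; it covers
#' every reporter the branch registry needs. OAA stands in for its
#' measurable proxies (malate/fumarate) in real data.
#'
#' @return Character vector of metabolite ids.
#' @export
default_measured_metabolites <- function() {
  c("3PG", "SER", "GLY", "R5P", "PYR", "OAA", "AKG", "ASP", "IMP", "UMP")
}

#' Build a ground-truth flux scenario
#'
#' A scenario bundles a balanced ground-truth flux vector for the packaged
#' network with the noise model and replicate count of the emulated
#' experiment. The `"phgdh_inhibited"` scenario scales serine synthesis
#' x0.5, PPP-fed de novo nucleotide synthesis x0.4, TCA-derived fluxes
#' x0.4 and leaves serine-to-glycine x1.0, then re-derives the branch
#' shares so that uptake and salvage fluxes re-balance the network exactly
#' (`S v = 0` holds by construction).
#'
#' @param name `"control"`, `"phgdh_inhibited"` or `"custom"`.
#' @param overrides Optional list with any of `ratios` (named branch
#'   shares), `scales` (named list `serine_synthesis`, `ppp`, `tca`,
#'   `ser_gly`), `noise_sd`, `n_replicates`.
#' @param seed Integer seed stored with the scenario; all simulation from
#'   the scenario is reproducible from it.
#' @return Object of class `"mfa_scenario"`: `list(name, network, ratios,
#'   fluxes, scales, noise_sd, n_replicates, seed)`.
#' @export
make_scenario <- function(name = c("control", "phgdh_inhibited", "custom"),
                          overrides = list(), seed = 1L) {
  name <- match.arg(name)
  network <- build_phgdh_network()
  base_ratios <- control_ratios()
  if (!is.null(overrides$ratios)) {
    base_ratios[names(overrides$ratios)] <- unlist(overrides$ratios)
  }
  scales <- list(serine_synthesis = 1, ppp = 1, tca = 1, ser_gly = 1)
  if (name == "phgdh_inhibited") {
    scales <- list(serine_synthesis = 0.5, ppp = 0.4, tca = 0.4, ser_gly = 1)
  }
  if (!is.null(overrides$scales)) {
    scales[names(overrides$scales)] <- overrides$scales
  }

  v0 <- solve_from_ratios(network, base_ratios, "control")
  ratios <- base_ratios
  if (any(unlist(scales) != 1)) {
    b <- network$biomass
    ratios["IMP"] <- scales$ppp * base_ratios[["IMP"]]
    ratios["UMP"] <- scales$ppp * base_ratios[["UMP"]]
    v_imps <- ratios[["IMP"]] * b[["IMP"]]
    v_umps <- ratios[["UMP"]] * b[["UMP"]]
    v_shmt <- scales$ser_gly * v0[["SHMT"]]
    ratios["GLY"] <- v_shmt / (v_imps + b[["GLY"]])
    ratios["SER"] <- scales$serine_synthesis * v0[["SSP"]] /
      (v_shmt + b[["SER"]])
    ratios["ASP"] <- scales$tca * v0[["ASPS"]] / (v_umps + b[["ASP"]])
    # the PC share of OAA production is preserved so PDH scales with PC
    bad <- ratios[!(ratios > 0 & ratios < 1)]
    if (length(bad) > 0L) {
      stop("scaling makes branch share(s) infeasible: ",
           paste(names(bad), collapse = ", "))
    }
  }
  fluxes <- solve_from_ratios(network, ratios, name)
  noise_sd <- if (!is.null(overrides$noise_sd)) overrides$noise_sd else 0.01
  n_replicates <- if (!is.null(overrides$n_replicates))
    overrides$n_replicates else 3L
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name, network = network, ratios = ratios,
                 fluxes = fluxes, scales = scales, noise_sd = noise_sd,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "mfa_scenario")
}

#' @export
print.mfa_scenario <- function(x, ...) {
  cat("MFA scenario '", x$name, "': noise sd ", x$noise_sd, ", ",
      x$n_replicates, " replicates, seed ", x$seed, "\n", sep = "")
  cat("  branch shares:",
      paste(sprintf("%s=%.3f", names(x$ratios), x$ratios), collapse = " "),
      "\n")
  invisible(x)
}

add_mid_noise <- function(v, sd) {
  if (sd == 0) return(v)
  v <- v + stats::rnorm(length(v), 0, sd)
  v[v < 0] <- 0
  if (sum(v) == 0) v[1L] <- 1
  v / sum(v)
}

#' Simulate a noisy steady-state MID dataset from a scenario
#'
#' EMU-simulates the true MIDs of the measured metabolites under the
#' scenario's ground-truth fluxes, then adds i.i.d. Gaussian noise to the
#' fractions of each replicate (clipped at zero and renormalized).
#' Identical seeds give identical datasets.
#'
#' @param scenario An `mfa_scenario`.
#' @param tracer A [tracer_spec()].
#' @param metabolites Metabolites to "measure"; the default covers the
#'   reporter set the branch registry needs.
#' @param seed Optional seed override (default: the scenario's).
#' @return A `mid_set` with `scenario$n_replicates` replicates under
#'   condition `scenario$name`.
#' @export
simulate_mid_dataset <- function(scenario, tracer = tracer_spec(),
                                 metabolites = default_measured_metabolites(),
                                 seed = NULL) {
  truth <- simulate_network_mids(scenario$network, scenario$fluxes, tracer,
                                 targets = metabolites)
  set.seed(if (is.null(seed)) scenario$seed else seed)
  sets <- lapply(seq_len(scenario$n_replicates), function(r) {
    noisy <- lapply(truth, add_mid_noise, sd = scenario$noise_sd)
    mids_to_set(noisy, condition = scenario$name, replicate = r)
  })
  do.call(bind_mid_sets, sets)
}

#' Default relative pool sizes for time-course simulation
#'
#' Relative to the growth-rate flux scale; small glycolytic pools turn
#' over in minutes, amino-acid pools much more slowly.
#'
#' @return Named numeric vector.
#' @export
default_pool_sizes <- function() {
  c("3PG" = 0.5, "SER" = 5, "GLY" = 5, "R5P" = 0.3, "AKG" = 2, "ASP" = 8)
}

#' Default reporter isotopomer (m+k) per time-course metabolite
#'
#' The informative isotopomer of each pool under the pure-tracer model.
#'
#' @return Named integer vector.
#' @export
default_reporters <- function() {
  c("3PG" = 3L, "SER" = 3L, "GLY" = 2L, "R5P" = 5L, "AKG" = 5L, "ASP" = 4L)
}

#' Simulate labeling time courses from a scenario
#'
#' Each reporter follows `F(t) = Finf * (1 - exp(-k t))` with plateau
#' `Finf` equal to the scenario's steady-state reporter fraction and rate
#' constant `k = flux / pool` (turnover of the pool under the scenario's
#' fluxes). Gaussian noise is added per measurement except at `t = 0`
#' (the pre-switch baseline defines zero), clipped to \[0, 1\].
#'
#' @param scenario An `mfa_scenario`.
#' @param pools Named pool sizes (> 0) per reporter metabolite.
#' @param times Sampling times in minutes, including early points.
#' @param reporters Named isotopomer index (m+k) per metabolite.
#' @param noise_sd Measurement noise sd on fractions.
#' @param tracer A [tracer_spec()].
#' @param seed Optional seed override.
#' @return Data frame in the time-course dialect: `metabolite, condition,
#'   replicate, isotopomer, time_min, fraction`.
#' @export
simulate_timecourse_dataset <- function(scenario,
                                        pools = default_pool_sizes(),
                                        times = c(0, 2, 5, 10, 20, 40, 60,
                                                  120),
                                        reporters = default_reporters(),
                                        noise_sd = 0.02,
                                        tracer = tracer_spec(),
                                        seed = NULL) {
  if (any(pools <= 0)) stop("pool sizes must be positive")
  mets <- names(reporters)
  if (!all(mets %in% names(pools))) {
    stop("missing pool size for: ",
         paste(setdiff(mets, names(pools)), collapse = ", "))
  }
  truth <- simulate_network_mids(scenario$network, scenario$fluxes, tracer,
                                 targets = mets)
  fprod <- production_flux(scenario$network, unclass(scenario$fluxes))
  set.seed(if (is.null(seed)) scenario$seed else seed)
  rows <- list()
  for (met in mets) {
    k_idx <- reporters[[met]]
    finf <- truth[[met]][k_idx + 1L]
    k_rate <- fprod[[met]] / pools[[met]]
    for (r in seq_len(scenario$n_replicates)) {
      f <- finf * (1 - exp(-k_rate * times))
      if (noise_sd > 0) {
        noisy <- f + stats::rnorm(length(f), 0, noise_sd)
        noisy[times == 0] <- 0
        f <- pmin(pmax(noisy, 0), 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, condition = scenario$name, replicate = r,
        isotopomer = k_idx, time_min = times, fraction = f,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write the time-course table dialect
#'
#' @param path File path.
#' @return A data frame with the time-course columns.
#' @export
read_timecourse_table <- function(path) {
  if (!file.exists(path)) stop("time-course table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("metabolite", "condition", "replicate", "isotopomer",
            "time_min", "fraction")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("time-course table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_timecourse_table
#' @param tc Time-course data frame.
#' @param header Optional comment lines.
#' @export
write_timecourse_table <- function(tc, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(tc, con, row.names = FALSE)
  invisible(path)
}
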