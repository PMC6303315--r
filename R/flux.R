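# Growth-rate-relative flux estimation: branch-point flux ratios from
# reporter MIDs, analytical solve against the stoichiometric matrix,
# replicate statistics, condition comparison and a least-squares refit.

#' Construct a flux vector
#'
#' @param values Named numeric vector of non-negative fluxes, one per
#'   reaction id, expressed relative to growth rate (biomass flux = 1).
#' @param condition Condition label.
#' @return Object of class `"flux_vector"`.
#' @export
flux_vector <- function(values, condition = NA_character_) {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("flux values must be named by reaction id")
  }
  if (any(values < -1e-9)) {
    stop("negative flux: ",
         paste(names(values)[values < -1e-9], collapse = ", "))
  }
  values[values < 0] <- 0
  structure(values, class = "flux_vector", condition = condition)
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("Growth-rate-relative fluxes",
      if (!is.na(attr(x, "condition")))
        paste0("(", attr(x, "condition"), ")"), ":\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Check steady-state mass balance of a flux vector
#'
#' @param network A `flux_network`.
#' @param fluxes A `flux_vector` or named numeric vector.
#' @param tol Tolerance on `max |S v|`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_mass_balance <- function(network, fluxes, tol = 1e-8) {
  S <- stoichiometric_matrix(network)
  v <- c(unclass(fluxes)[head(colnames(S), -1L)], biomass = 1)
  resid <- max(abs(S %*% v))
  if (is.na(resid) || resid > tol) {
    stop(sprintf("flux vector violates mass balance (max |Sv| = %.3g)",
                 resid))
  }
  invisible(TRUE)
}

branch_reporter_env <- function(get_fraction) {
  # evaluation environment for BRANCH expressions; division is guarded by
  # an identifiability floor on the denominator
  env <- new.env(parent = baseenv())
  env$m <- function(met, k) get_fraction(met, k)
  env$m0 <- function(met) get_fraction(met, 0L)
  env$L <- function(met) 1 - get_fraction(met, 0L)
  env[["/"]] <- function(num, den) {
    if (!is.finite(den) || abs(den) < 1e-4) return(NaN)
    base::"/"(num, den)
  }
  env
}

#' Solve branch-point flux ratios from measured MIDs
#'
#' Evaluates each reporter relation of the network's branch registry on
#' one replicate's MIDs. Each registered branch names the share of one
#' producing reaction of a two-producer pool; the other producer receives
#' the complement. Shares outside \[0, 1\] (measurement noise) are clipped
#' with a warning; relations whose reporter denominator falls below the
#' identifiability floor (1e-4) are flagged unidentifiable (`NA` share).
#'
#' @param mids A `mid_set`.
#' @param network A `flux_network` with a branch registry.
#' @param tracer A [tracer_spec()] (the shipped registry expressions assume
#'   the default pure \[U-13C\]glucose tracer; kept for interface symmetry).
#' @param condition,replicate Entry keys into `mids`.
#' @return List of `flux_ratio` objects: `list(pool, shares, identifiable,
#'   clipped)` with shares named by reaction and summing to one.
#' @export
compute_branch_ratios <- function(mids, network, tracer = tracer_spec(),
                                  condition, replicate) {
  get_fraction <- function(met, k) {
    v <- get_mid(mids, met, condition, replicate)
    if (k + 1L > length(v)) 0 else v[k + 1L]
  }
  env <- branch_reporter_env(get_fraction)
  lapply(network$branches, function(b) {
    prods <- producers_of(network, b$pool)
    if (length(prods) != 2L) {
      stop("branch registry pool ", b$pool,
           " must have exactly 2 producers, found ", length(prods))
    }
    other <- setdiff(prods, b$flux)
    r <- eval(b$expr, env)
    identifiable <- is.finite(r)
    clipped <- FALSE
    if (identifiable && (r < 0 || r > 1)) {
      warning(sprintf("branch %s: share %.4f outside [0,1], clipped",
                      b$pool, r))
      r <- min(max(r, 0), 1)
      clipped <- TRUE
    }
    structure(list(pool = b$pool,
                   shares = stats::setNames(c(r, 1 - r), c(b$flux, other)),
                   identifiable = identifiable, clipped = clipped),
              class = "flux_ratio")
  })
}

ratio_constraints_from_values <- function(network, ratio_values) {
  # named share values keyed by branch pool -> list of flux_ratio objects
  lapply(network$branches, function(b) {
    prods <- producers_of(network, b$pool)
    other <- setdiff(prods, b$flux)
    r <- ratio_values[[b$pool]]
    structure(list(pool = b$pool,
                   shares = stats::setNames(c(r, 1 - r), c(b$flux, other)),
                   identifiable = TRUE, clipped = FALSE),
              class = "flux_ratio")
  })
}

#' Solve growth-rate-relative fluxes analytically
#'
#' Combines the steady-state balance rows of the stoichiometric matrix
#' (with the biomass flux fixed at one) with one linear constraint per
#' branch ratio and solves the resulting square (or consistently
#' overdetermined) linear system exactly via QR. No iteration is involved.
#'
#' @param ratios List of `flux_ratio` objects (all identifiable).
#' @param network A `flux_network`.
#' @param condition Condition label attached to the result.
#' @return A `flux_vector` satisfying `S v = 0` within 1e-8 and every
#'   input ratio.
#' @export
solve_fluxes_analytical <- function(ratios, network,
                                    condition = NA_character_) {
  if (any(!vapply(ratios, `[[`, TRUE, "identifiable"))) {
    bad <- vapply(ratios, `[[`, "", "pool")[
      !vapply(ratios, `[[`, TRUE, "identifiable")]
    stop("unidentifiable branch ratio(s): ", paste(bad, collapse = ", "))
  }
  S <- stoichiometric_matrix(network)
  rids <- head(colnames(S), -1L)
  A <- S[, rids, drop = FALSE]
  b <- -S[, "biomass"]
  for (r in ratios) {
    prods <- names(r$shares)
    # (1 - share_i) v_i - share_i * sum(v_others) = 0 for the first producer
    row <- stats::setNames(numeric(length(rids)), rids)
    row[prods[1L]] <- 1 - r$shares[1L]
    row[prods[-1L]] <- -r$shares[1L]
    A <- rbind(A, row)
    b <- c(b, 0)
  }
  qr_A <- qr(A)
  if (qr_A$rank < length(rids)) {
    stop("underdetermined flux system: rank ", qr_A$rank, " < ",
         length(rids), " fluxes; add branch constraints")
  }
  v <- qr.coef(qr_A, b)
  resid <- max(abs(A %*% v - b))
  if (resid > 1e-6) {
    stop(sprintf("inconsistent constraints (max residual %.3g)", resid))
  }
  if (any(v < -1e-8)) {
    stop("infeasible ratios: negative solved flux for ",
         paste(rids[v < -1e-8], collapse = ", "))
  }
  v[v < 0] <- 0
  fv <- flux_vector(stats::setNames(as.numeric(v), rids), condition)
  check_mass_balance(network, fv)
  fv
}

#' Solve fluxes from named branch-share values
#'
#' Convenience front-end to [solve_fluxes_analytical()] taking shares
#' keyed by branch pool (e.g. `c(SER = 0.1, GLY = 0.5, ...)`).
#'
#' @param network A `flux_network`.
#' @param ratio_values Named numeric vector/list, one share in (0, 1) per
#'   registered branch, keyed by branch pool.
#' @param condition Condition label.
#' @return A `flux_vector`.
#' @export
solve_from_ratios <- function(network, ratio_values,
                              condition = NA_character_) {
  pools <- vapply(network$branches, `[[`, "", "pool")
  missing <- setdiff(pools, names(ratio_values))
  if (length(missing) > 0L) {
    stop("missing ratio values for branch(es): ",
         paste(missing, collapse = ", "))
  }
  solve_fluxes_analytical(
    ratio_constraints_from_values(network, ratio_values), network, condition)
}

#' Re-derive branch shares from a solved flux vector
#'
#' @param network A `flux_network`.
#' @param fluxes A `flux_vector`.
#' @return Named shares keyed by branch pool.
#' @export
ratios_from_fluxes <- function(network, fluxes) {
  v <- unclass(fluxes)
  out <- vapply(network$branches, function(b) {
    prods <- producers_of(network, b$pool)
    v[[b$flux]] / sum(v[prods])
  }, 0)
  stats::setNames(out, vapply(network$branches, `[[`, "", "pool"))
}

#' Estimate fluxes per replicate with mean and sd
#'
#' Runs ratio estimation plus the analytical solve for every replicate of
#' a condition; replicates with unidentifiable branches are excluded with
#' a message. Mean and standard deviation are computed across the usable
#' replicates, as for the three biological replicates of the emulated
#' experiment.
#'
#' @inheritParams compute_branch_ratios
#' @param replicates Optional replicate ids (default: all present).
#' @return Object of class `"flux_estimate"`: `list(condition, per_replicate,
#'   mean, sd, n, excluded)`.
#' @export
estimate_fluxes <- function(mids, network, tracer = tracer_spec(),
                            condition, replicates = NULL) {
  if (is.null(replicates)) replicates <- replicates_of(mids, condition)
  if (length(replicates) == 0L) {
    stop("no replicates found for condition ", condition)
  }
  per <- list()
  excluded <- character(0)
  for (r in replicates) {
    ratios <- compute_branch_ratios(mids, network, tracer, condition, r)
    if (any(!vapply(ratios, `[[`, TRUE, "identifiable"))) {
      message("replicate ", r, " excluded: unidentifiable branch ratio")
      excluded <- c(excluded, as.character(r))
      next
    }
    fit <- tryCatch(
      solve_fluxes_analytical(ratios, network, condition),
      error = function(e) {
        message("replicate ", r, " excluded: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) per[[as.character(r)]] <- fit
  }
  if (length(per) == 0L) stop("no usable replicate for ", condition)
  mat <- do.call(rbind, lapply(per, unclass))
  structure(list(condition = condition,
                 per_replicate = per,
                 mean = colMeans(mat),
                 sd = if (nrow(mat) > 1L) apply(mat, 2, stats::sd)
                      else stats::setNames(rep(0, ncol(mat)), colnames(mat)),
                 n = nrow(mat),
                 excluded = excluded),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat("Flux estimate for condition '", x$condition, "' (n = ", x$n, "):\n",
      sep = "")
  print(data.frame(flux = names(x$mean), mean = round(x$mean, 5),
                   sd = round(x$sd, 5), row.names = NULL))
  invisible(x)
}

#' Compare flux estimates between two conditions
#'
#' Per-flux ratio (treated over control) plus an unpaired two-sample
#' Student's t-test on the per-replicate fluxes.
#'
#' @param control,treated `flux_estimate` objects over the same network.
#' @return Data frame with columns `flux`, `control_mean`, `treated_mean`,
#'   `ratio`, `t`, `p`.
#' @export
compare_conditions <- function(control, treated) {
  if (!identical(names(control$mean), names(treated$mean))) {
    stop("flux names differ between the two estimates")
  }
  a <- do.call(rbind, lapply(control$per_replicate, unclass))
  b <- do.call(rbind, lapply(treated$per_replicate, unclass))
  out <- lapply(names(control$mean), function(f) {
    x <- a[, f]; y <- b[, f]
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
      tt <- list(statistic = if (abs(mean(x) - mean(y)) < 1e-12) 0 else Inf,
                 p.value = if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
    } else {
      tt <- stats::t.test(y, x, var.equal = TRUE)
    }
    data.frame(flux = f, control_mean = mean(x), treated_mean = mean(y),
               ratio = if (mean(x) > 0) mean(y) / mean(x) else NA_real_,
               t = as.numeric(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Least-squares flux refit against measured MIDs
#'
#' Independent cross-check of the analytical route: parameterizes the flux
#' space by the registered branch shares, reconstructs a balanced flux
#' vector for each candidate, simulates the target MIDs through the EMU
#' cascade, and minimizes the squared deviation from the measured
#' (replicate-averaged) MIDs with L-BFGS-B. On noise-free data this agrees
#' with [solve_fluxes_analytical()] to the optimizer tolerance.
#'
#' @inheritParams estimate_fluxes
#' @param n_starts Number of optimizer starts (first start: uniform shares
#'   0.5; further starts: random in (0.05, 0.95) using `seed`).
#' @param seed Seed for the random restarts.
#' @return A `flux_vector` with attributes `objective` (residual sum of
#'   squares) and `convergence`.
#' @export
fit_fluxes_least_squares <- function(mids, network, tracer = tracer_spec(),
                                     condition, n_starts = 3L, seed = 1L) {
  reps <- replicates_of(mids, condition)
  mets <- intersect(unique(mids$metabolite),
                    network$pools$id[network$pools$role != "source"])
  meas <- lapply(mets, function(met) {
    mat <- do.call(rbind, lapply(reps, function(r)
      get_mid(mids, met, condition, r)))
    colMeans(mat)
  })
  names(meas) <- mets
  system <- emu_decompose(network, mets)
  pools <- vapply(network$branches, `[[`, "", "pool")

  objective <- function(theta) {
    rv <- stats::setNames(theta, pools)
    fv <- tryCatch(solve_from_ratios(network, rv, condition),
                   error = function(e) NULL)
    if (is.null(fv)) return(1e6)
    sim <- tryCatch(simulate_mids(system, fv, tracer),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    sum(vapply(mets, function(met)
      sum((sim[[met]] - meas[[met]])^2), 0))
  }

  starts <- list(rep(0.5, length(pools)))
  if (n_starts > 1L) {
    rng <- local({set.seed(seed); stats::runif((n_starts - 1L) * length(pools),
                                               0.05, 0.95)})
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- rng[(i - 1L) * length(pools) + seq_along(pools)]
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "L-BFGS-B",
                        lower = rep(1e-6, length(pools)),
                        upper = rep(1 - 1e-6, length(pools)),
                        control = list(factr = 1e3, maxit = 500L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value > 1e5) {
    stop("least-squares refit failed to find a feasible optimum")
  }
  fv <- solve_from_ratios(network, stats::setNames(best$par, pools),
                          condition)
  attr(fv, "objective") <- best$value
  attr(fv, "convergence") <- best$convergence
  fv
}
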