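# Elementary metabolite unit (EMU) decomposition and steady-state MID
# simulation, plus a full positional-isotopomer brute-force oracle.
#
# An EMU is a subset of a metabolite's carbons; its mass distribution obeys
# a linear balance once all strictly smaller EMUs are known, so the network
# is solved size by size with dense direct factorizations (systems here are
# tiny, a few dozen EMUs per size at most).

emu_key <- function(met, pos) paste0(met, "|", paste(pos, collapse = ","))

#' Tracer specification
#'
#' Describes the labeled substrate: which medium metabolite carries the
#' tracer, the per-carbon 13C labeling probability (isotopic purity), and
#' the unlabeled fraction of that substrate pool. The default corresponds
#' to pure [U-13C]glucose.
#'
#' @param metabolite Source metabolite id carrying the label.
#' @param purity Per-carbon labeling probability in \[0, 1\].
#' @param unlabeled_fraction Fraction of the substrate pool that is
#'   unlabeled (e.g. residual pre-switch material).
#' @param label_probs Optional explicit per-carbon probabilities; overrides
#'   `purity`.
#' @return Object of class `"tracer_spec"`.
#' @export
tracer_spec <- function(metabolite = "GLC", purity = 1,
                        unlabeled_fraction = 0, label_probs = NULL) {
  if (!is.null(label_probs) && any(label_probs < 0 | label_probs > 1)) {
    stop("label probabilities must lie in [0, 1]")
  }
  if (purity < 0 || purity > 1 || unlabeled_fraction < 0 ||
      unlabeled_fraction > 1) {
    stop("purity and unlabeled_fraction must lie in [0, 1]")
  }
  structure(list(metabolite = metabolite, purity = purity,
                 unlabeled_fraction = unlabeled_fraction,
                 label_probs = label_probs), class = "tracer_spec")
}

tracer_probs <- function(tracer, n_carbons) {
  p <- tracer$label_probs
  if (is.null(p)) p <- rep(tracer$purity, n_carbons)
  if (length(p) != n_carbons) {
    stop("tracer label_probs length does not match substrate carbon count")
  }
  p
}

# MID of a source-pool EMU given the tracer spec (delta at m+0 for every
# source other than the tracer substrate).
source_emu_mid <- function(met, pos, tracer, network) {
  s <- length(pos)
  if (!identical(met, tracer$metabolite)) {
    return(c(1, rep(0, s)))
  }
  p <- tracer_probs(tracer, n_carbons_of(network, met))[pos]
  m <- 1
  for (pi in p) m <- convolve_mids(m, c(1 - pi, pi))
  u <- tracer$unlabeled_fraction
  u * c(1, rep(0, s)) + (1 - u) * m
}

#' Decompose a network into the EMU system reaching a set of targets
#'
#' Walks backwards from the target EMUs through every atom-map variant,
#' recording for each EMU the flux-weighted inflow terms: a single source
#' EMU (carbon transfer) or a convolution of several smaller EMUs
#' (condensation). The resulting system is stratified by EMU size;
#' EMUs are ordered lexicographically by (metabolite, positions) so the
#' balance matrices are reproducible.
#'
#' @param network A `flux_network`.
#' @param targets Character vector of metabolite ids (full-molecule EMUs)
#'   or a list of `list(met, pos)` EMU specifications.
#' @return Object of class `"emu_system"`.
#' @export
emu_decompose <- function(network, targets) {
  if (is.character(targets)) {
    targets <- lapply(targets, function(m)
      list(met = m, pos = seq_len(n_carbons_of(network, m))))
  }
  target_keys <- vapply(targets, function(t) emu_key(t$met, t$pos), "")

  emus <- list()       # key -> list(met, pos)
  inflows <- list()    # key -> list of list(rid, weight, parts = keys)
  queue <- targets
  seen <- character(0)

  while (length(queue) > 0L) {
    e <- queue[[1L]]; queue <- queue[-1L]
    key <- emu_key(e$met, e$pos)
    if (key %in% seen) next
    seen <- c(seen, key)
    emus[[key]] <- e
    if (identical(role_of(network, e$met), "source")) next

    terms <- list()
    for (v in network$variants) {
      for (pt in v$products) {
        if (pt$met != e$met) next
        letters <- pt$map[e$pos]
        parts <- list()
        for (st in v$substrates) {
          qpos <- which(st$map %in% letters)
          if (length(qpos) == 0L) next
          parts[[length(parts) + 1L]] <- list(met = st$met, pos = sort(qpos))
        }
        if (sum(vapply(parts, function(p) length(p$pos), 0L)) !=
            length(e$pos)) {
          stop(sprintf("atom map of %s does not cover EMU %s", v$rid, key))
        }
        # lexicographic ordering of convolution parts for reproducibility
        ord <- order(vapply(parts, function(p) emu_key(p$met, p$pos), ""))
        parts <- parts[ord]
        terms[[length(terms) + 1L]] <- list(
          rid = v$rid, weight = v$weight,
          parts = vapply(parts, function(p) emu_key(p$met, p$pos), ""))
        for (p in parts) queue[[length(queue) + 1L]] <- p
      }
    }
    if (length(terms) == 0L) {
      stop("EMU ", key, " is unreachable: its metabolite has no producer")
    }
    inflows[[key]] <- terms
  }

  sizes <- vapply(emus, function(e) length(e$pos), 0L)
  ord <- order(sizes, names(emus))
  emus <- emus[ord]
  structure(list(network = network, emus = emus,
                 inflows = inflows, targets = target_keys),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  sizes <- vapply(x$emus, function(e) length(e$pos), 0L)
  cat("EMU system:", length(x$emus), "EMUs, sizes",
      paste(sort(unique(sizes)), collapse = "/"),
      "->", length(x$targets), "targets\n")
  invisible(x)
}

production_flux <- function(network, fluxes) {
  f <- stats::setNames(numeric(nrow(network$pools)), network$pools$id)
  for (v in network$variants) {
    fv <- v$weight * fluxes[[v$rid]]
    for (pt in v$products) f[pt$met] <- f[pt$met] + fv
  }
  f
}

check_fluxes <- function(system, fluxes) {
  rids <- unique(unlist(lapply(system$inflows, function(tt)
    vapply(tt, `[[`, "", "rid"))))
  missing <- setdiff(rids, names(fluxes))
  if (length(missing) > 0L) {
    stop("flux vector lacks values for: ", paste(missing, collapse = ", "))
  }
  if (any(fluxes[rids] < 0)) {
    stop("negative flux for: ",
         paste(rids[fluxes[rids] < 0], collapse = ", "))
  }
  invisible(rids)
}

#' Simulate steady-state MIDs through the EMU cascade
#'
#' Solves the size-stratified EMU balance systems for the given flux
#' vector and tracer and returns the MID of every target EMU. Steady-state
#' MIDs are invariant to rescaling all fluxes by a positive constant.
#'
#' @param system An `emu_system` from [emu_decompose()].
#' @param fluxes Named numeric vector of non-negative reaction fluxes
#'   (`flux_vector` objects work as-is).
#' @param tracer A [tracer_spec()].
#' @return Named list of MID vectors keyed by target metabolite (or EMU
#'   key for sub-molecule targets); each sums to one within 1e-9.
#' @export
simulate_mids <- function(system, fluxes, tracer = tracer_spec()) {
  network <- system$network
  fluxes <- unclass(fluxes)
  check_fluxes(system, fluxes)
  fprod <- production_flux(network, fluxes)

  mids <- list()
  is_source <- vapply(system$emus, function(e)
    identical(role_of(network, e$met), "source"), TRUE)
  for (key in names(system$emus)[is_source]) {
    e <- system$emus[[key]]
    mids[[key]] <- source_emu_mid(e$met, e$pos, tracer, network)
  }

  sizes <- vapply(system$emus, function(e) length(e$pos), 0L)
  for (s in sort(unique(sizes[!is_source]))) {
    keys <- names(system$emus)[sizes == s & !is_source]
    n <- length(keys)
    A <- matrix(0, n, n, dimnames = list(keys, keys))
    B <- matrix(0, n, s + 1L)
    for (ti in seq_len(n)) {
      key <- keys[ti]
      e <- system$emus[[key]]
      A[ti, ti] <- fprod[[e$met]]
      for (term in system$inflows[[key]]) {
        fv <- term$weight * fluxes[[term$rid]]
        if (length(term$parts) == 1L && term$parts %in% keys) {
          A[ti, term$parts] <- A[ti, term$parts] - fv
        } else {
          y <- 1
          for (pk in term$parts) {
            if (is.null(mids[[pk]])) {
              stop("internal: EMU ", pk, " not yet solved")
            }
            y <- convolve_mids(y, mids[[pk]])
          }
          B[ti, ] <- B[ti, ] + fv * y
        }
      }
    }
    X <- tryCatch(solve(A, B), error = function(err) {
      bad <- keys[which.min(abs(diag(A)))]
      stop("singular EMU balance at size ", s,
           " (disconnected or zero-influx EMU near ", bad, "): ",
           conditionMessage(err), call. = FALSE)
    })
    for (ti in seq_len(n)) {
      v <- X[ti, ]
      if (any(v < -1e-9) || abs(sum(v) - 1) > 1e-9) {
        stop("EMU solution for ", keys[ti], " is not a valid MID")
      }
      v[v < 0] <- 0
      mids[[keys[ti]]] <- v / sum(v)
    }
  }

  out <- mids[system$targets]
  nm <- vapply(system$targets, function(k) {
    e <- system$emus[[k]]
    if (length(e$pos) == n_carbons_of(network, e$met)) e$met else k
  }, "")
  stats::setNames(out, nm)
}

#' Simulate MIDs of whole metabolites directly from a network
#'
#' Convenience wrapper: decomposes and simulates in one call.
#'
#' @inheritParams emu_decompose
#' @inheritParams simulate_mids
#' @return Named list of MID vectors.
#' @export
simulate_network_mids <- function(network, fluxes, tracer = tracer_spec(),
                                  targets = NULL) {
  if (is.null(targets)) {
    targets <- network$pools$id[network$pools$role != "source"]
  }
  simulate_mids(emu_decompose(network, targets), fluxes, tracer)
}

# ---------------------------------------------------------------------------
# Brute-force positional-isotopomer oracle.

bit_pattern <- function(states, pos) {
  # value of the |pos|-bit pattern formed by carbons `pos` across `states`
  out <- integer(length(states))
  for (j in seq_along(pos)) {
    out <- out + bitwShiftL(bitwAnd(bitwShiftR(states, pos[j] - 1L), 1L),
                            j - 1L)
  }
  out
}

marginalize_states <- function(dist, pos) {
  pat <- bit_pattern(seq_along(dist) - 1L, pos)
  as.numeric(tapply(dist, factor(pat, levels = 0:(2^length(pos) - 1L)), sum))
}

#' Brute-force steady-state isotopomer enumeration
#'
#' Independent verification oracle for [simulate_mids()]: solves the full
#' positional-isotopomer balance of every non-source metabolite by
#' fixed-point iteration over the 2^n labeling states, then marginalizes to
#' mass distributions. Intended for networks whose largest metabolite has
#' at most ~12 carbons.
#'
#' @inheritParams simulate_network_mids
#' @param targets Character vector of metabolite ids.
#' @param tol Convergence tolerance on the sup-norm change per sweep.
#' @param max_iter Iteration cap.
#' @return Named list of MID vectors, one per target.
#' @export
enumerate_isotopomers_bruteforce <- function(network, fluxes,
                                             tracer = tracer_spec(),
                                             targets = NULL,
                                             tol = 1e-14,
                                             max_iter = 20000L) {
  if (is.null(targets)) {
    targets <- network$pools$id[network$pools$role != "source"]
  }
  fluxes <- unclass(fluxes)
  ncar <- stats::setNames(network$pools$n_carbons, network$pools$id)
  if (any(ncar > 12L)) {
    stop("metabolite with more than 12 carbons: state space too large, ",
         "use the EMU path")
  }
  roles <- stats::setNames(network$pools$role, network$pools$id)
  fprod <- production_flux(network, fluxes)

  dist <- list()
  for (id in names(ncar)) {
    n <- ncar[[id]]
    d <- numeric(2^n); d[1L] <- 1
    if (roles[[id]] == "source" && identical(id, tracer$metabolite)) {
      p <- tracer_probs(tracer, n)
      states <- 0:(2^n - 1L)
      d <- vapply(states, function(s) {
        bits <- bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L)
        prod(ifelse(bits == 1L, p, 1 - p))
      }, 0)
      u <- tracer$unlabeled_fraction
      d <- (1 - u) * d
      d[1L] <- d[1L] + u
    }
    dist[[id]] <- d
  }

  # precompute delivery plans: per variant, per product term, the substrate
  # instances with their product/substrate position alignments
  plans <- list()
  for (v in network$variants) {
    for (pt in v$products) {
      if (roles[[pt$met]] == "source") next
      instances <- list()
      for (st in v$substrates) {
        ppos <- which(pt$map %in% st$map)
        if (length(ppos) == 0L) next
        qpos <- match(pt$map[ppos], st$map)
        instances[[length(instances) + 1L]] <-
          list(met = st$met, ppos = ppos, qpos = qpos)
      }
      nstate <- 2^ncar[[pt$met]]
      # index of each product state into each instance's marginal table
      idx <- lapply(instances, function(ins)
        bit_pattern(0:(nstate - 1L), ins$ppos) + 1L)
      plans[[length(plans) + 1L]] <- list(
        rid = v$rid, weight = v$weight, met = pt$met,
        instances = instances, idx = idx)
    }
  }

  unknown <- names(ncar)[roles != "source"]
  produced <- unknown[fprod[unknown] > 0]
  if (!all(targets %in% names(ncar))) {
    stop("unknown target metabolite(s): ",
         paste(setdiff(targets, names(ncar)), collapse = ", "))
  }

  for (iter in seq_len(max_iter)) {
    acc <- lapply(dist[produced], function(d) numeric(length(d)))
    for (pl in plans) {
      if (!(pl$met %in% produced)) next
      fv <- pl$weight * fluxes[[pl$rid]]
      if (fv == 0) next
      deliv <- rep(1, length(acc[[pl$met]]))
      for (j in seq_along(pl$instances)) {
        ins <- pl$instances[[j]]
        # bit j of the marginal pattern corresponds to qpos[j], which is
        # aligned elementwise with ppos[j] used to build the idx table
        marg <- marginalize_states(dist[[ins$met]], ins$qpos)
        deliv <- deliv * marg[pl$idx[[j]]]
      }
      acc[[pl$met]] <- acc[[pl$met]] + fv * deliv
    }
    delta <- 0
    for (id in produced) {
      newd <- acc[[id]] / fprod[[id]]
      delta <- max(delta, max(abs(newd - dist[[id]])))
      dist[[id]] <- newd
    }
    if (delta < tol) break
    if (iter == max_iter) {
      warning("brute-force iteration hit max_iter without full convergence")
    }
  }

  out <- lapply(targets, function(id) {
    n <- ncar[[id]]
    pop <- vapply(0:(2^n - 1L), function(s)
      sum(bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L)), 0L)
    as.numeric(tapply(dist[[id]], factor(pop, levels = 0:n), sum))
  })
  stats::setNames(out, targets)
}
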