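# Atom-mapped metabolic network: plain-text format, validation, stoichiometry.
#
# File grammar (one statement per line, '#' starts a comment):
#   SOURCE <id> [n_carbons]     medium pool; labeling set by the tracer spec
#                               (unlabeled unless it is the tracer substrate)
#   SINK <id> [n_carbons]       intracellular pool excluded from steady-state
#                               balance rows (overflow/biomass-side pool);
#                               labeling is still tracked if it is produced
#   BIOMASS <id> <coeff>        drain of <id> into biomass per unit growth
#   <rid>[<w>]: <lhs> -> <rhs>  reaction; terms "MET (map)" joined by '+';
#                               lowercase letters name carbons 1..n left to
#                               right; substrate and product letter multisets
#                               must match. [<w>] is an optional variant
#                               weight: several lines sharing <rid> define
#                               weighted atom-map variants of one reaction
#                               (used for symmetric-intermediate scrambling).
#   BRANCH <pool> <rid> : <expr> reporter relation giving the flux share of
#                               <rid> among the producers of <pool>; <expr>
#                               is an R expression over m(met, k), m0(met)
#                               and L(met) (labeled fraction 1 - m+0).
#
# Stoichiometric multiplicity is written by repeating a term with distinct
# maps (e.g. one G6P producing two 3PG terms); numeric coefficients are not
# part of the grammar because an atom map names each carbon exactly once.

parse_term_list <- function(text, line_no) {
  parts <- strsplit(text, "+", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    mm <- regmatches(p, regexec("^(\\S+)\\s*\\(([a-z]+)\\)$", p))[[1]]
    if (length(mm) != 3L) {
      stop(sprintf("line %d: malformed term '%s' (expected 'MET (map)')",
                   line_no, p), call. = FALSE)
    }
    out[[length(out) + 1L]] <- list(met = mm[2], map = strsplit(mm[3], "")[[1]])
  }
  if (length(out) == 0L) {
    stop(sprintf("line %d: empty side of reaction", line_no), call. = FALSE)
  }
  out
}

#' Parse an atom-mapped reaction network from text lines
#'
#' @param lines Character vector, one statement per line.
#' @return A validated object of class `"flux_network"`.
#' @keywords internal
parse_network_lines <- function(lines) {
  raw <- sub("#.*$", "", lines)
  declared <- list()     # id -> list(role, n_carbons or NA)
  biomass <- numeric(0)
  variants <- list()     # each: rid, weight, substrates, products
  branches <- list()     # each: pool, flux, expr (language), text
  decl_order <- character(0)

  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (line == "") next
    if (grepl("^SOURCE\\s", line) || grepl("^SINK\\s", line)) {
      tok <- strsplit(line, "\\s+")[[1]]
      if (!length(tok) %in% c(2L, 3L)) {
        stop(sprintf("line %d: malformed declaration '%s'", i, line))
      }
      nc <- if (length(tok) == 3L) as.integer(tok[3]) else NA_integer_
      role <- if (tok[1] == "SOURCE") "source" else "sink"
      declared[[tok[2]]] <- list(role = role, n_carbons = nc)
      decl_order <- c(decl_order, tok[2])
    } else if (grepl("^BIOMASS\\s", line)) {
      tok <- strsplit(line, "\\s+")[[1]]
      if (length(tok) != 3L || is.na(suppressWarnings(as.numeric(tok[3])))) {
        stop(sprintf("line %d: malformed BIOMASS line '%s'", i, line))
      }
      coeff <- as.numeric(tok[3])
      if (coeff < 0) stop(sprintf("line %d: negative biomass coefficient", i))
      biomass[tok[2]] <- coeff
    } else if (grepl("^BRANCH\\s", line)) {
      mm <- regmatches(line,
        regexec("^BRANCH\\s+(\\S+)\\s+(\\S+)\\s*:\\s*(.+)$", line))[[1]]
      if (length(mm) != 4L) {
        stop(sprintf("line %d: malformed BRANCH line '%s'", i, line))
      }
      expr <- tryCatch(str2lang(mm[4]),
                       error = function(e) stop(sprintf(
                         "line %d: unparsable branch expression '%s'",
                         i, mm[4]), call. = FALSE))
      branches[[length(branches) + 1L]] <-
        list(pool = mm[2], flux = mm[3], expr = expr, text = trimws(mm[4]))
    } else if (grepl("->", line, fixed = TRUE)) {
      mm <- regmatches(line,
        regexec("^(\\S+?)(\\[([0-9.eE+-]+)\\])?\\s*:\\s*(.+?)\\s*->\\s*(.+)$",
                line))[[1]]
      if (length(mm) != 6L) {
        stop(sprintf("line %d: malformed reaction line '%s'", i, line))
      }
      w <- if (mm[4] == "" && mm[3] == "") 1 else as.numeric(mm[4])
      if (mm[3] == "") w <- 1
      variants[[length(variants) + 1L]] <- list(
        rid = mm[2], weight = w,
        substrates = parse_term_list(mm[5], i),
        products = parse_term_list(mm[6], i))
    } else {
      stop(sprintf("line %d: unrecognized statement '%s'", i, line))
    }
  }
  if (length(variants) == 0L) stop("network file declares no reactions")

  # infer pools and carbon counts from the maps
  pools <- list()
  note_pool <- function(pools, met, n) {
    if (is.null(pools[[met]])) {
      pools[[met]] <- n
    } else if (pools[[met]] != n) {
      stop(sprintf("metabolite %s used with %d and %d carbons",
                   met, pools[[met]], n))
    }
    pools
  }
  for (v in variants) {
    for (tm in c(v$substrates, v$products)) {
      pools <- note_pool(pools, tm$met, length(tm$map))
    }
  }
  for (id in names(declared)) {
    nc <- declared[[id]]$n_carbons
    if (!is.na(nc)) {
      if (is.null(pools[[id]])) {
        pools <- note_pool(pools, id, nc)
      } else if (pools[[id]] != nc) {
        stop(sprintf("declared %d carbons for %s but maps use %d",
                     nc, id, pools[[id]]))
      }
    }
    if (is.null(pools[[id]])) {
      stop(sprintf("declared metabolite %s never appears in a reaction ",
                   id), "and has no carbon count")
    }
  }
  roles <- vapply(names(pools), function(id) {
    if (!is.null(declared[[id]])) declared[[id]]$role else "balanced"
  }, character(1))

  net <- structure(list(
    pools = data.frame(id = names(pools),
                       n_carbons = unlist(pools, use.names = FALSE),
                       role = unname(roles),
                       stringsAsFactors = FALSE),
    variants = variants,
    reaction_ids = unique(vapply(variants, `[[`, "", "rid")),
    biomass = biomass,
    branches = branches
  ), class = "flux_network")

  viol <- validate_atom_balance(net)
  if (length(viol) > 0L) {
    stop("atom-balance violations:\n  ", paste(viol, collapse = "\n  "))
  }
  net
}

#' Parse an atom-mapped reaction network file
#'
#' Reads the plain-text carbon-transition dialect documented at the top of
#' this file (SOURCE/SINK/BIOMASS/BRANCH headers plus one reaction per
#' line) and returns a validated network.
#'
#' @param path Path to a network file.
#' @return An object of class `"flux_network"` with components `pools`
#'   (data frame id/n_carbons/role), `variants` (atom-map variants; several
#'   weighted variants may share a reaction id), `reaction_ids`, `biomass`
#'   (named drain coefficients per unit growth) and `branches` (reporter
#'   registry).
#' @export
parse_network_file <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parse_network_lines(lines)
}

#' @export
print.flux_network <- function(x, ...) {
  cat("Atom-mapped metabolic network:",
      length(x$reaction_ids), "reactions,",
      nrow(x$pools), "metabolites\n")
  cat("  balanced:", sum(x$pools$role == "balanced"),
      " source:", sum(x$pools$role == "source"),
      " sink:", sum(x$pools$role == "sink"), "\n")
  cat("  biomass drains:", paste(names(x$biomass), collapse = ", "), "\n")
  cat("  branch registry:",
      paste(vapply(x$branches, `[[`, "", "pool"), collapse = ", "), "\n")
  invisible(x)
}

n_carbons_of <- function(network, met) {
  i <- match(met, network$pools$id)
  if (is.na(i)) stop("unknown metabolite: ", met)
  network$pools$n_carbons[i]
}

role_of <- function(network, met) {
  network$pools$role[match(met, network$pools$id)]
}

#' Check carbon-atom conservation of every reaction variant
#'
#' @param network A `flux_network`.
#' @return Character vector of human-readable violations; empty if every
#'   variant conserves its atom letters and all map lengths match the
#'   metabolite carbon counts.
#' @export
validate_atom_balance <- function(network) {
  viol <- character(0)
  for (v in network$variants) {
    sub_letters <- unlist(lapply(v$substrates, `[[`, "map"))
    prod_letters <- unlist(lapply(v$products, `[[`, "map"))
    if (anyDuplicated(sub_letters) || anyDuplicated(prod_letters)) {
      viol <- c(viol, sprintf("%s: repeated atom letter within one side",
                              v$rid))
    }
    if (!identical(sort(sub_letters), sort(prod_letters))) {
      viol <- c(viol, sprintf(
        "%s: substrate letters {%s} != product letters {%s}",
        v$rid, paste(sort(sub_letters), collapse = ""),
        paste(sort(prod_letters), collapse = "")))
    }
    for (tm in c(v$substrates, v$products)) {
      nc <- n_carbons_of(network, tm$met)
      if (length(tm$map) != nc) {
        viol <- c(viol, sprintf("%s: map '%s' for %s has %d letters, not %d",
                                v$rid, paste(tm$map, collapse = ""),
                                tm$met, length(tm$map), nc))
      }
    }
  }
  # every balanced pool must be produced and consumed
  for (id in network$pools$id[network$pools$role == "balanced"]) {
    prod <- any(vapply(network$variants, function(v)
      any(vapply(v$products, function(t) t$met == id, TRUE)), TRUE))
    cons <- any(vapply(network$variants, function(v)
      any(vapply(v$substrates, function(t) t$met == id, TRUE)), TRUE)) ||
      id %in% names(network$biomass)
    if (!prod) viol <- c(viol, sprintf("balanced pool %s is never produced", id))
    if (!cons) viol <- c(viol, sprintf("balanced pool %s is never consumed", id))
  }
  viol
}

#' Stoichiometric matrix of a network
#'
#' One row per balanced pool, one column per reaction id plus a final
#' `biomass` column holding the (negative) biomass drain coefficients. At
#' steady state `S %*% c(v, 1) = 0` for any admissible growth-rate-relative
#' flux vector `v`.
#'
#' @param network A `flux_network`.
#' @return Numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(network) {
  balanced <- network$pools$id[network$pools$role == "balanced"]
  if (length(balanced) == 0L) stop("network has no balanced pool")
  cols <- c(network$reaction_ids, "biomass")
  S <- matrix(0, nrow = length(balanced), ncol = length(cols),
              dimnames = list(balanced, cols))
  for (v in network$variants) {
    for (tm in v$substrates) {
      if (tm$met %in% balanced) S[tm$met, v$rid] <- S[tm$met, v$rid] - v$weight
    }
    for (tm in v$products) {
      if (tm$met %in% balanced) S[tm$met, v$rid] <- S[tm$met, v$rid] + v$weight
    }
  }
  for (met in names(network$biomass)) {
    if (met %in% balanced) S[met, "biomass"] <- -network$biomass[[met]]
  }
  S
}

#' Producing reactions of a pool
#' @keywords internal
producers_of <- function(network, pool) {
  unique(unlist(lapply(network$variants, function(v) {
    if (any(vapply(v$products, function(t) t$met == pool, TRUE))) v$rid
  })))
}

#' Write a network back to its file dialect
#'
#' Emits the same dialect the parser reads, in stable order (declarations,
#' biomass, reactions in input order, branch registry), so that
#' `parse_network_file(write_network_file(net, path))` round-trips.
#'
#' @param network A `flux_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_file <- function(network, path) {
  lines <- character(0)
  for (i in seq_len(nrow(network$pools))) {
    p <- network$pools[i, ]
    if (p$role == "source") {
      lines <- c(lines, sprintf("SOURCE %s %d", p$id, p$n_carbons))
    } else if (p$role == "sink") {
      lines <- c(lines, sprintf("SINK %s %d", p$id, p$n_carbons))
    }
  }
  for (met in names(network$biomass)) {
    lines <- c(lines, sprintf("BIOMASS %s %.10g", met, network$biomass[[met]]))
  }
  fmt_side <- function(terms) {
    paste(vapply(terms, function(t)
      sprintf("%s (%s)", t$met, paste(t$map, collapse = "")), ""),
      collapse = " + ")
  }
  for (v in network$variants) {
    head <- if (v$weight == 1) v$rid else sprintf("%s[%.10g]", v$rid, v$weight)
    lines <- c(lines, sprintf("%s: %s -> %s", head,
                              fmt_side(v$substrates), fmt_side(v$products)))
  }
  for (b in network$branches) {
    lines <- c(lines, sprintf("BRANCH %s %s : %s", b$pool, b$flux, b$text))
  }
  writeLines(lines, path)
  invisible(path)
}

#' The packaged serine/PPP/TCA/nucleotide network
#'
#' Returns the 19-reaction, 21-metabolite atom-mapped model used throughout
#' the package: glycolysis from glucose to pyruvate, the oxidative pentose
#' phosphate branch to ribose-5-phosphate, serine synthesis from
#' 3-phosphoglycerate with the serine/glycine/one-carbon cleavage, a lumped
#' TCA cycle with pyruvate dehydrogenase and pyruvate carboxylase
#' (anaplerosis) and succinate/fumarate scrambling, aspartate synthesis and
#' uptake, and de novo versus salvage synthesis of IMP and UMP, with
#' biomass drains for serine, glycine, aspartate and both nucleotides.
#' The reaction list is a documented reconstruction shipped as a packaged
#' reaction file (`system.file("extdata", "phgdh_network.txt", package =
#' "emuflux")`); every other operation in the package is network-agnostic,
#' so a corrected file can be dropped in.
#'
#' @return A validated `flux_network`.
#' @export
build_phgdh_network <- function() {
  path <- system.file("extdata", "phgdh_network.txt", package = "emuflux")
  if (path == "") {  # during in-source development
    path <- file.path("inst", "extdata", "phgdh_network.txt")
  }
  parse_network_file(path)
}

#' Human-readable labels for the reported fluxes of the packaged network
#'
#' Maps reaction ids of [build_phgdh_network()] to the twelve flux groups
#' reported for this model: 3PG to serine, serine to glycine, G6P to R5P,
#' pyruvate to acetyl-CoA, pyruvate to OAA, exogenous serine/glycine/
#' aspartate inputs, and de novo/salvage synthesis of IMP and UMP.
#'
#' @return Data frame with columns `reaction`, `label`, `pathway`.
#' @export
reported_flux_table <- function() {
  data.frame(
    reaction = c("SSP", "SHMT", "PPPOX", "PDH", "PC", "SERUP",
                 "GLYUP", "ASPUP", "IMPS", "IMPSAL", "UMPS", "UMPSAL"),
    label = c("3PG->Ser", "Ser->Gly", "G6P->R5P", "Pyr->AcCoA", "Pyr->OAA",
              "exogenous serine input", "exogenous glycine input",
              "exogenous aspartate uptake", "IMP synthesis", "IMP salvage",
              "UMP synthesis", "UMP salvage"),
    pathway = c("serine synthesis", "serine-glycine-one-carbon", "PPP",
                "TCA", "TCA", "uptake", "uptake", "uptake",
                "nucleotide", "nucleotide", "nucleotide", "nucleotide"),
    stringsAsFactors = FALSE)
}

#' Packaged toy networks for oracle verification
#'
#' Small atom-mapped networks (chain, cleavage, convergence, a TCA-like
#' scramble cycle with a convolution node, split/recombine) used to verify
#' the EMU cascade against the brute-force isotopomer oracle.
#'
#' @return Named character vector of file paths.
#' @export
list_toy_networks <- function() {
  dir <- system.file("extdata", "toy", package = "emuflux")
  if (dir == "") dir <- file.path("inst", "extdata", "toy")
  paths <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  stats::setNames(paths, sub("\\.txt$", "", basename(paths)))
}
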