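# Measured isotopologue data: the MID table dialect, replicate handling.
#
# Table dialect (delimited text, '#' comment lines allowed):
#   metabolite, condition, replicate, m0, m1, ..., mN
# Rows of metabolites with fewer carbons leave trailing columns empty (NA).

#' Build a measured MID set from a data frame
#'
#' @param df Data frame with columns `metabolite`, `condition`,
#'   `replicate` and `m0 ... mN` fraction columns (trailing NAs allowed
#'   for short MIDs).
#' @param tol Ingestion tolerance on the sum-to-one constraint per row
#'   (instrument rounding); rows are renormalized after the check.
#' @return Object of class `"mid_set"` (a validated data frame).
#' @export
mid_set <- function(df, tol = 1e-3) {
  need <- c("metabolite", "condition", "replicate")
  if (!all(need %in% names(df))) {
    stop("MID table must have columns: ", paste(need, collapse = ", "))
  }
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  if (length(mcols) == 0L) stop("MID table has no m0...mN columns")
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  df <- df[, c(need, mcols)]
  lens <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- as.numeric(df[i, mcols])
    n <- length(v) - match(TRUE, rev(!is.na(v))) + 1L
    if (is.na(n) || n < 1L) stop("row ", i, ": empty MID")
    v <- v[seq_len(n)]
    if (anyNA(v)) stop("row ", i, ": ragged MID (internal NA)")
    if (any(v < 0)) stop("row ", i, ": negative fraction")
    if (abs(sum(v) - 1) > tol) {
      stop(sprintf("row %d (%s): fractions sum to %.6f, outside tolerance %g",
                   i, df$metabolite[i], sum(v), tol))
    }
    df[i, mcols[seq_len(n)]] <- v / sum(v)
    lens[i] <- n
  }
  # all replicates of a metabolite must share vector length
  bad <- tapply(lens, df$metabolite, function(x) length(unique(x)) > 1L)
  if (any(bad)) {
    stop("inconsistent MID lengths for: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  structure(df, class = c("mid_set", "data.frame"))
}

#' Extract one MID from a measured set
#'
#' @param set A `mid_set`.
#' @param metabolite,condition,replicate Keys identifying the entry.
#' @return Numeric MID vector (trailing NAs trimmed).
#' @export
get_mid <- function(set, metabolite, condition, replicate) {
  i <- which(set$metabolite == metabolite & set$condition == condition &
             set$replicate == replicate)
  if (length(i) != 1L) {
    stop(sprintf("expected exactly one MID for (%s, %s, %s), found %d",
                 metabolite, condition, replicate, length(i)))
  }
  mcols <- grep("^m[0-9]+$", names(set), value = TRUE)
  v <- as.numeric(set[i, mcols])
  v[seq_len(length(v) - match(TRUE, rev(!is.na(v))) + 1L)]
}

#' Replicates present for a condition
#' @keywords internal
replicates_of <- function(set, condition) {
  sort(unique(set$replicate[set$condition == condition]))
}

#' Aggregate replicate MIDs to mean and s.e.m.
#'
#' Elementwise mean across biological replicates (renormalized) with the
#' standard error of the mean (sd / sqrt(n)) per isotopologue.
#'
#' @param set A `mid_set`.
#' @param metabolite,condition Entry keys.
#' @param replicates Optional replicate ids; default all present.
#' @return List with `mean` (normalized MID), `sem` and `n`.
#' @export
aggregate_replicates <- function(set, metabolite, condition,
                                 replicates = NULL) {
  if (is.null(replicates)) {
    reps <- sort(unique(set$replicate[set$metabolite == metabolite &
                                      set$condition == condition]))
  } else {
    reps <- replicates
    have <- unique(set$replicate[set$metabolite == metabolite &
                                 set$condition == condition])
    missing <- setdiff(reps, have)
    if (length(missing) > 0L) {
      stop("missing replicates for ", metabolite, "/", condition, ": ",
           paste(missing, collapse = ", "))
    }
  }
  if (length(reps) < 2L) {
    stop("need at least 2 replicates, found ", length(reps))
  }
  mat <- do.call(rbind, lapply(reps, function(r)
    get_mid(set, metabolite, condition, r)))
  mu <- colMeans(mat)
  list(mean = mu / sum(mu),
       sem = apply(mat, 2, stats::sd) / sqrt(nrow(mat)),
       n = nrow(mat))
}

#' Read / write the MID table dialect
#'
#' CSV with columns `metabolite, condition, replicate, m0...mN`; comment
#' lines start with `#`. The writer/reader round-trip is lossless.
#'
#' @param path File path.
#' @return [read_mid_table()] returns a `mid_set`.
#' @export
read_mid_table <- function(path) {
  if (!file.exists(path)) stop("MID table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  mid_set(df)
}

#' @rdname read_mid_table
#' @param set A `mid_set`.
#' @param header Optional comment lines written before the table.
#' @export
write_mid_table <- function(set, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(set), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert simulated MIDs to a `mid_set`
#'
#' @param mids Named list of MID vectors (as from [simulate_mids()]).
#' @param condition Condition label.
#' @param replicate Replicate id.
#' @return A one-replicate `mid_set`.
#' @export
mids_to_set <- function(mids, condition = "control", replicate = 1L) {
  nmax <- max(vapply(mids, length, 0L))
  rows <- lapply(names(mids), function(met) {
    v <- c(as.numeric(mids[[met]]), rep(NA_real_, nmax - length(mids[[met]])))
    c(list(metabolite = met, condition = condition, replicate = replicate),
      stats::setNames(as.list(v), paste0("m", seq_len(nmax) - 1L)))
  })
  mid_set(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
}

#' Bind several `mid_set`s
#' @param ... `mid_set` objects.
#' @return A combined `mid_set`.
#' @export
bind_mid_sets <- function(...) {
  sets <- list(...)
  nmax <- max(vapply(sets, function(s)
    length(grep("^m[0-9]+$", names(s))), 0L))
  pad <- function(s) {
    have <- grep("^m[0-9]+$", names(s), value = TRUE)
    for (k in seq_len(nmax) - 1L) {
      cn <- paste0("m", k)
      if (!cn %in% have) s[[cn]] <- NA_real_
    }
    as.data.frame(s)[, c("metabolite", "condition", "replicate",
                         paste0("m", seq_len(nmax) - 1L))]
  }
  mid_set(do.call(rbind, lapply(sets, pad)))
}
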