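#' Construct a clonal repopulation kinetic
#'
#' A clonal kinetic is the time series of percent donor-type cells measured
#' in the blood of a host transplanted with a single hematopoietic stem cell
#' (HSC), typically sampled every other month until the clone goes extinct.
#' Besides the total chimerism it may carry the per-lineage decomposition
#' into T, B and myeloid cells.
#'
#' @param clone_id Character label, unique within a batch.
#' @param times Numeric vector of observation times in months, strictly
#'   increasing, all `>= 0`.
#' @param total Numeric vector of percent donor-type cells (0-100 scale),
#'   same length as `times`.
#' @param lineages Optional named list of numeric vectors (names among
#'   `"T"`, `"B"`, `"My"`), each the same length as `times`. At every time
#'   the lineage sum may exceed `total` by at most a factor `1 + lineage_tol`
#'   (measurement noise allowance).
#' @param lifespan Clone lifespan (time-to-failure) in months. Defaults to
#'   the last observation time: kinetics are followed to extinction.
#' @param n_min Minimum number of observations required for meaningful
#'   reliability analysis (default 4, the smallest length for which rates,
#'   densities and a nontrivial failure-rate series all exist).
#' @param lineage_tol Relative tolerance for the lineage-sum check
#'   (default 0.05).
#' @return An object of class `"clonal_kinetic"`.
#' @examples
#' k <- clonal_kinetic("c1", times = c(0, 2, 4, 6, 8),
#'                     total = c(0, 10, 20, 10, 0))
#' k
#' @export
clonal_kinetic <- function(clone_id, times, total, lineages = NULL,
                           lifespan = NULL, n_min = 4L, lineage_tol = 0.05) {
  k <- structure(
    list(clone_id = as.character(clone_id)[1],
         times = as.numeric(times),
         total = as.numeric(total),
         lineages = lineages,
         lifespan = if (is.null(lifespan)) max(times) else as.numeric(lifespan)[1],
         n_min = as.integer(n_min),
         lineage_tol = lineage_tol),
    class = "clonal_kinetic")
  v <- validate_kinetic(k)
  if (length(v) > 0L)
    stop("invalid kinetic '", k$clone_id, "': ", paste(v, collapse = "; "),
         call. = FALSE)
  k
}

#' Validate a clonal kinetic
#'
#' Checks every structural invariant of a [clonal_kinetic()] and reports all
#' violations; never raises. An empty return value means the object is valid.
#'
#' @param k A `clonal_kinetic` (or a bare list with the same fields).
#' @return Character vector of violation descriptions, each naming the
#'   offending field and index; `character(0)` if all invariants hold.
#' @export
validate_kinetic <- function(k) {
  out <- character(0)
  n_min <- if (is.null(k$n_min)) 4L else k$n_min
  tol <- if (is.null(k$lineage_tol)) 0.05 else k$lineage_tol
  tt <- k$times
  yy <- k$total
  if (length(tt) != length(yy))
    out <- c(out, sprintf("times/total length mismatch (%d vs %d)",
                          length(tt), length(yy)))
  n <- length(tt)
  if (n < n_min)
    out <- c(out, sprintf("series too short: length %d < n_min %d", n, n_min))
  if (anyNA(tt) || anyNA(yy))
    out <- c(out, "missing values in times or total")
  if (n > 1 && !all(diff(tt) > 0)) {
    bad <- which(diff(tt) <= 0)[1]
    out <- c(out, sprintf("non-monotone times at index %d", bad + 1L))
  }
  if (any(tt < 0, na.rm = TRUE))
    out <- c(out, sprintf("negative time at index %d", which(tt < 0)[1]))
  if (any(yy < 0, na.rm = TRUE))
    out <- c(out, sprintf("negative total at index %d", which(yy < 0)[1]))
  if (any(yy > 100, na.rm = TRUE))
    out <- c(out, sprintf("total > 100%% at index %d", which(yy > 100)[1]))
  if (!is.null(k$lineages)) {
    for (nm in names(k$lineages)) {
      lv <- k$lineages[[nm]]
      if (length(lv) != n) {
        out <- c(out, sprintf("lineage %s length %d != %d", nm, length(lv), n))
        next
      }
      if (any(lv < 0, na.rm = TRUE))
        out <- c(out, sprintf("negative lineage %s value at index %d",
                              nm, which(lv < 0)[1]))
    }
    lens <- vapply(k$lineages, length, 0L)
    if (all(lens == n)) {
      lsum <- Reduce(`+`, k$lineages)
      bad <- which(lsum > yy * (1 + tol) + 1e-12)
      if (length(bad) > 0)
        out <- c(out, sprintf("lineage sum %.4g exceeds total %.4g at index %d",
                              lsum[bad[1]], yy[bad[1]], bad[1]))
    }
  }
  if (!is.null(k$lifespan) && length(k$lifespan) == 1 &&
      is.finite(k$lifespan) && n > 0 && k$lifespan < max(tt))
    out <- c(out, "lifespan earlier than last observation")
  out
}

#' @export
print.clonal_kinetic <- function(x, ...) {
  cat(sprintf("Clonal kinetic '%s': %d observations over %.4g-%.4g months, lifespan %.4g months\n",
              x$clone_id, length(x$times), min(x$times), max(x$times), x$lifespan))
  if (!is.null(x$lineages))
    cat("  lineages:", paste(names(x$lineages), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.clonal_kinetic <- function(x, ...) {
  df <- data.frame(clone_id = x$clone_id, time_months = x$times,
                   pct_total = x$total, stringsAsFactors = FALSE)
  if (!is.null(x$lineages)) {
    map <- c(T = "pct_T", B = "pct_B", My = "pct_My")
    for (nm in names(x$lineages)) df[[map[[nm]]]] <- x$lineages[[nm]]
  }
  df
}

#' Construct a batch of clonal kinetics
#'
#' @param clones List of [clonal_kinetic()] objects with unique `clone_id`s.
#' @param provenance Free-text metadata (source file, generator seed, ...).
#' @return An object of class `"kinetic_batch"`.
#' @export
kinetic_batch <- function(clones, provenance = "") {
  ids <- vapply(clones, function(k) k$clone_id, "")
  if (anyDuplicated(ids))
    stop("duplicate clone_id in batch: ", ids[anyDuplicated(ids)], call. = FALSE)
  names(clones) <- ids
  structure(list(clones = clones, provenance = provenance),
            class = "kinetic_batch")
}

#' @export
print.kinetic_batch <- function(x, ...) {
  L <- vapply(x$clones, function(k) k$lifespan, 0)
  cat(sprintf("Kinetic batch: %d clones, lifespans %.4g-%.4g months\n",
              length(x$clones), min(L), max(L)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.kinetic_batch <- function(x) length(x$clones)

#' @export
as.data.frame.kinetic_batch <- function(x, ...) {
  do.call(rbind, c(lapply(unname(x$clones), as.data.frame), make.row.names = FALSE))
}

#' Read clonal kinetics from a delimited table
#'
#' Reads a long-format table with one row per (clone, time): required columns
#' `clone_id`, `time_months`, `pct_total`; optional lineage columns `pct_T`,
#' `pct_B`, `pct_My`; optional `lifespan_months` (constant within a clone).
#' Rows are sorted by time within each clone and all kinetic invariants are
#' enforced; a malformed table yields a diagnostic error naming the clone,
#' never a partial batch.
#'
#' @param path Path to an existing CSV or TSV file (header row, UTF-8,
#'   `.` decimal separator).
#' @param dialect `"csv"` or `"tsv"`; default guessed from the extension.
#' @param n_min Minimum observations per clone (see [clonal_kinetic()]).
#' @return A [kinetic_batch()].
#' @export
read_kinetics <- function(path, dialect = c("auto", "csv", "tsv"), n_min = 4L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("clone_id", "time_months", "pct_total")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lincols <- intersect(c("pct_T", "pct_B", "pct_My"), names(df))
  linmap <- c(pct_T = "T", pct_B = "B", pct_My = "My")
  clones <- lapply(split(df, factor(df$clone_id, levels = unique(df$clone_id))),
                   function(d) {
    d <- d[order(d$time_months), , drop = FALSE]
    lineages <- NULL
    if (length(lincols) > 0) {
      lineages <- lapply(lincols, function(cc) as.numeric(d[[cc]]))
      names(lineages) <- linmap[lincols]
    }
    L <- if ("lifespan_months" %in% names(d)) d$lifespan_months[1] else NULL
    k <- structure(list(clone_id = d$clone_id[1],
                        times = as.numeric(d$time_months),
                        total = as.numeric(d$pct_total),
                        lineages = lineages,
                        lifespan = if (is.null(L)) max(d$time_months) else L,
                        n_min = as.integer(n_min), lineage_tol = 0.05),
                   class = "clonal_kinetic")
    v <- validate_kinetic(k)
    if (length(v) > 0)
      stop("clone '", k$clone_id, "': ", paste(v, collapse = "; "),
           call. = FALSE)
    k
  })
  kinetic_batch(unname(clones), provenance = paste0("file:", path))
}

#' Write a pipeline result to disk
#'
#' Serializes any of the package's result objects deterministically: field
#' order is fixed and floating-point values carry 12 significant digits, so
#' the same object always produces the same bytes and every written table or
#' JSON file round-trips.
#'
#' @param obj A `kinetic_batch`, `reliability_profile`, `ou_fit`,
#'   `drift_fit`, `rs_result`, `power_law_fit`, `gumbel_fit`, or plain
#'   data frame / list.
#' @param path Output file path.
#' @param format `"tsv"` for tabular objects, `"json"` for fit objects;
#'   default picked by object class.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (inherits(obj, c("kinetic_batch", "reliability_profile",
                                  "data.frame", "clonal_kinetic"))) "tsv" else "json"
  }
  if (format == "tsv") {
    df <- if (is.data.frame(obj)) obj else as.data.frame(obj)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(z) signif(z, 12))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    x <- if (is.list(obj)) unclass(obj) else obj
    x <- x[!vapply(x, is.function, TRUE)]
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
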