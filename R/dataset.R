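#' Release-recapture dataset
#'
#' A distance ladder from a release-recapture experiment: at each distance
#' from the trap a known number of marked insects was released and the
#' number recaptured in the trap (converged catch) recorded. The recapture
#' proportion at each distance estimates the catch probability there.
#'
#' Records are sorted by distance. Records sharing a distance are pooled
#' (catches and releases summed, i.e. a catch-weighted average proportion)
#' with a warning.
#'
#' @param distance Release distances in meters, >= 0.
#' @param released Number of insects released per distance, >= 0.
#' @param caught Number recaptured per distance, `0 <= caught <= released`.
#' @param sem Optional standard error of the recapture proportion; when
#'   `NULL` the exact binomial SE `sqrt(p(1-p)/n)` is filled in.
#' @param species,trap_type,note Free-text metadata (species label, trap
#'   type, trapping-interval note).
#' @return A data frame of class `"release_recapture"` with columns
#'   `distance`, `released`, `caught`, `proportion`, `sem`.
#' @export
release_recapture <- function(distance, released, caught, sem = NULL,
                              species = "", trap_type = "", note = "") {
  stopifnot(is.numeric(distance), is.numeric(released), is.numeric(caught))
  n <- length(distance)
  if (length(released) == 1L) released <- rep_len(released, n)
  if (length(caught) == 1L) caught <- rep_len(caught, n)
  if (length(released) != n || length(caught) != n)
    stop("'distance', 'released' and 'caught' must have equal length")
  if (n == 0L) stop("empty dataset")
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distances must be finite and >= 0")
  if (any(released < 0) || any(caught < 0))
    stop("counts must be >= 0")
  bad <- which(caught > released)
  if (length(bad))
    stop("caught > released at distance(s) ",
         paste(distance[bad], collapse = ", "))
  if (!is.null(sem)) {
    if (length(sem) != n) stop("'sem' must match the number of records")
    if (any(sem < 0, na.rm = TRUE)) stop("'sem' must be >= 0")
  }

  o <- order(distance)
  distance <- distance[o]; released <- released[o]; caught <- caught[o]
  if (!is.null(sem)) sem <- sem[o]

  if (anyDuplicated(distance)) {
    warning("duplicate distances pooled (catches and releases summed)")
    f <- factor(distance, levels = unique(distance))
    released <- as.numeric(tapply(released, f, sum))
    caught <- as.numeric(tapply(caught, f, sum))
    distance <- unique(distance)
    sem <- NULL  # recomputed from pooled counts
  }

  proportion <- ifelse(released > 0, caught / released, NA_real_)
  if (is.null(sem))
    sem <- ifelse(released > 0,
                  sqrt(proportion * (1 - proportion) / released), NA_real_)

  ds <- data.frame(distance = distance, released = released,
                   caught = caught, proportion = proportion, sem = sem)
  structure(ds,
            species = species, trap_type = trap_type, note = note,
            class = c("release_recapture", "data.frame"))
}

#' @export
print.release_recapture <- function(x, ...) {
  sp <- attr(x, "species"); tt <- attr(x, "trap_type")
  if (nzchar(sp) || nzchar(tt))
    cat("Release-recapture dataset:", sp,
        if (nzchar(tt)) paste0("(", tt, " trap)"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Check a dataset against the design criteria for fitting
#'
#' Screens a release-recapture dataset against the three design criteria a
#' dataset should satisfy before the catch-probability curve is fitted to
#' it: (1) converged catch reported for at least 4 distances; (2) the number
#' of insects released at large distances is the same or larger than at
#' short distances; (3) no zero-catch records between non-zero records.
#' Violations yield warnings describing the problem, never errors -- field
#' data are often imperfect and the fit may still be informative.
#'
#' @param ds A [release_recapture()] dataset.
#' @param warn Emit each finding as an R warning (default) in addition to
#'   returning it.
#' @return Invisibly, a character vector of findings (empty when all
#'   criteria hold).
#' @export
validate_recapture <- function(ds, warn = TRUE) {
  stopifnot(inherits(ds, "release_recapture"))
  if (nrow(ds) == 0L) stop("empty dataset")
  out <- character()
  if (length(unique(ds$distance)) < 4L)
    out <- c(out, paste0(
      "criterion 1: converged catch reported for only ",
      length(unique(ds$distance)), " distances (at least 4 required)"))
  if (any(diff(ds$released) < 0))
    out <- c(out, paste0(
      "criterion 2: number released decreases with distance (",
      paste(ds$released, collapse = ", "), ")"))
  nz <- which(ds$caught > 0)
  if (length(nz) >= 2L) {
    interior <- seq(min(nz), max(nz))
    if (any(ds$caught[interior] == 0))
      out <- c(out, paste0(
        "criterion 3: zero catch at distance(s) ",
        paste(ds$distance[interior][ds$caught[interior] == 0],
              collapse = ", "),
        " m between non-zero catches"))
  }
  if (warn) for (w in out) warning(w, call. = FALSE)
  invisible(out)
}

#' Read a release-recapture dataset from CSV
#'
#' Strict dialect: comma-separated, UTF-8, '.' decimal separator, mandatory
#' header with columns `distance_m`, `released`, `caught` and optional
#' `sem`. Lines starting with `#` are comments. Malformed rows are reported
#' with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param validate Run [validate_recapture()] on the result (warnings only).
#' @return A [release_recapture()] dataset.
#' @export
read_recapture <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         strip.white = TRUE)
  need <- c("distance_m", "released", "caught")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in intersect(c(need, "sem"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row(s) ",
           paste(bad, collapse = ", "))
    raw[[col]] <- v
  }
  bad <- which(raw$caught > raw$released)
  if (length(bad))
    stop("caught > released at data row(s) ", paste(bad, collapse = ", "))
  ds <- release_recapture(raw$distance_m, raw$released, raw$caught,
                          sem = if ("sem" %in% names(raw)) raw$sem)
  if (validate) validate_recapture(ds)
  ds
}

#' Write a release-recapture dataset to CSV
#'
#' Emits the same dialect [read_recapture()] reads, so simulate -> write ->
#' read -> fit round-trips losslessly on the counts.
#'
#' @param ds A [release_recapture()] dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recapture <- function(ds, path) {
  stopifnot(inherits(ds, "release_recapture"))
  out <- data.frame(distance_m = ds$distance, released = ds$released,
                    caught = ds$caught, sem = ds$sem)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
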