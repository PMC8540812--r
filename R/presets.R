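#' Published trap-insect system presets
#'
#' Fitted parameter sets for ten published trap-insect systems spanning five
#' insect orders and two trapping methods (chemical attractants and light).
#' Each row carries the catch probability at the trap `sptfer0`, the
#' half-catch distance `d50` (m, with its SEM), and the collection radius
#' `rmax` (m). `rmax_estimated` flags systems whose collection radius was
#' estimated indirectly rather than observed in a release-recapture
#' experiment.
#'
#' @return A data frame with columns `key`, `insect`, `trap_type`,
#'   `sptfer0`, `d50`, `d50_sem`, `rmax`, `rmax_estimated`.
#' @seealso [trap_preset()] to fetch one row as a [trap_params()] object.
#' @export
trap_presets <- function() {
  path <- system.file("extdata", "trap_presets.csv", package = "trapdensity",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fetch one preset as a trap_params object
#'
#' @param key Preset key (see `trap_presets()$key`) or a unique prefix of
#'   one, matched case-insensitively.
#' @return A [trap_params()] object.
#' @examples
#' trap_preset("codling_moth")
#' @export
trap_preset <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  tab <- trap_presets()
  hit <- which(tab$key == tolower(key))
  if (length(hit) == 0L)
    hit <- which(startsWith(tab$key, tolower(key)))
  if (length(hit) == 0L)
    stop("unknown preset '", key, "'; available: ",
         paste(tab$key, collapse = ", "))
  if (length(hit) > 1L)
    stop("preset '", key, "' is ambiguous: ",
         paste(tab$key[hit], collapse = ", "))
  row <- tab[hit, ]
  trap_params(sptfer0 = row$sptfer0, d50 = row$d50, rmax = row$rmax,
              d50_sem = row$d50_sem,
              label = paste0(row$insect, " / ", row$trap_type, " trap"))
}
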