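#' Stage maps: translating raw hypnogram codes to the canonical alphabet
#'
#' A stage map translates the per-epoch codes found in a hypnogram file to
#' the canonical stage alphabet `W, N1, N2, N3, N4, R` (plus `N` once NREM
#' sub-stages are merged). Two conventions ship with the package: the SHHS
#' numeric convention (`0` = wake, `1`-`4` = NREM1-4, `5` = REM) and plain
#' letter codes.
#'
#' @param unscored One of `"error"` (default) or `"wake"`: what to do with
#'   movement/unscored epochs should a file contain codes mapped to
#'   `"UNSCORED"`. The shipped maps contain no such codes; custom maps may.
#' @param mapping Named character vector: names are raw file tokens, values
#'   are canonical codes (or `"UNSCORED"`).
#' @param nrem_mode `"substages"` or `"merged"`: whether the map emits NREM
#'   sub-stage codes or the single merged code `N`.
#'
#' @return An object of class `stage_map`.
#' @examples
#' m <- stage_map_shhs()
#' m$mapping[["5"]]  # "R"
#' @name stage_map
NULL

#' @rdname stage_map
#' @export
stage_map <- function(mapping, nrem_mode = c("substages", "merged"),
                      unscored = c("error", "wake")) {
  nrem_mode <- match.arg(nrem_mode)
  unscored <- match.arg(unscored)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  allowed <- c(stage_alphabet(), "UNSCORED")
  bad <- setdiff(unique(mapping), allowed)
  if (length(bad) > 0L) {
    stop("stage_map targets must be in {", paste(stage_alphabet(), collapse = ", "),
         ", UNSCORED}; got: ", paste(bad, collapse = ", "))
  }
  structure(list(mapping = mapping, nrem_mode = nrem_mode, unscored = unscored),
            class = "stage_map")
}

#' @rdname stage_map
#' @export
stage_map_shhs <- function(unscored = c("error", "wake")) {
  stage_map(c(`0` = "W", `1` = "N1", `2` = "N2", `3` = "N3", `4` = "N4", `5` = "R"),
            nrem_mode = "substages", unscored = match.arg(unscored))
}

#' @rdname stage_map
#' @export
stage_map_letters <- function(unscored = c("error", "wake")) {
  stage_map(c(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", N4 = "N4", R = "R", N = "N"),
            nrem_mode = "substages", unscored = match.arg(unscored))
}

#' Canonical stage alphabet
#'
#' @param merged Logical; if `TRUE` return the 3-state alphabet used after
#'   NREM sub-stages are merged.
#' @return Character vector of stage codes.
#' @export
stage_alphabet <- function(merged = FALSE) {
  if (merged) c("W", "N", "R") else c("W", "N1", "N2", "N3", "N4", "N", "R")
}

#' @export
print.stage_map <- function(x, ...) {
  cat("<stage_map> ", length(x$mapping), " codes, nrem_mode=", x$nrem_mode,
      ", unscored=", x$unscored, "\n", sep = "")
  invisible(x)
}
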