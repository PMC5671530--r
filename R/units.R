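#' Unit conversions
#'
#' Exact conversions used throughout the package. Pressures are stored in
#' MPa internally (1 mmHg = 133.322 Pa exactly, not the rounded MPa values
#' sometimes quoted for NPWT levels); lengths in metres.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_mpa <- function(x) x * 133.322e-6

#' @rdname units
#' @export
kpa_to_mpa <- function(x) x * 1e-3

#' @rdname units
#' @export
cm_to_m <- function(x) x * 1e-2

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

# internal: convert a length given in `units` to metres
.len_to_m <- function(x, units) {
  switch(units,
    m = x,
    cm = cm_to_m(x),
    mm = mm_to_m(x),
    um = um_to_m(x),
    stop("unknown length unit: ", units)
  )
}
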