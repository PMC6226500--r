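#' Latitudinal band grid
#'
#' Defines the discretisation of latitude into equal-width bands. The default
#' grid spans -80 to 85 degrees (Antarctic continent to Arctic ice cap) in
#' 5-degree bands, giving 33 bands. Bands are half-open `[low, high)` except
#' the topmost band, which is closed at the upper edge so that every latitude
#' in the span is assignable.
#'
#' @param lower Lower edge of the grid in decimal degrees.
#' @param upper Upper edge of the grid in decimal degrees.
#' @param width Band width in degrees; must divide `upper - lower` exactly.
#' @return An object of class `band_grid`: a list with elements `lower`,
#'   `upper`, `width` and `n_bands`.
#' @examples
#' g <- band_grid()
#' g$n_bands  # 33
#' band_index(2.5, g)  # the band spanning [0, 5)
#' @export
band_grid <- function(lower = -80, upper = 85, width = 5) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(width),
            length(lower) == 1, length(upper) == 1, length(width) == 1,
            is.finite(lower), is.finite(upper), is.finite(width),
            width > 0, upper > lower)
  n <- (upper - lower) / width
  if (abs(n - round(n)) > 1e-8)
    stop("band width (", width, ") must divide the grid span (",
         upper - lower, ") exactly", call. = FALSE)
  structure(list(lower = lower, upper = upper, width = width,
                 n_bands = as.integer(round(n))),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("Latitudinal band grid: [%g, %g] in %g-degree bands (%d bands)\n",
              x$lower, x$upper, x$width, x$n_bands))
  invisible(x)
}

#' Band index of a latitude
#'
#' Maps latitudes to 1-based band indices on a [band_grid()]. Band `b` covers
#' `[lower + (b-1)*width, lower + b*width)`; the topmost band additionally
#' contains the upper edge.
#'
#' @param latitude Numeric vector of latitudes in decimal degrees.
#' @param grid A [band_grid()].
#' @return Integer vector of band indices in `1:grid$n_bands`. `NA` latitudes
#'   yield `NA` indices.
#' @export
band_index <- function(latitude, grid = band_grid()) {
  bad <- !is.na(latitude) & (latitude < grid$lower | latitude > grid$upper)
  if (any(bad))
    stop("latitude outside grid range [", grid$lower, ", ", grid$upper, "]: ",
         paste(utils::head(latitude[bad], 3), collapse = ", "), call. = FALSE)
  # small tolerance so latitudes sitting exactly on an edge after floating-
  # point arithmetic land in the upper band
  b <- floor((latitude - grid$lower) / grid$width + 1e-9) + 1L
  b[!is.na(b) & b > grid$n_bands] <- grid$n_bands
  as.integer(b)
}

#' Band boundary table
#'
#' @param grid A [band_grid()].
#' @return A data frame with columns `band`, `lat_low`, `lat_high`, `lat_mid`.
#' @export
band_bounds <- function(grid = band_grid()) {
  b <- seq_len(grid$n_bands)
  lo <- grid$lower + (b - 1L) * grid$width
  data.frame(band = b, lat_low = lo, lat_high = lo + grid$width,
             lat_mid = lo + grid$width / 2)
}

# shared check that two objects were built on the same grid
same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("lower", "upper", "width")],
                   unclass(b)[c("lower", "upper", "width")]))
}
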