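#' Mask non-cropland pixels out of a maize map
#'
#' Pixels where the cropland mask is 0 are forced to 0 (non-maize); pixels
#' inside cropland are left unchanged. `NA` (nodata) map pixels propagate.
#'
#' @param map integer matrix with values 1 (maize), 0 (non-maize) or `NA`.
#' @param mask integer matrix with values 1 (cropland) and 0, aligned with
#'   `map`.
#' @return The masked map.
#' @export
applyCroplandMask <- function(map, mask) {
  if (!identical(dim(map), dim(mask)))
    stop(sprintf("map (%s) and mask (%s) grids are not aligned",
                 paste(dim(map), collapse = "x"),
                 paste(dim(mask), collapse = "x")))
  if (!all(mask %in% c(0L, 1L)))
    stop("cropland mask must contain only 0 and 1")
  out <- map
  out[mask == 0L & !is.na(out)] <- 0L
  out
}

# Label 4-connected components of TRUE cells; returns an integer matrix of
# component ids (0 = background) plus component sizes.
.labelComponents <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  sizes <- integer(0)
  stack <- integer(nr * nc)
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nxt
    size <- 0L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      size <- size + 1L
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cl > 1L) p - nr, if (cl < nc) p + nr)) {
        if (fg[q] && lab[q] == 0L) {
          lab[q] <- nxt
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
    sizes[nxt] <- size
  }
  list(labels = lab, sizes = sizes)
}

#' Remove speckle with a minimum-mapping-unit filter
#'
#' Deletes 4-connected components of maize (value 1) pixels smaller than
#' `minPatchPx`, setting them to 0. Components of at least `minPatchPx`
#' pixels are untouched; `minPatchPx = 1` is the identity. `NA` pixels are
#' treated as background and never modified.
#'
#' @param map integer matrix with values 1, 0 or `NA`.
#' @param minPatchPx minimum component size in pixels to survive; the
#'   default 4 corresponds to ~0.36 ha at 30 m resolution.
#' @return The cleaned map.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[3, 3] <- 1L
#' sum(removeSpeckle(m, minPatchPx = 2))  # isolated pixel removed
removeSpeckle <- function(map, minPatchPx = 4L) {
  stopifnot(minPatchPx >= 1)
  if (minPatchPx == 1L) return(map)
  fg <- !is.na(map) & map == 1L
  comp <- .labelComponents(fg)
  small <- which(comp$sizes < minPatchPx)
  if (length(small)) map[comp$labels %in% small] <- 0L
  map
}
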