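#' Confusion matrix of predicted against true labels
#'
#' Rows index the true class, columns the predicted class: entry (A, B)
#' counts the samples of true class A predicted as B, so row sums are
#' class prevalences and the trace is the number of correct predictions.
#'
#' @param truth vector of true labels.
#' @param predicted vector of predicted labels, same length.
#' @param classes class labels fixing row/column order; defaults to the
#'   union of observed labels. Unknown labels raise an error.
#' @return Integer matrix with dimnames `truth` x `predicted`.
#' @export
#' @examples
#' confusionCounts(c("maize", "maize"), c("maize", "others"),
#'                 classes = c("maize", "others"))
confusionCounts <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Collapse a multiclass confusion matrix to positive vs rest
#'
#' Merges every class other than `positive` into a single negative class;
#' counts are conserved.
#'
#' @param m square confusion matrix (rows truth, columns prediction).
#' @param positive name of the positive class (must be a row of `m`).
#' @param negativeLabel label for the merged class.
#' @return 2 x 2 confusion matrix (positive first).
#' @export
binarizeMatrix <- function(m, positive = "maize",
                           negativeLabel = "nonmaize") {
  stopifnot(positive %in% rownames(m))
  pos <- rownames(m) == positive
  out <- rbind(c(sum(m[pos, pos]), sum(m[pos, !pos])),
               c(sum(m[!pos, pos]), sum(m[!pos, !pos])))
  dimnames(out) <- list(truth = c(positive, negativeLabel),
                        predicted = c(positive, negativeLabel))
  storage.mode(out) <- "integer"
  out
}

# Round half away from zero at `digits` decimals (printed-table convention,
# unlike R's round-half-even).
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Thematic-map accuracy metrics from a confusion matrix
#'
#' Computes, per class, user's accuracy (UA, precision: correct fraction of
#' the prediction column), producer's accuracy (PA, recall: correct fraction
#' of the truth row) and their harmonic mean F1, plus the overall accuracy
#' (OA, trace over total). Values are reported at full precision and rounded
#' (half-up) at `digits` decimals, matching how such tables are printed.
#' A class with an empty row or column gets `NA` for the undefined metrics.
#'
#' @param m square confusion matrix (rows truth, columns prediction).
#' @param digits decimals for the rounded columns (2 by convention; some
#'   published cells carry 3).
#' @return List with `perClass` (data.frame: class, ua, pa, f1 and their
#'   rounded counterparts) and `oa` / `oaRounded` scalars.
#' @export
#' @examples
#' m <- rbind(c(605L, 134L), c(130L, 2345L))
#' dimnames(m) <- list(truth = c("maize", "nonmaize"),
#'                     predicted = c("maize", "nonmaize"))
#' accuracyMetrics(m)$perClass
accuracyMetrics <- function(m, digits = 2) {
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  colTot <- colSums(m)
  rowTot <- rowSums(m)
  diagv <- diag(m)
  ua <- ifelse(colTot == 0, NA_real_, diagv / colTot)
  pa <- ifelse(rowTot == 0, NA_real_, diagv / rowTot)
  f1 <- ifelse(is.na(ua) | is.na(pa) | (ua + pa) == 0, NA_real_,
               2 * ua * pa / (ua + pa))
  oa <- sum(diagv) / sum(m)
  list(perClass = data.frame(class = rownames(m), ua = ua, pa = pa, f1 = f1,
                             uaRounded = roundHalfUp(ua, digits),
                             paRounded = roundHalfUp(pa, digits),
                             f1Rounded = roundHalfUp(f1, digits),
                             row.names = NULL),
       oa = oa, oaRounded = roundHalfUp(oa, digits))
}

#' Mapped maize area per region
#'
#' Counts value-1 pixels per region and converts to hectares (pixel count x
#' pixel area). `NA` (nodata) pixels are excluded.
#'
#' @param map integer matrix with values 1, 0 or `NA`.
#' @param regions integer region raster aligned with `map`, or `NULL` for a
#'   single whole-grid record (region id 1).
#' @param year year recorded with each record.
#' @param pixelAreaM2 pixel area in square meters (30 m pixels: 900).
#' @return data.frame with columns region, year, area_ha.
#' @export
areaByRegion <- function(map, regions = NULL, year = 2019L,
                         pixelAreaM2 = 900) {
  if (is.null(regions)) regions <- matrix(1L, nrow(map), ncol(map))
  stopifnot(identical(dim(map), dim(regions)))
  ids <- sort(unique(as.vector(regions)))
  area <- vapply(ids, function(r) {
    sum(map == 1L & regions == r, na.rm = TRUE) * pixelAreaM2 / 1e4
  }, numeric(1))
  data.frame(region = ids, year = year, area_ha = area)
}

#' Squared Pearson correlation between mapped and reference areas
#'
#' The area-consistency statistic: `R^2 = cor(mapped, reference)^2`. At
#' least three pairs are required; constant vectors give `NA` (undefined).
#'
#' @param mapped numeric vector of mapped areas.
#' @param reference numeric vector of reference areas, same length.
#' @return Scalar in [0, 1], or `NA` if undefined.
#' @seealso [agreementR2()] for the identity-line variant.
#' @export
#' @examples
#' rSquared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
rSquared <- function(mapped, reference) {
  stopifnot(length(mapped) == length(reference))
  if (length(mapped) < 3) stop("need at least 3 paired records")
  if (stats::sd(mapped) == 0 || stats::sd(reference) == 0) return(NA_real_)
  cor(mapped, reference)^2
}

#' Coefficient of determination against the identity line
#'
#' Secondary agreement statistic `1 - SSE/SST`, where SSE is the squared
#' departure of mapped from reference and SST the reference variance times
#' (n - 1). Unlike [rSquared()] this penalizes bias, not just scatter, and
#' can be negative.
#'
#' @inheritParams rSquared
#' @return Scalar `<= 1`, or `NA` if undefined.
#' @export
agreementR2 <- function(mapped, reference) {
  stopifnot(length(mapped) == length(reference))
  if (length(mapped) < 3) stop("need at least 3 paired records")
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((mapped - reference)^2) / sst
}
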