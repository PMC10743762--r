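# Standardized centerline tracking accuracy measures: total overlap (OV),
# overlap until first error (OF), overlap of the clinically relevant
# portion (OT) and average inside distance (AI). Both curves are resampled
# to n uniformly spaced points (reference radii interpolated alongside);
# correspondences are nearest-neighbour in Euclidean distance, thresholded
# by the local reference radius in both directions.

# resample a reference centerline to n points with radii carried along
.resampleReference <- function(ref, n) {
    p <- ref@points
    arc <- c(0, cumsum(sqrt(rowSums(diff(p[, 1:3, drop = FALSE])^2))))
    L <- arc[length(arc)]
    s <- seq(0, L, length.out = n)
    list(points = cbind(
             stats::approx(arc, p[, 1L], xout = s, ties = "ordered", rule = 2)$y,
             stats::approx(arc, p[, 2L], xout = s, ties = "ordered", rule = 2)$y,
             stats::approx(arc, p[, 3L], xout = s, ties = "ordered", rule = 2)$y),
         radii = stats::approx(arc, p[, 4L], xout = s, ties = "ordered", rule = 2)$y,
         arc = s)
}

#' Classify extracted and reference points
#'
#' Resamples both centerlines to `n` uniformly spaced points (reference
#' radii linearly interpolated alongside) and classifies every point by the
#' radius-thresholded nearest-neighbour rule: an extracted point is a true
#' positive (TPM) iff its distance to the nearest reference sample is at
#' most that sample's radius, else a false positive (FP); a reference
#' sample is a true positive (TPR) iff its distance to the nearest
#' extracted point is at most its own radius, else a false negative (FN).
#'
#' @param extracted a [Centerline-class], or `NULL` for an empty
#'   extraction (every reference point becomes FN).
#' @param reference a [ReferenceCenterline-class] (radii required).
#' @param n resample count (default 1000).
#' @return A list with elements `counts` ([MetricCounts-class], scope OV),
#'   `extLabels`/`refLabels` (`"TPM"/"FP"` and `"TPR"/"FN"` in curve
#'   order), `extDist`/`refDist` (match distances, mm), `nearestRef`
#'   (index of the nearest reference sample per extracted point),
#'   `refArc` (reference arc length per sample), `refRadii`, and `n`.
#' @export
classifyPoints <- function(extracted, reference, n = 1000L) {
    stopifnot(is(reference, "ReferenceCenterline"))
    n <- as.integer(n)
    rs <- .resampleReference(reference, n)
    if (is.null(extracted)) {
        return(list(counts = MetricCounts(0L, 0L, 0L, n, scope = "OV"),
                    extLabels = character(0L), refLabels = rep("FN", n),
                    extDist = numeric(0L), refDist = rep(Inf, n),
                    nearestRef = integer(0L), refArc = rs$arc,
                    refRadii = rs$radii, n = n))
    }
    stopifnot(is(extracted, "Centerline"))
    E <- resampleCenterline(extracted, n)@points
    R <- rs$points
    # squared distance matrix: extracted rows x reference columns
    D2 <- outer(rowSums(E^2), rowSums(R^2), "+") - 2 * tcrossprod(E, R)
    D2[D2 < 0] <- 0
    nearestRef <- max.col(-D2, ties.method = "first")
    # recompute matched distances from coordinates: the expanded-square
    # matrix form cancels catastrophically for near-identical points
    extDist <- sqrt(rowSums((E - R[nearestRef, , drop = FALSE])^2))
    extTP <- extDist <= rs$radii[nearestRef] + 1e-12
    nearestExt <- max.col(-t(D2), ties.method = "first")
    refDist <- sqrt(rowSums((R - E[nearestExt, , drop = FALSE])^2))
    refTP <- refDist <= rs$radii + 1e-12
    list(counts = MetricCounts(sum(extTP), sum(!extTP), sum(refTP),
                               sum(!refTP), scope = "OV"),
         extLabels = ifelse(extTP, "TPM", "FP"),
         refLabels = ifelse(refTP, "TPR", "FN"),
         extDist = extDist, refDist = refDist,
         nearestRef = nearestRef, refArc = rs$arc, refRadii = rs$radii,
         n = n)
}

#' Total overlap (OV)
#'
#' `100 * (TPM + TPR) / (TPM + TPR + FN + FP)`; 0 when the denominator is
#' 0. Ranges from 0 (no extracted point within one vessel radius of the
#' reference) to 100 (perfect overlap, no extraneous points).
#'
#' @param counts a [MetricCounts-class] with scope `"OV"`, or the list
#'   returned by [classifyPoints()].
#' @return Percentage in `[0, 100]`.
#' @export
metricOV <- function(counts) {
    if (is.list(counts)) counts <- counts$counts
    stopifnot(is(counts, "MetricCounts"))
    num <- counts@tpm + counts@tpr
    den <- num + counts@fn + counts@fp
    if (den == 0L) 0 else 100 * num / den
}

#' Overlap until first error (OF)
#'
#' The fraction of the reference tracked before the first error, where the
#' first error is the most proximal false negative beyond the first
#' `skipMm` of reference arc length (false negatives within the first
#' `skipMm` are forgiven and counted as tracked). `100 * TPR_OF / n`,
#' where `n` is the total number of reference samples.
#'
#' @param cls result of [classifyPoints()].
#' @param skipMm arc length at the reference start within which false
#'   negatives are ignored (mm).
#' @return Percentage in `[0, 100]`.
#' @export
metricOF <- function(cls, skipMm = 5) {
    fn <- cls$refLabels == "FN"
    eligible <- fn & cls$refArc > skipMm
    if (!any(eligible))
        return(100 * (sum(cls$refLabels == "TPR") +
                      sum(fn & cls$refArc <= skipMm)) / cls$n)
    first <- which(eligible)[1L]
    100 * sum(cls$refLabels[seq_len(first - 1L)] == "TPR") / cls$n
}

#' Overlap of the clinically relevant portion (OT)
#'
#' Restricts the evaluation to the reference span from the start to the
#' most distal sample whose radius is at least `minRadius` (diameter above
#' the clinical threshold), and to the extracted points whose nearest
#' reference sample lies in that span, then recomputes the symmetric
#' overlap ratio. `NA` when no reference sample reaches `minRadius`.
#'
#' @param cls result of [classifyPoints()].
#' @param minRadius clinical radius threshold in mm (1.5 mm diameter).
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
metricOT <- function(cls, minRadius = 0.75) {
    ok <- which(cls$refRadii >= minRadius)
    if (length(ok) == 0L) return(NA_real_)
    last <- max(ok)
    refIn <- seq_len(last)
    extIn <- which(cls$nearestRef <= last)
    tpm <- sum(cls$extLabels[extIn] == "TPM")
    fp <- length(extIn) - tpm
    tpr <- sum(cls$refLabels[refIn] == "TPR")
    fn <- last - tpr
    den <- tpm + tpr + fn + fp
    if (den == 0L) return(NA_real_)
    100 * (tpm + tpr) / den
}

#' Average inside distance (AI)
#'
#' Mean Euclidean match distance over all true-positive correspondences,
#' pooling both directions (TPM and TPR). Bounded below by 0 and above by
#' the mean radius over matched reference samples; `NA` when nothing
#' matched.
#'
#' @param cls result of [classifyPoints()].
#' @return Distance in mm, or `NA`.
#' @export
metricAI <- function(cls) {
    d <- c(cls$extDist[cls$extLabels == "TPM"],
           cls$refDist[cls$refLabels == "TPR"])
    if (length(d) == 0L) return(NA_real_)
    mean(d)
}

#' Evaluate an extracted centerline against a reference
#'
#' Runs [classifyPoints()] at `n` samples and assembles the four accuracy
#' measures into a [MetricReport-class].
#'
#' @param extracted a [Centerline-class] (or `NULL` for an empty
#'   extraction).
#' @param reference a [ReferenceCenterline-class].
#' @param n resample count.
#' @param skipMm OF start-tolerance (mm).
#' @param otMinRadius OT clinical radius threshold (mm).
#' @return A [MetricReport-class].
#' @export
evaluateCenterline <- function(extracted, reference, n = 1000L, skipMm = 5,
                               otMinRadius = 0.75) {
    cls <- classifyPoints(extracted, reference, n = n)
    matchedRadii <- cls$refRadii[cls$refLabels == "TPR"]
    new("MetricReport",
        ov = metricOV(cls), of = metricOF(cls, skipMm = skipMm),
        ot = metricOT(cls, minRadius = otMinRadius), ai = metricAI(cls),
        counts = list(ov = cls$counts,
                      meanMatchedRadius = if (length(matchedRadii))
                          mean(matchedRadii) else NA_real_),
        nSamples = cls$n)
}
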