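# Validation metrics: DICE segmentation overlap and the CORA
# cross-correlation sub-method (shape V, size G, phase P) with equal-weight
# combination and two-level aggregation (per-channel -> per-case -> across
# cases, mean +/- sample SD).

#' DICE similarity coefficient of two binary masks
#'
#' \code{DICE(A, B) = 2 |A intersect B| / (|A| + |B|)}: 0 means no overlap,
#' 1 perfect overlap.  Two empty masks are defined as DICE 1 with a warning.
#'
#' @param A,B binary [ImageVolume-class] masks on the same grid, or plain
#'   arrays of identical shape.
#' @return DICE value in [0, 1].
#' @export
diceCoefficient <- function(A, B) {
  if (is(A, "ImageVolume")) {
    if (!identical(dim(imgData(A)), dim(imgData(B))) ||
        max(abs(imgAffine(A) - imgAffine(B))) > 1e-6)
      stop("DICE requires both masks on the same grid")
    A <- imgData(A); B <- imgData(B)
  } else if (!identical(dim(A), dim(B))) {
    stop("DICE requires arrays of identical shape")
  }
  a <- A > 0.5; b <- B > 0.5
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks empty; DICE defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' CORA settings constructor
#'
#' Defaults \code{dMin = 0.01}, \code{dMax = 0.12}, unit exponents.  The
#' combined score depends only on the (V + G + P)/3 combination; the window
#' and exponents are fully config-exposed.
#'
#' @param dMin,dMax admissible shift window as fractions of the evaluation
#'   interval length.
#' @param kV,kG,kP sub-rating exponents.
#' @param interval optional fixed evaluation interval \code{c(tMin, tMax)} ms.
#' @param resampleDt optional uniform resampling step, ms.
#' @return a [CoraSettings-class].
#' @export
coraSettings <- function(dMin = 0.01, dMax = 0.12, kV = 1, kG = 1, kP = 1,
                         interval = NA_real_, resampleDt = NA_real_) {
  new("CoraSettings", dMin = dMin, dMax = dMax, kV = kV, kG = kG, kP = kP,
      interval = as.numeric(interval), resampleDt = resampleDt)
}

#' CORA cross-correlation sub-ratings for a pair of time-history curves
#'
#' Both curves are linearly resampled onto a common uniform grid over the
#' evaluation interval (by default their temporal overlap, with the smaller
#' of the two native median steps).  The normalized cross-correlation
#' \code{K(delta)} is scanned over shifts \code{|delta| <= dMax * T} (T the
#' interval length), normalizing over the valid overlap at each shift;
#' \code{delta* = argmax K} (ties to the smallest |shift|).  Then
#' \itemize{
#'   \item shape \code{V = max(K(delta*), 0)^kV},
#'   \item phase \code{P = 1} if \code{|delta*|/T <= dMin}, 0 if
#'     \code{>= dMax}, else
#'     \code{((dMax - |delta*|/T) / (dMax - dMin))^kP},
#'   \item size \code{G = (min(Qr, Qc) / max(Qr, Qc))^kG} with
#'     \code{Q = integral of curve^2 dt} after applying \code{delta*} to the
#'     candidate.
#' }
#' All components are clipped to [0, 1].  A flat zero reference is an error
#' (the normalization is undefined).
#'
#' @param reference,candidate 2-column matrices or data.frames (time ms,
#'   value); each strictly increasing in time with a non-empty overlap.
#' @param settings a [CoraSettings-class].
#' @return a [CoraComponents-class].
#' @export
coraComponents <- function(reference, candidate, settings = coraSettings()) {
  ref <- .asCurve(reference); cand <- .asCurve(candidate)
  if (is.na(settings@interval[1])) {
    t0 <- max(min(ref[, 1]), min(cand[, 1]))
    t1 <- min(max(ref[, 1]), max(cand[, 1]))
  } else {
    t0 <- settings@interval[1]; t1 <- settings@interval[2]
  }
  if (t1 <= t0) stop("curves have no overlapping time interval")
  dt <- settings@resampleDt
  if (is.na(dt))
    dt <- min(stats::median(diff(ref[, 1])), stats::median(diff(cand[, 1])))
  tt <- seq(t0, t1, by = dt)
  Tlen <- t1 - t0
  f <- stats::approx(ref[, 1], ref[, 2], xout = tt, rule = 2)$y
  g <- stats::approx(cand[, 1], cand[, 2], xout = tt, rule = 2)$y
  if (all(abs(f) < 1e-300))
    stop("flat zero reference curve: CORA normalization undefined")
  nShift <- floor(settings@dMax * Tlen / dt)
  shifts <- (-nShift):nShift
  K <- vapply(shifts, function(s) {
    # positive s: candidate delayed by s*dt (candidate compared at t - delta)
    if (s >= 0) { fi <- f[seq_len(length(f) - s)]; gi <- g[(s + 1):length(g)] }
    else { fi <- f[(1 - s):length(f)]; gi <- g[seq_len(length(g) + s)] }
    den <- sqrt(sum(fi^2) * sum(gi^2))
    if (den < 1e-300) return(-Inf)
    sum(fi * gi) / den
  }, numeric(1))
  best <- which(K >= max(K) - 1e-12)
  bi <- best[which.min(abs(shifts[best]))]
  deltaStar <- shifts[bi] * dt
  V <- min(1, max(0, K[bi]))^settings@kV
  # a maximum attained at the scan boundary means the true best shift lies at
  # or beyond dMax * T: rated as the limit shift (phase 0)
  ratio <- if (nShift > 0L && abs(shifts[bi]) == nShift) settings@dMax
           else abs(deltaStar) / Tlen
  P <- if (ratio <= settings@dMin) 1
       else if (ratio >= settings@dMax) 0
       else ((settings@dMax - ratio) /
             (settings@dMax - settings@dMin))^settings@kP
  s <- shifts[bi]
  if (s >= 0) { fi <- f[seq_len(length(f) - s)]; gi <- g[(s + 1):length(g)] }
  else { fi <- f[(1 - s):length(f)]; gi <- g[seq_len(length(g) + s)] }
  Qr <- sum(fi^2) * dt; Qc <- sum(gi^2) * dt
  G <- if (max(Qr, Qc) < 1e-300) 1
       else (min(Qr, Qc) / max(Qr, Qc))^settings@kG
  new("CoraComponents", V = min(1, max(0, V)), G = min(1, max(0, G)),
      P = min(1, max(0, P)), bestShift = deltaStar, interval = c(t0, t1))
}

.asCurve <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("curves must have two columns (time, value)")
  if (any(diff(x[, 1]) <= 0)) stop("curve times must be strictly increasing")
  x
}

#' Combined CORA score: equal-weight mean of the sub-ratings
#'
#' \code{score = (V + G + P) / 3}, ranging 0 to 1 with 1 a perfect match.
#'
#' @param c a [CoraComponents-class], or a numeric vector \code{c(V, G, P)}.
#' @return the combined score.
#' @export
coraScore <- function(c) {
  if (is(c, "CoraComponents")) return((c@V + c@G + c@P) / 3)
  v <- as.numeric(c)
  if (length(v) != 3L) stop("expected three components (V, G, P)")
  if (any(v < 0 | v > 1)) stop("components must lie in [0, 1]")
  mean(v)
}

#' Aggregate CORA scores: mean and sample standard deviation
#'
#' Arithmetic mean with the n-1 (sample) standard deviation, matching the
#' across-case "mean +/- SD" summaries of validation tables; per-case scores
#' are themselves means over all evaluated channels, computed the same way.
#' A single score returns SD 0 with the attribute \code{singleton = TRUE}.
#'
#' @param scores non-empty numeric vector.
#' @param level bookkeeping tag, \code{"ndt"} (channels within a case) or
#'   \code{"case"} (cases within a summary); does not alter the arithmetic.
#' @return named numeric \code{c(mean, sd)} (with singleton attribute when
#'   applicable).
#' @export
aggregateScores <- function(scores, level = c("case", "ndt")) {
  level <- match.arg(level)
  if (!length(scores)) stop("cannot aggregate an empty score list")
  out <- c(mean = mean(scores),
           sd = if (length(scores) > 1L) stats::sd(scores) else 0)
  if (length(scores) == 1L) attr(out, "singleton") <- TRUE
  out
}
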