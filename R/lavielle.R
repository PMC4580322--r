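#' Penalized-contrast change-point segmentation (Lavielle)
#'
#' Exact dynamic-programming partition of a series into K homogeneous
#' segments, minimising the within-segment squared error about the segment
#' mean, subject to a minimum segment length. The number of segments is
#' chosen adaptively: the contrast J(K) is rescaled affinely so that it
#' decreases from Kmax - 1 at K = 1 to 0 at K = Kmax, and K* is the largest
#' K whose second difference of the rescaled contrast exceeds `alpha`
#' (K* = 1 when none does, i.e. the series is homogeneous).
#'
#' @param series Numeric vector (finite values; length >= 2 * Lmin).
#' @param Lmin Minimum segment length in points (default 5).
#' @param Kmax Maximum number of segments considered (default 20; capped at
#'   `floor(length(series) / Lmin)`).
#' @param alpha Threshold on the second difference of the rescaled contrast
#'   (default 0.75).
#' @return An object of class `lavielle_seg`: list with `series`, `K`,
#'   `changepoints` (last index of each segment but the final one),
#'   `segments` (tibble: start, end, mean, length), `contrast` (J(K) for
#'   K = 1..Kmax), and parameters.
#' @export
lavielle_segment <- function(series, Lmin = 5, Kmax = 20, alpha = 0.75) {
  y <- as.numeric(series)
  if (any(!is.finite(y))) abort("series must be finite; drop undefined values upstream")
  n <- length(y)
  if (n < 2 * Lmin) abort(sprintf("series too short: need >= %d points, got %d", 2 * Lmin, n))
  Kcap <- min(Kmax, n %/% Lmin)
  S1 <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y^2))
  segcost <- function(a, b) { # vectorised over a; cost of segment [a, b]
    len <- b - a + 1
    S2[b + 1] - S2[a] - (S1[b + 1] - S1[a])^2 / len
  }
  D <- matrix(Inf, Kcap, n)
  B <- matrix(NA_integer_, Kcap, n)
  D[1, Lmin:n] <- segcost(1, Lmin:n)
  if (Kcap > 1) {
    for (k in 2:Kcap) {
      for (i in (k * Lmin):n) {
        j <- ((k - 1) * Lmin):(i - Lmin)  # last index of segment k-1
        tot <- D[k - 1, j] + segcost(j + 1, i)
        m <- which.min(tot)
        D[k, i] <- tot[m]
        B[k, i] <- j[m]
      }
    }
  }
  J <- D[, n]
  K <- choose_K(J, alpha)
  ends <- integer(K)
  ends[K] <- n
  if (K > 1) for (k in K:2) ends[k - 1] <- B[k, ends[k]]
  starts <- c(1L, head(ends, -1) + 1L)
  segs <- tibble::tibble(
    start = starts, end = ends,
    mean = (S1[ends + 1] - S1[starts]) / (ends - starts + 1),
    length = ends - starts + 1L
  )
  structure(list(series = y, K = K, changepoints = head(ends, -1),
                 segments = segs, contrast = J,
                 Lmin = Lmin, Kmax = Kcap, alpha = alpha, modes = NULL),
            class = "lavielle_seg")
}

# adaptive choice of segment count from the contrast curve
choose_K <- function(J, alpha) {
  Kcap <- length(J)
  if (Kcap < 2 || !is.finite(J[1]) || J[1] - J[Kcap] <= 0) return(1L)
  Jt <- (J - J[Kcap]) / (J[1] - J[Kcap]) * (Kcap - 1)
  if (Kcap < 3) { # only K = 2 testable: compare drop J~(1) - J~(2) directly
    return(if (Jt[1] - Jt[2] > alpha) 2L else 1L)
  }
  K <- 2:(Kcap - 1)
  d2 <- Jt[K - 1] - 2 * Jt[K] + Jt[K + 1]
  hit <- K[d2 > alpha]
  if (length(hit) == 0) 1L else max(hit)
}

#' @export
print.lavielle_seg <- function(x, ...) {
  cat(sprintf("<lavielle_seg> n = %d, K = %d segment(s)\n", length(x$series), x$K))
  print(x$segments)
  invisible(x)
}

#' @export
tidy.lavielle_seg <- function(x, ...) {
  out <- x$segments
  if (!is.null(x$modes)) out$mode <- x$segment_modes
  out
}

#' Split segments into transiting and foraging modes
#'
#' Classifies the segments of a [lavielle_segment()] result into two classes
#' by the threshold on segment means that maximises the between-class
#' variance (1-D two-class split). Segments in the upper class (high FPT) are
#' labelled `ARS` (foraging), the rest `NoARS` (transiting). A single segment,
#' or all-equal means, yields all `NoARS`.
#'
#' @param seg A `lavielle_seg` object.
#' @return `seg` with `modes` (per-point labels) and `segment_modes` filled.
#' @export
classify_modes <- function(seg) {
  stopifnot(inherits(seg, "lavielle_seg"))
  m <- seg$segments$mean
  K <- seg$K
  if (K == 1 || length(unique(m)) == 1) {
    seg$segment_modes <- rep("NoARS", K)
  } else {
    len <- seg$segments$length
    # FPT is heavy-tailed: split on the log scale when all means are positive,
    # so the transit/foraging gap dominates spread within the foraging class
    if (all(m > 0)) m <- log(m)
    sm <- sort(unique(m))
    th <- vapply(seq_len(length(sm) - 1), function(i) (sm[i] + sm[i + 1]) / 2, numeric(1))
    # between-class variance of the point distribution (segments weighted by
    # length), maximised over thresholds between adjacent segment means
    bcv <- vapply(th, function(tt) {
      lo <- m <= tt
      w1 <- sum(len[lo]) / sum(len); w2 <- 1 - w1
      m1 <- sum(m[lo] * len[lo]) / sum(len[lo])
      m2 <- sum(m[!lo] * len[!lo]) / sum(len[!lo])
      w1 * w2 * (m1 - m2)^2
    }, numeric(1))
    cut <- th[which.max(bcv)]
    seg$segment_modes <- ifelse(m > cut, "ARS", "NoARS")
  }
  seg$modes <- rep(seg$segment_modes, seg$segments$length)
  seg
}
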