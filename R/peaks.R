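#' Locate modes of a distance distribution
#'
#' Finds local maxima above `threshold` times the global maximum and
#' partitions the probability mass between peaks at the intervening minima
#' (watershed), so each mode gets a center, height, mole fraction and an
#' RMS-width estimate.
#'
#' @param dist a [distance_distribution()]
#' @param threshold minimum relative height of a reported mode
#' @return data frame with columns `center`, `height`, `fraction`, `sd`,
#'   `lo`, `hi` (the mass-partition boundaries, nm)
#' @export
find_peaks <- function(dist, threshold = 0.01) {
  r <- dist$r; p <- dist$density
  n <- length(p)
  is_max <- which(p[2:(n - 1)] >= p[1:(n - 2)] & p[2:(n - 1)] > p[3:n]) + 1
  # include boundary maxima
  if (p[1] > p[2]) is_max <- c(1L, is_max)
  if (p[n] > p[n - 1]) is_max <- c(is_max, n)
  is_max <- is_max[p[is_max] >= threshold * max(p)]
  empty <- data.frame(center = numeric(0), height = numeric(0),
                      fraction = numeric(0), sd = numeric(0),
                      lo = numeric(0), hi = numeric(0))
  if (!length(is_max)) return(empty)
  is_max <- sort(is_max)
  # watershed boundaries: minimum between consecutive peaks
  bounds <- c(1L, vapply(seq_len(length(is_max) - 1), function(i) {
    seg <- is_max[i]:is_max[i + 1]
    seg[which.min(p[seg])]
  }, integer(1)), n)
  w <- trapz_weights(r)
  out <- lapply(seq_along(is_max), function(i) {
    seg <- bounds[i]:bounds[i + 1]
    mass <- sum(w[seg] * p[seg])
    mu <- sum(w[seg] * p[seg] * r[seg]) / mass
    v <- sum(w[seg] * p[seg] * (r[seg] - mu)^2) / mass
    data.frame(center = r[is_max[i]], height = p[is_max[i]],
               fraction = mass, sd = sqrt(max(v, 0)),
               lo = r[bounds[i]], hi = r[bounds[i + 1]])
  })
  out <- do.call(rbind, out)
  out$fraction <- out$fraction / sum(out$fraction)
  out
}
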