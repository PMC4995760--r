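#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical cdf and the class of unimodal distribution functions (convex up
#' to a mode, concave beyond it). It is computed by the iterative greatest
#' convex minorant / least concave majorant algorithm: the candidate modal
#' interval is narrowed to the location of the largest gap between the two
#' hulls, accumulating the one-sided deviations of the empirical cdf from
#' the committed convex and concave fits; the dip is half the largest such
#' deviation. The statistic is invariant under affine transformations of the
#' values (location, scale, reflection).
#'
#' @param x numeric vector (length >= 2 for a meaningful value).
#' @return the dip statistic, in `[0, 0.25]`; `0` for degenerate input.
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)

  low <- 1L
  high <- n
  D <- 1 # accumulated max deviation, in units of counts; 1 is the floor

  # interpolate the hull chord (a, b) at point t; a vertical chord (tied
  # values) covers every count at that x, so the deviation floor applies
  interp <- function(a, b, t) {
    if (x[b] == x[a]) return(NA_real_)
    a + (x[t] - x[a]) * (b - a) / (x[b] - x[a])
  }

  repeat {
    cand <- low:high
    gcm <- cand[hull_indices(x[cand], cand, lower = TRUE)]
    lcm <- cand[hull_indices(x[cand], cand, lower = FALSE)]
    l_gcm <- length(gcm)
    l_lcm <- length(lcm)

    if (l_gcm == 2 && l_lcm == 2) {
      d <- 1
      ig <- l_gcm # modal interval would be the whole range
      ih <- 1L
    } else {
      # walk both hulls bottom-up; the largest gap between the concave
      # majorant and the convex minorant locates the modal interval
      gcm_r <- rev(gcm) # descending in x: gcm_r[1] = high ... gcm_r[l_gcm] = low
      d <- 0
      ig <- l_gcm
      ih <- 1L
      ix <- l_gcm - 1L
      iv <- 2L
      repeat {
        if (gcm_r[ix] > lcm[iv]) {
          # lcm touchpoint inside gcm segment (gcm_r[ix+1], gcm_r[ix])
          a <- gcm_r[ix + 1L]
          b <- gcm_r[ix]
          t <- lcm[iv]
          line <- interp(a, b, t)
          dx <- if (is.na(line)) 1 else (t + 1) - line
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
          iv <- iv + 1L
          if (iv > l_lcm) iv <- l_lcm
        } else {
          # gcm touchpoint inside lcm segment (lcm[iv-1], lcm[iv])
          cc <- lcm[iv - 1L]
          dd <- lcm[iv]
          t <- gcm_r[ix]
          line <- interp(cc, dd, t)
          dx <- if (is.na(line)) 1 else line - (t - 1)
          if (dx >= d) {
            d <- dx
            ig <- ix
            ih <- iv
          }
          ix <- ix - 1L
          if (ix < 1L) ix <- 1L
        }
        if (gcm_r[ix] == lcm[iv]) break
      }
    }

    if (d <= D) break

    # one-sided deviations of the empirical cdf from the committed fits:
    # along the convex minorant below the modal interval ...
    dip_l <- 0
    if (ig < l_gcm) {
      gcm_r <- rev(gcm)
      for (j in ig:(l_gcm - 1L)) {
        a <- gcm_r[j + 1L]
        b <- gcm_r[j]
        dev <- 1
        if (b > a + 1L && x[b] > x[a]) {
          i <- (a + 1L):(b - 1L)
          line <- a + (x[i] - x[a]) * (b - a) / (x[b] - x[a])
          dev <- max(dev, i - line + 1)
        }
        if (dev > dip_l) dip_l <- dev
      }
    }
    # ... and along the concave majorant above it
    dip_u <- 0
    if (ih < l_lcm) {
      for (j in ih:(l_lcm - 1L)) {
        cc <- lcm[j]
        dd <- lcm[j + 1L]
        dev <- 1
        if (dd > cc + 1L && x[dd] > x[cc]) {
          i <- (cc + 1L):(dd - 1L)
          line <- cc + (x[i] - x[cc]) * (dd - cc) / (x[dd] - x[cc])
          dev <- max(dev, line - i + 1)
        }
        if (dev > dip_u) dip_u <- dev
      }
    }
    D <- max(D, dip_l, dip_u)
    new_low <- rev(gcm)[ig]
    new_high <- lcm[ih]
    if (new_low == low && new_high == high) break
    low <- new_low
    high <- new_high
    if (high - low < 1L) break
  }
  D / (2 * n)
}

# indices of the lower (convex) or upper (concave) hull of (x, y), x sorted
hull_indices <- function(x, y, lower = TRUE) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  s <- if (lower) 1 else -1
  h <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      cross <- (x[h[m]] - x[h[m - 1L]]) * (y[i] - y[h[m - 1L]]) -
        (x[i] - x[h[m - 1L]]) * (y[h[m]] - y[h[m - 1L]])
      if (s * cross > 0) break # h[m] is a strict hull vertex
      m <- m - 1L
    }
    m <- m + 1L
    h[m] <- i
  }
  h[seq_len(m)]
}

#' Monte-Carlo null distribution of the dip statistic
#'
#' Dip statistics of `B` uniform samples of size `n`. The uniform is the
#' asymptotically least favorable unimodal distribution for the dip, making
#' it the standard null for the test.
#'
#' @param n sample size.
#' @param B number of draws (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of `B` null dip values.
#' @export
dip_null_distribution <- function(n, B = 1000, seed = 1) {
  set.seed(seed)
  vapply(seq_len(B), function(b) dip_statistic(stats::runif(n)), 0)
}

#' Dip test with Monte-Carlo p-value
#'
#' @param x numeric vector.
#' @param B number of null draws (default 1000).
#' @param seed RNG seed for the null draws.
#' @param null optional pre-computed null distribution (from
#'   [dip_null_distribution()] with matching `n`), reused across many tests.
#' @return list with `statistic` and `p_value` (add-one Monte-Carlo estimate).
#' @export
dip_test <- function(x, B = 1000, seed = 1, null = NULL) {
  if (is.null(null)) null <- dip_null_distribution(length(x), B = B, seed = seed)
  stat <- dip_statistic(x)
  p <- (1 + sum(null >= stat)) / (1 + length(null))
  list(statistic = stat, p_value = p)
}
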