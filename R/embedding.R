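#' Embedding delay from average mutual information
#'
#' Computes the average mutual information (AMI) between the series and its
#' lagged copy over lags up to `max_lag_s`, using equiquantile binning with
#' `floor(sqrt(n / 5))` bins, and returns the lag of the first local
#' minimum. If no local minimum exists (e.g. white noise), the first lag at
#' which AMI drops below `1/e` of its lag-0 value is used; failing that,
#' one sample.
#'
#' @param x numeric series (>= 200 samples).
#' @param fs sampling rate, Hz.
#' @param max_lag_s largest lag to scan, seconds.
#' @return list with `tau_s`, `tau_samples`, `ami` (lag profile),
#'   `rule` (`"local_min"` or `"one_over_e"`).
#' @export
select_delay_ami <- function(x, fs, max_lag_s = 2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 200L)
    stop("insufficient data: need at least 200 samples", call. = FALSE)
  nb <- max(2L, floor(sqrt(n / 5)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nb + 1L),
                               names = FALSE))
  if (length(br) < 3L)
    stop("degenerate series: zero entropy under equiquantile binning",
         call. = FALSE)
  bx <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  max_lag <- max(2L, min(round(max_lag_s * fs), n - 50L))
  ami <- vapply(0:max_lag, function(lag) {
    a <- bx[1:(n - lag)]; b <- bx[(1 + lag):n]
    tab <- table(a, b) / (n - lag)
    px <- rowSums(tab); py <- colSums(tab)
    pp <- tab[tab > 0]
    ee <- outer(px, py)[tab > 0]
    sum(pp * log(pp / ee))
  }, numeric(1))
  # first local minimum of the (lightly smoothed) profile; estimator
  # ripple is ignored by requiring the subsequent rise to be material
  ams <- stats::filter(ami, rep(1 / 3, 3), sides = 2)
  ams[c(1, length(ami))] <- ami[c(1, length(ami))]
  d1 <- diff(ams)
  loc <- which(d1[-length(d1)] < 0 & d1[-1] > 0) + 1L
  prominence <- vapply(loc, function(k) {
    ahead <- ams[(k + 1L):min(k + 10L, length(ams))]
    max(ahead) - ams[k]
  }, numeric(1))
  loc <- loc[prominence > 0.02 * ami[1]]
  if (length(loc)) {
    lag <- loc[1] - 1L
    rule <- "local_min"
  } else {
    below <- which(ami < ami[1] / exp(1))
    lag <- if (length(below)) below[1] - 1L else 1L
    if (lag < 1L) lag <- 1L
    rule <- "one_over_e"
  }
  list(tau_s = lag / fs, tau_samples = as.integer(lag), ami = ami,
       rule = rule)
}

#' Embedding dimension from false nearest neighbours
#'
#' Kennel-style false-nearest-neighbour test: for each candidate dimension
#' m, the nearest neighbour of each embedded point is declared false when
#' adding the (m+1)-th coordinate stretches the pair by more than `rtol`
#' relative to its m-dimensional distance, or beyond `atol` attractor
#' radii. The smallest m with a false-neighbour fraction below 1% is
#' returned; when none qualifies, `max_dim` with a warning.
#'
#' @param x numeric series (>= 500 samples).
#' @param tau_s embedding delay, seconds.
#' @param fs sampling rate, Hz.
#' @param max_dim largest dimension to test.
#' @param rtol,atol Kennel tolerances.
#' @param max_points cap on embedded points used (subsampled evenly) to
#'   bound the O(n^2) neighbour search.
#' @return list with `m`, `fnn_fraction` (per tested dimension), `warning`
#'   (TRUE when no dimension met the 1% criterion).
#' @export
select_dim_fnn <- function(x, tau_s, fs, max_dim = 10L, rtol = 15, atol = 2,
                           max_points = 1000L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 500L)
    stop("insufficient data: need at least 500 samples", call. = FALSE)
  tau <- max(1L, round(tau_s * fs))
  sigma <- stats::sd(x)
  if (sigma == 0)
    stop("degenerate series: zero variance", call. = FALSE)
  frac <- rep(NA_real_, max_dim)
  for (m in seq_len(max_dim)) {
    n_emb <- n - m * tau            # leave room for the (m+1)-th coordinate
    if (n_emb < 50L) break
    emb <- .delay_embed(x[seq_len(n - tau)], m, tau)
    emb <- emb[seq_len(n_emb), , drop = FALSE]
    keep <- if (n_emb > max_points)
      round(seq(1L, n_emb, length.out = max_points)) else seq_len(n_emb)
    sub <- emb[keep, , drop = FALSE]
    D <- as.matrix(stats::dist(sub))
    diag(D) <- Inf
    # Theiler exclusion: temporal neighbours are not candidate neighbours
    D[abs(outer(keep, keep, "-")) <= tau] <- Inf
    nn <- max.col(-D)
    dm <- D[cbind(seq_along(nn), nn)]
    extra_i <- x[keep + m * tau]
    extra_j <- x[keep[nn] + m * tau]
    stretch <- abs(extra_i - extra_j)
    d_next <- sqrt(dm^2 + stretch^2)
    # exact duplicates in m dimensions (plateaus, repeated states) cannot
    # support the relative-stretch test; only the absolute criterion applies
    false_nn <- ifelse(dm > 0,
                       (stretch / dm > rtol) | (d_next / sigma > atol),
                       d_next / sigma > atol)
    frac[m] <- mean(false_nn)
    if (frac[m] < 0.01)
      return(list(m = m, fnn_fraction = frac[seq_len(m)], warning = FALSE))
  }
  warning("false-nearest-neighbour fraction never fell below 1%; ",
          "returning max_dim", call. = FALSE)
  list(m = as.integer(max_dim), fnn_fraction = frac, warning = TRUE)
}
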