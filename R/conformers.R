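#' Gaussian kernel density estimate on a CCS axis
#'
#' Works from raw CCS samples or from an existing `ccs_distribution`
#' (grid points weighted by density). Bandwidth defaults to Silverman's
#' rule; the bandwidth used is recorded in the output attributes.
#'
#' @param x Numeric CCS samples, or a `ccs_distribution`.
#' @param bw Bandwidth (A^2) or a rule name accepted by
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @param n Grid size.
#' @param from,to Grid limits (defaults: data range padded by 3 bandwidths).
#' @return A `ccs_distribution` (unit area) with attribute `bw`.
#' @export
kde_ccs <- function(x, bw = "nrd0", n = 512, from = NULL, to = NULL) {
  if (inherits(x, "ccs_distribution")) {
    w <- x$density / sum(x$density)
    samples <- x$ccs
  } else {
    samples <- x
    w <- rep(1 / length(samples), length(samples))
  }
  if (length(samples) < 2) stop("need at least 2 samples")
  if (stats::var(samples) == 0 || (is.numeric(w) &&
      sum(w > 0) == 1)) {
    warning("zero-variance samples: density degenerates to a delta")
  }
  args <- list(x = samples, weights = w, bw = bw, n = n)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  out <- ccs_distribution(d$x, pmax(d$y, 0))
  attr(out, "bw") <- d$bw
  out
}

.conformer_labels <- c("alpha", "beta", "gamma", "delta", "epsilon",
                       "zeta", "eta", "theta")

#' Detect conformer populations in a CCS distribution
#'
#' Peak picking on the (optionally re-smoothed) density with a prominence
#' threshold, followed by Gaussian mixture refinement of centroids, widths
#' and weights by nonlinear least squares. Peaks are labelled alpha, beta,
#' gamma, ... in ascending CCS order, matching the conformer nomenclature
#' used in multistage mobility experiments. The default 5% prominence is
#' low enough to retain minor extended conformers.
#'
#' @param ccsd A `ccs_distribution`.
#' @param max_peaks Maximum number of conformers returned (by prominence).
#' @param prominence Minimum peak prominence, fraction of the density
#'   maximum.
#' @param smooth_bw Optional Gaussian smoothing bandwidth (A^2) applied
#'   before picking; default 1.5 grid steps.
#' @param refine Run the Gaussian-mixture refinement (default TRUE).
#' @return A `conformer_set` tibble: `label`, `centroid`, `width`,
#'   `weight` (weights sum to 1).
#' @export
detect_conformers <- function(ccsd, max_peaks = 6, prominence = 0.05,
                              smooth_bw = NULL, refine = TRUE) {
  x <- ccsd$ccs; y <- ccsd$density
  h <- stats::median(diff(x))
  smooth_bw <- smooth_bw %||% (1.5 * h)
  if (smooth_bw > 0) {
    k <- stats::dnorm(seq(-4 * smooth_bw, 4 * smooth_bw, by = h), 0,
                      smooth_bw)
    k <- k / sum(k)
    y <- stats::filter(c(rep(y[1], length(k)), y, rep(y[length(y)],
                                                      length(k))),
                       k, sides = 2)
    y <- as.numeric(y)[length(k) + seq_along(x)]
  }
  pk <- find_peaks(y, prominence * max(y))
  if (nrow(pk) == 0) stop("no peak above the prominence threshold")
  pk <- pk[order(pk$prominence, decreasing = TRUE), ][
    seq_len(min(max_peaks, nrow(pk))), ]
  pk <- pk[order(pk$index), ]
  centroids <- x[pk$index]
  heights <- y[pk$index]
  widths <- vapply(seq_len(nrow(pk)), function(i) {
    # half-max walk, stopped at the first valley so overlapping neighbours
    # do not inflate the estimate
    half <- heights[i] / 2
    j <- pk$index[i]
    l <- j; while (l > 1 && y[l] > half && y[l - 1] <= y[l]) l <- l - 1
    r <- j; while (r < length(y) && y[r] > half && y[r + 1] <= y[r]) r <- r + 1
    w <- (x[r] - x[l]) / (2 * sqrt(2 * log(2)))
    gap <- min(abs(centroids[-i] - centroids[i]), Inf)
    max(min(w, gap / 2.355, na.rm = TRUE), h)
  }, numeric(1))

  if (refine && nrow(pk) >= 1) {
    np <- nrow(pk)
    mix <- function(p) {
      a <- exp(p[seq_len(np)])
      mu <- p[np + seq_len(np)]
      s <- exp(p[2 * np + seq_len(np)])
      rowSums(vapply(seq_len(np), function(k) {
        a[k] * exp(-0.5 * ((x - mu[k]) / s[k])^2)
      }, numeric(length(x))))
    }
    p0 <- c(log(heights), centroids, log(widths))
    # keep each component tied to its picked peak so refinement sharpens
    # rather than reassigns peaks
    lower <- c(log(heights) - 5, centroids - 3 * widths,
               log(pmax(widths / 4, h)))
    upper <- c(log(heights) + 2, centroids + 3 * widths,
               log(widths * 4))
    fit <- minpack.lm::nls.lm(par = p0, fn = function(p) y - mix(p),
                              lower = lower, upper = upper,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100))
    p <- fit$par
    a <- exp(p[seq_len(np)])
    centroids <- p[np + seq_len(np)]
    widths <- exp(p[2 * np + seq_len(np)])
    weights <- a * widths
  } else {
    weights <- heights * widths
  }
  ord <- order(centroids)
  out <- tibble(
    label = .conformer_labels[seq_along(ord)],
    centroid = centroids[ord], width = widths[ord],
    weight = (weights / sum(weights))[ord]
  )
  structure(out, class = c("conformer_set", class(out)))
}

# local maxima with topographic prominence above min_prom
find_peaks <- function(y, min_prom) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1
  if (length(is_max) == 0) {
    return(tibble(index = integer(0), prominence = numeric(0)))
  }
  prom <- vapply(is_max, function(i) {
    # walk out to the nearest higher terrain on each side; the base is the
    # lowest point passed; prominence = height - higher of the two bases
    left <- y[seq_len(i - 1)]
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    lb <- base_level(rev(left), y[i])
    rb <- base_level(right, y[i])
    y[i] - max(lb, rb)
  }, numeric(1))
  keep <- prom >= min_prom
  tibble(index = is_max[keep], prominence = prom[keep])
}

base_level <- function(path, height) {
  if (length(path) == 0) return(min(height, min(path, Inf)))
  higher <- which(path > height)
  seg <- if (length(higher)) path[seq_len(higher[1])] else path
  min(seg)
}
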