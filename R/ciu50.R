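#' Fit CIU50 transition midpoints to a fingerprint
#'
#' The intensity-weighted CCS centroid of each energy column is fitted with
#' a sequential-logistic model: n_states plateau CCS levels joined by
#' n_states - 1 logistic steps,
#' c(E) = A1 + sum_i (A_{i+1} - A_i) / (1 + exp(-(E - m_i)/w_i)).
#' The fitted midpoints m_i are the CIU50 values: the collision energy at
#' which half the ions have moved to the next conformation. Midpoints are
#' initialised at the steepest-gradient energies of the centroid curve,
#' plateaus at the first/last column centroids, and all parameters are
#' bounded by the energy span and CCS range.
#'
#' @param fp A [ciu_fingerprint()].
#' @param n_states Number of conformational states (>= 2).
#' @return A `ciu50_result`: list with `transitions` (tibble: `transition`,
#'   `ciu50`, `width`, `ccs_from`, `ccs_to`), `centroids`, `vcov`,
#'   `converged`, `rss`, `in_span` (FALSE if a midpoint sits on the energy
#'   boundary). `tidy()` returns the transitions, `glance()` the fit
#'   summary.
#' @examples
#' fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
#'                             seq(50, 150, 2.5),
#'                             generator_config(seed = 7))
#' tidy(fit_ciu50(fp, 2))
#' @export
fit_ciu50 <- function(fp, n_states = 2) {
  stopifnot(n_states >= 2)
  cen <- fp_centroids(fp)
  E <- cen$energy_ev; y <- cen$centroid
  if (length(E) < 2 * n_states) stop("too few energy levels for the model")
  span <- range(E)
  nt <- n_states - 1

  # initial midpoints: energies of the nt largest centroid gradients
  grad <- abs(diff(y) / diff(E))
  mids <- (E[-1] + E[-length(E)]) / 2
  m0 <- sort(mids[order(grad, decreasing = TRUE)][seq_len(nt)])
  # initial plateaus: first/last centroids, interior levels between midpoints
  cuts <- c(span[1] - 1, m0, span[2] + 1)
  A0 <- vapply(seq_len(n_states), function(s) {
    sel <- E >= cuts[s] & E < cuts[s + 1]
    if (any(sel)) mean(y[sel]) else stats::approx(E, y, xout = m0[min(s, nt)])$y
  }, numeric(1))
  w0 <- rep(diff(span) / 20, nt)

  model <- function(p, E) {
    A <- p[seq_len(n_states)]
    m <- p[n_states + seq_len(nt)]
    w <- p[n_states + nt + seq_len(nt)]
    out <- rep(A[1], length(E))
    for (i in seq_len(nt)) {
      out <- out + (A[i + 1] - A[i]) * stats::plogis((E - m[i]) / w[i])
    }
    out
  }
  p0 <- c(A0, m0, w0)
  lower <- c(rep(min(fp$ccs), n_states), rep(span[1], nt),
             rep(0.2, nt))
  upper <- c(rep(max(fp$ccs), n_states), rep(span[2], nt),
             rep(diff(span) / 2, nt))
  res <- minpack.lm::nls.lm(
    par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
    fn = function(p) y - model(p, E),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- res$par
  A <- p[seq_len(n_states)]
  m <- p[n_states + seq_len(nt)]
  w <- p[n_states + nt + seq_len(nt)]
  ord <- order(m)
  rss <- sum(res$fvec^2)
  dof <- max(length(E) - length(p), 1)
  vcov <- tryCatch(solve(res$hessian) * 2 * rss / dof,
                   error = function(e) matrix(NA_real_, length(p), length(p)))
  converged <- res$info %in% 1:4
  if (!converged) {
    warning("CIU50 fit did not converge (residual ", format(rss), ")")
  }
  in_span <- all(m > span[1] + 1e-6 & m < span[2] - 1e-6)
  if (!in_span) warning("fitted transition(s) at the energy boundary")
  transitions <- tibble(
    transition = seq_len(nt), ciu50 = m[ord], width = w[ord],
    ccs_from = A[c(1, ord + 1)][seq_len(nt)], ccs_to = A[ord + 1]
  )
  structure(list(transitions = transitions, centroids = cen,
                 plateaus = A, vcov = vcov, converged = converged,
                 rss = rss, in_span = in_span, model = model, par = p),
            class = "ciu50_result")
}

#' @export
print.ciu50_result <- function(x, ...) {
  cat("<ciu50_result> ", nrow(x$transitions), " transition(s)\n", sep = "")
  print(x$transitions)
  invisible(x)
}

#' @rdname fit_ciu50
#' @param x A `ciu50_result`.
#' @param ... Unused.
#' @export
tidy.ciu50_result <- function(x, ...) x$transitions

#' @rdname fit_ciu50
#' @export
glance.ciu50_result <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, in_span = x$in_span,
         n_states = length(x$plateaus))
}
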