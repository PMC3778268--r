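# Scaled conjugate gradients (Moller 1993), the classic neural-network-era
# minimizer: conjugate directions with a model-trust-region scaling lambda in
# place of a line search. `fn` must return list(f = value, g = gradient); one
# call yields both (the GP evidence and its gradient share their expensive
# factorization).
#
# Accepted steps strictly decrease f, so the evidence trace of a GP fit is
# non-increasing in nlml by construction.
scg_minimize <- function(par, fn, maxit = 200, tol = 1e-5, ftol = 1e-10) {
  sigma0 <- 1e-4
  w <- par
  ev <- fn(w)
  fw <- ev$f
  gw <- ev$g
  if (!is.finite(fw)) stop("objective not finite at the initial point")
  trace_f <- fw
  p <- -gw
  r <- -gw
  lambda <- 1e-6
  lambdabar <- 0
  success <- TRUE
  pnorm2 <- sum(p^2)
  delta <- 0
  n_eval <- 1L
  for (k in seq_len(maxit)) {
    if (success) {
      pnorm2 <- sum(p^2)
      if (pnorm2 < .Machine$double.eps) break
      sigma <- sigma0 / sqrt(pnorm2)
      g_probe <- fn(w + sigma * p)$g
      n_eval <- n_eval + 1L
      if (any(!is.finite(g_probe))) { lambda <- lambda * 10; next }
      s <- (g_probe - gw) / sigma
      delta <- sum(p * s)
    }
    delta2 <- delta + (lambda - lambdabar) * pnorm2
    if (delta2 <= 0) {
      lambdabar <- 2 * (lambda - delta2 / pnorm2)
      delta2 <- -delta2 + lambda * pnorm2
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta2
    ev_new <- fn(w + alpha * p)
    n_eval <- n_eval + 1L
    Delta <- if (is.finite(ev_new$f)) 2 * delta2 * (fw - ev_new$f) / mu^2 else -1
    if (is.finite(Delta) && Delta >= 0) {
      f_old <- fw
      w <- w + alpha * p
      fw <- ev_new$f
      gw <- ev_new$g
      trace_f <- c(trace_f, fw)
      r_new <- -gw
      lambdabar <- 0
      success <- TRUE
      if (k %% length(w) == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- max(lambda * 0.25, 1e-15)
      if (max(abs(gw)) < tol) break
      if (abs(f_old - fw) < ftol * (abs(f_old) + ftol)) break
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25)
      lambda <- lambda + delta2 * (1 - Delta) / pnorm2
    if (lambda > 1e15) break
  }
  list(par = w, value = fw, grad = gw, trace = trace_f,
       iterations = k, n_eval = n_eval)
}
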