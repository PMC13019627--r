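# Continuous resilient (CoRe) optimizer: Adam-style first and second
# moments with a momentum coefficient beta1(t) that relaxes from beta1a
# to beta1b under a Gaussian decay of width beta1c, plus an exponential
# learning-rate schedule eta(t) = eta0 * r^(t/T).

#' Initialize CoRe optimizer state
#'
#' @param n number of parameters.
#' @param eta0 base learning rate.
#' @param beta1a,beta1b,beta1c momentum schedule: \eqn{\beta_1(t) =
#'   \beta_1^b + (\beta_1^a - \beta_1^b) \exp[-((t-1)/\beta_1^c)^2]}.
#' @param beta2 second-moment decay.
#' @param eps denominator regularizer.
#' @param decay learning-rate decay factor \code{r} over the full run:
#'   \code{eta(T) = r * eta0}.
#' @param total_steps total step count \code{T} of the schedule.
#' @return object of class \code{core_state} with zeroed moments.
#' @export
core_state <- function(n, eta0 = 0.05, beta1a = 0.9, beta1b = 0.5,
                       beta1c = 100, beta2 = 0.99, eps = 1e-8,
                       decay = 1, total_steps = 1L) {
  if (decay <= 0 || decay > 1) stop("decay rate must be in (0, 1]")
  if (total_steps < 1L) stop("total_steps must be >= 1")
  structure(list(g = numeric(n), h2 = numeric(n), t = 0L,
                 eta0 = eta0, beta1a = beta1a, beta1b = beta1b,
                 beta1c = beta1c, beta2 = beta2, eps = eps,
                 decay = decay, total_steps = total_steps),
            class = "core_state")
}

#' Exponentially decaying learning rate
#'
#' \eqn{\eta(t) = \eta_0\, r^{t/T}}: the rate starts at \eqn{\eta_0} and
#' ends at \eqn{r \eta_0} after \eqn{T} steps (\code{r = 1} gives a
#' constant schedule).
#'
#' @param t current step.
#' @param total_steps total step count \code{T}.
#' @param decay decay factor \code{r} in \code{(0, 1]}.
#' @param eta0 base learning rate.
#' @return learning rate at step \code{t}.
#' @export
learning_rate <- function(t, total_steps, decay, eta0) {
  if (decay <= 0) stop("decay rate must be positive")
  eta0 * decay^(t / total_steps)
}

#' One CoRe update
#'
#' Advances the step counter, updates the biased moments with the given
#' gradient, and returns the bias-corrected, RMS-normalized parameter
#' increment \eqn{-\eta(t) \hat g / (\sqrt{\hat h} + \epsilon)}.
#'
#' @param state a \code{\link{core_state}}.
#' @param F gradient vector (finite).
#' @return \code{list(state = <updated state>, increment = <parameter
#'   change>)}.
#' @export
core_update <- function(state, F) {
  if (any(!is.finite(F))) stop("nonfinite gradient passed to core_update")
  t <- state$t + 1L
  b1 <- state$beta1b + (state$beta1a - state$beta1b) *
    exp(-((t - 1) / state$beta1c)^2)
  g <- b1 * state$g + (1 - b1) * F
  h2 <- state$beta2 * state$h2 + (1 - state$beta2) * F^2
  ghat <- g / (1 - b1^t)
  hhat <- sqrt(h2 / (1 - state$beta2^t))
  eta <- learning_rate(t, state$total_steps, state$decay, state$eta0)
  state$g <- g
  state$h2 <- h2
  state$t <- t
  list(state = state, increment = -eta * ghat / (hhat + state$eps))
}
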