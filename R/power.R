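#' Power of a chi-square restriction test
#'
#' Power of a likelihood-ratio test with `df` degrees of freedom at level
#' `alpha` against an alternative of effect size `w` observed over
#' `n_trials` trials: the upper tail, beyond the central chi-square
#' critical value, of the noncentral chi-square distribution with
#' noncentrality \eqn{\lambda = N w^2}.
#'
#' @param n_trials Number of trials entering the tested model.
#' @param w Cohen's w effect size (>= 0; at `w = 0` the power equals
#'   `alpha`).
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom of the test (1 for all battery tests).
#' @return Power in \eqn{[\alpha, 1)}.
#' @examples
#' chi2_power(10176, 0.03)  # ~ .86
#' @export
chi2_power <- function(n_trials, w, alpha = 0.05, df = 1) {
  .check_alpha(alpha)
  if (any(n_trials <= 0) || any(w < 0)) {
    stop("n_trials must be positive and w nonnegative")
  }
  crit <- stats::qchisq(alpha, df = df, lower.tail = FALSE)
  stats::pchisq(crit, df = df, ncp = n_trials * w^2, lower.tail = FALSE)
}

#' Trials required for a target power
#'
#' Solves the noncentral chi-square power equation for the sample size.
#' Two numbers are returned: `planning_n`, the conventional planning value
#' \eqn{\mathrm{round}(\lambda^*/w^2)} where \eqn{\lambda^*} is the exact
#' real-valued noncentrality at which power equals `target_power` (this is
#' what standard power software prints), and `smallest_n`, the smallest
#' integer trial count whose power actually reaches the target (the two can
#' differ by one through rounding).
#'
#' @param w Effect size to detect (> 0).
#' @param alpha Significance level.
#' @param target_power Desired power, with `alpha < target_power < 1`.
#' @param df Degrees of freedom.
#' @return List with `planning_n`, `smallest_n`, `lambda_star`, and the
#'   achieved power at each.
#' @examples
#' required_trials(0.03, 0.05, 0.80)$planning_n  # 8721
#' @export
required_trials <- function(w, alpha = 0.05, target_power = 0.80, df = 1) {
  .check_alpha(alpha)
  if (w <= 0) stop("w must be positive")
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must lie strictly between alpha and 1")
  }
  crit <- stats::qchisq(alpha, df = df, lower.tail = FALSE)
  pw <- function(lambda) {
    stats::pchisq(crit, df = df, ncp = lambda, lower.tail = FALSE)
  }
  hi <- 1
  while (pw(hi) < target_power) hi <- hi * 2
  lambda_star <- stats::uniroot(function(l) pw(l) - target_power,
                                lower = 0, upper = hi, tol = 1e-10)$root
  planning_n <- max(1L, round(lambda_star / w^2))
  # smallest integer N reaching the target (rounding can fall either side)
  n <- max(1L, floor(lambda_star / w^2))
  while (chi2_power(n, w, alpha, df) < target_power) n <- n + 1L
  while (n > 1L && chi2_power(n - 1L, w, alpha, df) >= target_power) n <- n - 1L
  list(planning_n = planning_n, smallest_n = n, lambda_star = lambda_star,
       power_at_planning_n = chi2_power(max(1L, planning_n), w, alpha, df),
       power_at_smallest_n = chi2_power(n, w, alpha, df))
}

#' Participants needed for a trial budget
#'
#' @param required_trials Total trials required by the design analysis.
#' @param trials_per_participant Analyzed trials each participant
#'   contributes to the tested model.
#' @return `ceiling(required_trials / trials_per_participant)`.
#' @examples
#' required_participants(8721, 96)  # 91
#' @export
required_participants <- function(required_trials, trials_per_participant) {
  if (any(required_trials <= 0) || any(trials_per_participant <= 0)) {
    stop("both arguments must be positive")
  }
  as.integer(ceiling(required_trials / trials_per_participant))
}

.check_alpha <- function(alpha) {
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must lie in (0, 1)")
}
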