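#' Prospect-theory utility parameters
#'
#' Two-part power value function relative to a reference point:
#' \deqn{u(x) = s\,(x - x_0)^{\alpha} \quad (x \ge x_0), \qquad
#'       u(x) = -\lambda\, s\,(x_0 - x)^{\beta} \quad (x < x_0),}
#' with gain curvature \eqn{\alpha}, loss curvature \eqn{\beta}, scale
#' \eqn{s} and loss aversion \eqn{\lambda}. The default calibration is
#' anchored so that, under control conditions, a gain of 79 has utility
#' +50 and a loss of 48 has utility -50 (the gamble-indifference anchors),
#' with the canonical prospect-theory curvature 0.88.
#'
#' @param gain_exponent,loss_exponent Curvatures in (0, 1].
#' @param gain_scale Utility units per value^exponent (> 0).
#' @param loss_aversion_lambda Loss-aversion multiplier (> 0).
#' @param reference_point Value mapped to zero utility.
#' @return A `utility_params` object.
#' @seealso [calibrate_utility()] for solving the scale and loss aversion
#'   from a pair of anchors.
#' @export
utility_params <- function(gain_exponent = 0.88, loss_exponent = 0.88,
                           gain_scale = NULL, loss_aversion_lambda = NULL,
                           reference_point = 0) {
  stopifnot(gain_exponent > 0, gain_exponent <= 1,
            loss_exponent > 0, loss_exponent <= 1)
  if (is.null(gain_scale) || is.null(loss_aversion_lambda)) {
    cal <- calibrate_utility(gain_anchor = c(79, 50),
                             loss_anchor = c(-48, -50),
                             gain_exponent = gain_exponent,
                             loss_exponent = loss_exponent,
                             reference_point = reference_point)
    if (is.null(gain_scale)) gain_scale <- cal$gain_scale
    if (is.null(loss_aversion_lambda))
      loss_aversion_lambda <- cal$loss_aversion_lambda
  }
  stopifnot(gain_scale > 0, loss_aversion_lambda > 0)
  structure(list(gain_exponent = gain_exponent,
                 loss_exponent = loss_exponent, gain_scale = gain_scale,
                 loss_aversion_lambda = loss_aversion_lambda,
                 reference_point = reference_point),
            class = "utility_params")
}

#' Solve utility scale and loss aversion from two anchors
#'
#' Given a gain anchor \eqn{(x_g, u_g)} and a loss anchor \eqn{(x_l, u_l)},
#' returns the `gain_scale` and `loss_aversion_lambda` for which the
#' two-part power function passes through both.
#'
#' @param gain_anchor,loss_anchor Length-2 vectors `c(value, utility)`.
#' @inheritParams utility_params
#' @return List with `gain_scale` and `loss_aversion_lambda`.
#' @export
calibrate_utility <- function(gain_anchor = c(79, 50),
                              loss_anchor = c(-48, -50),
                              gain_exponent = 0.88, loss_exponent = 0.88,
                              reference_point = 0) {
  stopifnot(gain_anchor[1] > reference_point, gain_anchor[2] > 0,
            loss_anchor[1] < reference_point, loss_anchor[2] < 0)
  s <- gain_anchor[2] / (gain_anchor[1] - reference_point)^gain_exponent
  lam <- -loss_anchor[2] /
    (s * (reference_point - loss_anchor[1])^loss_exponent)
  list(gain_scale = s, loss_aversion_lambda = lam)
}

#' Agency context for the decision layer
#'
#' The decision layer sees agency through two multipliers: `g(A)` scaling
#' the utility of gains and `l(A)` scaling the utility of losses, both 1
#' at the control level and increasing with agency, with gains amplified
#' more than losses (the dopamine system contributes far more to valuing
#' gains than losses). Defaults anchored to the worked high-agency values:
#' at `A = A_high`, a control-utility +50 gain becomes +69
#' (`g = 69/50 = 1.38`) and a control -50 loss becomes -53
#' (`l = 53/50 = 1.06`). Intermediate levels interpolate linearly in
#' (multiplier - 1); below control both multipliers stay at 1.
#'
#' A context can also carry the tonic DA level from a circuit simulation
#' (see [context_from_recording()]) for DA-coupled probability weighting
#' and temporal discounting.
#'
#' @param agency Agency level in \eqn{[0, 1]}.
#' @param A_control,A_high Reference levels (defaults 0.35 and 0.85).
#' @param gain_multiplier_high,loss_multiplier_high Multipliers at
#'   `A_high`.
#' @param gain_multiplier,loss_multiplier Optional explicit multipliers
#'   (override the interpolation).
#' @param tonic_da Optional tonic DA level, a.u.
#' @return An `agency_context` object.
#' @examples
#' agency_context(0.85)  # high agency: g = 1.38, l = 1.06
#' @export
agency_context <- function(agency, A_control = 0.35, A_high = 0.85,
                           gain_multiplier_high = 1.38,
                           loss_multiplier_high = 1.06,
                           gain_multiplier = NULL, loss_multiplier = NULL,
                           tonic_da = NULL) {
  stopifnot(agency >= 0, agency <= 1, A_high > A_control)
  frac <- max(0, (agency - A_control) / (A_high - A_control))
  if (is.null(gain_multiplier))
    gain_multiplier <- 1 + frac * (gain_multiplier_high - 1)
  if (is.null(loss_multiplier))
    loss_multiplier <- 1 + frac * (loss_multiplier_high - 1)
  stopifnot(gain_multiplier >= 1, loss_multiplier >= 1)
  if (gain_multiplier < loss_multiplier)
    stop("gain multiplier must be at least the loss multiplier")
  structure(list(agency = agency, A_control = A_control, A_high = A_high,
                 gain_multiplier = gain_multiplier,
                 loss_multiplier = loss_multiplier, tonic_da = tonic_da),
            class = "agency_context")
}

#' @export
print.agency_context <- function(x, ...) {
  cat(sprintf("Agency context: A = %.2f (g = %.3f, l = %.3f%s)\n",
              x$agency, x$gain_multiplier, x$loss_multiplier,
              if (!is.null(x$tonic_da))
                sprintf(", tonic DA = %.2f", x$tonic_da) else ""))
  invisible(x)
}

#' Build an agency context from a circuit recording
#'
#' Uses the simulated DA population as the tonic-DA proxy: the number of
#' non-silent DA neurons times their mean rate, normalized by the same
#' quantity under control, forms `tonic_da` (1 = control level).
#'
#' @param recording An `adds_recording`.
#' @param control_recording Reference recording at the control level.
#' @param ... Passed to [agency_context()].
#' @return An `agency_context` with `tonic_da` set.
#' @export
context_from_recording <- function(recording, control_recording, ...) {
  proxy <- function(rec) {
    st <- classify_da_states(rec)
    r <- attr(st, "rate")
    act <- st != "silent"
    sum(act) * mean(r[act])
  }
  lev <- tail(recording$agency$levels, 1)
  agency_context(lev, tonic_da = proxy(recording) / proxy(control_recording),
                 ...)
}

#' Agency-dependent utility
#'
#' Evaluates the two-part power utility with the context's gain and loss
#' multipliers applied: gains are scaled by `g(A)`, losses by `l(A)`.
#'
#' @param x Outcome value(s).
#' @param params A [utility_params()].
#' @param ctx An [agency_context()]; defaults to the control context.
#' @return Utility (vectorized over `x`).
#' @examples
#' u <- utility_params()
#' utility(79, u)                       # +50 at control
#' utility(79, u, agency_context(0.85)) # +69 at high agency
#' utility(-48, u, agency_context(0.85))# -53
#' @export
utility <- function(x, params = utility_params(),
                    ctx = agency_context(0.35)) {
  stopifnot(inherits(params, "utility_params"))
  d <- x - params$reference_point
  gain <- params$gain_scale * pmax(d, 0)^params$gain_exponent
  loss <- -params$loss_aversion_lambda * params$gain_scale *
    pmax(-d, 0)^params$loss_exponent
  ifelse(d >= 0, ctx$gain_multiplier * gain, ctx$loss_multiplier * loss)
}

#' Probability-weighting parameters
#'
#' @param distortion_gamma Distortion parameter in (0, 1]; 1 is no
#'   distortion.
#' @param da_modulation Signed coefficient coupling tonic DA to the
#'   distortion (0 by default: the direction of the DA effect on
#'   probability weighting is left neutral).
#' @param mode `"identity"` (default) or `"one_parameter_weighting"`
#'   (inverse-S weighting).
#' @return A `prob_weight_params` object.
#' @export
prob_weight_params <- function(distortion_gamma = 0.61, da_modulation = 0,
                               mode = c("identity",
                                        "one_parameter_weighting")) {
  mode <- match.arg(mode)
  stopifnot(distortion_gamma > 0, distortion_gamma <= 1)
  structure(list(distortion_gamma = distortion_gamma,
                 da_modulation = da_modulation, mode = mode),
            class = "prob_weight_params")
}

#' Subjective probability weight
#'
#' Identity mode returns `p`. Weighting mode applies the one-parameter
#' inverse-S function
#' \deqn{\pi(p) = \frac{p^{\gamma}}{\left(p^{\gamma} +
#'   (1-p)^{\gamma}\right)^{1/\gamma}},}
#' which overweights small probabilities and underweights large ones, with
#' fixed endpoints \eqn{\pi(0)=0}, \eqn{\pi(1)=1}. If the context carries
#' `tonic_da`, the effective \eqn{\gamma} is shifted by
#' `da_modulation * (tonic_da - 1)` and clipped to (0, 1].
#'
#' @param p Probability in \eqn{[0, 1]} (vectorized).
#' @param params A [prob_weight_params()].
#' @param ctx An [agency_context()].
#' @return Weight(s) in \eqn{[0, 1]}.
#' @export
probability_weight <- function(p, params = prob_weight_params(),
                               ctx = agency_context(0.35)) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (params$mode == "identity") return(p)
  g <- params$distortion_gamma
  if (!is.null(ctx$tonic_da) && params$da_modulation != 0)
    g <- min(max(g + params$da_modulation * (ctx$tonic_da - 1), 1e-6), 1)
  p^g / (p^g + (1 - p)^g)^(1 / g)
}

#' A gamble
#'
#' A finite set of (value, probability, delay) outcomes. Probabilities
#' must sum to 1; delays are in days (0 = immediate).
#'
#' @param values Outcome values.
#' @param probabilities Outcome probabilities (sum to 1 within 1e-9).
#' @param delays Outcome delays, days.
#' @return A `gamble` object.
#' @examples
#' gamble(c(79, -48), c(0.5, 0.5))  # the coin-toss gamble
#' @export
gamble <- function(values, probabilities, delays = 0) {
  stopifnot(length(values) >= 1,
            length(values) == length(probabilities))
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must sum to 1")
  delays <- rep_len(delays, length(values))
  if (any(delays < 0)) stop("delays must be non-negative")
  structure(list(values = values, probabilities = probabilities,
                 delays = delays), class = "gamble")
}

#' Expected (weighted, discounted) utility of a gamble
#'
#' \deqn{U = \sum_{i=1}^{r} \pi(p_i)\, u(x_i)\, D(t_i),}
#' with the probability weight \eqn{\pi}, the agency-dependent utility
#' \eqn{u}, and the hyperbolic discount factor \eqn{D} applied to delayed
#' outcomes. With identity weighting and zero delays this is standard
#' expected utility.
#'
#' @param g A [gamble()].
#' @param uparams A [utility_params()].
#' @param wparams A [prob_weight_params()].
#' @param ctx An [agency_context()].
#' @param dparams A [discount_params()] (used only for nonzero delays).
#' @return Expected utility (utility units).
#' @examples
#' g <- gamble(c(79, -48), c(0.5, 0.5))
#' expected_utility(g, ctx = agency_context(0.35))  # 0: indifference
#' expected_utility(g, ctx = agency_context(0.85))  # +8
#' @export
expected_utility <- function(g, uparams = utility_params(),
                             wparams = prob_weight_params(),
                             ctx = agency_context(0.35),
                             dparams = discount_params()) {
  stopifnot(inherits(g, "gamble"))
  u <- utility(g$values, uparams, ctx)
  w <- probability_weight(g$probabilities, wparams, ctx)
  D <- ifelse(g$delays > 0,
              discount_factor(g$delays, effective_alpha(dparams, ctx)), 1)
  sum(w * u * D)
}

#' Accept, reject, or be indifferent to a gamble
#'
#' Accepts when the expected utility exceeds `tolerance`, rejects when it
#' is below `-tolerance`, is indifferent otherwise.
#'
#' @inheritParams expected_utility
#' @param tolerance Indifference band, utility units.
#' @return `"accept"`, `"reject"`, or `"indifferent"`.
#' @export
accept_gamble <- function(g, uparams = utility_params(),
                          wparams = prob_weight_params(),
                          ctx = agency_context(0.35),
                          dparams = discount_params(),
                          tolerance = 1e-9) {
  eu <- expected_utility(g, uparams, wparams, ctx, dparams)
  if (eu > tolerance) "accept"
  else if (eu < -tolerance) "reject"
  else "indifferent"
}

#' Hyperbolic discount factor
#'
#' \deqn{D(t) = \frac{1}{1 + \alpha t},} with \eqn{D(0) = 1}; larger
#' \eqn{\alpha} means steeper temporal discounting.
#'
#' @param t Delay(s), same time units as `1/alpha` (days by default
#'   elsewhere).
#' @param alpha Discounting rate, > 0.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(t, alpha) {
  stopifnot(alpha > 0)
  if (any(t < 0)) stop("delays must be non-negative")
  1 / (1 + alpha * t)
}

#' Temporal-discounting parameters with U-shaped DA coupling
#'
#' The discounting rate depends on tonic DA through a convex (U-shaped)
#' function minimized at `da_optimum`:
#' \deqn{\log \alpha(\mathrm{DA}) = \log \alpha_{\min} +
#'   \kappa\,(\mathrm{DA} - \mathrm{DA}_{opt})^2.}
#' Below the optimum, raising DA (e.g. via agency) reduces discounting;
#' past the optimum (the overdose regime) it increases discounting again.
#'
#' @param alpha Baseline discounting rate when no DA information is
#'   available, 1/days.
#' @param alpha_min Minimum rate, attained at the optimum.
#' @param da_optimum Tonic DA level (a.u., 1 = control) of minimum
#'   discounting.
#' @param curvature U-shape strength \eqn{\kappa} (>= 0).
#' @return A `discount_params` object.
#' @export
discount_params <- function(alpha = 0.01, alpha_min = 0.005,
                            da_optimum = 1.5, curvature = 2) {
  stopifnot(alpha > 0, alpha_min > 0, curvature >= 0)
  structure(list(alpha = alpha, alpha_min = alpha_min,
                 da_optimum = da_optimum, curvature = curvature),
            class = "discount_params")
}

#' Discounting rate from tonic DA
#'
#' @param tonic_da Tonic DA level, a.u. (>= 0).
#' @param params A [discount_params()].
#' @return The discounting rate alpha (1/days).
#' @export
alpha_from_da <- function(tonic_da, params = discount_params()) {
  if (any(tonic_da < 0)) stop("tonic_da must be non-negative")
  exp(log(params$alpha_min) +
        params$curvature * (tonic_da - params$da_optimum)^2)
}

# alpha actually used by a context: DA-coupled when tonic_da is known,
# otherwise the baseline alpha
effective_alpha <- function(dparams, ctx) {
  if (!is.null(ctx$tonic_da)) alpha_from_da(ctx$tonic_da, dparams)
  else dparams$alpha
}

#' Choose between a sooner-smaller and a later-larger reward
#'
#' Picks the option with the greater discounted utility
#' \eqn{u(x) D(t)}; ties go to the sooner option (the impulsive default).
#'
#' @param sooner,later Length-2 vectors `c(value, delay_days)`; the later
#'   option must have the longer delay.
#' @param uparams A [utility_params()].
#' @param dparams A [discount_params()].
#' @param ctx An [agency_context()].
#' @return `"sooner"` or `"later"`, with attribute `values` holding both
#'   discounted utilities.
#' @export
choose_delayed <- function(sooner, later, uparams = utility_params(),
                           dparams = discount_params(),
                           ctx = agency_context(0.35)) {
  if (later[2] <= sooner[2]) stop("later option must have the longer delay")
  a <- effective_alpha(dparams, ctx)
  vs <- utility(sooner[1], uparams, ctx) * discount_factor(sooner[2], a)
  vl <- utility(later[1], uparams, ctx) * discount_factor(later[2], a)
  out <- if (vl > vs) "later" else "sooner"
  attr(out, "values") <- c(sooner = vs, later = vl)
  out
}
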