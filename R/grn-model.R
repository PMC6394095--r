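#' Biochemical parameter set for the regulator--target network
#'
#' Bundles the rate constants of the simplest bacterial transcription unit:
#' a constitutively expressed regulator `R` that, in the presence of a
#' constant environmental signal `S`, converts to its active form `R*`,
#' which (acting as a dimer) activates production of a target protein `T`.
#' The dynamics are
#' \deqn{dR/dt = bas - k_{act} R S + k_r R^* - k_d R}
#' \deqn{dR^*/dt = k_{act} R S - k_r R^* - k_d R^*}
#' \deqn{dT/dt = \beta R^{*2} / (K_m^2 + R^{*2}) - k_{dT} T}
#'
#' The reversion rate `k_r` is not independently evolvable: by default it is
#' coupled to the activation rate as `k_r = kr_ratio * k_act`
#' (`kr_ratio = 1e-3`). Supplying `k_r` directly overrides the coupling.
#'
#' @param bas basal regulator production rate (concentration/time); may be 0.
#' @param k_act activation rate constant of `R -> R*` (per signal per time).
#' @param k_d degradation/dilution rate of both `R` and `R*` (1/time).
#' @param beta maximal target production rate (concentration/time); may be 0.
#' @param K_m active-regulator concentration at half-maximal target
#'   production (concentration).
#' @param k_dT degradation/dilution rate of the target (1/time).
#' @param kr_ratio coupling ratio giving `k_r = kr_ratio * k_act`.
#' @param k_r optional explicit reversion rate overriding the coupling.
#' @return An object of class `param_set` (a named list).
#' @export
#' @examples
#' p <- param_set(bas = 0.1, k_act = 0.5, k_d = 1e-3,
#'                beta = 1, K_m = 50, k_dT = 1e-3)
#' steady_state(p, S = 1)
param_set <- function(bas, k_act, k_d, beta, K_m, k_dT,
                      kr_ratio = 1e-3, k_r = NULL) {
  pos <- c(k_act = k_act, k_d = k_d, K_m = K_m, k_dT = k_dT)
  nn <- c(bas = bas, beta = beta)
  if (any(!is.finite(c(pos, nn))) || any(pos <= 0) || any(nn < 0))
    stop("invalid parameter set: rate constants must be finite and strictly positive, production rates non-negative",
         call. = FALSE)
  k_r <- k_r %||% (kr_ratio * k_act)
  if (!is.finite(k_r) || k_r <= 0)
    stop("invalid parameter set: k_r must be finite and strictly positive", call. = FALSE)
  structure(list(bas = bas, k_act = k_act, k_d = k_d, beta = beta,
                 K_m = K_m, k_dT = k_dT, k_r = k_r),
            class = "param_set")
}

#' Closed-form steady state of the regulator--target network
#'
#' Solves the fixed point of the dynamics analytically:
#' `R = bas (k_r + k_d) / (k_d (k_r + k_d + k_act S))`,
#' `R* = k_act R S / (k_r + k_d)`,
#' `T = (beta / k_dT) R*^2 / (K_m^2 + R*^2)`.
#' Adaptive walks evaluate millions of genotypes, so the steady state is
#' always computed in closed form; [integrate_dynamics()] exists as an
#' independent numerical cross-check.
#'
#' @param p a [param_set()].
#' @param S constant signal level, `S >= 0`.
#' @return An object of class `steady_state`: list with `R`, `R_star`, `T`.
#' @seealso [steady_state_residuals()] to verify the fixed point,
#'   [integrate_dynamics()] for the ODE route.
#' @export
steady_state <- function(p, S = 1) {
  stopifnot(inherits(p, "param_set"))
  if (!is.finite(S) || S < 0) stop("signal level S must be finite and >= 0", call. = FALSE)
  kr <- p$k_r
  kd <- p$k_d
  R  <- p$bas * (kr + kd) / (kd * (kr + kd + p$k_act * S))
  Rs <- p$k_act * R * S / (kr + kd)
  T  <- (p$beta / p$k_dT) * (Rs * Rs) / (p$K_m * p$K_m + Rs * Rs)
  structure(list(R = R, R_star = Rs, T = T), class = "steady_state")
}

#' Right-hand sides of the dynamics at a candidate state
#'
#' @param p a [param_set()].
#' @param S signal level.
#' @param state list or numeric with `R`, `R_star`, `T`.
#' @return Numeric vector `c(dR, dR_star, dT)`.
#' @export
steady_state_residuals <- function(p, S = 1, state) {
  R <- state$R %||% state[[1]]
  Rs <- state$R_star %||% state[[2]]
  T <- state$T %||% state[[3]]
  c(dR = p$bas - p$k_act * R * S + p$k_r * Rs - p$k_d * R,
    dR_star = p$k_act * R * S - p$k_r * Rs - p$k_d * Rs,
    dT = p$beta * Rs^2 / (p$K_m^2 + Rs^2) - p$k_dT * T)
}

#' Numerically integrate the network dynamics
#'
#' Stiff integration (lsoda) of the three-species system; the long-time
#' limit converges to [steady_state()] for any non-negative initial
#' condition, which makes this the independent oracle for the closed form.
#'
#' @param p a [param_set()].
#' @param S signal level.
#' @param init initial `(R, R_star, T)`, default the origin.
#' @param t_end final time; defaults to 60 relaxation times of the slowest
#'   first-order sink, `60 / min(k_d, k_dT)`.
#' @param n_out number of output time points.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `time`, `R`, `R_star`, `T`.
#' @export
integrate_dynamics <- function(p, S = 1, init = c(R = 0, R_star = 0, T = 0),
                               t_end = NULL, n_out = 50,
                               rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(p, "param_set"))
  if (any(init < 0)) stop("initial condition must be non-negative", call. = FALSE)
  t_end <- t_end %||% (60 / min(p$k_d, p$k_dT))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  rhs <- function(t, y, parms) {
    list(unname(steady_state_residuals(p, S, list(R = y[1], R_star = y[2], T = y[3]))))
  }
  times <- seq(0, t_end, length.out = n_out)
  y0 <- c(R = unname(init[1]), R_star = unname(init[2]), T = unname(init[3]))
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop("ODE integration failed (istate = ", istate, ")", call. = FALSE)
  out <- as.data.frame(out)
  names(out) <- c("time", "R", "R_star", "T")
  out
}

#' Constants of the cost-benefit fitness function
#'
#' Benefit saturates in the steady-state target level, `B = a T / (T + b)`;
#' cost is proportional to the total steady-state protein burden,
#' `C = alpha (T + R* + R)`; fitness is `F = B - C`.
#'
#' @param a benefit saturation level (default 1).
#' @param b target level at half-maximal benefit (default 10).
#' @param alpha cost per molecule times degradation constant
#'   (default 2.5e-5).
#' @return An object of class `fitness_constants`.
#' @export
fitness_constants <- function(a = 1, b = 10, alpha = 2.5e-5) {
  if (!all(is.finite(c(a, b, alpha))) || a <= 0 || b <= 0 || alpha < 0)
    stop("fitness constants require a > 0, b > 0, alpha >= 0", call. = FALSE)
  structure(list(a = a, b = b, alpha = alpha), class = "fitness_constants")
}

#' Benefit, cost and fitness of a steady state
#'
#' @param ss a [steady_state()].
#' @param fc a [fitness_constants()].
#' @return An object of class `fitness_components`: list with `B`, `C`, `F`.
#' @export
fitness_components <- function(ss, fc = fitness_constants()) {
  B <- fc$a * ss$T / (ss$T + fc$b)
  C <- fc$alpha * (ss$T + ss$R_star + ss$R)
  structure(list(B = B, C = C, F = B - C), class = "fitness_components")
}

#' Fitness of a parameter set (steady state composed with cost-benefit)
#'
#' @param p a [param_set()].
#' @param S signal level.
#' @param fc a [fitness_constants()].
#' @return A `fitness_components` object.
#' @export
genotype_fitness <- function(p, S = 1, fc = fitness_constants()) {
  fitness_components(steady_state(p, S), fc)
}

#' Model configuration shared by landscape-level operations
#'
#' Groups the signal level, the fitness constants and the `k_r` coupling
#' rule so landscape, walk and ensemble functions take a single argument.
#' With `kr_const = NULL` (default) the reversion rate is proportional to
#' the activation rate, `k_r = kr_ratio * k_act`; a numeric `kr_const`
#' fixes `k_r` at that value for every genotype instead.
#'
#' @param S constant signal level (default 1; dimensionless saturating
#'   signal).
#' @param constants a [fitness_constants()].
#' @param kr_ratio coupling ratio for `k_r = kr_ratio * k_act`.
#' @param kr_const optional fixed reversion rate overriding the coupling.
#' @return An object of class `grn_model`.
#' @export
grn_model <- function(S = 1, constants = fitness_constants(),
                      kr_ratio = 1e-3, kr_const = NULL) {
  if (!is.finite(S) || S < 0) stop("signal level S must be finite and >= 0", call. = FALSE)
  stopifnot(inherits(constants, "fitness_constants"))
  structure(list(S = S, constants = constants,
                 kr_ratio = kr_ratio, kr_const = kr_const),
            class = "grn_model")
}

# Vectorized closed-form fitness over a matrix of raw parameter values
# (columns in .PARAMS order). Operation order mirrors src/walk.cpp exactly
# so the two routes agree bitwise.
.fitness_vec <- function(P, model) {
  dimnames(P) <- NULL
  bas <- P[, 1L]; k <- P[, 2L]; kd <- P[, 3L]
  beta <- P[, 4L]; Km <- P[, 5L]; kdT <- P[, 6L]
  kr <- if (is.null(model$kr_const)) model$kr_ratio * k else rep(model$kr_const, length(k))
  S <- model$S
  fc <- model$constants
  R  <- bas * (kr + kd) / (kd * (kr + kd + k * S))
  Rs <- k * R * S / (kr + kd)
  T  <- (beta / kdT) * (Rs * Rs) / (Km * Km + Rs * Rs)
  B  <- fc$a * T / (T + fc$b)
  C  <- fc$alpha * (T + Rs + R)
  list(R = R, R_star = Rs, T = T, B = B, C = C, F = B - C)
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> R = %.6g, R* = %.6g, T = %.6g\n", x$R, x$R_star, x$T))
  invisible(x)
}

#' @export
print.fitness_components <- function(x, ...) {
  cat(sprintf("<fitness> B = %.6g, C = %.6g, F = %.6g\n", x$B, x$C, x$F))
  invisible(x)
}

#' @export
print.grn_model <- function(x, ...) {
  fc <- x$constants
  cat(sprintf("<grn_model> S = %g, a = %g, b = %g, alpha = %g, k_r %s\n",
              x$S, fc$a, fc$b, fc$alpha,
              if (is.null(x$kr_const)) sprintf("= %g * k_act", x$kr_ratio)
              else sprintf("= %g (fixed)", x$kr_const)))
  invisible(x)
}
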