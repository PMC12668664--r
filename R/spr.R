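# Single-cycle-kinetics SPR under the 1:1 Langmuir model: closed-form
# simulation, global nonlinear least-squares fitting, K_D = kd/ka.
#
# During an injection at analyte concentration C the surface response
# follows dR/dt = ka*C*(Rmax - R) - kd*R, whose solution from a phase
# boundary is
#   R(t) = Req + (R0 - Req) * exp(-(ka*C + kd) * (t - t0)),
#   Req  = ka*C*Rmax / (ka*C + kd);
# during dissociation (C = 0) it decays as R0 * exp(-kd * (t - t0)).
# Single-cycle kinetics chains these phases without regeneration, so
# each phase inherits the previous phase's final response.

#' Single-cycle injection schedule
#'
#' Builds the phase table for a single-cycle kinetics run: each analyte
#' concentration is injected for `t_inject` seconds followed by
#' `t_dissoc` seconds of dissociation before the next injection.  The
#' default series is five 2-fold steps from 31.25 to 500 nM with
#' 120 s phases, the standard protocol for antibody/MHC affinity
#' measurements.
#'
#' @param concentrations analyte concentrations in molar, in injection
#'   order.
#' @param t_inject injection phase length, seconds.
#' @param t_dissoc dissociation phase length, seconds.
#' @return An `sck_schedule`: data frame with `t_start`, `t_end`,
#'   `conc` (M), attribute `t_end` giving the terminal time.
#' @examples
#' sck_schedule()            # 31.25 -> 500 nM, 120 s phases
#' @export
sck_schedule <- function(concentrations = 500e-9 / 2^(4:0),
                         t_inject = 120, t_dissoc = 120) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (t_inject <= 0 || t_dissoc < 0) stop("phase lengths must be positive")
  n <- length(concentrations)
  starts <- (seq_len(n) - 1) * (t_inject + t_dissoc)
  ph <- data.frame(
    t_start = as.vector(rbind(starts, starts + t_inject)),
    t_end = as.vector(rbind(starts + t_inject, starts + t_inject + t_dissoc)),
    conc = as.vector(rbind(concentrations, rep(0, n))))
  as_sck_schedule(ph)
}

#' Validate and class a phase table as a schedule
#'
#' @param phases data frame with `t_start`, `t_end`, `conc` (M);
#'   phases must be contiguous non-overlapping and increasing.
#' @return An `sck_schedule`.
#' @export
as_sck_schedule <- function(phases) {
  stopifnot(all(c("t_start", "t_end", "conc") %in% names(phases)))
  if (any(phases$conc < 0)) stop("concentrations must be >= 0")
  if (any(phases$t_end <= phases$t_start)) stop("phases must have t_end > t_start")
  if (nrow(phases) > 1 &&
      any(abs(phases$t_start[-1] - phases$t_end[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and increasing")
  structure(phases, class = c("sck_schedule", "data.frame"),
            t_end = max(phases$t_end))
}

#' Kinetic parameters of the 1:1 Langmuir model
#'
#' @param ka association rate, 1/(M s).
#' @param kd dissociation rate, 1/s.
#' @param Rmax surface capacity, RU.
#' @param R0 response at t = 0, RU.
#' @return A `kinetic_params` list; `KD` is derived as exactly
#'   `kd / ka` (molar).
#' @export
kinetic_params <- function(ka, kd, Rmax, R0 = 0) {
  if (ka <= 0 || kd <= 0 || Rmax <= 0) stop("ka, kd, Rmax must be > 0")
  structure(list(ka = ka, kd = kd, Rmax = Rmax, R0 = R0, KD = kd / ka),
            class = "kinetic_params")
}

#' Equilibrium dissociation constant from kinetic rates
#'
#' @param params a `kinetic_params`.
#' @return `kd / ka`, molar.
#' @export
kd_of <- function(params) params$kd / params$ka

#' Closed-form 1:1 response over a phase schedule
#'
#' @param times numeric vector of times (s) within the schedule span.
#' @param params a `kinetic_params`.
#' @param schedule an `sck_schedule`.
#' @return response in RU at each time; continuous across phase
#'   boundaries (each phase starts from the previous phase's final
#'   response).
#' @export
sck_response <- function(times, params, schedule) {
  ka <- params$ka; kd <- params$kd; Rmax <- params$Rmax
  out <- numeric(length(times))
  r_at <- params$R0
  for (p in seq_len(nrow(schedule))) {
    t0 <- schedule$t_start[p]; t1 <- schedule$t_end[p]
    C <- schedule$conc[p]
    in_phase <- times >= t0 & (times < t1 | (p == nrow(schedule) & times <= t1))
    if (C > 0) {
      kobs <- ka * C + kd
      req <- ka * C * Rmax / kobs
      if (any(in_phase))
        out[in_phase] <- req + (r_at - req) * exp(-kobs * (times[in_phase] - t0))
      r_at <- req + (r_at - req) * exp(-kobs * (t1 - t0))
    } else {
      if (any(in_phase))
        out[in_phase] <- r_at * exp(-kd * (times[in_phase] - t0))
      r_at <- r_at * exp(-kd * (t1 - t0))
    }
  }
  out
}

#' Simulate a single-cycle kinetics sensorgram
#'
#' Piecewise closed-form 1:1 model with chained initial conditions,
#' plus optional Gaussian noise reproducible from `seed`.
#'
#' @param schedule an `sck_schedule`.
#' @param params a `kinetic_params`.
#' @param noise_sd Gaussian noise standard deviation, RU (0 = none).
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @param dt time step, seconds.
#' @return A `sensorgram`: data frame `time`, `response` with
#'   attributes `schedule`, `noise_sd`, `seed`.
#' @export
simulate_sck <- function(schedule, params, noise_sd = 0, seed = NULL,
                         dt = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  times <- seq(0, attr(schedule, "t_end"), by = dt)
  resp <- sck_response(times, params, schedule)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    resp <- resp + rnorm(length(resp), 0, noise_sd)
  }
  structure(data.frame(time = times, response = resp),
            class = c("sensorgram", "data.frame"),
            schedule = schedule, noise_sd = noise_sd, seed = seed)
}

.sck_predict <- function(p, times, schedule) {
  sck_response(times,
               list(ka = exp(p[1]), kd = exp(p[2]), Rmax = p[3], R0 = p[4]),
               schedule)
}

#' Globally fit a sensorgram to the 1:1 single-cycle model
#'
#' Nonlinear least squares over (log ka, log kd, Rmax, R0) on the full
#' trace, with multistart over a log-uniform grid of rate constants
#' (ka in 1e3..1e7 1/(M s), kd in 1e-5..1e-1 1/s); the best converged
#' restart wins.
#'
#' @param sgram a `sensorgram` (or data frame with `time`, `response`).
#' @param schedule the `sck_schedule` (defaults to the sensorgram's
#'   attribute).
#' @param init optional `kinetic_params` used as the first start.
#' @param n_restarts number of multistart points (default 16).
#' @return An `sck_fit`: list with `params` (`kinetic_params` incl.
#'   `KD`), `rss`, `se` (standard errors for log ka, log kd, Rmax, R0),
#'   `converged`, `n_restarts`, `restart_rss`.
#' @export
fit_sck <- function(sgram, schedule = attr(sgram, "schedule"), init = NULL,
                    n_restarts = 16) {
  if (is.null(schedule)) stop("no schedule supplied or attached")
  times <- sgram$time; resp <- sgram$response
  if (var(resp) < 1e-9)
    stop("flat sensorgram (variance < 1e-9 RU^2): parameters not identifiable")
  cpos <- unique(schedule$conc[schedule$conc > 0])
  if (length(cpos) < 2)
    stop("at least two distinct analyte concentrations are required ",
         "for an identifiable single-cycle fit")
  n_grid <- max(1, ceiling(sqrt(n_restarts)))
  ka0 <- 10^seq(3, 7, length.out = n_grid)
  kd0 <- 10^seq(-5, -1, length.out = n_grid)
  starts <- expand.grid(log_ka = log(ka0), log_kd = log(kd0))
  starts <- starts[seq_len(min(nrow(starts), n_restarts)), , drop = FALSE]
  rmax0 <- max(resp) * 1.5
  if (rmax0 <= 0) rmax0 <- 1
  start_list <- lapply(seq_len(nrow(starts)), function(i)
    c(starts$log_ka[i], starts$log_kd[i], rmax0, resp[1]))
  if (!is.null(init))
    start_list <- c(list(c(log(init$ka), log(init$kd), init$Rmax, init$R0)),
                    start_list)
  best <- NULL
  restart_rss <- numeric(0)
  for (p0 in start_list) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) resp - .sck_predict(p, times, schedule),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) { restart_rss <- c(restart_rss, NA); next }
    rss <- sum(fit$fvec^2)
    restart_rss <- c(restart_rss, rss)
    conv <- fit$info %in% 1:3
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && rss < best$rss))
      best <- list(fit = fit, rss = rss, conv = conv)
  }
  if (is.null(best)) stop("all restarts failed")
  p <- best$fit$par
  se <- tryCatch({
    covm <- best$rss / (length(resp) - 4) *
      solve(best$fit$hessian)
    sqrt(pmax(0, diag(covm)))
  }, error = function(e) rep(NA_real_, 4))
  names(se) <- c("log_ka", "log_kd", "Rmax", "R0")
  params <- kinetic_params(exp(p[1]), exp(p[2]), max(p[3], .Machine$double.eps),
                           p[4])
  structure(list(params = params, rss = best$rss, se = se,
                 converged = best$conv,
                 n_restarts = length(start_list),
                 restart_rss = restart_rss),
            class = "sck_fit")
}

#' @export
print.sck_fit <- function(x, ...) {
  p <- x$params
  cat("1:1 single-cycle kinetic fit", if (!x$converged) " (NOT converged; unreliable)",
      ":\n", sep = "")
  cat(sprintf("  ka   = %.4g 1/(M s)\n  kd   = %.4g 1/s\n  Rmax = %.4g RU\n",
              p$ka, p$kd, p$Rmax))
  cat(sprintf("  KD   = %.4g M (%.4g nM)\n  RSS  = %.4g RU^2\n",
              p$KD, p$KD * 1e9, x$rss))
  invisible(x)
}

#' Reference K_D table for antibody/HLA and KIR/HLA binding
#'
#' A packaged table of reported equilibrium dissociation constants used
#' to annotate fit reports: the wild-type antibody/HLA-B*44:05 affinity,
#' the extremes of the peptide position-8 substitution series, the
#' HLA-A*02:01 alpha2-1 transplant mutants that gain binding, and the
#' affinity range typical of KIR/HLA interactions.  Values are
#' annotation fixtures, not measurements made by this package.
#'
#' @return data frame with `label`, `kd_molar`, `kd_display`, `source`.
#' @export
load_kd_fixtures <- function() {
  path <- system.file("extdata", "kd_reference.csv", package = "epiblock")
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
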