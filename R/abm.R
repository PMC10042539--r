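#' Parameters for the agent-based transfer model
#'
#' Bundles and validates the parameters of the agent-based Monte-Carlo model
#' of tumor-population growth under sporadic mitochondrial transfer. Each cell
#' agent grows exponentially (Euler update `m <- m * (1 + k*dt)`), where the
#' growth constant is `k0` for cells without transferred mitochondria and
#' `k0*r` for carriers. Per time step, each non-carrier gains mitochondria
#' with probability `f*dt/Td`, and a cell that exceeds twice its birth mass
#' divides into two half-mass daughters, exactly one of which inherits the
#' carrier state.
#'
#' By default `k0` is calibrated to the discrete update so that one mass
#' doubling takes exactly `Td` at step size `dt`, i.e.
#' `k0 = (2^(dt/Td) - 1)/dt`. With `growth_calibration = "continuous"` the
#' continuous-time constant `k0 = log(2)/Td` is used instead, which doubles
#' slightly slower than `Td` under the Euler discretization.
#'
#' @param n0 Initial number of cell agents.
#' @param m0 Initial dry mass per agent (pg).
#' @param f Fraction of the population gaining transferred mitochondria per
#'   doubling time (dimensionless, in `[0, 1]`).
#' @param r Growth-rate multiplier for carrier cells (dimensionless, >= 1).
#' @param Td Population doubling time (h).
#' @param dt Simulation time step (h); must satisfy `dt <= Td/20`.
#' @param d_target Number of population doublings to simulate.
#' @param k0 Baseline exponential growth constant (1/h), or `NULL` to derive
#'   it from `Td` and `growth_calibration`.
#' @param growth_calibration `"discrete"` (default) or `"continuous"`; see
#'   Details.
#' @param divide_loss `"one_daughter"` (default: exactly one daughter of a
#'   carrier keeps the mitochondria) or `"bernoulli"` (each daughter keeps
#'   them independently with probability 1/2).
#' @param agent_cap Maximum number of simulated agents before uniform
#'   subsampling back to `n0` (with exact mass bookkeeping) is applied.
#' @param seed RNG seed used by [run_simulation()].
#'
#' @return An object of class `"abm_params"` (a named list).
#' @seealso [run_simulation()], [relative_increase()]
#' @export
#' @examples
#' p <- abm_params(n0 = 100, d_target = 5)
#' p$k0 * p$Td  # close to log(2)
abm_params <- function(n0 = 1000, m0 = 250, f = 0.05, r = 1.15, Td = 40,
                       dt = Td / 100, d_target = 20, k0 = NULL,
                       growth_calibration = c("discrete", "continuous"),
                       divide_loss = c("one_daughter", "bernoulli"),
                       agent_cap = 2L * n0, seed = 1L) {
  growth_calibration <- match.arg(growth_calibration)
  divide_loss <- match.arg(divide_loss)
  if (!is.numeric(n0) || n0 < 1) stop("'n0' must be a positive count", call. = FALSE)
  if (!is.numeric(m0) || m0 <= 0) stop("'m0' must be a positive mass (pg)", call. = FALSE)
  if (!is.numeric(f) || f < 0 || f > 1) stop("'f' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(r) || r < 1) stop("'r' must be >= 1", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (!is.numeric(Td) || Td <= 0) stop("'Td' must be positive", call. = FALSE)
  if (dt > Td / 20) stop("'dt' must satisfy dt <= Td/20 for an accurate Euler update", call. = FALSE)
  if (f * dt / Td > 1) stop("per-step transfer probability f*dt/Td exceeds 1", call. = FALSE)
  if (!is.numeric(d_target) || d_target < 0) stop("'d_target' must be non-negative", call. = FALSE)
  if (agent_cap < n0) stop("'agent_cap' must be at least n0", call. = FALSE)
  if (is.null(k0)) {
    k0 <- switch(growth_calibration,
                 discrete   = (2^(dt / Td) - 1) / dt,
                 continuous = log(2) / Td)
  }
  if (k0 < 0) stop("'k0' must be non-negative", call. = FALSE)
  structure(list(n0 = as.integer(n0), m0 = m0, f = f, r = r, Td = Td, dt = dt,
                 d_target = d_target, k0 = k0,
                 growth_calibration = growth_calibration,
                 divide_loss = divide_loss,
                 agent_cap = as.integer(agent_cap), seed = as.integer(seed)),
            class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat("Agent-based transfer model parameters\n")
  cat(sprintf("  n0 = %d agents, m0 = %g pg\n", x$n0, x$m0))
  cat(sprintf("  f = %g per Td, r = %g, Td = %g h, dt = %g h\n", x$f, x$r, x$Td, x$dt))
  cat(sprintf("  k0 = %.6g /h (%s calibration), target %g doublings, seed %d\n",
              x$k0, x$growth_calibration, x$d_target, x$seed))
  invisible(x)
}

#' Create a population of cell agents
#'
#' A vectorized container for cell agents: parallel vectors of current dry
#' mass, dry mass at birth, and the carrier flag for transferred mitochondria.
#'
#' @param mass Numeric vector of current dry masses (pg), all positive.
#' @param baseline_mass Numeric vector of dry masses at birth (pg); defaults
#'   to `mass`.
#' @param has_transfer Logical vector of carrier flags; defaults to all
#'   `FALSE`.
#' @return An object of class `"agent_population"`.
#' @export
#' @examples
#' agents <- agent_population(mass = c(1, 2.2), has_transfer = c(FALSE, TRUE))
agent_population <- function(mass, baseline_mass = mass,
                             has_transfer = logical(length(mass))) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("agent masses must be positive and finite", call. = FALSE)
  if (any(!is.finite(baseline_mass)) || any(baseline_mass <= 0))
    stop("baseline masses must be positive and finite", call. = FALSE)
  if (length(baseline_mass) != length(mass) || length(has_transfer) != length(mass))
    stop("'mass', 'baseline_mass' and 'has_transfer' must have equal length", call. = FALSE)
  structure(list(mass = as.numeric(mass),
                 baseline_mass = as.numeric(baseline_mass),
                 has_transfer = as.logical(has_transfer)),
            class = "agent_population")
}

#' @export
length.agent_population <- function(x) length(x$mass)

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("<agent_population> %d agents, total mass %.4g pg, %d carriers\n",
              length(x), sum(x$mass), sum(x$has_transfer)))
  invisible(x)
}

#' One Euler step of exponential mass growth
#'
#' Advances every agent's mass by one time step of the exponential growth law
#' `m <- m * (1 + k*dt)`, with `k = k0` for non-carriers and `k = k0*r` for
#' carriers. Flags and baseline masses are unchanged.
#'
#' @param agents An [agent_population()].
#' @param params An [abm_params()] object.
#' @return The updated `agent_population`.
#' @export
#' @examples
#' a <- agent_population(1)
#' p <- abm_params(n0 = 1, Td = 40, dt = 1, k0 = 0.1)
#' step_growth(a, p)$mass  # 1.1
step_growth <- function(agents, params) {
  stopifnot(inherits(agents, "agent_population"), inherits(params, "abm_params"))
  if (params$dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (any(agents$mass <= 0)) stop("agent masses must be positive", call. = FALSE)
  k <- ifelse(agents$has_transfer, params$k0 * params$r, params$k0)
  agents$mass <- agents$mass * (1 + k * params$dt)
  agents
}

#' Stochastic gain of transferred mitochondria
#'
#' Each non-carrier agent independently becomes a carrier with per-step
#' probability `f*dt/Td`; carriers are unchanged. Uses R's global RNG stream
#' (seed it, or let [run_simulation()] do so).
#'
#' @inheritParams step_growth
#' @return The updated `agent_population`.
#' @export
apply_transfer <- function(agents, params) {
  stopifnot(inherits(agents, "agent_population"), inherits(params, "abm_params"))
  p_gain <- params$f * params$dt / params$Td
  if (p_gain > 1) stop("per-step transfer probability f*dt/Td exceeds 1", call. = FALSE)
  if (p_gain > 0) {
    neg <- which(!agents$has_transfer)
    if (length(neg))
      agents$has_transfer[neg[runif(length(neg)) < p_gain]] <- TRUE
  }
  agents
}

#' Division with carrier-state partitioning
#'
#' Every agent whose mass exceeds twice its baseline (birth) mass divides into
#' two daughters, each at exactly half the parent mass, with `baseline_mass`
#' reset to the birth mass. For a carrier parent, by default exactly one
#' daughter inherits the mitochondria (`divide_loss = "one_daughter"`); the
#' `"bernoulli"` variant flips a fair coin per daughter. Total population mass
#' is conserved exactly by every division.
#'
#' @inheritParams step_growth
#' @return The updated `agent_population` (daughters appended).
#' @export
#' @examples
#' a <- agent_population(2.2, baseline_mass = 1, has_transfer = TRUE)
#' d <- divide_and_partition(a, abm_params(n0 = 1))
#' d$mass          # 1.1 1.1
#' sum(d$has_transfer)  # 1
divide_and_partition <- function(agents, params = abm_params(n0 = length(agents))) {
  stopifnot(inherits(agents, "agent_population"))
  div <- which(agents$mass > 2 * agents$baseline_mass)
  if (length(div)) {
    half <- agents$mass[div] / 2
    agents$mass[div] <- half
    agents$baseline_mass[div] <- half
    if (identical(params$divide_loss, "bernoulli")) {
      was_pos <- agents$has_transfer[div]
      keep1 <- runif(length(div)) < 0.5
      keep2 <- runif(length(div)) < 0.5
      agents$has_transfer[div] <- was_pos & keep1
      new_flags <- was_pos & keep2
    } else {
      # parent slot keeps the carrier flag; the appended daughter loses it
      new_flags <- rep(FALSE, length(div))
    }
    agents$mass <- c(agents$mass, half)
    agents$baseline_mass <- c(agents$baseline_mass, half)
    agents$has_transfer <- c(agents$has_transfer, new_flags)
  }
  agents
}

#' Run the agent-based transfer simulation
#'
#' Iterates growth, stochastic mitochondria gain, and division per time step
#' until the elapsed time reaches `d_target * Td` (at the default discrete
#' growth calibration the baseline population has then doubled exactly
#' `d_target` times). When the agent count exceeds `agent_cap`, the population
#' is uniformly subsampled back to `n0` and a mass bookkeeping factor keeps
#' the recorded total mass exact. Reproducible: the RNG is seeded from
#' `params$seed` at entry.
#'
#' @param params An [abm_params()] object.
#' @return An object of class `"abm_trajectory"`: a data frame with one row
#'   per recorded step and columns `time_h`, `total_mass_pg`, `n_agents`,
#'   `fraction_positive`, `doublings`, carrying the parameters as attribute
#'   `"params"`.
#' @seealso [relative_increase()], [baseline_mass()]
#' @export
#' @examples
#' traj <- run_simulation(abm_params(n0 = 50, d_target = 2, seed = 7))
#' tail(traj, 1)$doublings  # ~2
run_simulation <- function(params) {
  stopifnot(inherits(params, "abm_params"))
  set.seed(params$seed)
  agents <- agent_population(mass = rep(params$m0, params$n0))
  scale <- 1
  total0 <- params$m0 * params$n0
  n_steps <- ceiling(params$d_target * params$Td / params$dt)
  time_h <- total_mass <- frac_pos <- numeric(n_steps + 1L)
  n_agents <- integer(n_steps + 1L)
  time_h[1L] <- 0
  total_mass[1L] <- total0
  n_agents[1L] <- params$n0
  frac_pos[1L] <- 0
  for (s in seq_len(n_steps)) {
    agents <- step_growth(agents, params)
    agents <- apply_transfer(agents, params)
    agents <- divide_and_partition(agents, params)
    if (length(agents) > params$agent_cap) {
      keep <- sample.int(length(agents), params$n0)
      total_before <- sum(agents$mass)
      agents$mass <- agents$mass[keep]
      agents$baseline_mass <- agents$baseline_mass[keep]
      agents$has_transfer <- agents$has_transfer[keep]
      scale <- scale * total_before / sum(agents$mass)
    }
    time_h[s + 1L] <- s * params$dt
    total_mass[s + 1L] <- scale * sum(agents$mass)
    n_agents[s + 1L] <- length(agents)
    frac_pos[s + 1L] <- mean(agents$has_transfer)
  }
  traj <- data.frame(time_h = time_h, total_mass_pg = total_mass,
                     n_agents = n_agents, fraction_positive = frac_pos,
                     doublings = log2(total_mass / total0))
  attr(traj, "params") <- params
  class(traj) <- c("abm_trajectory", "data.frame")
  traj
}

#' @export
print.abm_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  last <- x[nrow(x), ]
  cat(sprintf("<abm_trajectory> %d steps over %.4g h (f = %g, r = %g, seed %d)\n",
              nrow(x) - 1L, last$time_h, p$f, p$r, p$seed))
  cat(sprintf("  final: total mass %.4g pg (%.3f doublings), %d agents, %.2f%% carriers\n",
              last$total_mass_pg, last$doublings, last$n_agents,
              100 * last$fraction_positive))
  invisible(x)
}

#' @export
summary.abm_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  d <- floor(p$d_target)
  res <- list(params = p,
              final_doublings = object$doublings[nrow(object)],
              mean_fraction_positive = mean(object$fraction_positive),
              relative_increase_pct = if (d >= 1) relative_increase(object, d) else NA_real_)
  class(res) <- "summary.abm_trajectory"
  res
}

#' @export
print.summary.abm_trajectory <- function(x, ...) {
  print(x$params)
  cat(sprintf("  final doublings: %.3f; mean carrier fraction: %.4f\n",
              x$final_doublings, x$mean_fraction_positive))
  if (!is.na(x$relative_increase_pct))
    cat(sprintf("  mass increase over pure-exponential baseline at %g doublings: %.2f%%\n",
                x$params$d_target, x$relative_increase_pct))
  invisible(x)
}

#' @export
plot.abm_trajectory <- function(x, log = "y", ...) {
  p <- attr(x, "params")
  plot(x$time_h, x$total_mass_pg, type = "l", log = log,
       xlab = "time (h)", ylab = "population dry mass (pg)", ...)
  lines(x$time_h, baseline_mass(x$total_mass_pg[1L], x$time_h / p$Td),
        lty = 2, col = "grey40")
  legend("topleft", legend = c("simulation", "pure exponential baseline"),
         lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Pure exponential baseline mass after d doublings
#'
#' Closed-form comparator: the mass of a population growing purely
#' exponentially for `d` doublings, `m0_total * exp(d * log(2)) = m0_total *
#' 2^d`.
#'
#' @param m0_total Initial total mass (pg).
#' @param d Number of doublings (non-negative; may be fractional).
#' @return Baseline mass (pg).
#' @export
#' @examples
#' baseline_mass(1, 20)  # 1048576
baseline_mass <- function(m0_total, d) {
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  m0_total * exp(d * log(2))
}

#' Percent mass increase over the exponential baseline
#'
#' Compares the simulated population mass at elapsed time `d * Td` (the epoch
#' at which the baseline population has doubled `d` times) with the pure
#' exponential baseline, returning
#' `100 * (m_P(d*Td) / (m0_total * 2^d) - 1)`.
#'
#' @param trajectory An `"abm_trajectory"` from [run_simulation()].
#' @param d Number of baseline doublings at which to evaluate.
#' @return Percent increase (may be negative).
#' @export
relative_increase <- function(trajectory, d) {
  stopifnot(inherits(trajectory, "abm_trajectory"))
  if (d < 0) stop("'d' must be non-negative", call. = FALSE)
  p <- attr(trajectory, "params")
  t_eval <- d * p$Td
  if (max(trajectory$time_h) < t_eval - p$dt / 2)
    stop(sprintf("trajectory ends at %.4g h, before the evaluation epoch %.4g h",
                 max(trajectory$time_h), t_eval), call. = FALSE)
  i <- which.min(abs(trajectory$time_h - t_eval))
  m_p <- trajectory$total_mass_pg[i]
  m_b <- baseline_mass(trajectory$total_mass_pg[1L], d)
  100 * (m_p / m_b - 1)
}

#' Replicate the transfer simulation over seeds
#'
#' Convenience wrapper running [run_simulation()] for several seeds and
#' collecting the percent mass increase over baseline at `d_target`
#' doublings.
#'
#' @param params An [abm_params()] object (its `seed` is ignored).
#' @param seeds Integer vector of seeds, one replicate each.
#' @return A data frame with columns `seed` and `relative_increase_pct`, with
#'   attribute `"summary"` holding mean and sd.
#' @export
#' @examples
#' res <- replicate_increase(abm_params(n0 = 100, d_target = 3), seeds = 1:3)
#' attr(res, "summary")
replicate_increase <- function(params, seeds = 1:10) {
  stopifnot(inherits(params, "abm_params"))
  vals <- vapply(seeds, function(s) {
    p <- params
    p$seed <- as.integer(s)
    relative_increase(run_simulation(p), p$d_target)
  }, numeric(1))
  out <- data.frame(seed = as.integer(seeds), relative_increase_pct = vals)
  attr(out, "summary") <- c(mean = mean(vals), sd = sd(vals))
  out
}
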