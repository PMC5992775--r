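# Independent reference simulators used to validate the product-basis
# engine: direct per-individual simulation, Monte Carlo over populations of
# probabilistic networks, and exact evolution of the full 2^N state-space
# distribution (the brute-force oracle).

#' Simulate one individual by direct rule application
#'
#' Synchronously applies every update rule at each step, starting from a
#' single Boolean state.
#'
#' @param net a deterministic [boolean_network()].
#' @param state0 initial state: dot-joined label of the ON variables
#'   (\code{"0"} for all-OFF), a character vector of ON variable names, or
#'   a 0/1 vector over all variables.
#' @param steps number of steps.
#' @return integer 0/1 matrix of dim \code{(steps + 1) x N} with variables
#'   as columns; row t+1 is the state after t steps.
#' @export
simulate_individual <- function(net, state0, steps) {
  if (net$kind != "deterministic") {
    stop("simulate_individual() needs a deterministic network; use ",
         "simulate_pbn_population() for stochastic ones", call. = FALSE)
  }
  state <- .parse_state(net, state0)
  traj <- matrix(0L, nrow = steps + 1L, ncol = n_variables(net),
                 dimnames = list(NULL, net$variables))
  traj[1L, ] <- state
  if (steps > 0) {
    for (t in seq_len(steps)) {
      state <- as.integer(.rule_outputs(net, matrix(state, nrow = 1L)))
      traj[t + 1L, ] <- state
    }
  }
  traj
}

.parse_state <- function(net, state0) {
  n <- n_variables(net)
  if (is.character(state0)) {
    state <- integer(n)
    if (length(state0) == 1L && (grepl(".", state0, fixed = TRUE) ||
                                 state0 == "0")) {
      state[mask_indices(subset_from_label(state0, net$variables), n)] <- 1L
    } else {
      state[.var_index(net, state0)] <- 1L
    }
    return(state)
  }
  stopifnot(length(state0) == n, all(state0 %in% c(0, 1)))
  as.integer(state0)
}

#' Monte Carlo simulation of a population of (probabilistic) networks
#'
#' Samples \code{n_runs} independent individuals from the population
#' specification and advances each by per-variable stochastic updates: at
#' every step variable i turns ON with the likelihood its rule assigns to
#' the current input pattern.  Deterministic networks are the special case
#' of 0/1 likelihoods.
#'
#' @param net a [boolean_network()].
#' @param spec a [population_spec] used to draw initial states.
#' @param n_runs number of Monte Carlo individuals.
#' @param steps number of time steps.
#' @param seed integer seed (reproducible; caller's RNG state restored).
#' @return a \code{pb_mc} object: list with \code{times}, per-variable
#'   \code{mean} and \code{stderr} matrices (N x steps+1), \code{n_runs}.
#' @export
simulate_pbn_population <- function(net, spec, n_runs, steps, seed = NULL) {
  stopifnot(n_runs >= 1L, steps >= 0L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- n_variables(net)
  states <- .sample_states(net, spec, n_runs)
  sum1 <- matrix(0, n, steps + 1L)
  sum2 <- matrix(0, n, steps + 1L)
  sum1[, 1L] <- colSums(states)
  sum2[, 1L] <- colSums(states)  # x^2 = x for 0/1
  if (steps > 0) {
    for (t in seq_len(steps)) {
      pr <- .rule_outputs(net, states)
      states <- (matrix(stats::runif(length(pr)), nrow(pr), ncol(pr)) < pr) + 0L
      sum1[, t + 1L] <- colSums(states)
      sum2[, t + 1L] <- colSums(states)
    }
  }
  mean <- sum1 / n_runs
  varr <- pmax(sum2 / n_runs - mean^2, 0) * n_runs / max(n_runs - 1L, 1L)
  stderr <- sqrt(varr / n_runs)
  dimnames(mean) <- dimnames(stderr) <- list(net$variables, NULL)
  structure(list(times = 0:steps, mean = mean, stderr = stderr,
                 n_runs = n_runs, variables = net$variables),
            class = "pb_mc")
}

#' @export
print.pb_mc <- function(x, ...) {
  cat("Monte Carlo estimate: ", x$n_runs, " runs, ",
      length(x$variables), " variables x ", length(x$times), " times\n",
      sep = "")
  invisible(x)
}

#' Write a Monte Carlo estimate as tidy TSV
#' @param mc a \code{pb_mc} object.
#' @param file output path.
#' @export
write_mc_estimate <- function(mc, file) {
  df <- data.frame(
    time = rep(mc$times, each = length(mc$variables)),
    variable = rep(mc$variables, times = length(mc$times)),
    mean = as.vector(mc$mean),
    stderr = as.vector(mc$stderr))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# draw n_runs initial 0/1 states (rows) from a population spec
.sample_states <- function(net, spec, n_runs) {
  n <- n_variables(net)
  switch(
    spec$kind,
    uniform = ,
    marginals = {
      p <- .spec_marginals(spec, net$variables)
      matrix(stats::runif(n_runs * n) < rep(p, each = n_runs), n_runs, n) + 0L
    },
    explicit = {
      smasks <- subset_from_label(spec$states, net$variables)
      pick <- sample.int(length(smasks), n_runs, replace = TRUE,
                         prob = spec$weights)
      out <- matrix(0L, n_runs, n)
      for (r in seq_len(n_runs)) {
        out[r, mask_indices(smasks[pick[r]], n)] <- 1L
      }
      out
    },
    knockout = {
      is_wt <- endsWith(net$variables, ".WT")
      wt_of <- match(paste0(net$variables, ".WT"), net$variables)
      p <- .spec_marginals(spec, net$variables)
      wt_states <- matrix(stats::runif(n_runs * n) >= spec$mu, n_runs, n)
      wt_states[, !is_wt] <- TRUE
      act <- matrix(stats::runif(n_runs * n) <
                      rep(ifelse(is_wt, 1, p), each = n_runs), n_runs, n)
      out <- (wt_states & act) + 0L
      # mutated genes always begin OFF: gene columns gated by their WT column
      for (i in which(!is.na(wt_of))) {
        out[, i] <- out[, i] * out[, wt_of[i]]
      }
      out
    },
    stop("unknown population kind: ", spec$kind, call. = FALSE)
  )
}

#' Exact full-state-space evolution (brute-force oracle)
#'
#' Builds the complete distribution over all 2^N network states implied by
#' the population specification, advances it with the exact transition map
#' (deterministic: a permutation-like 0/1 map; probabilistic: the full
#' master-equation transition matrix; differential: the continuous-time
#' master equation of single-variable flips toward the logic target at the
#' per-variable rates), and reads off the moment
#' \eqn{\langle x_\alpha \rangle = \sum_{\kappa \supseteq \alpha} w_\kappa}
#' for every requested subset.  Deliberately brute force -- the network size
#' is capped at 12 variables -- and used as the independent check of the
#' product-basis engine.
#'
#' @param net a [boolean_network()] with at most 12 variables.
#' @param spec a [population_spec].
#' @param steps number of discrete steps, or (differential mode) a numeric
#'   grid of output times.
#' @param subsets subsets to report, as dot-joined labels (default: all
#'   single variables).
#' @param mode \code{"discrete"} or \code{"differential"}.
#' @param rates per-variable rates for differential mode (default
#'   \code{net$rates} or 1).
#' @param tol ODE tolerance for differential mode.
#' @return a \code{pb_timeseries}-compatible list with \code{times},
#'   \code{values} (subsets x times), \code{labels}.
#' @export
state_space_oracle <- function(net, spec, steps,
                               subsets = net$variables,
                               mode = c("discrete", "differential"),
                               rates = NULL, tol = 1e-10) {
  mode <- match.arg(mode)
  n <- n_variables(net)
  if (n > 12L) {
    stop("state_space_oracle() enumerates all 2^N states and refuses ",
         "N > 12 (got ", n, ")", call. = FALSE)
  }
  ns <- 2^n
  all_states <- matrix(0L, ns, n)
  for (j in seq_len(n)) {
    all_states[, j] <- ((0:(ns - 1)) %/% 2^(j - 1)) %% 2
  }
  w0 <- .spec_state_weights(net, spec, all_states)
  masks <- subset_from_label(subsets, net$variables)
  state_masks <- as.numeric(all_states %*% 2^(seq_len(n) - 1L))
  moment_of <- function(w) {
    vapply(masks, function(a) {
      sum(w[mask_contains(state_masks, rep(a, ns))])
    }, numeric(1))
  }

  if (mode == "discrete") {
    stopifnot(length(steps) == 1L, steps >= 0)
    out <- .rule_outputs(net, all_states)  # per-state ON likelihoods
    vals <- matrix(0, length(masks), steps + 1L)
    w <- w0
    vals[, 1L] <- moment_of(w)
    if (all(out %in% c(0, 1))) {
      nxt <- as.integer(out %*% 2^(seq_len(n) - 1L)) + 1L
      for (t in seq_len(steps)) {
        agg <- rowsum(w, nxt)
        w <- numeric(ns)
        w[as.integer(rownames(agg))] <- agg[, 1L]
        vals[, t + 1L] <- moment_of(w)
      }
    } else {
      P <- .master_matrix(out, all_states)
      for (t in seq_len(steps)) {
        w <- as.numeric(w %*% P)
        vals[, t + 1L] <- moment_of(w)
      }
    }
    times <- 0:steps
  } else {
    times <- steps
    stopifnot(is.numeric(times), length(times) >= 2L)
    r <- if (!is.null(rates)) rep_len(rates, n) else
      if (!is.null(net$rates)) net$rates else rep(1, n)
    out <- .rule_outputs(net, all_states)
    Q <- matrix(0, ns, ns)  # generator: single-variable flips toward target
    for (i in seq_len(n)) {
      cur <- all_states[, i]
      tgt <- out[, i]
      # flip rate of variable i in state s: r_i * P(target != current)
      rate <- r[i] * abs(tgt - cur)
      dest <- seq_len(ns) + ifelse(cur == 1L, -1, 1) * 2^(i - 1)
      for (s in which(rate > 0)) {
        Q[s, dest[s]] <- Q[s, dest[s]] + rate[s]
        Q[s, s] <- Q[s, s] - rate[s]
      }
    }
    sol <- deSolve::ode(y = w0, times = times,
                        func = function(t, y, parms) list(as.numeric(y %*% Q)),
                        parms = NULL, method = "ode45", rtol = tol,
                        atol = tol * 1e-2)
    vals <- apply(unname(sol[, -1L, drop = FALSE]), 1L, moment_of)
    vals <- matrix(vals, nrow = length(masks))
  }
  rownames(vals) <- subsets
  structure(list(times = times, values = vals, omega = masks,
                 labels = subsets, mode = mode, variables = net$variables),
            class = "pb_timeseries")
}

# full master-equation transition matrix P[s, s'] for a probabilistic
# network: product over variables of the per-variable outcome likelihoods
.master_matrix <- function(out, all_states) {
  ns <- nrow(all_states)
  n <- ncol(all_states)
  P <- matrix(1, ns, ns)
  for (i in seq_len(n)) {
    p_on <- out[, i]                     # per source state
    s_on <- all_states[, i]              # per destination state
    P <- P * outer(p_on, s_on, function(p, b) ifelse(b == 1, p, 1 - p))
  }
  P
}

# exact initial distribution over all full states implied by a spec
.spec_state_weights <- function(net, spec, all_states) {
  n <- ncol(all_states)
  ns <- nrow(all_states)
  switch(
    spec$kind,
    uniform = ,
    marginals = {
      p <- .spec_marginals(spec, net$variables)
      w <- rep(1, ns)
      for (i in seq_len(n)) {
        w <- w * ifelse(all_states[, i] == 1L, p[i], 1 - p[i])
      }
      w
    },
    explicit = {
      smasks <- subset_from_label(spec$states, net$variables)
      state_masks <- as.numeric(all_states %*% 2^(seq_len(n) - 1L))
      w <- numeric(ns)
      for (s in seq_along(smasks)) {
        w[match(smasks[s], state_masks)] <-
          w[match(smasks[s], state_masks)] + spec$weights[s]
      }
      w
    },
    knockout = {
      is_wt <- endsWith(net$variables, ".WT")
      wt_of <- match(paste0(net$variables, ".WT"), net$variables)
      p <- .spec_marginals(spec, net$variables)
      mu <- spec$mu
      w <- rep(1, ns)
      for (i in seq_len(n)) {
        if (is_wt[i]) {
          w <- w * ifelse(all_states[, i] == 1L, 1 - mu, mu)
        } else if (!is.na(wt_of[i])) {
          # P(gene | wt): wt ON -> p[i]; wt OFF -> gene OFF
          wt_on <- all_states[, wt_of[i]] == 1L
          g_on <- all_states[, i] == 1L
          w <- w * ifelse(wt_on,
                          ifelse(g_on, p[i], 1 - p[i]),
                          ifelse(g_on, 0, 1))
        } else {
          w <- w * ifelse(all_states[, i] == 1L, p[i], 1 - p[i])
        }
      }
      w
    },
    stop("unknown population kind: ", spec$kind, call. = FALSE)
  )
}
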