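# Population specifications, initial moment vectors, and time evolution of
# population moments under the assembled product-basis operator.
#
# A population is a weighted mixture of individuals in different Boolean
# states.  Its moment vector holds <x_alpha>, the fraction of the population
# (under the W = 1 normalization used throughout) in which every variable of
# alpha is ON simultaneously.  Because the time-evolution operator is
# linear, the same operator that advances an individual advances any
# mixture: evolution commutes with the population average.

#' Population specifications
#'
#' Constructors for the supported population kinds:
#' \describe{
#'   \item{\code{pop_uniform()}}{uniform mixture of all activation states
#'     (every variable ON independently with probability 1/2).  Wild-type
#'     \code{.WT} variables are held ON, since they encode mutations, not
#'     activation states.}
#'   \item{\code{pop_marginals(p)}}{independent per-variable ON
#'     probabilities; \code{p} is a named vector, unnamed variables default
#'     to 1/2 (\code{.WT} variables to 1).}
#'   \item{\code{pop_states(states, weights)}}{explicit weighted list of
#'     states; \code{states} are dot-joined labels of the ON-variable sets
#'     (\code{"0"} = all OFF) and \code{weights} must sum to 1.}
#'   \item{\code{pop_knockout(mu, p)}}{knockout-augmented mixture for a
#'     wild-type-augmented network: each gene's \code{.WT} variable is OFF
#'     with probability \code{mu} independently, activation states are
#'     uniform (or \code{p}), and mutated genes always begin OFF.}
#' }
#'
#' @param p named numeric vector of marginal ON probabilities in \[0,1\].
#' @param states character vector of subset labels of ON variables.
#' @param weights numeric weights, same length as \code{states}, summing
#'   to 1 (within 1e-12).
#' @param mu per-gene knockout probability in \[0,1\].
#' @return an object of class \code{population_spec}.
#' @name population_spec
NULL

#' @rdname population_spec
#' @export
pop_uniform <- function() {
  structure(list(kind = "uniform"), class = "population_spec")
}

#' @rdname population_spec
#' @export
pop_marginals <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0), all(p <= 1))
  structure(list(kind = "marginals", p = p), class = "population_spec")
}

#' @rdname population_spec
#' @export
pop_states <- function(states, weights) {
  stopifnot(length(states) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("population weights must sum to 1 (W = 1 normalization); got ",
         format(sum(weights)), call. = FALSE)
  }
  structure(list(kind = "explicit", states = as.character(states),
                 weights = as.numeric(weights)),
            class = "population_spec")
}

#' @rdname population_spec
#' @export
pop_knockout <- function(mu, p = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1)
  if (!is.null(p)) stopifnot(is.numeric(p), all(p >= 0), all(p <= 1))
  structure(list(kind = "knockout", mu = mu, p = p),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population spec:", x$kind, "\n")
  invisible(x)
}

# per-variable marginal ON probabilities implied by a spec (independent
# kinds only); .WT variables default to ON
.spec_marginals <- function(spec, variables) {
  p <- ifelse(endsWith(variables, ".WT"), 1, 0.5)
  names(p) <- variables
  if (!is.null(spec$p)) {
    given <- spec$p
    if (is.null(names(given))) {
      if (length(given) != length(variables)) {
        stop("unnamed marginal vector must cover every variable",
             call. = FALSE)
      }
      p[] <- given
    } else {
      bad <- setdiff(names(given), variables)
      if (length(bad)) {
        stop("marginals name unknown variable(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      p[names(given)] <- given
    }
  }
  p
}

#' Initial moment vector of a population over a closed system
#'
#' Computes \eqn{\langle x_\alpha \rangle} at time 0 for every tracked
#' subset of the system.  For explicit mixtures this is
#' \eqn{\sum_s w_s [\alpha \subseteq s]}; for independent marginals
#' \eqn{\prod_{i \in \alpha} p_i}; for knockout-augmented populations a
#' per-gene factor model with \eqn{P(WT) = 1 - \mu},
#' \eqn{P(\mathrm{gene\ ON}) = p_i (1 - \mu)} (mutated genes always begin
#' OFF), multiplied over genes -- never by enumerating mutational profiles,
#' which is what makes very heterogeneous populations feasible.
#'
#' @param spec a [population_spec] object.
#' @param sys a \code{pb_system} (or \code{pb_operator}) whose tracked
#'   subsets the moments are aligned to.
#' @return named numeric vector of moments, one per tracked subset.
#' @export
initial_moments <- function(spec, sys) {
  stopifnot(inherits(spec, "population_spec"))
  omega <- sys$omega
  variables <- sys$variables
  vals <- switch(
    spec$kind,
    uniform = ,
    marginals = {
      p <- .spec_marginals(spec, variables)
      vapply(omega, function(m) prod(p[mask_indices(m, length(variables))]),
             numeric(1))
    },
    explicit = {
      smasks <- subset_from_label(spec$states, variables)
      vapply(omega, function(m) {
        sum(spec$weights[mask_contains(smasks, rep(m, length(smasks)))])
      }, numeric(1))
    },
    knockout = {
      is_wt <- endsWith(variables, ".WT")
      if (!any(is_wt)) {
        stop("knockout populations need a wild-type-augmented network ",
             "(no .WT variables found); see augment_wildtype()",
             call. = FALSE)
      }
      wt_of <- match(paste0(variables, ".WT"), variables)  # per gene
      gene_of <- ifelse(is_wt, match(sub("\\.WT$", "", variables), variables),
                        NA_integer_)
      p <- .spec_marginals(spec, variables)
      mu <- spec$mu
      # independence across genes: each factor accounts for one gene/WT
      # pair, so moments of 2^N mutational profiles never get enumerated
      vapply(omega, function(m) {
        ix <- mask_indices(m, length(variables))
        val <- 1
        for (i in ix) {
          if (is_wt[i]) {
            # WT alone contributes (1 - mu); if its gene is also present,
            # the gene's factor below already includes WT intactness
            if (is.na(gene_of[i]) || !(gene_of[i] %in% ix)) {
              val <- val * (1 - mu)
            }
          } else if (!is.na(wt_of[i])) {
            # gene ON requires an intact WT and activation
            val <- val * p[i] * (1 - mu)
          } else {
            val <- val * p[i]
          }
        }
        val
      }, numeric(1))
    },
    stop("unknown population kind: ", spec$kind, call. = FALSE)
  )
  names(vals) <- sys$labels
  vals
}

#' Evolve population moments in discrete time
#'
#' Applies \code{x(t+1) = F x(t)} for the given number of synchronous
#' steps.  With integer operator coefficients and dyadic-rational starting
#' moments the arithmetic is exact.
#'
#' @param op a \code{pb_operator} in discrete mode (from
#'   [assemble_operator()]), or a \code{pb_system}.
#' @param x0 initial moment vector aligned to the operator (see
#'   [initial_moments()]).
#' @param steps number of time steps (>= 0).
#' @return a \code{pb_timeseries}: times 0..steps and a moments matrix with
#'   one row per tracked subset.
#' @export
evolve_discrete <- function(op, x0, steps) {
  op <- .as_operator(op)
  if (op$mode != "discrete") {
    stop("evolve_discrete() needs a discrete-mode operator", call. = FALSE)
  }
  d <- nrow(op$F)
  if (length(x0) != d) {
    stop("moment vector has length ", length(x0), ", operator expects ", d,
         call. = FALSE)
  }
  stopifnot(steps >= 0)
  vals <- matrix(0, nrow = d, ncol = steps + 1L,
                 dimnames = list(op$labels, NULL))
  x <- as.numeric(x0)
  vals[, 1L] <- x
  if (steps > 0) {
    for (t in seq_len(steps)) {
      x <- as.numeric(op$F %*% x)
      vals[, t + 1L] <- x
    }
  }
  .timeseries(0:steps, vals, op)
}

#' Evolve population moments in continuous time
#'
#' Integrates \code{dx/dt = F x} with an explicit adaptive Runge-Kutta
#' integrator (Dormand-Prince via \pkg{deSolve}).
#'
#' @param op a differential-mode \code{pb_operator} or \code{pb_system}.
#' @param x0 initial moment vector.
#' @param times numeric grid of output times (first entry is the initial
#'   time).
#' @param tol local relative error tolerance.
#' @return a \code{pb_timeseries} over \code{times}.
#' @export
evolve_continuous <- function(op, x0, times, tol = 1e-8) {
  op <- .as_operator(op)
  if (op$mode != "differential") {
    stop("evolve_continuous() needs a differential-mode operator",
         call. = FALSE)
  }
  if (length(x0) != nrow(op$F)) {
    stop("moment vector has length ", length(x0), ", operator expects ",
         nrow(op$F), call. = FALSE)
  }
  stopifnot(is.numeric(times), length(times) >= 2L, !is.unsorted(times))
  F <- op$F
  sol <- deSolve::ode(y = as.numeric(x0), times = times,
                      func = function(t, y, parms) list(as.numeric(F %*% y)),
                      parms = NULL, method = "ode45", rtol = tol,
                      atol = tol * 1e-2)
  if (!is.matrix(sol) || nrow(sol) < length(times)) {
    stop("ODE integration failed near t = ",
         if (is.matrix(sol)) max(sol[, 1]) else times[1], call. = FALSE)
  }
  vals <- t(unname(sol[, -1L, drop = FALSE]))
  rownames(vals) <- op$labels
  .timeseries(times, vals, op)
}

.as_operator <- function(op) {
  if (inherits(op, "pb_system")) op <- assemble_operator(op)
  stopifnot(inherits(op, "pb_operator"))
  op
}

.timeseries <- function(times, vals, op) {
  structure(list(times = times, values = vals, omega = op$omega,
                 labels = op$labels, mode = op$mode,
                 variables = op$variables),
            class = "pb_timeseries")
}

#' @export
print.pb_timeseries <- function(x, ...) {
  cat("Product-basis time series: ", length(x$labels), " subsets x ",
      length(x$times), " times (t = ", format(x$times[1]), " .. ",
      format(x$times[length(x$times)]), ")\n", sep = "")
  invisible(x)
}

#' Extract the time series of one tracked population fraction
#'
#' Returns \eqn{\langle x_\alpha \rangle} over time for a tracked subset;
#' with \code{minus}, returns the difference of two tracked series (e.g.
#' the fraction co-expressing A and B *without* intact C.WT, for necessity
#' analyses).
#'
#' @param ts a \code{pb_timeseries}.
#' @param subset dot-joined subset label (e.g. \code{"A.B"}; \code{"0"} for
#'   the empty set).
#' @param minus optional second label whose series is subtracted.
#' @return numeric vector over \code{ts$times}.
#' @export
query <- function(ts, subset, minus = NULL) {
  stopifnot(inherits(ts, "pb_timeseries"))
  pick <- function(lab) {
    j <- match(lab, ts$labels)
    if (is.na(j)) {
      stop("subset '", lab, "' is not tracked by this system; add it to ",
           "omega0 and rebuild with close_system()", call. = FALSE)
    }
    ts$values[j, ]
  }
  out <- pick(subset)
  if (!is.null(minus)) out <- out - pick(minus)
  out
}

#' @export
as.data.frame.pb_timeseries <- function(x, ...) {
  data.frame(time = rep(x$times, each = length(x$labels)),
             subset = rep(x$labels, times = length(x$times)),
             value = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Write a time series to disk
#'
#' \code{"tsv"} writes the tidy long form (time, subset, value);
#' \code{"csv"} writes the wide form (one column per subset).
#'
#' @param ts a \code{pb_timeseries}.
#' @param file output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param provenance optional named list written as \code{# key: value}
#'   header lines.
#' @export
write_timeseries <- function(ts, file, format = c("tsv", "csv"),
                             provenance = NULL) {
  format <- match.arg(format)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      writeLines(paste0("# ", nm, ": ", format(provenance[[nm]])), con)
    }
  }
  if (format == "tsv") {
    utils::write.table(as.data.frame(ts), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    wide <- data.frame(time = ts$times, t(ts$values), check.names = FALSE)
    utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
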