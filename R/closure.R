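# The product-basis algebra: linear single-variable update rules, idempotent
# reduction of products, the differential product rule, worklist closure of
# the equation system, and assembly of the sparse transition operator.

#' Linear update rule of a single variable in the product basis
#'
#' Computes \eqn{f_i = k^{[i]} (T^{(N^{[i]})})^{-1} x^{[i]}} as a linear
#' expression over subsets of variable i's inputs.  The coefficient of
#' \eqn{x_\kappa} is the subset Moebius transform
#' \eqn{\sum_{\alpha \subseteq \kappa} (-1)^{|\kappa|-|\alpha|} k_\alpha},
#' computed by the fast in-place transform; the 2^n basis matrix is never
#' materialised.  For the 3-node example network this yields
#' f_A = x_0 - x_B, f_B = x_A.C, f_C = x_A + x_B - x_A.B.
#'
#' @param net a [boolean_network()].
#' @param var variable name or index.
#' @param tol drop tolerance for coefficients (0 keeps exact integers).
#' @param cap maximum number of inputs per rule.
#' @return a \code{pb_expr} linear expression.
#' @export
single_rule <- function(net, var, tol = 0, cap = 20L) {
  i <- .var_index(net, var)
  stopifnot(length(i) == 1L)
  r <- net$rules[[i]]
  n <- length(r$inputs)
  if (n > cap) {
    stop("variable '", net$variables[i], "' has ", n,
         " inputs, above the per-rule cap of ", cap, call. = FALSE)
  }
  coefs <- mobius_transform(r$k)
  # map local masks (bit j-1 = j-th input) to global masks
  gmask <- numeric(2^n)
  if (n > 0L) {
    m <- 0:(2^n - 1)
    for (j in seq_len(n)) {
      gmask <- gmask + ((m %/% 2^(j - 1)) %% 2) * 2^(r$inputs[j] - 1L)
    }
  }
  expr_collect(gmask, coefs, tol)
}

#' Idempotent product of linear expressions
#'
#' Distributes the product of the given expressions, replaces every
#' monomial product \eqn{x_\beta x_\gamma \cdots} by
#' \eqn{x_{\beta \cup \gamma \cup \cdots}} (Boolean idempotence), merges
#' like terms and drops zeros.  This is how a multi-index discrete rule
#' \eqn{f_{ij\ldots} = f_i f_j \cdots} is reduced to linear form.
#'
#' @param factors nonempty list of \code{pb_expr} objects.
#' @param tol coefficient drop tolerance.
#' @return a \code{pb_expr}.
#' @export
reduce_product <- function(factors, tol = 0) {
  if (!is.list(factors) || length(factors) == 0L) {
    stop("'factors' must be a nonempty list of expressions", call. = FALSE)
  }
  out <- factors[[1L]]
  for (f in factors[-1L]) out <- expr_multiply(out, f, tol)
  out
}

#' Differential update rule of a product variable
#'
#' In continuous time \eqn{f_\alpha = dx_\alpha/dt} follows the product rule
#' of derivatives: \eqn{f_{AB\ldots} = x_B x_C \cdots f_A + x_A x_C \cdots
#' f_B + \cdots}, idempotent-reduced.  The empty subset has \eqn{f_\emptyset
#' = 0}.
#'
#' @param subset integer vector of the subset's member variable indices
#'   (empty for the empty set).
#' @param singles list of \code{pb_expr}, indexed by variable, holding the
#'   continuous-time single-variable rates \eqn{f_i}.
#' @param tol coefficient drop tolerance.
#' @return a \code{pb_expr}.
#' @export
differential_rule <- function(subset, singles, tol = 0) {
  members <- sort(unique(as.integer(subset)))
  if (length(members) == 0L) return(expr_zero())
  .differential_rule_mask(mask_from_indices(members), singles, tol)
}

# fast path used by close_system: subset given as a mask
.differential_rule_mask <- function(mask, singles, tol) {
  members <- mask_indices(mask)
  if (length(members) == 0L) return(expr_zero())
  total <- expr_zero()
  for (i in members) {
    rest <- mask - 2^(i - 1L)
    term <- if (rest > 0) {
      expr_multiply(singles[[i]], pb_expr(rest, 1), tol)
    } else {
      singles[[i]]
    }
    total <- expr_add(total, term, tol = tol)
  }
  total
}

.mask_key <- function(mask) sprintf("%.0f", mask)

#' Close the product-basis equation system over a set of tracked variables
#'
#' Starting from the product variables of interest \code{omega0}, solves the
#' update rule of every required subset and iterates -- adding each subset
#' that appears on a right-hand side to the tracked set -- until the system
#' is closed (every referenced subset has its own rule).  Singleton rules
#' come from [single_rule()]; multi-index rules from [reduce_product()] of
#' the cached single rules (discrete) or from the derivative product rule
#' (differential).  The worklist is FIFO and term order canonical, so the
#' resulting ordering of the tracked set is reproducible.
#'
#' In differential mode the single-variable rate is taken as
#' \eqn{f_i = r_i (g_i - x_i)}: relaxation at rate \eqn{r_i} toward the
#' logic target \eqn{g_i}, the continuous-time limit of the discrete rate
#' augmentation of [attach_rates()].  Rates default to
#' \code{net$rates} or 1.
#'
#' @param net a [boolean_network()].
#' @param omega0 the product variables of interest: a character vector of
#'   dot-joined subset labels (e.g. \code{c("A", "A.B")}, \code{"0"} for the
#'   empty set), or a list of variable-name vectors.
#' @param mode \code{"discrete"} (default; also serves probabilistic
#'   networks) or \code{"differential"}.
#' @param rates per-variable rates for differential mode.
#' @param tol coefficient drop tolerance; defaults to 0 for deterministic
#'   discrete networks and 1e-12 otherwise, so exact integer cancellation
#'   is preserved where it is available.
#' @param max_size cap on the number of tracked subsets; exceeding it stops
#'   with an informative error naming the frontier.
#' @param input_cap per-rule input cap passed to [single_rule()].
#' @return an object of class \code{pb_system} with fields \code{omega}
#'   (subset masks in discovery order), \code{labels}, \code{rules} (one
#'   \code{pb_expr} per subset), \code{mode}, \code{variables}.
#' @export
#' @examples
#' net <- parse_network(c("A, !B", "B, A & C", "C, A | B"))
#' sys <- close_system(net, "A")
#' print(sys)
close_system <- function(net, omega0, mode = c("discrete", "differential"),
                         rates = NULL, tol = NULL, max_size = 1e6,
                         input_cap = 20L) {
  mode <- match.arg(mode)
  if (is.null(tol)) {
    tol <- if (net$kind == "deterministic" && mode == "discrete") 0 else 1e-12
  }
  masks0 <- .parse_omega0(net, omega0)
  if (length(masks0) == 0L) stop("omega0 must be nonempty", call. = FALSE)

  nv <- n_variables(net)
  singles <- vector("list", nv)
  need_single <- function(i) {
    if (is.null(singles[[i]])) {
      g <- single_rule(net, i, tol = tol, cap = input_cap)
      if (mode == "differential") {
        r_i <- if (!is.null(rates)) rates[i] else
          if (!is.null(net$rates)) net$rates[i] else 1
        g <- expr_add(g, pb_expr(2^(i - 1L), 1), w1 = r_i, w2 = -r_i,
                      tol = tol)
      }
      singles[[i]] <<- g
    }
    singles[[i]]
  }

  omega <- numeric(0)
  labels_env <- new.env(hash = TRUE, parent = emptyenv())
  rules <- list()
  queue <- masks0[!duplicated(masks0)]
  for (m in queue) assign(.mask_key(m), TRUE, envir = labels_env)
  head_i <- 1L

  while (head_i <= length(queue)) {
    alpha <- queue[head_i]
    head_i <- head_i + 1L
    card <- mask_card(alpha)
    rule <- if (card == 0L) {
      if (mode == "discrete") pb_expr(0, 1) else expr_zero()
    } else if (card == 1L) {
      need_single(mask_indices(alpha)[1L])
    } else if (mode == "discrete") {
      members <- mask_indices(alpha)
      out <- need_single(members[1L])
      for (i in members[-1L]) out <- expr_multiply(out, need_single(i), tol)
      out
    } else {
      members <- mask_indices(alpha)
      for (i in members) need_single(i)
      .differential_rule_mask(alpha, singles, tol)
    }
    omega <- c(omega, alpha)
    rules[[length(rules) + 1L]] <- rule
    for (m in rule$masks) {
      key <- .mask_key(m)
      if (!exists(key, envir = labels_env, inherits = FALSE)) {
        assign(key, TRUE, envir = labels_env)
        queue <- c(queue, m)
      }
    }
    if (length(queue) > max_size) {
      frontier <- queue[seq(head_i, min(head_i + 9L, length(queue)))]
      stop("closure exceeded max_size = ", max_size, " tracked subsets; ",
           "frontier includes: ",
           paste(subset_label(frontier, net$variables), collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(length(omega) == length(rules))  # Omega_S == Omega on exit

  structure(list(omega = omega,
                 labels = subset_label(omega, net$variables),
                 rules = rules,
                 mode = mode,
                 variables = net$variables,
                 kind = net$kind,
                 tol = tol),
            class = "pb_system")
}

.parse_omega0 <- function(net, omega0) {
  if (is.character(omega0)) {
    subset_from_label(omega0, net$variables)
  } else if (is.list(omega0)) {
    vapply(omega0, function(s) {
      if (length(s) == 0L) 0 else mask_from_indices(.var_index(net, s))
    }, numeric(1))
  } else if (is.numeric(omega0)) {
    as.numeric(omega0)  # raw masks
  } else {
    stop("omega0 must be subset labels, a list of name vectors, or masks",
         call. = FALSE)
  }
}

#' @export
print.pb_system <- function(x, max_rules = 20L, ...) {
  cat("Product-basis system (", x$mode, "): ", length(x$omega),
      " tracked subsets\n", sep = "")
  for (j in seq_len(min(length(x$omega), max_rules))) {
    cat("  f_", x$labels[j], " = ", format_expr(x$rules[[j]], x$variables),
        "\n", sep = "")
  }
  if (length(x$omega) > max_rules) {
    cat("  ... (", length(x$omega) - max_rules, " more)\n", sep = "")
  }
  invisible(x)
}

#' Assemble the sparse transition operator of a closed system
#'
#' Builds the square operator F aligned to the system's subset order, with
#' row alpha holding the coefficients of rule f_alpha, so that
#' \code{x(t+1) = F x(t)} (discrete) or \code{dx/dt = F x} (differential).
#'
#' @param sys a \code{pb_system} from [close_system()].
#' @return a \code{pb_operator}: list with the \code{Matrix::dgCMatrix}
#'   \code{F}, the subset \code{omega}/\code{labels}, and the \code{mode}.
#' @export
assemble_operator <- function(sys) {
  d <- length(sys$omega)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(d)) {
    e <- sys$rules[[r]]
    if (expr_is_zero(e)) next
    j <- match(e$masks, sys$omega)
    stopifnot(!anyNA(j))  # closure guarantees every referenced subset is tracked
    ii <- c(ii, rep.int(r, length(j)))
    jj <- c(jj, j)
    xx <- c(xx, e$coefs)
  }
  F <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(d, d),
                            dimnames = list(sys$labels, sys$labels))
  structure(list(F = F, omega = sys$omega, labels = sys$labels,
                 mode = sys$mode, variables = sys$variables),
            class = "pb_operator")
}

#' @export
print.pb_operator <- function(x, ...) {
  cat("Product-basis transition operator (", x$mode, "): ",
      nrow(x$F), " x ", ncol(x$F), ", ", Matrix::nnzero(x$F),
      " nonzeros\n", sep = "")
  invisible(x)
}

#' Serialize a closed system as equations and operator triplets
#'
#' Writes (or returns) a plain-text equation listing, one
#' \code{f_SUBSET = ...} line per tracked subset in system order, and
#' optionally a coordinate-format dump of the operator
#' (\code{row_subset<TAB>col_subset<TAB>coefficient}).
#'
#' @param sys a \code{pb_system}.
#' @param file optional path for the equation listing.
#' @param coo_file optional path for the operator triplets.
#' @return the equation lines, invisibly when \code{file} is given.
#' @export
serialize_system <- function(sys, file = NULL, coo_file = NULL) {
  lines <- vapply(seq_along(sys$omega), function(j) {
    paste0("f_", sys$labels[j], " = ",
           format_expr(sys$rules[[j]], sys$variables))
  }, character(1))
  if (!is.null(coo_file)) {
    op <- assemble_operator(sys)
    tr <- Matrix::summary(op$F)
    coo <- data.frame(row = sys$labels[tr$i], col = sys$labels[tr$j],
                      coef = tr$x)
    utils::write.table(coo, coo_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
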