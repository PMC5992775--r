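# Subset-lattice primitives.
#
# A subset of model variables ("product variable" index) is stored as a bit
# mask in a double: bit (i-1) set iff variable i is a member.  Doubles hold
# integers exactly up to 2^53, so masks are exact for networks of up to
# .BOOLPOP_MAX_VARS variables.  Unions are computed by splitting each mask
# into two <=27-bit words so that bitwOr() (32-bit) applies.

.BOOLPOP_MAX_VARS <- 52L
.MASK_SPLIT <- 2^27

#' Build a subset mask from variable indices
#'
#' @param idx integer vector of 1-based variable indices (may be empty).
#' @return a double encoding the subset as a bit mask.
#' @keywords internal
mask_from_indices <- function(idx) {
  if (length(idx) == 0L) return(0)
  idx <- unique(as.integer(idx))
  stopifnot(all(idx >= 1L), all(idx <= .BOOLPOP_MAX_VARS))
  sum(2^(idx - 1L))
}

#' Decode a subset mask into sorted variable indices
#' @keywords internal
mask_indices <- function(mask, n_vars = .BOOLPOP_MAX_VARS) {
  which((mask %/% 2^(seq_len(n_vars) - 1L)) %% 2 == 1)
}

#' Vectorised union of two equal-length vectors of masks
#' @keywords internal
mask_union <- function(a, b) {
  lo <- bitwOr(as.integer(a %% .MASK_SPLIT), as.integer(b %% .MASK_SPLIT))
  hi <- bitwOr(as.integer(a %/% .MASK_SPLIT), as.integer(b %/% .MASK_SPLIT))
  lo + hi * .MASK_SPLIT
}

#' Vectorised intersection of two equal-length vectors of masks
#' @keywords internal
mask_intersect <- function(a, b) {
  lo <- bitwAnd(as.integer(a %% .MASK_SPLIT), as.integer(b %% .MASK_SPLIT))
  hi <- bitwAnd(as.integer(a %/% .MASK_SPLIT), as.integer(b %/% .MASK_SPLIT))
  lo + hi * .MASK_SPLIT
}

#' Is each subset a contained in the corresponding subset b?
#' @keywords internal
mask_contains <- function(big, small) {
  mask_intersect(big, small) == small
}

#' Cardinality of each subset mask
#' @keywords internal
mask_card <- function(mask) {
  card <- numeric(length(mask))
  m <- mask
  while (any(m > 0)) {
    card <- card + m %% 2
    m <- m %/% 2
  }
  as.integer(card)
}

#' Order subsets canonically: by cardinality, then lexicographically on the
#' sorted member indices (so for 3 variables: 0, A, B, C, AB, AC, BC, ABC).
#' @keywords internal
order_subsets <- function(masks, n_vars = .BOOLPOP_MAX_VARS) {
  if (length(masks) <= 1L) return(seq_along(masks))
  card <- mask_card(masks)
  kmax <- max(card)
  pad <- matrix(Inf, nrow = length(masks), ncol = max(kmax, 1L))
  for (r in seq_along(masks)) {
    ix <- mask_indices(masks[r], n_vars)
    if (length(ix)) pad[r, seq_along(ix)] <- ix
  }
  do.call(order, c(list(card), split(pad, col(pad))))
}

#' Format subset masks as dot-joined variable names
#'
#' The empty set is printed as \code{"0"}.
#' @param masks vector of subset masks.
#' @param variables character vector of variable names in index order.
#' @return character vector of labels such as \code{"A.C"}.
#' @keywords internal
subset_label <- function(masks, variables) {
  vapply(masks, function(m) {
    ix <- mask_indices(m, length(variables))
    if (length(ix) == 0L) "0" else paste(variables[ix], collapse = ".")
  }, character(1))
}

#' Parse dot-joined subset labels back into masks
#'
#' Variable names may themselves contain dots (the \code{.WT} convention),
#' so tokens are matched against declared names with backtracking,
#' preferring the longest name first.
#' @keywords internal
subset_from_label <- function(labels, variables) {
  vapply(labels, function(s) {
    if (identical(s, "0") || !nzchar(s)) return(0)
    toks <- strsplit(s, ".", fixed = TRUE)[[1]]
    ix <- .match_label_tokens(toks, variables)
    if (is.null(ix)) {
      stop("cannot resolve subset label '", s,
           "' against the declared variables", call. = FALSE)
    }
    mask_from_indices(ix)
  }, numeric(1), USE.NAMES = FALSE)
}

# recursive longest-first match of dot-separated tokens to variable names;
# returns indices or NULL if no tiling works
.match_label_tokens <- function(toks, variables) {
  if (length(toks) == 0L) return(integer(0))
  for (take in rev(seq_along(toks))) {
    cand <- paste(toks[seq_len(take)], collapse = ".")
    i <- match(cand, variables)
    if (!is.na(i)) {
      rest <- .match_label_tokens(toks[-seq_len(take)], variables)
      if (!is.null(rest)) return(c(i, rest))
    }
  }
  NULL
}

# ---------------------------------------------------------------------------
# Linear expressions over product variables: f = sum_alpha c_alpha x_alpha.
# Stored as parallel vectors (masks, coefs), masks strictly increasing,
# no zero coefficients.  Deterministic networks yield exact integer coefs.

#' Construct a linear expression over product-basis variables
#'
#' @param masks subset masks (doubles).
#' @param coefs numeric coefficients, same length.
#' @param tol coefficients with absolute value at or below \code{tol} are
#'   dropped after merging like terms.  Exact integer arithmetic makes true
#'   cancellations land on 0.0, so the default 0 keeps everything nonzero;
#'   probabilistic/continuous systems pass a small positive tolerance.
#' @return an object of class \code{pb_expr}.
#' @keywords internal
pb_expr <- function(masks = numeric(0), coefs = numeric(0), tol = 0) {
  stopifnot(length(masks) == length(coefs))
  expr_collect(as.numeric(masks), as.numeric(coefs), tol)
}

expr_collect <- function(masks, coefs, tol = 0) {
  if (length(masks) > 1L) {
    ug <- sort(unique(masks))
    if (length(ug) < length(masks)) {
      coefs <- unname(rowsum(coefs, match(masks, ug), reorder = TRUE)[, 1L])
      masks <- ug
    } else {
      o <- order(masks)
      masks <- masks[o]
      coefs <- coefs[o]
    }
  }
  keep <- abs(coefs) > tol
  structure(list(masks = masks[keep], coefs = coefs[keep]), class = "pb_expr")
}

expr_zero <- function() pb_expr()

expr_is_zero <- function(e) length(e$masks) == 0L

#' Multiply two expressions with idempotent reduction
#'
#' Products of product variables collapse by union: x_beta * x_gamma =
#' x_{beta union gamma}, because Boolean indicators satisfy x^p = x.
#' @keywords internal
expr_multiply <- function(e1, e2, tol = 0) {
  a <- length(e1$masks)
  b <- length(e2$masks)
  if (a == 0L || b == 0L) return(expr_zero())
  masks <- mask_union(rep(e1$masks, times = b), rep(e2$masks, each = a))
  coefs <- rep(e1$coefs, times = b) * rep(e2$coefs, each = a)
  expr_collect(masks, coefs, tol)
}

#' Add expressions (optionally scaled)
#' @keywords internal
expr_add <- function(e1, e2, w1 = 1, w2 = 1, tol = 0) {
  expr_collect(c(e1$masks, e2$masks), c(w1 * e1$coefs, w2 * e2$coefs), tol)
}

#' Evaluate an expression given values of its product variables
#' @keywords internal
expr_eval <- function(e, values_by_mask) {
  if (expr_is_zero(e)) return(0)
  sum(e$coefs * values_by_mask[as.character(e$masks)])
}

#' Format an expression as text, e.g. "x_0 - x_B + x_A.C"
#' @keywords internal
format_expr <- function(e, variables) {
  if (expr_is_zero(e)) return("0")
  o <- order_subsets(e$masks, length(variables))
  masks <- e$masks[o]
  coefs <- e$coefs[o]
  lab <- subset_label(masks, variables)
  piece <- function(c, l) {
    mag <- if (c %% 1 == 0) format(abs(c)) else format(abs(c), digits = 12)
    if (mag == "1") paste0("x_", l) else paste0(mag, "*x_", l)
  }
  out <- piece(coefs[1], lab[1])
  if (coefs[1] < 0) out <- paste0("-", out)
  for (j in seq_along(masks)[-1]) {
    out <- paste0(out, if (coefs[j] < 0) " - " else " + ", piece(coefs[j], lab[j]))
  }
  out
}

#' @export
print.pb_expr <- function(x, variables = NULL, ...) {
  if (is.null(variables)) {
    variables <- paste0("v", seq_len(.BOOLPOP_MAX_VARS))
  }
  cat(format_expr(x, variables), "\n")
  invisible(x)
}
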