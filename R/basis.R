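# Change of basis between the state basis b (one indicator per full network
# state) and the product basis x (one monomial per variable subset).
#
# For an individual in state kappa (the set of ON variables),
#   b_alpha = [alpha == kappa]      x_alpha = [alpha subseteq kappa],
# so x = T b with T the zeta matrix of the subset lattice, and b = T^{-1} x
# with the Moebius matrix T^{-1}.

#' Enumerate all subsets of an n-element set in canonical order
#'
#' Canonical order is by cardinality, then lexicographically on the sorted
#' member positions: for n = 2 over inputs (A, C) this is (0, A, C, A.C).
#'
#' @param n number of elements (positions 1..n).
#' @return numeric vector of 2^n local masks.
#' @keywords internal
enumerate_subsets <- function(n) {
  masks <- as.numeric(0:(2^n - 1))
  masks[order_subsets(masks, n)]
}

.check_basis_n <- function(n, cap) {
  if (!is.numeric(n) || length(n) != 1L || n %% 1 != 0 || n < 0) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  if (n > cap) {
    stop("basis size n = ", n, " exceeds the cap of ", cap,
         " (the matrix has 2^n rows; raise 'cap' deliberately if you",
         " really want this)", call. = FALSE)
  }
}

#' Change-of-basis (zeta) matrix of the subset lattice
#'
#' Returns the 2^n x 2^n 0/1 matrix \eqn{T^{(n)}} with entry
#' \eqn{T_{\alpha\kappa} = 1} iff \eqn{\alpha \subseteq \kappa}, which maps a
#' state-basis indicator vector \code{b} to its product-basis image
#' \code{x = T b}.  Rows and columns are indexed by subsets in canonical
#' order (cardinality, then lexicographic), and labelled accordingly.
#'
#' @param n number of variables spanned by the basis.
#' @param cap safety cap on n (the matrix is dense of size 4^n).
#' @return an integer matrix with subset dimnames; \code{n = 1} gives
#'   \code{rbind(c(1, 1), c(0, 1))}.
#' @seealso [invert_change_of_basis()]
#' @export
#' @examples
#' change_of_basis(2)
change_of_basis <- function(n, cap = 20L) {
  .check_basis_n(n, cap)
  masks <- enumerate_subsets(n)
  m <- outer(masks, masks, function(a, k) as.integer(mask_contains(k, a)))
  lab <- subset_label(masks, LETTERS1n(n))
  dimnames(m) <- list(lab, lab)
  m
}

#' Inverse change-of-basis (Moebius) matrix
#'
#' The closed-form inverse of [change_of_basis()]: entry
#' \eqn{(\alpha,\kappa)} is \eqn{(-1)^{|\kappa|-|\alpha|}} if
#' \eqn{\alpha \subseteq \kappa} and 0 otherwise.  Exact integers; no
#' numeric inversion is performed.
#'
#' @inheritParams change_of_basis
#' @return an integer matrix such that
#'   \code{change_of_basis(n) \%*\% invert_change_of_basis(n)} is the
#'   identity.
#' @export
#' @examples
#' invert_change_of_basis(1)
invert_change_of_basis <- function(n, cap = 20L) {
  .check_basis_n(n, cap)
  masks <- enumerate_subsets(n)
  card <- mask_card(masks)
  m <- outer(seq_along(masks), seq_along(masks), function(a, k) {
    as.integer(mask_contains(masks[k], masks[a])) * (-1L)^(card[k] - card[a])
  })
  storage.mode(m) <- "integer"
  lab <- subset_label(masks, LETTERS1n(n))
  dimnames(m) <- list(lab, lab)
  m
}

# default positional names A, B, C, ... for printing small bases
LETTERS1n <- function(n) {
  if (n <= 26L) LETTERS[seq_len(max(n, 0L))] else paste0("v", seq_len(n))
}

#' In-place subset Moebius transform
#'
#' Given values k indexed by local bit masks 0..2^n-1 (bit j-1 = element j),
#' returns c with c_kappa = sum_{alpha subseteq kappa} (-1)^{|kappa|-|alpha|}
#' k_alpha.  This is the row vector k T^{-1} without materialising T, in
#' O(n 2^n) operations.
#' @keywords internal
mobius_transform <- function(k) {
  len <- length(k)
  n <- as.integer(round(log2(len)))
  stopifnot(2^n == len)
  if (n == 0L) return(k)
  idx_all <- 0:(len - 1L)
  for (j in seq_len(n) - 1L) {
    with_bit <- which(bitwAnd(idx_all, bitwShiftL(1L, j)) != 0L)
    k[with_bit] <- k[with_bit] - k[with_bit - 2^j]
  }
  k
}
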