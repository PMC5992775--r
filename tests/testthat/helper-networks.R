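# Shared fixtures, built in code.

example1_net <- function() {
  parse_network(c("A, !B", "B, A & C", "C, A | B"))
}

toy_feedforward_net <- function() {
  parse_network(file = system.file("extdata", "toy_feedforward.bnet",
                                   package = "boolpop"))
}

# name a pb_expr's coefficients by subset label, for readable comparisons
expr_as_named <- function(e, variables) {
  stats::setNames(e$coefs, boolpop:::subset_label(e$masks, variables))
}

# independent derivation of a multi-index rule: enumerate all input patterns
# of the union of the members' input sets, AND the member outputs, and
# Moebius-transform the resulting truth table.  Never calls reduce_product.
brute_rule <- function(net, members) {
  members <- sort(boolpop:::.var_index(net, members))
  U <- sort(unique(unlist(lapply(net$rules[members], `[[`, "inputs"))))
  n <- length(U)
  k <- numeric(max(2^n, 1))
  for (m in 0:(2^n - 1)) {
    bits <- (m %/% 2^(seq_len(max(n, 1)) - 1L)) %% 2
    val <- 1
    for (i in members) {
      r <- net$rules[[i]]
      loc <- if (length(r$inputs)) {
        sum(bits[match(r$inputs, U)] * 2^(seq_along(r$inputs) - 1L))
      } else 0
      val <- val * r$k[loc + 1]
    }
    k[m + 1] <- val
  }
  coefs <- boolpop:::mobius_transform(k)
  gmask <- numeric(2^n)
  if (n > 0) {
    m <- 0:(2^n - 1)
    for (j in seq_len(n)) {
      gmask <- gmask + ((m %/% 2^(j - 1)) %% 2) * 2^(U[j] - 1L)
    }
  }
  keep <- coefs != 0
  stats::setNames(coefs[keep],
                  boolpop:::subset_label(gmask[keep], net$variables))
}

# product-basis image of a single full state over a tracked subset list
state_to_x <- function(masks, state_mask) {
  as.numeric(boolpop:::mask_contains(rep(state_mask, length(masks)), masks))
}
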