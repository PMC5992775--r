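vars3 <- c("A", "B", "C")

test_that("single-variable rules are the Moebius transform of the truth table", {
  net <- example1_net()
  expect_equal(expr_as_named(single_rule(net, "A"), vars3),
               c("0" = 1, B = -1))
  expect_equal(expr_as_named(single_rule(net, "B"), vars3), c(A.C = 1))
  expect_equal(expr_as_named(single_rule(net, "C"), vars3),
               c(A = 1, B = 1, A.B = -1))
  # agreement with the explicit k %*% T^{-1} route, on random rules
  set.seed(21)
  for (rep in 1:20) {
    rnet <- generate_random_network(8, c(1, 4), seed = 1000 + rep)
    i <- sample(8, 1)
    got <- expr_as_named(single_rule(rnet, i), rnet$variables)
    want <- brute_rule(rnet, i)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("idempotent product reduction reproduces the worked ladder", {
  net <- example1_net()
  fA <- single_rule(net, "A")
  fB <- single_rule(net, "B")
  fC <- single_rule(net, "C")
  expect_equal(expr_as_named(reduce_product(list(fA, fC)), vars3),
               c(A = 1, A.B = -1))                      # f_AC
  expect_equal(expr_as_named(reduce_product(list(fA, fB, fC)), vars3),
               c(A.C = 1, A.B.C = -1))                  # f_ABC
  e <- pb_expr(c(1, 6), c(2, -1))
  expect_equal(reduce_product(list(pb_expr(0, 1), e)), e)  # x_0 * e = e
  expect_error(reduce_product(list()), "nonempty")
})

test_that("multi-index discrete rules match an independent truth-table derivation", {
  set.seed(31)
  for (rep in 1:15) {
    net <- generate_random_network(8, c(1, 3), seed = 2000 + rep)
    members <- sample(8, sample(2:4, 1))
    singles <- lapply(sort(members), function(i) single_rule(net, i))
    got <- expr_as_named(reduce_product(singles), net$variables)
    want <- brute_rule(net, members)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("the derivative product rule assembles continuous multi-index rates", {
  net <- example1_net()
  singles <- lapply(1:3, function(i) {
    # relaxation toward the logic target at unit rate
    boolpop:::expr_add(single_rule(net, i), pb_expr(2^(i - 1), 1), 1, -1)
  })
  # f_{AB} = x_B f_A + x_A f_B
  fAB <- differential_rule(c(1, 2), singles)
  byhand <- boolpop:::expr_add(
    boolpop:::expr_multiply(pb_expr(2, 1), singles[[1]]),
    boolpop:::expr_multiply(pb_expr(1, 1), singles[[2]]))
  expect_equal(expr_as_named(fAB, vars3), expr_as_named(byhand, vars3))
  expect_true(boolpop:::expr_is_zero(differential_rule(integer(0), singles)))
  expect_equal(expr_as_named(differential_rule(1, singles), vars3),
               expr_as_named(singles[[1]], vars3))
})

test_that("closure from the tracked variable of interest yields the printed system", {
  net <- example1_net()
  sys <- close_system(net, "A")
  expect_setequal(sys$labels, c("A", "0", "B", "A.C", "A.B", "A.B.C"))
  rule_of <- function(lab) {
    expr_as_named(sys$rules[[match(lab, sys$labels)]], vars3)
  }
  expect_equal(rule_of("A"), c("0" = 1, B = -1))
  expect_equal(rule_of("B"), c(A.C = 1))
  expect_equal(rule_of("0"), c("0" = 1))
  expect_equal(rule_of("A.C"), c(A = 1, A.B = -1))
  expect_equal(rule_of("A.B"), c(A.C = 1, A.B.C = -1))
  expect_equal(rule_of("A.B.C"), c(A.C = 1, A.B.C = -1))

  triv <- close_system(net, "0")
  expect_identical(triv$labels, "0")
  expect_equal(expr_as_named(triv$rules[[1]], vars3), c("0" = 1))
})

test_that("closure equals a brute-force symbolic fixpoint on random networks", {
  for (s in 1:5) {
    net <- generate_random_network(7, c(1, 3), seed = 3000 + s)
    sys <- close_system(net, net$variables)
    # independent fixpoint: substitute with brute_rule until no new subsets
    known <- character(0)
    frontier <- net$variables
    rules <- list()
    while (length(frontier)) {
      lab <- frontier[1]
      frontier <- frontier[-1]
      members <- if (lab == "0") character(0) else
        strsplit(lab, ".", fixed = TRUE)[[1]]
      r <- if (lab == "0") c("0" = 1) else brute_rule(net, members)
      known <- c(known, lab)
      rules[[lab]] <- r
      for (ref in names(r)) {
        if (!(ref %in% known) && !(ref %in% frontier)) {
          frontier <- c(frontier, ref)
        }
      }
    }
    expect_setequal(sys$labels, known)
    for (lab in sys$labels) {
      got <- expr_as_named(sys$rules[[match(lab, sys$labels)]],
                           net$variables)
      expect_equal(got[order(names(got))],
                   rules[[lab]][order(names(rules[[lab]]))])
    }
  }
})

test_that("closure terminates with every referenced subset tracked", {
  for (s in 1:10) {
    net <- generate_random_network(9, c(1, 4), seed = 4000 + s)
    sys <- close_system(net, sample(net$variables, 2))
    refs <- unique(unlist(lapply(sys$rules, `[[`, "masks")))
    expect_true(all(refs %in% sys$omega))
    expect_identical(anyDuplicated(sys$omega), 0L)
  }
})

test_that("the closure size cap fails loudly with the frontier", {
  net <- generate_random_network(10, c(3, 4), seed = 77)
  expect_error(close_system(net, net$variables, max_size = 20),
               "max_size.*frontier", ignore.case = TRUE)
})

test_that("the assembled operator acts as one synchronous update on every state", {
  net <- example1_net()
  sys <- close_system(net, "A")
  op <- assemble_operator(sys)
  expect_equal(dim(op$F), c(6L, 6L))
  r0 <- as.numeric(op$F[match("0", op$labels), ])
  expect_equal(r0, as.numeric(op$labels == "0"))  # row for empty set is e_0
  rAB <- op$F[match("A.B", op$labels), ]
  expect_equal(as.numeric(rAB[match(c("A.C", "A.B.C"), op$labels)]),
               c(1, -1))
  expect_equal(sum(rAB != 0), 2)
  for (s in 0:7) {
    st <- as.integer(intToBits(s))[1:3]
    x_now <- state_to_x(sys$omega, mask_from_indices(which(st == 1)))
    nxt <- simulate_individual(net, st, 1)[2, ]
    x_next <- state_to_x(sys$omega, mask_from_indices(which(nxt == 1)))
    expect_equal(as.numeric(op$F %*% x_now), x_next)
  }
})

test_that("system serialization lists equations and operator triplets", {
  net <- example1_net()
  sys <- close_system(net, "A")
  lines <- serialize_system(sys)
  expect_identical(lines[1], "f_A = x_0 - x_B")
  expect_true("f_A.B = x_A.C - x_A.B.C" %in% lines)
  f <- tempfile(); coo <- tempfile()
  serialize_system(sys, file = f, coo_file = coo)
  expect_identical(readLines(f), lines)
  tab <- read.delim(coo)
  expect_identical(names(tab), c("row", "col", "coef"))
  expect_equal(nrow(tab), sum(vapply(sys$rules, function(e)
    length(e$masks), integer(1))))
})
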