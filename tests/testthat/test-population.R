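test_that("initial moments follow the population specification", {
  net <- example1_net()
  sys <- close_system(net, "A")
  u <- initial_moments(pop_uniform(), sys)
  expect_equal(unname(u[match(c("0", "A", "A.C", "A.B.C"), sys$labels)]),
               c(1, 0.5, 0.25, 0.125))
  one <- initial_moments(pop_states("A", 1), sys)
  expect_equal(unname(one[match(c("0", "A", "B", "A.C"), sys$labels)]),
               c(1, 1, 0, 0))
  expect_error(pop_states(c("A", "B"), c(0.6, 0.6)), "sum to 1")

  m <- initial_moments(pop_marginals(c(A = 1, B = 0, C = 0.5)), sys)
  expect_equal(unname(m[match(c("A", "B", "A.C", "A.B.C"), sys$labels)]),
               c(1, 0, 0.5, 0))
})

test_that("knockout-augmented moments use the per-gene factor model", {
  net <- parse_network(c("A, B", "B, A"))
  aug <- augment_wildtype(net)
  sys <- close_system(aug, c("A", "A.WT", "A.A.WT", "A.B", "B.WT"))
  mu <- 1e-4
  x0 <- initial_moments(pop_knockout(mu), sys)
  expect_equal(unname(x0[match("A.WT", sys$labels)]), 1 - mu)
  expect_equal(unname(x0[match("A", sys$labels)]), 0.5 * (1 - mu))
  # gene and its own WT are perfectly coupled, distinct genes independent
  expect_equal(unname(x0[match("A.A.WT", sys$labels)]), 0.5 * (1 - mu))
  expect_equal(unname(x0[match("A.B", sys$labels)]), (0.5 * (1 - mu))^2)
  # and they agree with exhaustive enumeration over the 2^4 full states
  orc <- state_space_oracle(aug, pop_knockout(mu), 0,
                            subsets = sys$labels)
  expect_equal(unname(orc$values[, 1]), unname(x0))
})

test_that("discrete evolution matches exhaustive state enumeration", {
  net <- example1_net()
  sys <- close_system(net, net$variables)
  op <- assemble_operator(sys)
  x0 <- initial_moments(pop_uniform(), sys)
  ts <- evolve_discrete(op, x0, 10)
  expect_equal(query(ts, "A")[1:3], c(0.5, 0.5, 0.75))
  orc <- state_space_oracle(net, pop_uniform(), 10)
  expect_equal(ts$values[match(net$variables, ts$labels), ], orc$values)
  expect_equal(evolve_discrete(op, x0, 0)$values[, 1], x0)
  expect_error(evolve_discrete(op, x0[-1], 3), "length")
})

test_that("single-state starts stay Boolean and track the individual exactly", {
  for (s in 1:5) {
    net <- generate_random_network(8, c(1, 3), seed = 500 + s)
    sys <- close_system(net, net$variables)
    st <- as.integer(intToBits(s * 17)[1:8])
    lab <- if (all(st == 0)) "0" else
      paste(net$variables[st == 1], collapse = ".")
    ts <- evolve_discrete(sys, initial_moments(pop_states(lab, 1), sys), 15)
    expect_true(all(ts$values %in% c(0, 1)))  # individuals stay Boolean
    tr <- simulate_individual(net, st, 15)
    expect_equal(unname(ts$values[match(net$variables, ts$labels), ]),
                 unname(t(tr)))
  }
  # the period-5 cycle of the 3-node example
  net <- example1_net()
  sys <- close_system(net, net$variables)
  ts <- evolve_discrete(sys, initial_moments(pop_states("A", 1), sys), 5)
  expect_equal(ts$values[, 6], ts$values[, 1])
})

test_that("evolution is a superposition: mixtures equal weighted sums of parts", {
  for (s in 1:5) {
    net <- generate_random_network(9, c(1, 4), seed = 600 + s)
    sys <- close_system(net, sample(net$variables, 3))
    op <- assemble_operator(sys)
    set.seed(s)
    picks <- sample(0:(2^9 - 1), 4)
    w <- runif(4); w <- w / sum(w)
    labs <- vapply(picks, function(m) {
      if (m == 0) "0" else
        paste(net$variables[boolpop:::mask_indices(m, 9)], collapse = ".")
    }, character(1))
    mixed <- evolve_discrete(op, initial_moments(pop_states(labs, w), sys), 12)
    parts <- lapply(labs, function(l) {
      evolve_discrete(op, initial_moments(pop_states(l, 1), sys), 12)$values
    })
    expect_equal(mixed$values, Reduce(`+`, Map(`*`, w, parts)))
  }
})

test_that("the empty-set moment is conserved and moments stay consistent", {
  for (s in 1:5) {
    net <- generate_random_network(8, c(1, 4), seed = 700 + s)
    sys <- close_system(net, net$variables)
    ts <- evolve_discrete(sys, initial_moments(pop_uniform(), sys), 20)
    j0 <- match("0", ts$labels)
    if (!is.na(j0)) expect_equal(ts$values[j0, ], rep(1, 21))
    expect_true(all(ts$values >= -1e-12 & ts$values <= 1 + 1e-12))
    # subset monotonicity wherever both subsets are tracked
    card <- boolpop:::mask_card(ts$omega)
    for (a in seq_along(ts$omega)) {
      sup <- which(boolpop:::mask_contains(ts$omega,
                                           rep(ts$omega[a], length(ts$omega))) &
                     card > card[a])
      for (b in sup) {
        expect_true(all(ts$values[b, ] <= ts$values[a, ] + 1e-12))
      }
    }
  }
})

test_that("continuous evolution integrates dx/dt = Fx accurately", {
  # all-frozen network: F = 0, x constant
  net <- parse_network(c("A, A", "B, B"))
  net$rates <- c(1, 1)
  sys <- close_system(net, c("A", "B"), mode = "differential")
  op <- assemble_operator(sys)
  expect_equal(Matrix::nnzero(op$F), 0)
  x0 <- initial_moments(pop_marginals(c(A = 0.3, B = 0.9)), sys)
  ts <- evolve_continuous(op, x0, seq(0, 5, 0.5))
  expect_equal(ts$values, matrix(rep(x0, 11), nrow = 2,
                                 dimnames = list(ts$labels, NULL)))

  # pure decay f_A = -x_A: exact exponential
  dec <- parse_network("A, 0")
  sys <- close_system(dec, "A", mode = "differential")
  times <- seq(0, 4, 0.25)
  ts <- evolve_continuous(sys, c(A = 0.8), times, tol = 1e-10)
  expect_equal(query(ts, "A"), 0.8 * exp(-times), tolerance = 1e-6)

  # random 6-node continuous networks vs the full master-equation oracle
  for (s in 1:3) {
    net <- generate_random_network(6, c(1, 3), seed = 800 + s)
    set.seed(s); net$rates <- runif(6)
    sys <- close_system(net, net$variables, mode = "differential")
    grid <- seq(0, 8, 0.5)
    ts <- evolve_continuous(sys, initial_moments(pop_uniform(), sys), grid,
                            tol = 1e-8)
    orc <- state_space_oracle(net, pop_uniform(), grid, mode = "differential")
    expect_lt(max(abs(ts$values[match(net$variables, ts$labels), ] -
                        orc$values)), 1e-6)
    j0 <- match("0", ts$labels)
    if (!is.na(j0)) expect_equal(ts$values[j0, ], rep(1, length(grid)),
                                 tolerance = 1e-8)
  }
})

test_that("queries return tracked fractions and support differences", {
  net <- parse_network(c("A, A", "B, B"))
  sys <- close_system(net, c("A", "B", "A.B"))
  # two equal subpopulations, perfectly anticorrelated
  spec <- pop_states(c("A", "B"), c(0.5, 0.5))
  ts <- evolve_discrete(sys, initial_moments(spec, sys), 3)
  expect_equal(query(ts, "A"), rep(0.5, 4))
  expect_equal(query(ts, "B"), rep(0.5, 4))
  expect_equal(query(ts, "A.B"), rep(0, 4))
  expect_equal(query(ts, "A", minus = "A.B"), rep(0.5, 4))
  expect_error(query(ts, "0"), "not tracked")
})

test_that("time series round-trip through their file formats", {
  net <- example1_net()
  sys <- close_system(net, "A")
  ts <- evolve_discrete(sys, initial_moments(pop_uniform(), sys), 4)
  tsv <- tempfile(fileext = ".tsv")
  write_timeseries(ts, tsv, provenance = list(seed = 1))
  df <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(df), 6 * 5)
  expect_equal(df$value[df$subset == "A" & df$time == 2], 0.75)
  csv <- tempfile(fileext = ".csv")
  write_timeseries(ts, csv, format = "csv")
  wide <- read.csv(csv, check.names = FALSE)
  expect_equal(wide$A, unname(query(ts, "A")))
})
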