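test_that("neighbour_sum wraps the torus and spans {-4,-2,0,2,4}", {
  # 3x3, focus only at (3,1), (2,1), (1,3), (1,2): the four torus
  # neighbours of the corner cell (1,1)
  m <- matrix(-1L, 3, 3)
  m[3, 1] <- 1L; m[2, 1] <- 1L; m[1, 3] <- 1L; m[1, 2] <- 1L
  l <- landscape(m)
  expect_equal(neighbour_sum(l, 1, 1), 4L)
  # neighbours of (3,3): (2,3)=-1, wrap (1,3)=+1, (3,2)=-1, wrap (3,1)=+1
  expect_equal(neighbour_sum(l, 3, 3), 0L)
  expect_error(neighbour_sum(l, 0, 1), "out of range")
  expect_error(neighbour_sum(l, 1, 4), "out of range")

  # all 16 neighbour configurations of a centre cell produce exactly
  # the five sums {-4, -2, 0, 2, 4}
  sums <- integer(0)
  for (bits in 0:15) {
    nb <- 2L * as.integer(intToBits(bits)[1:4]) - 1L
    m <- matrix(-1L, 3, 3)
    m[1, 2] <- nb[1]; m[3, 2] <- nb[2]; m[2, 1] <- nb[3]; m[2, 3] <- nb[4]
    sums <- c(sums, neighbour_sum(landscape(m), 2, 2))
  }
  expect_setequal(unique(sums), c(-4L, -2L, 0L, 2L, 4L))
})

test_that("two focus and two background neighbours sum to zero", {
  m <- matrix(-1L, 3, 3)
  m[1, 2] <- 1L; m[2, 1] <- 1L
  expect_equal(neighbour_sum(landscape(m), 2, 2), 0L)
})

test_that("total energy counts each torus pair once", {
  l <- landscape(matrix(1L, 3, 3))
  # 18 torus edges all aligned, 9 cells in the field term
  expect_equal(total_energy(l, ising_params(B = 1, J = 1, Q = 0)), -27)
  expect_equal(total_energy(l, ising_params(B = 0, J = 0, Q = 0)), 0)

  withr::with_seed(5, {
    for (i in 1:10) {
      s <- random_states(6)
      B <- runif(1, -1, 1); J <- runif(1, 0, 1)
      expect_equal(total_energy(landscape(s), ising_params(B, J, 0)),
                   energy_bruteforce(s, B, J))
    }
  })
})

test_that("pair interaction is consistent with summed neighbour fields", {
  # sum_k x_k * S_k double-counts every torus edge, so it equals twice the
  # pair sum, i.e. -2 * E at J = 1, B = 0
  withr::with_seed(7, {
    s <- random_states(8)
    l <- landscape(s)
    xs_sum <- sum(vapply(seq_len(8), function(r) {
      sum(vapply(seq_len(8), function(c) s[r, c] * neighbour_sum(l, r, c),
                 numeric(1)))
    }, numeric(1)))
    expect_equal(xs_sum, -2 * total_energy(l, ising_params(0, 1, 0)))
  })
})

test_that("delta_energy matches the flip rule and the Q asymmetry", {
  # background cell in an all-background neighbourhood
  m <- matrix(-1L, 3, 3)
  l <- landscape(m)
  expect_equal(delta_energy(l, 2, 2, ising_params(B = 0.2, J = 0.5, Q = 0)), 3.6)
  expect_equal(delta_energy(l, 2, 2, ising_params(B = 0.2, J = 0.5, Q = 100)), 103.6)
  # focus cell in an all-background neighbourhood: Q never applies, and the
  # flip (focus -> background) has dE = 2 x_bf (J S + B) = -3.6
  m[2, 2] <- 1L
  expect_equal(delta_energy(landscape(m), 2, 2, ising_params(0.2, 0.5, 100)),
               2 * (0.5 * -4 + 0.2))
  expect_error(delta_energy(l, 5, 1, ising_params(0, 0)), "out of range")
})

test_that("delta_energy (Q = 0) equals the total-energy difference of the flip", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_states(8)
      p <- ising_params(runif(1, -2, 2), runif(1, 0, 2), 0)
      r <- sample(8, 1); c <- sample(8, 1)
      s2 <- s; s2[r, c] <- -s2[r, c]
      expect_equal(delta_energy(landscape(s), r, c, p),
                   total_energy(landscape(s2), p) - total_energy(landscape(s), p),
                   tolerance = 1e-12)
    }
  })
})

test_that("flip probability is the logistic of -dE, stable and symmetric", {
  expect_identical(flip_probability(0), 0.5)
  expect_equal(flip_probability(log(3)), 0.25)
  expect_lt(flip_probability(100), 1e-43)
  expect_gt(flip_probability(100), 0)
  # no overflow/NaN far beyond the naive exp() range
  expect_false(is.nan(flip_probability(1e6)))
  expect_false(is.nan(flip_probability(-1e6)))
  x <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(flip_probability(x)) < 0))
  expect_equal(flip_probability(x) + flip_probability(-x), rep(1, length(x)))
})

test_that("simulation of zero steps is the identity and seeds give determinism", {
  l <- random_landscape(15, 0.3, seed = 3)
  p <- ising_params(0.1, 0.4)
  expect_identical(unclass(simulate_landscape(l, p, 0)), unclass(l))
  a <- simulate_landscape(l, p, 5000, seed = 42)
  b <- simulate_landscape(l, p, 5000, seed = 42)
  expect_identical(unclass(a), unclass(b))
  expect_error(simulate_landscape(l, p, -1), "non-negative")
})

test_that("free dynamics (B = J = Q = 0) drift toward an even composition", {
  l <- landscape(matrix(-1L, 30, 30))
  fin <- simulate_landscape(l, ising_params(0, 0, 0), 3e4, seed = 9)
  expect_lt(abs(focus_fraction(fin) - 0.5), 0.1)
})

test_that("a positive external force raises the composition index", {
  l <- random_landscape(30, 0.3, seed = 21)
  m0 <- composition_imbalance(l)
  ms <- vapply(1:5, function(i) {
    composition_imbalance(
      simulate_landscape(l, ising_params(B = 1, J = 0.45), 5 * 900, seed = 100 + i))
  }, numeric(1))
  expect_true(all(ms > m0))
})

test_that("balanced dynamics without suppression keep <m> near zero", {
  # B = 0, subcritical J: magnetization fluctuates around 0
  l <- random_landscape(20, 0.5, seed = 13)
  p <- ising_params(0, 0.2, 0)
  ms <- withr::with_seed(14, {
    cur <- l
    vapply(1:300, function(i) {
      cur <<- simulate_landscape(cur, p, 400) # one sweep per sample
      composition_imbalance(cur)
    }, numeric(1))
  })
  expect_lt(abs(mean(ms)), 0.05)
})

test_that("step duration and transition step counts follow the year convention", {
  expect_equal(step_duration(3, 30000), 0.876)
  expect_equal(step_duration(1, 8760), 1.0)
  expect_equal(step_duration(2, 20000), 0.876)
  expect_error(step_duration(-1, 10), "positive")

  expect_equal(steps_for_transition(2, step_hours = 0.876), 20000L)
  expect_equal(steps_for_transition(3, step_hours = 0.876), 30000L)
  expect_equal(steps_for_transition(1, steps_per_year = 62500), 62500L)
  expect_error(steps_for_transition(1e-9, steps_per_year = 100), "zero steps")
  expect_error(steps_for_transition(1), "exactly one")
  expect_error(steps_for_transition(1, steps_per_year = 10, step_hours = 1),
               "exactly one")
})

test_that("schedule_steps expands observation years into per-transition steps", {
  sch <- schedule_steps(c(2001, 2004, 2006, 2008, 2011, 2013, 2016, 2019),
                        steps_per_year = 10000)
  expect_equal(nrow(sch), 7)
  expect_equal(sch$duration_years, c(3, 2, 2, 3, 2, 3, 3))
  expect_equal(sch$n_steps,
               c(30000L, 20000L, 20000L, 30000L, 20000L, 30000L, 30000L))
  expect_error(schedule_steps(c(2001, 2001)), "strictly increasing")
})
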