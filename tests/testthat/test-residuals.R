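test_that("distance residual matches its closed form", {
  expect_equal(residual_distance(c(0, 0, 0), c(1, 0, 0), 1), 0)
  expect_equal(residual_distance(c(5, 5, 5), c(5, 5, 5), 0), 0)
  expect_equal(residual_distance(c(0, 0, 0), c(3, 4, 0), 6), 1)
  expect_error(residual_distance(c(0, 0, NA), c(1, 0, 0), 1),
               class = "jointpart_invalid_input")
  expect_error(residual_distance(c(0, 0, 0), c(1, 0, 0), -1),
               class = "jointpart_invalid_input")
  # rest length equal to realized distance gives a zero residual
  set.seed(41)
  for (i in 1:25) {
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(residual_distance(p, q, sqrt(sum((p - q)^2))), 0,
                 tolerance = 1e-12)
  }
})

test_that("angle residual handles boundary, lock and degeneracy", {
  r <- residual_angle(c(2, 0, 0), c(2, 0, 0), c(5, 1, 1), theta = 30)
  expect_equal(r$angle, -30)
  expect_null(r$axis)
  r <- residual_angle(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0), theta = 90)
  expect_equal(r$angle, 0, tolerance = 1e-12)
  r <- residual_angle(c(4, 5, 3), c(1, 2, 3), c(0, 0, 0), theta = 90,
                      axis = "z")
  expect_equal(r$axis, 0)
  expect_error(residual_angle(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1), 30),
               class = "jointpart_degenerate_geometry")
})

test_that("angle residual is invariant under rigid rotation", {
  set.seed(42)
  for (i in 1:20) {
    p_i <- rnorm(3); p_io <- rnorm(3); p_j <- rnorm(3) + 2
    R <- random_rotation()
    a <- residual_angle(p_i, p_io, p_j, theta = 45)$angle
    b <- residual_angle(drop(R %*% p_i), drop(R %*% p_io),
                        drop(R %*% p_j), theta = 45)$angle
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("flexibility residual pair brackets the rest distance", {
  expect_equal(residual_flexibility(c(0, 0, 0), c(1, 0, 0), 1, 0.5),
               c(lower = -0.5, upper = -0.5))
  expect_equal(residual_flexibility(c(0, 0, 0), c(2, 0, 0), 1, 0.5),
               c(lower = -1.5, upper = 0.5))
  expect_equal(residual_flexibility(c(0, 0, 0), c(1, 0, 0), 1, 0),
               c(lower = 0, upper = 0))
  # with dmax = 0 the pair collapses to +/- the distance residual
  set.seed(43)
  for (i in 1:20) {
    p <- rnorm(3); q <- rnorm(3); rest <- abs(rnorm(1))
    fl <- residual_flexibility(p, q, rest, 0)
    rd <- residual_distance(p, q, rest)
    expect_equal(unname(fl), c(rd, -rd), tolerance = 1e-12)
  }
})

test_that("cone residual follows its aperture geometry", {
  # zero radius: residual is -aperture regardless of geometry
  expect_equal(residual_cone(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), 0, 30), -30)
  # atan(1 / sqrt(3)) = 30 deg, aligned: 2 * 30 - 30 = 30
  d <- sqrt(3)
  expect_equal(
    residual_cone(c(0, 0, 0), c(d, 0, 0), c(d, 0, 0), r = 1, a_ij = 30),
    30, tolerance = 1e-9)
  # anti-aligned reference flips the sign: -2 * 45 - 30
  expect_equal(
    residual_cone(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), r = 1, a_ij = 30),
    -120, tolerance = 1e-9)
  expect_error(residual_cone(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1), 1, 30),
               class = "jointpart_degenerate_geometry")
  # invariant under joint scaling of (r, d)
  set.seed(44)
  for (i in 1:20) {
    r <- runif(1, 0.1, 2); dd <- runif(1, 0.5, 5); s <- runif(1, 0.5, 10)
    a <- residual_cone(c(0, 0, 0), c(dd, 0, 0), c(dd, 0, 0), r, 40)
    b <- residual_cone(c(0, 0, 0), c(s * dd, 0, 0), c(s * dd, 0, 0),
                       s * r, 40)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("cone radius is the tangent-aperture radius", {
  expect_equal(cone_radius(1, 90), 1, tolerance = 1e-12)
  expect_equal(cone_radius(1, 30), 2 - sqrt(3), tolerance = 1e-12)
  expect_equal(cone_radius(2, 30), 2 * (2 - sqrt(3)), tolerance = 1e-12)
  expect_error(cone_radius(0, 30), class = "jointpart_invalid_input")
  expect_error(cone_radius(1, 180), class = "jointpart_invalid_input")
  # monotone in both arguments, and consistent with the cone residual
  # boundary: a cone of aperture a at distance d has residual 0 at its own
  # radius
  set.seed(45)
  for (i in 1:20) {
    dd <- runif(1, 0.5, 5); a <- runif(1, 10, 170)
    r <- cone_radius(dd, a)
    expect_equal(
      residual_cone(c(0, 0, 0), c(dd, 0, 0), c(dd, 0, 0), r, a), 0,
      tolerance = 1e-9)
  }
})

test_that("distance-constraint diagnostics satisfy the stationarity relations", {
  d <- distance_constraint_diagnostics(c(1, 0, 0), c(0, 0, 0), 1,
                                       c(0, 1, 0), c(-1, 0, 0))
  expect_equal(d$C, 0)
  expect_equal(d$C_dot, 0)
  expect_equal(d$C_ddot, 0)
  expect_equal(d$lambda_abs, 1)
  expect_false(d$clipped)

  d <- distance_constraint_diagnostics(c(0, 0, 0), c(0, 0, 0), 0,
                                       c(0, 0, 0), c(0, 0, 0))
  expect_equal(unlist(d[c("C", "C_dot", "C_ddot", "lambda_abs")]),
               c(C = 0, C_dot = 0, C_ddot = 0, lambda_abs = 0))

  d <- distance_constraint_diagnostics(c(2, 0, 0), c(0, 0, 0), 2,
                                       c(0, 0, 0), c(-1, 0, 0))
  expect_equal(d$lambda_abs, sqrt(2))
  # negative radicand is clipped and flagged
  d <- distance_constraint_diagnostics(c(1, 0, 0), c(0, 0, 0), 1,
                                       c(0, 0, 0), c(1, 0, 0))
  expect_equal(d$lambda_abs, 0)
  expect_true(d$clipped)
})

test_that("circular trajectories satisfy the diagnostics to discretization order", {
  # p(t) = p0 + rest (cos wt, sin wt, 0) with central finite differences:
  # C is exactly 0, C_dot and C_ddot vanish at O(h^2), |lambda| -> rest * w
  p0 <- c(1, 2, 3); rest <- 1.7; w <- 0.9
  traj <- function(t) p0 + rest * c(cos(w * t), sin(w * t), 0)
  for (h in c(1e-3, 5e-4)) {
    t <- 0.4
    p <- traj(t)
    p_dot <- (traj(t + h) - traj(t - h)) / (2 * h)
    p_ddot <- (traj(t + h) - 2 * p + traj(t - h)) / h^2
    d <- distance_constraint_diagnostics(p, p0, rest, p_dot, p_ddot)
    expect_equal(d$C, 0, tolerance = 1e-10)
    expect_lt(abs(d$C_dot), 10 * rest^2 * w^3 * h^2)
    expect_lt(abs(d$C_ddot), 10 * rest^2 * w^4 * h^2)
    expect_equal(d$lambda_abs, rest * w, tolerance = 1e-4)
  }
})

test_that("evaluate_all classifies residuals under the tolerance", {
  g <- joint_graph(
    data.frame(id = c("a", "b"), x = c(0, 1), y = 0, z = 0),
    data.frame(kind = "A", i = "a", j = "b", dist = 1)
  )
  rep0 <- evaluate_all(g)
  expect_equal(rep0$n_violations, 0)
  expect_equal(rep0$max_equality_violation, 0)

  tau <- rep0$tol
  moved <- positions(g)
  moved["b", "x"] <- 1 + 2 * tau
  rep1 <- evaluate_all(g, positions = moved)
  expect_equal(rep1$n_violations, 1)
  expect_equal(rep1$max_equality_violation, 2 * tau, tolerance = 1e-3)

  # a generated problem is feasible at its initial state by construction
  g2 <- small_problem(50, 2, seed = 9, moved = FALSE)
  expect_equal(evaluate_all(g2)$n_violations, 0)
})

test_that("evaluate_all covers every constraint kind in one report", {
  g <- joint_graph(
    data.frame(id = c("a", "b", "c", "v"),
               x = c(0, 1, 0, 2), y = c(0, 0, 1, 0), z = 0,
               virtual = c(FALSE, FALSE, FALSE, TRUE),
               twin = c(NA, NA, NA, "b")),
    data.frame(kind = c("A", "B", "C", "D"),
               i = c("a", "a", "b", "a"),
               j = c("b", "c", "c", "v"),
               dist = c(1, NA, sqrt(2), NA),
               dmax = c(NA, NA, 0.5, NA),
               theta = c(NA, 60, NA, NA),
               axis = NA,
               cone_angle = c(NA, NA, NA, 30),
               cone_radius = c(NA, NA, NA, cone_radius(2, 30)))
  )
  rep <- evaluate_all(g)
  expect_equal(nrow(rep$rows), 5L)  # A eq, B ineq, C two ineq, D ineq
  expect_equal(rep$n_violations, 0)
  expect_setequal(unique(rep$rows$kind), c("A", "B", "C", "D"))
})
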