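test_that("group state is the component-wise mean and validates input", {
  expect_equal(group_state(matrix(c(0, 2), 2, 1)), 1)
  m <- rbind(c(1, 0.5, 0.8), c(1, 0.5, 0.8))
  expect_equal(group_state(m), c(1, 0.5, 0.8))
  states <- list(participant_state(1, 0.4, 0.6), participant_state(3, 0.8, 0.2))
  expect_equal(group_state(states), c(2, 0.6, 0.4))
  expect_error(group_state(list(c(1, 2), c(1, 2, 3))),
               class = "apeo_shape_error")
  expect_error(group_state(matrix(numeric(0), 0, 2)),
               class = "apeo_invalid_argument")
})

test_that("cohesion loss is zero iff equal, permutation invariant, variance-linked", {
  expect_equal(cohesion_loss(matrix(c(1, 1, 1), 3, 1)), 0)
  expect_equal(cohesion_loss(matrix(c(0, 2), 2, 1)), 2)
  set.seed(14)
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(cohesion_loss(m), cohesion_loss(m[sample(5), ]))
  # adding a participant exactly at G leaves L unchanged
  g <- colMeans(m)
  expect_equal(cohesion_loss(rbind(m, g)), cohesion_loss(m))
  # scalar case: N * population variance
  x <- rnorm(7)
  expect_equal(cohesion_loss(matrix(x)), 7 * mean((x - mean(x))^2))
  expect_error(cohesion_loss(matrix(c(0, 2), 2, 1), g = 5),
               class = "apeo_invalid_argument")
})

test_that("constraint checks flag values below floors with >= semantics", {
  states <- tibble::tibble(engagement = c(0.5, 0.7), fitness = c(1, 2))
  rep1 <- check_constraints(states, group_constraints(e_min = 0.6))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$participant, 1)
  expect_equal(rep1$quantity, "engagement")
  expect_equal(nrow(check_constraints(states, group_constraints(e_min = 0.4))), 0)
  # boundary value exactly at the floor is not flagged
  expect_equal(nrow(check_constraints(states, group_constraints(e_min = 0.5))), 0)
})

test_that("group reward term and reward distribution match their formulas", {
  expect_equal(group_reward(2, 1, 1, 1, 1), 0)
  expect_equal(group_reward(0, 0.7, 0.4, 0, 0), 0)
  ls <- seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(ls, function(l) group_reward(l, 1, 1), numeric(1))) < 0))
  expect_equal(distribute_group_rewards(c(0.4, 0.6), c(0, 0), 1, 0), 0.5)
  expect_equal(distribute_group_rewards(c(0.4, 0.6), c(0.2, 0.2), 1, 1), 0.7)
  expect_equal(distribute_group_rewards(c(0, 0), c(0, 0)), 0)
  expect_error(distribute_group_rewards(c(1, 2), 1), class = "apeo_shape_error")
})

test_that("graph cohesion handles edges, duplicates and the empty graph", {
  g1 <- social_graph(tibble::tibble(src = 1, dst = 2, weight = 1))
  expect_equal(graph_cohesion(g1, matrix(c(0, 2), 2, 1)), 4)
  expect_equal(graph_cohesion(g1, matrix(c(1, 1), 2, 1)), 0)
  g2 <- social_graph(tibble::tibble(src = c(1, 1), dst = c(2, 2),
                                    weight = c(1, 1)))
  expect_equal(graph_cohesion(g2, matrix(c(0, 2), 2, 1)), 4)
  g0 <- social_graph(tibble::tibble(src = integer(), dst = integer(),
                                    weight = numeric()))
  expect_warning(out <- graph_cohesion(g0, matrix(1)), "undefined")
  expect_true(is.na(out))
  expect_error(social_graph(tibble::tibble(src = 1, dst = 1, weight = 1)),
               class = "apeo_invalid_argument")
})

test_that("complete-graph cohesion cross-checks against the mean-deviation loss", {
  set.seed(44)
  for (k in 1:5) {
    n <- sample(3:8, 1)
    x <- rnorm(n)
    edges <- expand.grid(src = 1:n, dst = 1:n)
    edges <- edges[edges$src != edges$dst, ]
    edges$weight <- 1
    cg <- graph_cohesion(social_graph(edges), matrix(x))
    lg <- cohesion_loss(matrix(x))
    # mean pairwise squared difference = 2 * variance = (2/(N-1)) * (L/ N) * N
    expect_equal(cg, (2 * n / (n - 1)) * (lg / n), tolerance = 1e-10)
  }
})

test_that("influence weights adapt toward more engaged peers and clamp at zero", {
  expect_equal(as.numeric(update_influence(0.3, 0.5, 0.5, 0.2)), 0.3)
  expect_equal(as.numeric(update_influence(0.3, 0.2, 0.7, 0.1)), 0.35)
  w <- update_influence(0.02, 0.9, 0.1, 0.1)
  expect_equal(as.numeric(w), 0)
  expect_true(attr(w, "clamped"))
})

test_that("group Q-learning beats every fixed action on a heterogeneous pair", {
  env <- group_env(preferred_intensities = c(0.25, 0.75))
  pol <- optimize_group_activity(env, episodes = 80, steps_per_episode = 15,
                                 schedule_steps = 15, seed = 7)
  learned <- mean(pol$schedule$l_group)
  # brute force: every fixed single action held for the same horizon
  fixed <- vapply(seq_len(env$n_actions), function(a) {
    env$reset()
    mean(vapply(1:15, function(t) env$step(a)$l_group, numeric(1)))
  }, numeric(1))
  expect_lte(learned, min(fixed) + 1e-9)
  # recommended actions always within the box constraints
  expect_true(all(pol$schedule$intensity >= env$bounds$i_min &
                    pol$schedule$intensity <= env$bounds$i_max))
  pol2 <- optimize_group_activity(env, episodes = 80, steps_per_episode = 15,
                                  schedule_steps = 15, seed = 7)
  expect_identical(pol$schedule, pol2$schedule)
})

test_that("homogeneous groups make the individually best action group-optimal", {
  env <- group_env(preferred_intensities = c(0.5, 0.5, 0.5))
  pol <- optimize_group_activity(env, episodes = 60, steps_per_episode = 10,
                                 schedule_steps = 10, seed = 3)
  # with identical members, cohesion stays 0 under any shared action, so
  # the group objective degenerates to the shared individual one
  expect_equal(max(pol$schedule$l_group), 0, tolerance = 1e-12)
  # and the schedule's mean reward is at least that of the worst fixed action
  fixed <- vapply(seq_len(env$n_actions), function(a) {
    env$reset()
    mean(vapply(1:10, function(t) env$step(a)$reward, numeric(1)))
  }, numeric(1))
  expect_gte(mean(pol$schedule$r_group), min(fixed))
})

test_that("constraint masking keeps infeasible actions out of schedules", {
  env <- group_env(preferred_intensities = c(0.3, 0.4),
                   constraints = group_constraints(e_min = 0.3))
  pol <- optimize_group_activity(env, episodes = 40, steps_per_episode = 10,
                                 schedule_steps = 10, seed = 5)
  # replay the schedule: every recommended action must be feasible at the
  # state in which it was chosen
  env$reset()
  for (a in pol$schedule$action) {
    expect_true(env$feasible()[a])
    env$step(a)
  }
  expect_true(all(pol$schedule$intensity >= env$bounds$i_min))
})

test_that("joint objective sums weighted terms with <= feasibility", {
  jo <- joint_objective(c(0.5, 0.5), c(0, 0), 1, 0, c_balance = 0.4,
                        tau_balance = 0.4)
  expect_equal(jo$value, 1.0)
  expect_true(jo$feasible)  # boundary inclusive
  jo2 <- joint_objective(0.5, 1, 1, 2, c_balance = 0.5, tau_balance = 0.4)
  expect_equal(jo2$value, 2.5)
  expect_false(jo2$feasible)
})

test_that("social graphs round-trip through edge-list CSV", {
  g <- social_graph(tibble::tibble(src = c(1, 2), dst = c(2, 3),
                                   weight = c(0.4, 1.2)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_social_graph(g, tmp)
  back <- read_social_graph(tmp)
  expect_equal(as.data.frame(back), as.data.frame(g), tolerance = 1e-12)
})
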