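test_that("activity parameters enforce their box constraints", {
  b <- activity_bounds(i_min = 0, i_max = 1, d_min = 5, d_max = 60)
  a <- activity_params(0.5, 30, "team", b)
  expect_equal(a$intensity, 0.5)
  expect_error(activity_params(1.2, 30, "team", b),
               class = "apeo_constraint_error")
  expect_error(activity_params(0.5, 100, "team", b),
               class = "apeo_constraint_error")
  expect_error(activity_params(0.5, 30, "chess", b),
               class = "apeo_constraint_error")
})

test_that("activity loss, effort cost and step reward match hand arithmetic", {
  b <- activity_bounds()
  acts <- list(activity_params(0.5, 30, "aerobic", b))
  expect_equal(activity_loss(1, function(a) 0.6, acts), 0.16)
  expect_equal(activity_loss(c(1, 2), function(a) c(1, 2), acts), 0)

  w <- reward_weights(gamma1 = 1, gamma2 = 1)
  a2 <- activity_params(2, 3, "skill", activity_bounds(i_max = 5, d_min = 1))
  expect_equal(effort_cost(a2, w), 7)
  a0 <- activity_params(0, 5, "skill", activity_bounds(d_min = 5))
  expect_equal(effort_cost(a0, reward_weights(gamma1 = 1, gamma2 = 0)), 0)
  # doubling intensity quadruples the intensity term
  a4 <- activity_params(4, 3, "skill", activity_bounds(i_max = 5, d_min = 1))
  expect_equal(effort_cost(a4, reward_weights(gamma1 = 1, gamma2 = 0)),
               4 * effort_cost(a2, reward_weights(gamma1 = 1, gamma2 = 0)))

  w1 <- reward_weights(alpha1 = 1, alpha2 = 1, beta_effort = 1)
  expect_equal(step_reward(0.5, 0.7, 0.2, w1), 1.0)
  expect_equal(step_reward(1, 1, 1, reward_weights(0, 0, 0)), 0)
})

test_that("reward is monotone in engagement and effort (finite differences)", {
  w <- reward_weights(alpha1 = 0.7, alpha2 = 0.3, beta_effort = 0.4)
  h <- 1e-6
  set.seed(6)
  for (k in 1:10) {
    e <- runif(1); f <- runif(1); c0 <- runif(1)
    de <- (step_reward(e + h, f, c0, w) - step_reward(e - h, f, c0, w)) / (2 * h)
    dc <- (step_reward(e, f, c0 + h, w) - step_reward(e, f, c0 - h, w)) / (2 * h)
    expect_gte(de, 0)
    expect_lte(dc, 0)
  }
})

test_that("q_update changes only the visited entry by the Bellman increment", {
  q <- q_table(3, 2, eta_lr = 1, gamma_discount = 0)
  q <- q_update(q, 1, 1, 1, 2)
  q <- q_update(q, 1, 2, 0, 2)
  expect_equal(q$values[1, ], c(1, 0))
  expect_equal(q$values[2, ], c(0, 0))
  q0 <- q_table(2, 2, eta_lr = 1)
  q0$eta_lr <- 1e-12  # effectively frozen
  qf <- q_update(q0, 1, 1, 100, 2)
  expect_lt(abs(qf$values[1, 1]), 1e-9)
  expect_error(q_update(q, 5, 1, 0, 1), class = "apeo_index_error")
})

test_that("deterministic-chain Q-learning reaches the value-iteration fixed point", {
  # 3-state deterministic chain with gamma = 0.9
  trans <- matrix(c(2, 1, 3, 2, 3, 3), 3, 2)
  rew <- matrix(c(0, 0.1, 1, 0, 0, 0.5), 3, 2)
  q_pkg <- q_sweeps(trans, rew, gamma = 0.9, sweeps = 300)
  q_vi <- value_iteration(trans, rew, gamma = 0.9)
  expect_lt(max(abs(q_pkg - q_vi)), 1e-6)
})

test_that("Q-learning matches value iteration on random small MDPs", {
  for (seed in 1:5) {
    mdp <- random_mdp(5, 5, seed)
    q_pkg <- q_sweeps(mdp$trans, mdp$rew, gamma = 0.8, sweeps = 400)
    q_vi <- value_iteration(mdp$trans, mdp$rew, gamma = 0.8)
    expect_lt(max(abs(q_pkg - q_vi)), 1e-6)
  }
})

test_that("greedy tie-breaking and masking are deterministic", {
  q <- q_table(1, 4)
  q$values[1, ] <- c(1, 1, 0.5, 1)
  expect_equal(greedy_action(q, 1), 1L)
  expect_equal(greedy_action(q, 1, mask = c(FALSE, TRUE, TRUE, TRUE)), 2L)
  expect_error(greedy_action(q, 1, mask = rep(FALSE, 4)),
               class = "apeo_infeasible_error")
})

test_that("training identifies the best arm of a bandit", {
  # single-state bandit: arm 3 pays 1, others pay 0
  env <- list(
    n_states = 1L, n_actions = 4L,
    reset = function() 1L,
    step = function(s, a) list(state = 1L, reward = as.numeric(a == 3L),
                               done = FALSE)
  )
  pol <- train_policy(env, episodes = 30, steps_per_episode = 20, seed = 11)
  expect_equal(greedy_action(pol$q, 1), 3L)
  pol2 <- train_policy(env, episodes = 30, steps_per_episode = 20, seed = 11)
  expect_identical(pol$returns, pol2$returns)
  expect_error(train_policy(env, episodes = 0),
               class = "apeo_invalid_argument")
  expect_error(train_policy(env, episodes = 1, epsilon_schedule = 0.3),
               class = "apeo_config_error")
})

test_that("a fully exploratory policy chooses actions uniformly", {
  counts <- integer(4)
  env <- list(
    n_states = 1L, n_actions = 4L,
    reset = function() 1L,
    step = function(s, a) {
      counts[a] <<- counts[a] + 1L
      list(state = 1L, reward = 0, done = FALSE)
    }
  )
  n_steps <- 4000
  train_policy(env, episodes = 1, steps_per_episode = n_steps,
               epsilon_schedule = function(ep) 1.0, seed = 21)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("greedy beats random on the simulated participant environment", {
  wins <- 0L
  for (seed in 1:20) {
    env <- participant_env(preferred_modality = 1L + (seed %% 5),
                           preferred_intensity = 0.3 + 0.05 * (seed %% 7))
    pol <- train_policy(env, episodes = 40, steps_per_episode = 25,
                        seed = seed)
    g <- evaluate_policy(env, pol$q, episodes = 5, steps_per_episode = 25,
                         seed = seed + 500)
    r <- evaluate_policy(env, NULL, episodes = 5, steps_per_episode = 25,
                         seed = seed + 500)
    wins <- wins + (g >= r)
  }
  expect_gte(wins, 18L)  # greedy at least matches random almost always
})

test_that("Q-tables round-trip through CSV", {
  q <- q_table(3, 4)
  q$values[] <- matrix(rnorm(12), 3, 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_q_table(q, tmp)
  back <- read_q_table(tmp)
  expect_equal(back$values, q$values, tolerance = 1e-12)
})
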