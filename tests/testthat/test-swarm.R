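test_that("swarm initialization satisfies the state invariants", {
  d <- random_dataset(40, 10, seed = 1)
  cfg <- swarm_config(particles = 5, order = 2, seed = 99)
  st <- initialize_swarm(d, cfg)
  expect_equal(dim(st$position), c(5, 2))
  expect_true(all(st$position >= 1 & st$position <= 10))
  expect_true(all(apply(st$position, 1, anyDuplicated) == 0))
  expect_true(all(abs(st$velocity) <= 9))
  expect_identical(st$pbest, st$position)
  expect_equal(st$gbest_mi, max(st$pbest_mi))
  expect_equal(sum(st$count), 5 * 2)  # each pbest contributes K occurrences
  expect_equal(st$iteration, 1L)

  st2 <- initialize_swarm(d, cfg)
  expect_identical(st, st2)  # same seed, same state

  expect_error(initialize_swarm(d, swarm_config(order = 10)), "below")
})

test_that("dynamic inertia spans [0, 1] with a static fallback", {
  count <- c(5L, 1L, 3L)
  expect_equal(dynamic_inertia(count, 1), 0)    # max-counter SNP exploits
  expect_equal(dynamic_inertia(count, 2), 1)    # min-counter SNP explores
  expect_equal(dynamic_inertia(count, 3), 0.5)
  expect_equal(dynamic_inertia(c(2L, 2L, 2L), 1), 0.65)
  expect_equal(dynamic_inertia(c(2L, 2L), 2, fallback = 0.3), 0.3)
  expect_error(dynamic_inertia(count, 4), "out of range")
})

test_that("velocity update reproduces the closed-form combination", {
  # no inertia, no attraction: stationary
  expect_equal(update_velocity(c(3, 4), c(2, -5), c(1, 1), c(2, 2),
                               weights = 0, c1 = 0, c2 = 0, m = 100),
               c(0, 0))
  # worked value: 0.65*2 + 2*0.5*5 + 2*0.5*15 = 21.3
  expect_equal(update_velocity(position = 10, velocity = 2, pbest = 15,
                               gbest = 25, weights = 0.65, c1 = 2, c2 = 2,
                               m = 100, r1 = 0.5, r2 = 0.5),
               21.3)
  # out-of-domain components are resampled inside [1-M, M-1]
  set.seed(5)
  for (rep in 1:20) {
    v <- update_velocity(position = 1, velocity = 8.9, pbest = 10,
                         gbest = 10, weights = 1, c1 = 2, c2 = 2, m = 10,
                         r1 = 1, r2 = 1)  # tilde v = 8.9 + 18 + 18, out
    expect_true(v >= -9 && v <= 9)
  }
})

test_that("position update truncates in range, resamples out of range, and keeps indices distinct", {
  expect_equal(update_position(10L, 21.3, m = 100), 31L)
  set.seed(8)
  for (rep in 1:20) {
    p <- update_position(95L, 21.3, m = 100)
    expect_true(p >= 1 && p <= 100)
  }
  # forced collision: both dimensions land on 7
  set.seed(9)
  for (rep in 1:20) {
    p <- update_position(c(5L, 6L), c(2, 1), m = 10)  # both -> 7
    expect_equal(anyDuplicated(p), 0)
    expect_true(7 %in% p)
  }
})

test_that("opposition mirrors indices and is an involution", {
  expect_equal(opposite_position(c(3L, 97L), m = 100), c(98L, 4L))
  expect_equal(opposite_position(51L, m = 101), 51L)  # fixed point, odd M
  set.seed(2)
  for (rep in 1:25) {
    m <- sample(5:200, 1)
    x <- sample(m, sample(1:3, 1))
    expect_identical(opposite_position(opposite_position(x, m), m), x)
  }
})

test_that("pbest adopts the fittest of position, opposite and previous best", {
  # M = 4: SNPs 3,4 jointly determine the phenotype, SNPs 1,2 are inert
  set.seed(21)
  n <- 120
  a <- sample(0:1, n, TRUE)
  b <- sample(0:1, n, TRUE)
  d <- snp_data(cbind(rep(0L, n), rep_len(0:2, n), a, b),
                phenotype = as.integer(xor(a == 1, b == 1)))
  # opposite of (1,2) is (4,3): strictly the best of the three
  upd <- update_pbest(d, position = c(1L, 2L), pbest = c(1L, 2L))
  expect_equal(sort(upd$pbest), c(3L, 4L))
  expect_equal(upd$mi, snp_mi(d, c(3, 4)))
  # previous pbest strictly best: unchanged
  upd2 <- update_pbest(d, position = c(1L, 2L), pbest = c(3L, 4L))
  expect_equal(upd2$pbest, c(3L, 4L))
  # exact three-way tie keeps the previous pbest
  dnull <- snp_data(matrix(rep(rep_len(0:2, 9), 4), ncol = 4),
                    phenotype = rep(c(0L, 1L, 0L), 3))
  upd3 <- update_pbest(dnull, position = c(1L, 2L), pbest = c(2L, 3L))
  expect_equal(upd3$pbest, c(2L, 3L))
  # without opposition only position vs pbest compete
  upd4 <- update_pbest(d, position = c(1L, 2L), pbest = c(1L, 2L),
                       opposition = FALSE)
  expect_equal(upd4$pbest, c(1L, 2L))
})

test_that("gbest only moves on strict improvement and counters accrue P*K", {
  d <- random_dataset(50, 8, seed = 33)
  st <- initialize_swarm(d, swarm_config(particles = 6, order = 2, seed = 5))
  # tie: clone state with gbest already at the best pbest
  before <- st$gbest
  st2 <- update_gbest(st)
  expect_identical(st2$gbest, before)
  expect_equal(sum(st2$count) - sum(st$count), 6 * 2)
  # strict improvement: plant a better pbest
  st$pbest_mi[3] <- st$gbest_mi + 0.5
  st$pbest[3, ] <- c(1L, 2L)
  st3 <- update_gbest(st)
  expect_equal(st3$gbest, c(1L, 2L))
  expect_equal(st3$gbest_mi, st$gbest_mi + 0.5)
})

test_that("post-search returns the best subset of the most visited SNPs", {
  d <- planted_xor_dataset(n = 200, m = 12, pair = c(4, 9), seed = 6)
  cfg <- swarm_config(particles = 8, iterations = 3, order = 2,
                      top_n = 12, seed = 17)
  st <- initialize_swarm(d, cfg)
  st <- step_swarm(st, d, cfg)
  # with top_n = M the post-search is exhaustive: global optimum guaranteed
  post <- postprocess_swarm(st, d, cfg)
  expect_setequal(post$snp_set, c(4, 9))
  expect_gte(post$mi, st$gbest_mi)
  # when gbest is already the optimum the answer is unchanged
  st$gbest <- c(4L, 9L)
  st$gbest_mi <- snp_mi(d, c(4, 9))
  post2 <- postprocess_swarm(st, d, cfg)
  expect_equal(post2$snp_set, c(4L, 9L))
  expect_false(post2$improved)
  expect_error(postprocess_swarm(st, d, swarm_config(order = 2, top_n = 2)),
               NA)
  cfg_bad <- swarm_config(order = 2, top_n = 2)
  cfg_bad$top_n <- 1L
  expect_error(postprocess_swarm(st, d, cfg_bad), "top_n")
})

test_that("full runs are reproducible and recover a planted pair", {
  d <- planted_xor_dataset(n = 300, m = 30, pair = c(5, 22), seed = 10)
  fit1 <- detect_interactions(d, particles = 20, iterations = 20, seed = 4)
  fit2 <- detect_interactions(d, particles = 20, iterations = 20, seed = 4)
  expect_identical(fit1$snp_set, fit2$snp_set)
  expect_identical(fit1$trace, fit2$trace)
  expect_setequal(fit1$snp_set, c(5, 22))
  expect_true(all(diff(fit1$trace$gbest_mi) >= 0))
  expect_gte(fit1$mi_interaction, max(fit1$mi_individual))
  expect_equal(nrow(fit1$trace), 20)
})

test_that("the plain pso variant never touches opposition, dynamic inertia or the post-search", {
  d <- planted_xor_dataset(n = 100, m = 10, pair = c(2, 8), seed = 2)
  local_mocked_bindings(
    dynamic_inertia = function(...) stop("dynamic_inertia called"),
    opposite_position = function(...) stop("opposite_position called"),
    .postprocess_swarm = function(...) stop("postprocess called"),
    .package = "episwarm"
  )
  fit <- detect_interactions(d, particles = 8, iterations = 5,
                             variant = "pso", seed = 3)
  expect_s3_class(fit, "epi_result")
  expect_true(is.na(fit$improved_by_postsearch))
})

test_that("multi-run reports group identical SNP sets with detection counts", {
  d <- planted_xor_dataset(n = 250, m = 15, pair = c(3, 11), seed = 14)
  multi <- detect_interactions(d, particles = 15, iterations = 15,
                               seed = 8, runs = 5)
  expect_s3_class(multi, "epi_multirun")
  rep <- tidy(multi)
  expect_equal(sum(rep$times), 5)
  expect_true(all(diff(rep$mi_interaction) <= 0))  # sorted by MI desc
  # strong planted signal: all runs agree on one pair
  expect_equal(nrow(rep), 1)
  expect_equal(rep$times[1], 5)
  # deterministic under the same seed
  multi2 <- detect_interactions(d, particles = 15, iterations = 15,
                                seed = 8, runs = 5)
  expect_identical(tidy(multi2), rep)
})

test_that("tidy, glance and autoplot expose the detection result", {
  d <- planted_xor_dataset(n = 150, m = 10, pair = c(1, 6), seed = 5)
  fit <- detect_interactions(d, particles = 10, iterations = 10, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("snp_id", "index", "mi_individual", "count",
                     "mi_interaction", "p_value", "p_bonferroni"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mi_interaction, fit$mi_interaction)
  expect_s3_class(autoplot(fit), "ggplot")
})
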