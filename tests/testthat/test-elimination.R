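# Stepwise elimination mechanics and the two-stage selection.

test_that("elimination counts, step sizes and termination follow the schedule", {
  sim <- sim_lpls_data(small_config(50), seed = 101)
  tr <- lpls_eliminate(sim$y, sim$X, sim$Z, stage = 1, u = 1, f = 0.5,
                       alpha = 0.5, ncomp = 2, cv_folds = 5, seed = 1)
  df <- as.data.frame(tr, long = FALSE)
  # S = ceiling(f * M) whenever the 2-variable floor is not hit
  uncapped <- df$n_active - df$S >= 2 & df$S > 0
  expect_true(all(df$S[uncapped] == ceiling(0.5 * df$M[uncapped])))
  # active sets strictly decrease and the count drops by exactly S
  expect_true(all(diff(df$n_active) < 0))
  expect_equal(df$n_active[-1], (df$n_active - df$S)[-nrow(df)])
  # terminal iteration: either M = 0 or the floor was reached
  last <- nrow(df)
  expect_true(df$M[last] == 0 || df$n_active[last] - df$S[last] <= 2)
  # cross-validated error is finite everywhere
  expect_true(all(is.finite(df$E_g) & df$E_g >= 0))
})

test_that("f = 1 removes every below-cutoff variable at once", {
  sim <- sim_lpls_data(small_config(40), seed = 7)
  tr <- lpls_eliminate(sim$y, sim$X, sim$Z, stage = 1, u = 1, f = 1,
                       alpha = 0.3, ncomp = 2, cv_folds = 5, seed = 2)
  df <- as.data.frame(tr, long = FALSE)
  expect_true(all(df$S[df$S > 0] ==
                    pmin(df$M, df$n_active - 2L)[df$S > 0]))
})

test_that("u = 0 keeps everything: no VIP can fall strictly below zero", {
  sim <- sim_lpls_data(small_config(40), seed = 8)
  tr <- lpls_eliminate(sim$y, sim$X, sim$Z, stage = 1, u = 0, f = 0.5,
                       alpha = 0.5, ncomp = 2, cv_folds = 5, seed = 3)
  expect_length(tr$iterations, 1)
  expect_identical(tr$iterations[[1]]$M, 0L)
  expect_equal(tr$iterations[[1]]$active, seq_len(ncol(sim$X)))
})

test_that("identical seeds give identical traces", {
  sim <- sim_lpls_data(small_config(40), seed = 9)
  t1 <- lpls_eliminate(sim$y, sim$X, sim$Z, u = 1, f = 0.5, ncomp = 2,
                       cv_folds = 5, seed = 11)
  t2 <- lpls_eliminate(sim$y, sim$X, sim$Z, u = 1, f = 0.5, ncomp = 2,
                       cv_folds = 5, seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("parameter validation rejects bad fractions and cutoffs", {
  sim <- sim_lpls_data(small_config(30), seed = 10)
  expect_error(lpls_eliminate(sim$y, sim$X, sim$Z, f = 0), "'f'")
  expect_error(lpls_eliminate(sim$y, sim$X, sim$Z, f = 1.2), "'f'")
  expect_error(lpls_eliminate(sim$y, sim$X, sim$Z, u = -1), "'u'")
  expect_error(lpls_eliminate(sim$y, sim$X, sim$Z, stage = 3), "'stage'")
})

test_that("model choice trades error for sparsity through the paired test", {
  # synthetic trace: residuals designed so the p-value crosses the
  # rejection threshold between two known iterations
  set.seed(42)
  base <- rnorm(30, sd = 1)
  mk_iter <- function(active, res) list(active = active,
                                        vip = rep(1, length(active)),
                                        M = 1L, S = 1L,
                                        E_g = sqrt(mean(res^2)),
                                        cv_residuals = res,
                                        p_value = NA_real_)
  # guarantee the intended RMSE ordering: scale each vector to a fixed
  # multiple of the optimum's mean squared residual
  rescale <- function(res, factor)
    res * sqrt(factor * mean(base^2) / mean(res^2))
  res_list <- list(
    rescale(base + rnorm(30, sd = 0.60), 1.4),  # pre-optimum
    base,                                       # optimum
    rescale(base + rnorm(30, sd = 0.05), 1.001),# indistinguishable
    base + 0.8 * sign(base)                     # clearly worse
  )
  trace <- structure(list(stage = 1, folds = NULL, u = 1, f = 0.5,
                          alpha = 0, ncomp = 1,
                          iterations = lapply(seq_along(res_list), function(g)
                            mk_iter(seq_len(10 - g), res_list[[g]])),
                          optimum_index = NA, chosen_index = NA),
                     class = "lpls_trace")
  # the paired p-values computed independently
  p3 <- t.test(res_list[[3]]^2, res_list[[2]]^2, paired = TRUE)$p.value
  p4 <- t.test(res_list[[4]]^2, res_list[[2]]^2, paired = TRUE)$p.value
  expect_gt(p3, 0.05)
  expect_lt(p4, 0.05)
  out <- choose_model(trace, d = 0.95)
  expect_identical(out$optimum_index, 2L)
  expect_identical(out$chosen_index, 3L)
  expect_equal(out$iterations[[2]]$p_value, 1)
  expect_equal(out$iterations[[3]]$p_value, p3)
  expect_equal(out$iterations[[4]]$p_value, p4)

  # a single-iteration trace chooses itself
  tr1 <- structure(list(stage = 1, iterations = list(mk_iter(1:5, base)),
                        optimum_index = NA, chosen_index = NA),
                   class = "lpls_trace")
  out1 <- choose_model(tr1, 0.9)
  expect_identical(out1$chosen_index, 1L)

  expect_error(choose_model(trace, d = 0), "'d'")
})

test_that("two-stage selection keeps X and Z dimensionally consistent", {
  sim <- sim_lpls_data(small_config(50), seed = 12)
  sel <- lpls_select(sim$y, sim$X, sim$Z, u = 1, f = 0.5, d = 0.90,
                     alpha = 0.5, ncomp = 2, cv_folds = 5, seed = 4)
  expect_true(all(sel$selected_x %in% seq_len(ncol(sim$X))))
  expect_true(all(sel$selected_z %in% seq_len(nrow(sim$Z))))
  expect_gt(length(sel$selected_x), 0)
  expect_gt(length(sel$selected_z), 0)
  # the refit model saw exactly the surviving blocks
  expect_identical(unname(sel$model$dims["k"]), length(sel$selected_x))
  expect_identical(unname(sel$model$dims["l"]), length(sel$selected_z))
  # stage-1 removal propagated to Z's columns: stage-2 trace ran on a Z
  # with the surviving column count
  expect_identical(unname(sel$trace_z$iterations[[1]]$active),
                   seq_len(nrow(sim$Z)))
  expect_equal(sel$final_rmse,
               sel$trace_z$iterations[[sel$trace_z$chosen_index]]$E_g)
})

test_that("selection on simulated data is enriched for the relevant groups", {
  # relevance is known by construction: groups 1-4 carry the response
  # signal, groups 5-8 are noise; selection frequency over replicates must
  # favour the relevant variables
  n_rel <- 0; n_irr <- 0; reps <- 20
  for (r in seq_len(reps)) {
    sim <- sim_lpls_data(small_config(50), seed = 1000 + r)
    sel <- lpls_select(sim$y, sim$X, sim$Z, u = 10, f = 0.5, d = 0.80,
                       alpha = 0.8, ncomp = 3, cv_folds = 5, seed = r)
    n_rel <- n_rel + sum(sim$relevant_x %in% sel$selected_x)
    n_irr <- n_irr + sum(!(sel$selected_x %in% sim$relevant_x))
  }
  freq_rel <- n_rel / (reps * 20)   # 20 relevant variables per dataset
  freq_irr <- n_irr / (reps * 20)   # 20 irrelevant variables per dataset
  expect_gt(freq_rel, freq_irr)
})
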