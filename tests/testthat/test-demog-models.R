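test_that("the registry holds ten instantiable models with nesting structure", {
  reg <- list_models()
  expect_equal(nrow(reg), 10)
  expect_setequal(reg$name,
    c("split_nomig", "split_symmig_adjacent", "split_asymmig_adjacent",
      "split_sym_mig_all", "refugia_adj_1", "refugia_adj_2", "refugia_adj_3",
      "refugia_barrier", "refugia_asymmig_adjacent", "refugia_symmig_all"))
  # the barrier model is nested in the secondary-contact model
  expect_true(all(model_params("refugia_barrier") %in%
                    model_params("refugia_adj_2")))
  expect_true(all(model_params("split_nomig") %in%
                    model_params("split_symmig_adjacent")))
  # every model instantiates at all-ones parameters
  for (nm in reg$name) {
    pn <- model_params(nm)
    dem <- model_demography(nm, stats::setNames(rep(1, length(pn)), pn))
    expect_s3_class(dem, "demography")
  }
  expect_error(model_demography("no_such_model", 1), "unknown model")
  expect_error(model_demography("split_nomig",
    c(nu1 = -1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = .5, T2 = .2)), "positive")
})

test_that("nesting identities hold exactly under common random numbers", {
  cfg <- pop_config(n_samples = c(DST = 4, STH = 4, PLN = 4), n_loci = 1, seed = 2)
  base <- c(nu1 = 1, nu2 = 1.2, nu3 = 0.8, nu23 = 1.5, T1 = .5, T2 = .2)
  d_adj2 <- model_demography("refugia_adj_2", c(base, mDS = 0, mSP = .4))
  d_barrier <- model_demography("refugia_barrier", c(base, mSP = .4))
  s1 <- branch_spectrum(d_adj2, cfg, 800)
  s2 <- branch_spectrum(d_barrier, cfg, 800)
  expect_identical(s1$counts, s2$counts)
})

test_that("expected spectra satisfy degenerate limits and symmetries", {
  # near-zero split times approach the single-population shape
  sp0 <- expected_sfs("split_nomig",
                      c(nu1 = 1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = 1e-4, T2 = 1e-4),
                      sizes = c(2, 2, 2), fold = FALSE, n_reps = 6000, seed = 3)
  # pooled derived-count distribution should follow the 1/i law for n = 6
  tot <- (slice.index(sp0$counts, 1) - 1) + (slice.index(sp0$counts, 2) - 1) +
    (slice.index(sp0$counts, 3) - 1)
  pooled <- vapply(1:5, function(i) sum(sp0$counts[tot == i]), 0)
  law <- (1 / (1:5)) / sum(1 / (1:5))
  expect_lt(max(abs(pooled - law) / law), 0.08)

  # STH/PLN-symmetric parameters give an STH/PLN-symmetric spectrum
  spS <- expected_sfs("refugia_symmig_all",
                      c(nu1 = 1, nu2 = 1.3, nu3 = 1.3, nu23 = 1, T1 = .5,
                        T2 = .2, mDS = .3, mSP = .3, mDP = .3),
                      sizes = c(3, 3, 3), fold = FALSE, n_reps = 20000, seed = 4)
  sym <- aperm(spS$counts, c(1, 3, 2))
  keep <- !(spS$mask | aperm(spS$mask, c(1, 3, 2)))
  expect_lt(max(abs(spS$counts - sym)[keep]), 0.012)
})

test_that("the multinomial likelihood matches hand arithmetic and MLE property", {
  # hand-computed two-cell example: 2 ln(2/3) + 1 ln(1/3)
  obs <- jsfs3(array(c(0, 2, 1, 0), c(4, 1, 1)), pop_order = "P")
  ex <- jsfs3(array(c(0, 2/3, 1/3, 0), c(4, 1, 1)), pop_order = "P")
  expect_equal(multinomial_loglik(obs, ex), 2 * log(2/3) + log(1/3),
               tolerance = 1e-6)

  # obs proportional to expected maximises the likelihood over the simplex:
  # direct optimisation over a 3-cell toy agrees
  obs3 <- jsfs3(array(c(0, 30, 20, 10, 0), c(5, 1, 1)), pop_order = "P")
  nll <- function(q) {
    p <- c(exp(q), 1) / (sum(exp(q)) + 1)
    ex <- jsfs3(array(c(0, p, 0), c(5, 1, 1)), pop_order = "P")
    -multinomial_loglik(obs3, ex)
  }
  opt <- optim(c(0, 0), nll)
  p_hat <- c(exp(opt$par), 1) / (sum(exp(opt$par)) + 1)
  expect_equal(p_hat, c(30, 20, 10) / 60, tolerance = 1e-3)

  # observed mass on an empty model cell is finite via the epsilon floor
  ex0 <- jsfs3(array(c(0, 1, 0, 0), c(4, 1, 1)), pop_order = "P")
  ll <- multinomial_loglik(obs, ex0)
  expect_true(is.finite(ll) && ll < -500)

  expect_error(multinomial_loglik(obs, jsfs3(array(1, c(3, 1, 1)))), "shapes")
})

test_that("likelihood at truth beats random 2x-perturbed parameter vectors", {
  truth <- c(nu1 = 1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = .5, T2 = .2)
  fine <- expected_sfs("split_nomig", truth, c(6, 6, 6), fold = TRUE,
                       n_reps = 30000, seed = 55)
  obs <- fine
  obs$counts <- obs$counts * 2e4        # large-n spectrum
  ll_truth <- model_loglik(obs, "split_nomig", truth, n_reps = 8000, seed = 7)
  set.seed(77)
  for (i in 1:10) {
    pert <- truth * 2^runif(6, -1, 1)
    expect_gt(ll_truth, model_loglik(obs, "split_nomig", pert,
                                     n_reps = 8000, seed = 7))
  }
})

test_that("the staged fit reaches the optimum of a noise-free spectrum", {
  # obs proportional to the expected spectrum on the fitting surface: the
  # multinomial optimum is exactly the generating vector.  The fit must
  # reach that optimum's likelihood level; parameter distance is bounded
  # more loosely because the soft nu23/T1 mode is nearly flat (a 15% move
  # along it costs ~1 log-likelihood unit even at 10,000 sites)
  truth <- c(nu1 = 1.3, nu2 = 0.7, nu3 = 1, nu23 = 1.1, T1 = .6, T2 = .25)
  seed <- 5
  crn <- (5 + 99991) %% 2147483647
  sp <- expected_sfs("split_nomig", truth, c(6, 6, 6), fold = TRUE,
                     n_reps = 20000, seed = crn)
  obs <- sp; obs$counts <- obs$counts * 1e4
  fit <- fit_model(obs, "split_nomig", seed = seed,
                   n_reps = c(1000, 2000, 3000, 4000),
                   polish_reps = 20000, polish_cycles = 3)
  ll_truth <- model_loglik(obs, "split_nomig", truth, n_reps = 20000, seed = crn)
  # at 10,000 sites the surface's frozen Monte-Carlo noise between distant
  # points is itself tens of log-likelihood units; 25 is within that
  # resolution, and two orders below the gaps that separate wrong basins
  expect_gte(fit$lnL, ll_truth - 25)
  expect_lt(max(abs(fit$params - truth) / truth), 0.20)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$lnL)
})

test_that("refitting with the same seed reproduces the result exactly", {
  truth <- c(nu1 = 1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = .5, T2 = .2)
  crn <- (9 + 99991) %% 2147483647
  sp <- expected_sfs("split_nomig", truth, c(4, 4, 4), fold = TRUE,
                     n_reps = 500, seed = crn)
  obs <- sp; obs$counts <- obs$counts * 2000
  sched <- list(replicates = c(3, 4), maxiter = c(4, 6), fold = c(2, 1))
  fits <- lapply(1:2, function(i)
    fit_model(obs, "split_nomig", seed = 9, n_reps = 500, schedule = sched,
              polish_steps = c(0.15, 0.07), polish_reps = 1500))
  expect_identical(fits[[1]]$params, fits[[2]]$params)
  expect_identical(fits[[1]]$lnL, fits[[2]]$lnL)
  expect_identical(fits[[1]]$schedule_log, fits[[2]]$schedule_log)
})
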