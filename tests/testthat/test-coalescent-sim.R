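test_that("simulation is bit-reproducible and validates inputs", {
  dem <- two_pop_split()
  cfg <- pop_config(n_samples = c(A = 2, B = 2), n_loci = 20, locus_len = 500,
                    mut_scale = 0.01, seed = 99)
  x <- simulate_msc(dem, cfg)
  y <- simulate_msc(dem, cfg)
  expect_identical(x, y)
  # distance representation is likewise reproducible
  xd <- simulate_msc(dem, cfg, representation = "distances")
  yd <- simulate_msc(dem, cfg, representation = "distances")
  expect_identical(xd, yd)
  # every sample is labelled; per-locus matrices carry all samples
  expect_named(x$sample_labels)
  expect_true(all(vapply(x$genotypes, ncol, 0L) == 4))

  expect_error(demography("P", sizes = -1), "positive")
  expect_error(demography("P", sizes = 1, migration = matrix(-1, 1, 1)),
               "non-negative")
  expect_error(pop_config(n_samples = c(A = 2), n_loci = 0), "n_loci")
})

test_that("within-population diversity matches theta and between matches 2 tau + theta_anc", {
  # one panmictic population: mean pairwise diversity ~ theta
  dem <- demography("P", sizes = 1, mu = NA)
  cfg <- pop_config(n_samples = c(P = 2), n_loci = 5000, locus_len = 5000,
                    mut_scale = 0.01, seed = 7)
  ls <- simulate_msc(dem, cfg, representation = "distances")
  divs <- vapply(ls$distances, function(D) D[1, 2], 0)
  expect_rel_error(mean(divs), 0.01, 0.05)

  # two populations split at T with ancestral size nu_anc, no migration:
  # E(d) = 2 tau + theta_anc, and the oracle is the same average computed
  # from the simulated coalescence times directly
  dem2 <- two_pop_split(T_split = 0.5, nu_anc = 2)
  cfg2 <- pop_config(n_samples = c(A = 1, B = 1), n_loci = 5000,
                     locus_len = 5000, mut_scale = 0.01, seed = 13)
  ls2 <- simulate_msc(dem2, cfg2, representation = "distances")
  d <- vapply(ls2$distances, function(D) D[1, 2], 0)
  tt <- vapply(ls2$coal_times, function(D) D[1, 2], 0)
  tau <- 0.5 * 0.01 / 2
  theta_anc <- 2 * 0.01
  expect_rel_error(mean(d), 2 * tau + theta_anc, 0.05)
  # brute-force averaging of coalescence times gives the same expectation
  expect_rel_error(mean(2 * tt * 0.01 / 2), 2 * tau + theta_anc, 0.05)
  # distances agree with mutation-count noise around the time-based values
  expect_rel_error(mean(d), mean(2 * tt * 0.01 / 2), 0.03)
})

test_that("branch spectrum obeys the neutral 1/i law and island-model symmetry", {
  dem <- demography("P", sizes = 1, mu = NA)
  cfg <- pop_config(n_samples = c(P = 4), n_loci = 1, seed = 11)
  sp <- branch_spectrum(dem, cfg, n_reps = 10000, axes = "P")
  v <- as.numeric(sp$counts[2:4, 1, 1])
  law <- (1 / (1:3)) / sum(1 / (1:3))
  expect_lt(max(abs(v - law) / law), 0.03)

  # symmetric two-population island model: spectrum symmetric under exchange
  mig <- matrix(c(0, 1, 1, 0), 2, 2)
  dem2 <- demography(c("A", "B"), sizes = c(1, 1), migration = mig, mu = NA)
  cfg2 <- pop_config(n_samples = c(A = 3, B = 3), n_loci = 1, seed = 5)
  sp2 <- branch_spectrum(dem2, cfg2, n_reps = 20000, axes = c("A", "B"))
  m <- sp2$counts[, , 1]
  keep <- !sp2$mask[, , 1] & !t(sp2$mask[, , 1])
  expect_lt(max(abs(m - t(m))[keep]), 0.01)
})

test_that("shared polymorphism decays as the split deepens", {
  cfg <- pop_config(n_samples = c(DST = 4, STH = 4, PLN = 4), n_loci = 1, seed = 3)
  shared <- vapply(c(0.1, 0.5, 2.0), function(T1) {
    dem <- model_demography("split_nomig",
                            c(nu1 = 1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = T1, T2 = 0.1))
    sp <- branch_spectrum(dem, cfg, n_reps = 4000)
    # mass on cells polymorphic in DST and in (STH+PLN) jointly
    i <- slice.index(sp$counts, 1) - 1
    jk <- (slice.index(sp$counts, 2) - 1) + (slice.index(sp$counts, 3) - 1)
    sum(sp$counts[i > 0 & i < 4 & jk > 0 & jk < 8 & !sp$mask])
  }, 0)
  expect_true(all(diff(shared) < 0))
})

test_that("a zero-probability introgression model reduces exactly to the species tree", {
  p <- msci_params_peak1()
  p0 <- p
  p0$phi_A <- p0$phi_B <- p0$phi_C <- p0$phi_D <- 0
  cfg <- pop_config(n_samples = c(DST = 3, STH = 3, PLN = 3, OG = 1),
                    n_loci = 200, locus_len = 1000, seed = 17)
  msci <- simulate_msci(p0, cfg, representation = "distances")
  msc <- simulate_msc(msci_demography(p, drop_phi = TRUE), cfg,
                      representation = "distances")
  expect_identical(msci$distances, msc$distances)
})

test_that("published-parameter simulation stays inside coalescent bounds", {
  p <- msci_params_peak1()
  cfg <- pop_config(n_samples = c(DST = 3, STH = 3, PLN = 3), n_loci = 400,
                    locus_len = 10000, seed = 23)
  ls <- simulate_msci(p, cfg, representation = "distances")
  s <- divergence_summary(ls, "DST", "STH")
  expect_gt(s$d_mean_between, 2 * p$tau_CD)
  expect_lt(s$d_mean_between, 2 * p$tau_R + max(p$theta))
})

test_that("hybrid loci split between parents at the mixing probability", {
  p <- msci_params_experiment(phi_C = 0)      # plain species tree
  hy <- hybrid_spec("DST", c("STH", "DST"), mixing_prob = 0.5)
  cfg <- pop_config(n_samples = c(DST = 2, STH = 2, PLN = 2), n_loci = 1000,
                    locus_len = 1e5, seed = 31)
  ls <- simulate_msci(p, cfg, hybrid = hy, representation = "distances")
  # loci where the hybrid coalesces first with an STH individual are its
  # STH-derived loci; their minimum distance to STH is on the within-pop
  # scale, far below the between-population floor 2 tau_T
  hyb <- "DST_hyb"
  sth <- names(ls$sample_labels)[ls$sample_labels == "STH"]
  d_sth <- vapply(ls$distances, function(D) min(D[hyb, sth]), 0)
  frac_sth <- mean(d_sth < 2 * p$tau_T)
  expect_gt(frac_sth, 0.5 - 3 * sqrt(0.25 / 1000))
  expect_lt(frac_sth, 0.5 + 3 * sqrt(0.25 / 1000))
  expect_error(simulate_msci(p, cfg, hybrid = hybrid_spec("DST", c("XX", "STH"))),
               "unknown")
})

test_that("locus sets round-trip through FASTA/TSV/JSON on disk", {
  dem <- two_pop_split()
  cfg <- pop_config(n_samples = c(A = 2, B = 2), n_loci = 5, locus_len = 100,
                    mut_scale = 0.05, seed = 41)
  ls <- simulate_msc(dem, cfg)
  dir <- tempfile()
  paths <- write_locus_set(ls, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_genotypes_tsv(paths["genotypes"])
  expect_equal(nrow(tab), sum(vapply(ls$genotypes, nrow, 0L)))
  # FASTA sequences classify consistently with the simulated genotypes
  fa <- readLines(paths["fasta"])
  seqs <- fa[!startsWith(fa, ">")]
  first_locus <- seqs[1:4]
  cs <- classify_sites(first_locus)
  expect_equal(cs$n_invariant + cs$n_variable_uninformative +
                 cs$n_parsimony_informative, 100)
  seg <- nrow(ls$genotypes[[1]])
  expect_equal(cs$n_variable_uninformative + cs$n_parsimony_informative,
               sum(apply(ls$genotypes[[1]], 1, function(x) var(x) > 0)))
})

test_that("spectra built from simulated loci match the branch-length expectation", {
  dem <- model_demography("split_nomig",
                          c(nu1 = 1, nu2 = 1, nu3 = 1, nu23 = 1, T1 = .5, T2 = .2))
  cfg <- pop_config(n_samples = c(DST = 2, STH = 2, PLN = 2), n_loci = 20000,
                    locus_len = 200, mut_scale = 0.02, seed = 19)
  obs <- build_jsfs(simulate_msc(dem, cfg), fold = FALSE, one_per_locus = TRUE)
  expect_gt(jsfs_mass(obs), 19000)
  ex <- branch_spectrum(dem, pop_config(n_samples = c(DST = 2, STH = 2, PLN = 2),
                                        n_loci = 1, seed = 5), n_reps = 40000)
  keep <- !(obs$mask | ex$mask)
  p_obs <- obs$counts[keep] / sum(obs$counts[keep])
  p_ex <- ex$counts[keep] / sum(ex$counts[keep])
  expect_lt(sum(abs(p_obs - p_ex)) / 2, 0.05)   # total-variation distance
})
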