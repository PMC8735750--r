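test_that("building a spectrum places mass at hand-computed cells", {
  # single SNP with derived counts (1, 0, 2) over 2 haploids per population
  gt <- data.frame(locus = "L1", pos = 0, a1 = 1, a2 = 0, b1 = 0, b2 = 0,
                   c1 = 1, c2 = 1)
  pm <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2", c1 = "P3", c2 = "P3")
  j <- build_jsfs(gt, pm)
  expect_equal(j$counts[2, 1, 3], 1)
  expect_equal(jsfs_mass(j), 1)

  # monomorphic input: zero mass
  gt0 <- gt
  gt0[, names(pm)] <- 0
  expect_equal(jsfs_mass(build_jsfs(gt0, pm)), 0)
})

test_that("one SNP per locus retains the first biallelic SNP of each locus", {
  set.seed(3)
  n_loci <- 10
  rows <- do.call(rbind, lapply(seq_len(n_loci), function(l)
    data.frame(locus = sprintf("L%02d", l), pos = c(5, 1, 9),
               a1 = 0, a2 = rbinom(3, 1, .5),
               b1 = rbinom(3, 1, .5), b2 = 1)))  # a1=0/b2=1: always segregating
  pm <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2")
  j <- build_jsfs(rows, pm, one_per_locus = TRUE)
  expect_equal(jsfs_mass(j), n_loci)
})

test_that("missing data are projected, unprojectable sites dropped with a message", {
  gt <- data.frame(locus = c("L1", "L2"), pos = 0,
                   a1 = c(1, 1), a2 = c(1, NA), b1 = c(0, 0), b2 = c(1, NA))
  pm <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2")
  # project to (1, 1): L1 contributes hypergeometric weights (half its mass
  # lands in the all-derived cell (1,1), which is masked away), L2 in P2 has
  # one observed haploid so it can still be projected to 1
  j <- build_jsfs(gt, pm, project_to = c(1, 1, 0))
  expect_equal(jsfs_mass(j), 1.5, tolerance = 1e-12)
  expect_equal(j$counts[2, 1, 1], 1.5, tolerance = 1e-12)  # cell (1, 0)
  # target (2, 2): the incomplete site is unprojectable and dropped
  expect_message(j2 <- build_jsfs(gt, pm, project_to = c(2, 2, 0)),
                 "dropped")
  expect_equal(jsfs_mass(j2), 1)
  # individual missing from the population map is an error
  expect_error(build_jsfs(gt, pm[-1]), "missing from pop_map")
})

test_that("folding follows the mirror arithmetic and conserves mass", {
  # n = (2,2,2), unit mass at (2,2,1): total 5 > 3, mirror is (0,0,1)
  a <- array(0, c(3, 3, 3)); a[3, 3, 2] <- 1
  f <- fold_jsfs(jsfs3(a))
  expect_equal(f$counts[1, 1, 2], 1)
  expect_true(f$folded)
  expect_error(fold_jsfs(f), "already folded")

  # mass conservation for random spectra, and tie-cell convention
  for (seed in 1:3) {
    r <- random_jsfs(seed = seed)
    f <- fold_jsfs(r)
    expect_equal(jsfs_mass(f), jsfs_mass(r))
    # folded mass only in the minor-allele half (ties allowed at n_tot/2)
    tot <- outer(outer(0:4, 0:4, "+"), 0:4, "+")
    expect_true(all(f$counts[tot > 6] == 0))
  }

  # mirror-symmetric spectrum folds to twice the lower half
  a <- array(1, c(3, 3, 3))
  f <- fold_jsfs(jsfs3(a))
  tot <- outer(outer(0:2, 0:2, "+"), 0:2, "+")
  strictly_lower <- tot < 3 & !f$mask
  expect_true(all(f$counts[strictly_lower][-1] == 2))
})

test_that("projection matches exhaustive subsampling on small cases", {
  # all-derived pop-1 site: any subsample of 1 from 2 carries the allele
  b <- array(0, c(3, 3, 3)); b[3, 1, 1] <- 1
  pj <- project_jsfs(jsfs3(b), c(1, 2, 2))
  expect_equal(pj$counts[2, 1, 1], 1)

  # identity projection
  r <- random_jsfs(seed = 9)
  expect_identical(project_jsfs(r, c(4, 4, 4)), r)
  expect_error(project_jsfs(r, c(5, 4, 4)), "project up")

  # 1-population 1/i law, n=4 -> n=2: the surviving (singleton) cell matches
  # the brute-force hypergeometric sum; the projected doubleton cell is the
  # fixed cell at n=2 and is masked away
  v <- array(0, c(5, 1, 1)); v[2:4] <- 1 / (1:3)
  p2 <- project_jsfs(jsfs3(v, pop_order = "P"), c(2, 0, 0))
  expected <- numeric(3)  # cells j = 0, 1, 2
  for (i in 1:3) for (j in 0:2)
    expected[j + 1] <- expected[j + 1] + (1 / i) * dhyper(j, i, 4 - i, 2)
  expect_equal(as.numeric(p2$counts[2, 1, 1]), expected[2], tolerance = 1e-12)
  expect_true(p2$mask[3, 1, 1])
  expect_equal(jsfs_mass(p2), expected[2], tolerance = 1e-12)
})

test_that("projection is an exhaustive-enumeration average on a toy spectrum", {
  # brute force: enumerate all subsamples of 2 from 4 haploids for every
  # 1-population cell and compare to the hypergeometric projection
  set.seed(5)
  mass <- runif(5)
  arr <- array(0, c(5, 1, 1)); arr[] <- mass
  pj <- project_jsfs(jsfs3(arr, pop_order = "P"), c(2, 0, 0))
  brute <- numeric(3)
  for (i in 0:4) {
    hap <- c(rep(1, i), rep(0, 4 - i))
    subs <- combn(4, 2)
    for (s in seq_len(ncol(subs))) {
      j <- sum(hap[subs[, s]])
      brute[j + 1] <- brute[j + 1] + mass[i + 1] / ncol(subs)
    }
  }
  # compare unmasked cells (j = 1 is the only never-fixed cell)
  expect_equal(as.numeric(pj$counts[2, 1, 1]), brute[2], tolerance = 1e-12)
})

test_that("the SFS text format round-trips and rejects malformed files", {
  f <- fold_jsfs(random_jsfs(seed = 4))
  tf <- tempfile(fileext = ".sfs")
  write_sfs(f, tf)
  g <- read_sfs(tf)
  expect_equal(g$counts, f$counts)
  expect_identical(g$mask, f$mask)
  expect_identical(g$folded, TRUE)
  expect_identical(g$pop_order, f$pop_order)

  # header declares folded but mass sits in the major-allele half
  r <- random_jsfs(seed = 8)
  tf2 <- tempfile(fileext = ".sfs")
  write_sfs(r, tf2)
  lines <- readLines(tf2)
  lines[1] <- sub("unfolded", "folded", lines[1])
  writeLines(lines, tf2)
  expect_error(read_sfs(tf2), "folded")

  # truncated mask line
  lines <- readLines(tf)
  lines[3] <- paste(strsplit(lines[3], " ")[[1]][1:10], collapse = " ")
  writeLines(lines, tf)
  expect_error(read_sfs(tf), "line 3")
})

test_that("fold, project and build conserve countable mass jointly", {
  set.seed(11)
  gt <- do.call(rbind, lapply(1:30, function(l) {
    g <- data.frame(locus = sprintf("L%02d", l), pos = 0:1,
                    a1 = rbinom(2, 1, .4), a2 = rbinom(2, 1, .4),
                    b1 = rbinom(2, 1, .4), b2 = rbinom(2, 1, .4),
                    c1 = rbinom(2, 1, .4), c2 = rbinom(2, 1, .4))
    g
  }))
  pm <- c(a1 = "P1", a2 = "P1", b1 = "P2", b2 = "P2", c1 = "P3", c2 = "P3")
  j <- build_jsfs(gt, pm)
  seg <- sum(apply(gt[, names(pm)], 1, function(x) {
    s <- sum(x); s > 0 && s < 6
  }))
  expect_equal(jsfs_mass(j), seg)
  expect_equal(jsfs_mass(fold_jsfs(j)), seg)
})

test_that("VCF input round-trips into the same spectrum as the genotype table", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=L1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
           paste("L1", "5", ".", "A", "T", ".", "PASS", ".", "GT",
                 "0/1", "0/0", "1/1", "./.", sep = "\t"),
           paste("L1", "9", ".", "C", "G,T", ".", "PASS", ".", "GT",
                 "0/1", "0/0", "0/0", "0/0", sep = "\t"),
           paste("L2", "3", ".", "G", "C", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "0/0", "0/1", sep = "\t"))
  tf <- tempfile(fileext = ".vcf")
  writeLines(vcf, tf)
  expect_warning(v <- read_vcf_genotypes(tf), "non-biallelic")
  expect_equal(v$ploidy, 2L)
  expect_equal(nrow(v$genotypes), 2)         # multiallelic site skipped
  expect_equal(v$genotypes$pos, c(4L, 2L))   # converted to 0-based
  pm <- c(s1 = "P1", s2 = "P1", s3 = "P2", s4 = "P2")
  j <- build_jsfs(v$genotypes, pm, ploidy = 2, project_to = c(2, 2, 0))
  # site 1: P1 derived 1/4 obs -> (0, 1) with weight 0.5 each; P2 derived
  # 2/2 obs (s4 missing) -> always 2.  site 2: (1, 1) of (4, 4) -> quarter
  # weights, of which the (0,0) quarter is masked.  unmasked mass = 1.75
  expect_equal(jsfs_mass(j), 1.75, tolerance = 1e-12)
  expect_equal(j$counts[2, 3, 1], 0.5, tolerance = 1e-12)   # cell (1, 2)
})
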