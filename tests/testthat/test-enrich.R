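mk_ld <- function(a, b, r2) data.frame(rsid_a = a, rsid_b = b, r2 = r2)

test_that("expand_ld uses strict direct lookups, no closure", {
  expect_identical(expand_ld(c("a", "b"), NULL)$a, "a")
  ld <- mk_ld(c("a", "b", "a"), c("b", "c", "c"), c(0.9, 0.9, 0.5))
  px <- expand_ld("a", ld)
  expect_setequal(px$a, c("a", "b")) # 0.5 edge and b-c chain excluded
  ## boundary: r2 exactly at the threshold is excluded
  expect_identical(expand_ld("x", mk_ld("x", "y", 0.8))$x, "x")
  expect_setequal(expand_ld("x", mk_ld("x", "y", 0.801))$x, c("x", "y"))
  ## symmetry: either column may carry the query SNP
  expect_setequal(expand_ld("y", mk_ld("x", "y", 0.9))$y, c("y", "x"))
})

test_that("catalog loci merge through LD connected components", {
  snps <- sprintf("s%04d", 1:3943)
  expect_identical(merge_catalog_loci(snps, NULL), 3943L)
  expect_identical(merge_catalog_loci(sprintf("s%d", 1:10),
                                      mk_ld("s1", "s2", 0.95)), 9L)
  ## three linked pairs collapse 6 SNPs into 3 loci: 3943 -> 3940
  ld <- mk_ld(c("s0001", "s0003", "s0005"),
              c("s0002", "s0004", "s0006"), 0.99)
  expect_identical(merge_catalog_loci(snps, ld), 3940L)
  ## edges to SNPs outside the catalog do not merge catalog loci
  ld2 <- mk_ld("s0001", "zzz", 0.99)
  expect_identical(merge_catalog_loci(snps, ld2), 3943L)
})

test_that("observed overlap counts unique tagged set members", {
  expect_identical(
    observed_overlap(c("a", "b"), NULL, character(0), character(0))$n_total,
    0L)
  ## a catalog SNP that is itself a set member counts via its self-proxy
  ov <- observed_overlap("c1", NULL, character(0), cnm_set = "c1")
  expect_identical(ov$n_cnm, 1L)
  expect_identical(ov$n_total, 1L)

  ## planted configuration: 5 MRESS + 7 CNM proxies
  catalog <- sprintf("g%02d", 1:20)
  mress <- sprintf("m%02d", 1:5)
  cnm <- sprintf("c%02d", 1:7)
  ld <- rbind(mk_ld(catalog[1:5], mress, 0.95),
              mk_ld(catalog[6:12], cnm, 0.9),
              mk_ld(catalog[13], "unrelated", 0.99),
              mk_ld(catalog[14], mress[1], 0.5)) # below threshold
  ov <- observed_overlap(catalog, ld, mress, cnm)
  expect_identical(ov$n_mress, 5L)
  expect_identical(ov$n_cnm, 7L)
  expect_identical(ov$n_total, 12L)
  ## exhaustive pairwise check
  manual <- unique(c(
    intersect(catalog, c(mress, cnm)),
    unlist(lapply(catalog, function(s) {
      nb <- c(ld$rsid_b[ld$rsid_a == s & ld$r2 > 0.8],
              ld$rsid_a[ld$rsid_b == s & ld$r2 > 0.8])
      intersect(nb, c(mress, cnm))
    }))))
  expect_identical(ov$n_total, length(manual))
})

test_that("resampling null behaves at the degenerate extremes", {
  universe <- data.frame(rsid = sprintf("u%03d", 1:200),
                         maf = runif(200, 0.05, 0.5))
  null0 <- resample_null(universe, character(0), NULL, n_draw = 50,
                         reps = 20, rng_seed = 5)
  expect_true(all(null0$replicate_counts == 0L))
  expect_identical(null0$mean, 0)
  expect_identical(null0$sd, 0)

  null_all <- resample_null(universe, universe$rsid, NULL, n_draw = 50,
                            reps = 20, rng_seed = 5)
  expect_true(all(null_all$replicate_counts == 50L))

  expect_error(resample_null(universe, universe$rsid, NULL, n_draw = 500,
                             reps = 5, rng_seed = 1),
               "universe too small")
})

test_that("null counts track the hypergeometric expectation and seed", {
  n <- 2000L
  universe <- data.frame(rsid = sprintf("u%04d", 1:n),
                         maf = rep(0.25, n))
  set <- universe$rsid[seq_len(n * 0.05)] # exactly 5%
  null <- resample_null(universe, set, NULL, n_draw = 200, reps = 500,
                        rng_seed = 42)
  expectation <- 200 * 0.05
  se <- null$sd / sqrt(null$reps)
  expect_lt(abs(null$mean - expectation), 3 * se + 1e-9)
  ## determinism
  null2 <- resample_null(universe, set, NULL, n_draw = 200, reps = 500,
                         rng_seed = 42)
  expect_identical(null$replicate_counts, null2$replicate_counts)
  null3 <- resample_null(universe, set, NULL, n_draw = 200, reps = 500,
                         rng_seed = 43)
  expect_false(identical(null$replicate_counts, null3$replicate_counts))
})

test_that("MAF filtering restricts the sampling pool", {
  universe <- data.frame(rsid = c(sprintf("lo%02d", 1:50),
                                  sprintf("hi%02d", 1:50)),
                         maf = c(rep(0.005, 50), rep(0.2, 50)))
  ## set = the rare SNPs: excluded from the pool, counts must be zero
  null <- resample_null(universe, sprintf("lo%02d", 1:50), NULL,
                        n_draw = 50, reps = 10, maf_min = 0.01,
                        rng_seed = 7)
  expect_true(all(null$replicate_counts == 0L))
})

test_that("tail probabilities follow the normal and add-one forms", {
  null <- structure(list(replicate_counts = c(10, 20, 30, 40),
                         mean = 25, sd = 10, reps = 4L, n_draw = 100L,
                         rng_seed = 1L), class = "null_distribution")
  tp <- tail_probability(null, 25)
  expect_equal(tp$p_normal, 0.5)
  expect_equal(tp$p_empirical, (1 + 2) / 5)

  tp2 <- tail_probability(null, 25 + 1.96 * 10)
  expect_lt(abs(tp2$p_normal - 0.025), 1e-3)

  ## monotone decreasing in the observed count
  ps <- vapply(seq(25, 85, by = 10),
               function(o) tail_probability(null, o)$p_normal, numeric(1))
  expect_true(all(diff(ps) < 0))

  ## zero-SD null: analytic tail undefined, empirical still returned
  null0 <- structure(list(replicate_counts = rep(5, 4), mean = 5, sd = 0,
                          reps = 4L, n_draw = 10L, rng_seed = 1L),
                     class = "null_distribution")
  tp0 <- tail_probability(null0, 7)
  expect_true(is.na(tp0$p_normal))
  expect_equal(tp0$p_empirical, 1 / 5)
})

test_that("the published-scale tail agrees with a Mills-ratio expansion", {
  null <- structure(list(replicate_counts = integer(0), mean = 24.99,
                         sd = 6.19, reps = 1000L, n_draw = 3940L,
                         rng_seed = 1L), class = "null_distribution")
  tp <- tail_probability(null, 87)
  z <- (87 - 24.99) / 6.19
  expect_equal(tp$z, z)
  ## upper tail via the asymptotic expansion phi(z)/z (1 - 1/z^2 + 3/z^4)
  mills <- exp(-z^2 / 2) / sqrt(2 * pi) / z * (1 - 1 / z^2 + 3 / z^4)
  expect_lt(abs(log10(tp$p_normal) - log10(mills)), 0.01)
  expect_lt(tp$p_normal, 1e-22) # far beyond any conventional threshold
})
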