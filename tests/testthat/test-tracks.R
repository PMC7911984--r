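# SNP density, distance weighting, the conservation score and MinMax scaling.

test_that("snp_density matches a brute-force windowed recount", {
  expect_equal(snp_density(integer(), 100), rep(0, 100))
  expect_equal(snp_density(0:99, 100), rep(1, 100))

  # single variant at 100: exactly the 20 window positions covering it get 1/20
  sig <- snp_density(100L, 300L, window = 20)
  expect_equal(sum(sig > 0), 20L)
  expect_equal(unique(sig[sig > 0]), 1 / 20)
  expect_equal(sig, oracle_snp_density(100L, 300L, 20))

  # random positions, including chromosome-end truncation
  set.seed(9)
  pos <- sort(sample(0:149, 25))
  expect_equal(snp_density(pos, 150L), oracle_snp_density(pos, 150L))
  expect_equal(snp_density(pos, 150L, window = 7),
               oracle_snp_density(pos, 150L, 7))
  expect_error(snp_density(c(5L, 3L), 10L), "sorted")
})

test_that("normalize_identity weights rows by distance", {
  I <- matrix(c(0.9, 0.9, 0.5, 0.2, 0, 1), nrow = 2,
              dimnames = list(c("s1", "s2"), NULL))
  attr(I, "chrom") <- "chr1"
  class(I) <- c("identity_matrix", "matrix", "array")
  d <- tibble::tibble(species = c("s1", "s2"), distance = c(0.1, 0.5))
  In <- normalize_identity(I, d)
  expect_equal(unname(In["s1", ]), c(0.9, 0.5, 0) * 0.1)
  expect_equal(unname(In["s2", ]), c(0.9, 0.2, 1) * 0.5)
  # same identity in a more distant species carries more weight
  expect_gt(In["s2", 1], In["s1", 1])
  # unit distances leave the matrix unchanged
  expect_equal(normalize_identity(I, c(s1 = 1, s2 = 1))[, ], I[, ])
  expect_error(normalize_identity(I, c(s1 = 0.1)), "s2")
})

test_that("conservation_score evaluates the stated per-base model", {
  I <- matrix(1, nrow = 2, ncol = 4, dimnames = list(c("a", "b"), NULL))
  class(I) <- c("identity_matrix", "matrix", "array")
  In <- normalize_identity(I, c(a = 0.5, b = 0.5))
  # neutral factors: raw score is the mean weighted identity
  tr <- conservation_score(In, sigma = rep(0, 4), phylop = rep(0, 4))
  expect_equal(tr$cs_raw, rep(0.5, 4))
  # sigma = 1 annihilates the score
  tr1 <- conservation_score(In, sigma = rep(1, 4), phylop = rep(0, 4))
  expect_equal(tr1$cs_raw, rep(0, 4))
  # direct evaluation: mean 0.5, sigma 0.05, p 1 -> 0.5 * (0.95/1.05) * 2
  tr2 <- conservation_score(In, sigma = rep(0.05, 4), phylop = rep(1, 4))
  expect_equal(tr2$cs_raw, rep(0.5 * (0.95 / 1.05) * 2, 4), tolerance = 1e-12)
  expect_error(conservation_score(In, sigma = rep(1.2, 4)), "sigma")
})

test_that("vectorised pipeline equals the scalar model on random inputs", {
  set.seed(20)
  for (rep in 1:5) {
    m <- sample(2:6, 1); n <- 1000L
    I <- matrix(stats::runif(m * n), nrow = m,
                dimnames = list(paste0("s", 1:m), NULL))
    class(I) <- c("identity_matrix", "matrix", "array")
    d <- stats::runif(m, 0.05, 1)
    names(d) <- rownames(I)
    sigma <- stats::runif(n)
    p <- stats::rnorm(n)
    tr <- conservation_score(normalize_identity(I, d), sigma, p)
    expect_equal(tr$cs_raw, oracle_cs_scalar(I, d, sigma, p), tolerance = 1e-12)
  }
})

test_that("the SNP and selection factors behave as designed", {
  sg <- seq(0, 1, by = 0.05)
  f <- (1 - sg) / (1 + sg)
  expect_equal(f[1], 1)
  expect_equal(f[length(f)], 0)
  expect_true(all(diff(f) < 0))
  # cs_raw monotone: non-increasing in sigma, non-decreasing in p
  I <- matrix(0.8, nrow = 1, ncol = length(sg), dimnames = list("s1", NULL))
  class(I) <- c("identity_matrix", "matrix", "array")
  In <- normalize_identity(I, c(s1 = 0.3))
  by_sigma <- conservation_score(In, sigma = sg, phylop = rep(0, length(sg)))$cs_raw
  expect_true(all(diff(by_sigma) <= 0))
  pg <- seq(-3, 3, length.out = length(sg))
  by_p <- conservation_score(In, sigma = rep(0.1, length(sg)), phylop = pg)$cs_raw
  expect_true(all(diff(by_p) >= 0))
  expect_true(all(by_p >= 0))
})

test_that("minmax_scale spans [0,1] and absorbs global distance rescaling", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_scale(c(3, 3, 3)), "constant")
  expect_equal(z, c(0, 0, 0))

  set.seed(31)
  I <- matrix(stats::runif(300), nrow = 3, dimnames = list(paste0("s", 1:3), NULL))
  class(I) <- c("identity_matrix", "matrix", "array")
  d <- c(s1 = 0.1, s2 = 0.3, s3 = 0.6)
  sigma <- stats::runif(100); p <- stats::rnorm(100)
  t1 <- minmax_scale(conservation_score(normalize_identity(I, d), sigma, p))
  t2 <- minmax_scale(conservation_score(normalize_identity(I, d * 7.3), sigma, p))
  expect_equal(t1$cs_scaled, t2$cs_scaled, tolerance = 1e-12)
  expect_equal(range(t1$cs_scaled), c(0, 1))

  # genome-wide domain pools min/max across arms
  tra <- conservation_score(normalize_identity(I, d), sigma, p)
  trb <- conservation_score(normalize_identity(I * 0.5, d), sigma, p)
  both <- minmax_scale(list(a = tra, b = trb), domain = "genome")
  expect_equal(max(c(both$a$cs_scaled, both$b$cs_scaled)), 1)
  expect_equal(min(c(both$a$cs_scaled, both$b$cs_scaled)), 0)
})

test_that("group_mean_identity averages species subsets over windows", {
  I <- matrix(c(rep(1, 10), rep(0.6, 10), rep(0.8, 10)), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  attr(I, "chrom") <- "chrX"
  class(I) <- c("identity_matrix", "matrix", "array")
  one <- group_mean_identity(I, "s3", window = 10)
  expect_equal(one$mean_identity, 80)
  two <- group_mean_identity(I, c("s1", "s2"), window = 10)
  expect_equal(two$mean_identity, 80)
  # truncated tail window averaged over its actual span
  I2 <- I[, 1:7, drop = FALSE]
  attr(I2, "chrom") <- "chrX"
  class(I2) <- c("identity_matrix", "matrix", "array")
  tr <- group_mean_identity(I2, c("s1", "s2"), window = 5)
  expect_equal(tr$end, c(5L, 7L))
  expect_equal(tr$mean_identity, c(80, 80))
  expect_error(group_mean_identity(I, "nope"), "nope")
})

test_that("tidy and glance expose tracks as tibbles", {
  I <- matrix(0.5, nrow = 1, ncol = 10, dimnames = list("s1", NULL))
  attr(I, "chrom") <- "chr1"
  class(I) <- c("identity_matrix", "matrix", "array")
  tr <- minmax_scale(conservation_score(
    normalize_identity(I, c(s1 = 1)), sigma = seq(0, 0.9, 0.1), phylop = rep(0, 10)))
  td <- tidy(tr)
  expect_equal(nrow(td), 10L)
  expect_named(td, c("chrom", "pos", "cs_raw", "cs_scaled"))
  gl <- glance(tr)
  expect_equal(gl$n_bases, 10L)
  expect_equal(gl$scaling, "arm")
})
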