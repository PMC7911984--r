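# Cas9 site enumeration, conservation scoring, ranking and percentiles.

make_track <- function(cs_scaled, chrom = "chr1") {
  I <- matrix(0, nrow = 1, ncol = length(cs_scaled), dimnames = list("s1", NULL))
  attr(I, "chrom") <- chrom
  class(I) <- c("identity_matrix", "matrix", "array")
  tr <- conservation_score(normalize_identity(I, c(s1 = 1)))
  tr$cs_scaled <- cs_scaled
  tr$scaling <- "arm"
  tr
}

test_that("enumerate_cas9_sites finds NGG sites on both strands", {
  expect_equal(nrow(enumerate_cas9_sites(strrep("A", 100))), 0L)

  # one + site: GG at positions 22-23 of the site
  seq <- paste0(strrep("A", 21), "GG", strrep("T", 10))
  s <- enumerate_cas9_sites(seq)
  expect_equal(s$strand, "+")
  expect_equal(c(s$start, s$end), c(0L, 23L))
  expect_equal(s$pam, "AGG")
  expect_equal(s$protospacer, strrep("A", 20))

  # one - site: CC at the left edge; protospacer reported on the site strand
  seq2 <- paste0("CCA", strrep("T", 25))
  s2 <- enumerate_cas9_sites(seq2)
  s2m <- s2[s2$strand == "-", ]
  expect_equal(nrow(s2m), 1L)
  expect_equal(s2m$pam, "TGG")
  expect_equal(s2m$protospacer, strrep("A", 20))

  # sites containing N are dropped
  seqN <- paste0(strrep("A", 10), "N", strrep("A", 10), "GG", strrep("A", 5))
  expect_equal(nrow(enumerate_cas9_sites(seqN)), 0L)
})

test_that("enumeration equals the brute-force pattern oracle, including region bounds", {
  set.seed(77)
  for (rep in 1:10) {
    seq <- rand_dna(500)
    got <- enumerate_cas9_sites(seq)
    exp <- oracle_cas9(seq)
    expect_equal(got$start, exp$start)
    expect_equal(got$strand, exp$strand)
    expect_true(all(got$end - got$start == 23))
    # truncated sites at region boundaries are dropped
    sub <- enumerate_cas9_sites(seq, start = 50, end = 200)
    exp_sub <- exp[exp$start >= 50 & exp$end <= 200, ]
    expect_equal(sub$start, exp_sub$start)
  }
  g <- ref_genome(c(c1 = rand_dna(100)))
  expect_error(enumerate_cas9_sites(g, "c1", 0, 200), "out of bounds")
})

test_that("reverse-complementing the sequence mirrors sites across strands", {
  set.seed(78)
  for (rep in 1:5) {
    seq <- rand_dna(300)
    L <- nchar(seq)
    fwd <- enumerate_cas9_sites(seq)
    rev <- enumerate_cas9_sites(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))))
    flip <- function(s, from, to) sort(L - s$end[s$strand == from])
    expect_equal(flip(fwd, "+", "-"), sort(rev$start[rev$strand == "-"]))
    expect_equal(flip(fwd, "-", "+"), sort(rev$start[rev$strand == "+"]))
    # protospacer sets match after the flip
    expect_setequal(fwd$protospacer[fwd$strand == "+"],
                    rev$protospacer[rev$strand == "-"])
  }
})

test_that("score_sites attaches site statistics and accessibility flags", {
  cs <- rep(0.4, 100)
  tr <- make_track(cs)
  sites <- tibble::tibble(chrom = "chr1", start = c(10L, 40L), end = c(33L, 63L),
                          strand = "+", protospacer = strrep("A", 20), pam = "AGG")
  sc <- score_sites(sites, tr)
  expect_equal(sc$cs_mean, c(0.4, 0.4))
  expect_equal(sc$cs_min, sc$cs_max)
  expect_true(all(sc$accessible))

  # linear ramp: mean at midpoint, min/max at the ends
  ramp <- seq(0, 1, length.out = 100)
  sc2 <- score_sites(sites[1, ], make_track(ramp))
  v <- ramp[11:33]
  expect_equal(sc2$cs_mean, mean(v))
  expect_equal(sc2$cs_min, v[1])
  expect_equal(sc2$cs_max, v[23])
  expect_true(sc2$cs_min <= sc2$cs_mean && sc2$cs_mean <= sc2$cs_max)

  # one-bp mask overlap flips accessibility
  mask <- tibble::tibble(chrom = "chr1", start = 32L, end = 35L)
  sc3 <- score_sites(sites, tr, mask)
  expect_equal(sc3$accessible, c(FALSE, TRUE))

  # sites beyond the track raise
  far <- tibble::tibble(chrom = "chr1", start = 90L, end = 113L, strand = "+",
                        protospacer = strrep("A", 20), pam = "AGG")
  expect_error(score_sites(far, tr), "beyond")
})

test_that("rank_sites orders deterministically and ignores input order", {
  set.seed(80)
  sites <- tibble::tibble(
    chrom = "chr1", start = as.integer(seq(0, 90, by = 10)),
    end = as.integer(seq(23, 113, by = 10)), strand = "+",
    protospacer = strrep("A", 20), pam = "AGG",
    cs_mean = c(0.60, 0.56, 0.51, 0.50, 0.48, 0.45, 0.44, 0.41, 0.36, 0.36),
    cs_min = c(0.26, 0.20, 0.19, 0.19, 0.19, 0.15, 0.17, 0.17, 0.17, 0.10),
    cs_max = 0.7, accessible = TRUE
  )
  shuffled <- sites[sample(nrow(sites)), ]
  r1 <- rank_sites(sites)
  r2 <- rank_sites(shuffled)
  expect_equal(r1$cs_mean, sort(sites$cs_mean, decreasing = TRUE))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # cs_mean tie broken by cs_min, then coordinates
  expect_lt(which(r1$start == 80), which(r1$start == 90))
  # equal scores fall back to coordinate order
  flat <- dplyr::mutate(sites, cs_mean = 0.5, cs_min = 0.1)
  expect_equal(rank_sites(flat)$start, flat$start)
  expect_equal(nrow(rank_sites(sites, top_k = 3)), 3L)
})

test_that("percentile_of places values within the positive score distribution", {
  track <- seq(0.1, 1.0, by = 0.1)
  expect_equal(percentile_of(1.0, track), 100)
  expect_equal(percentile_of(0.05, track), 0)
  expect_equal(percentile_of(0.55, track), 50)
  # zeros are excluded from the reference distribution
  expect_equal(percentile_of(0.55, c(rep(0, 50), track)), 50)
  expect_error(percentile_of(0.5, rep(0, 10)), "positive")
})
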