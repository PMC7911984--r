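# Synthetic fixture generator: determinism, composition and ground truth.

small_cfg <- function(seed = 1, L = 20000L) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = L),
             conserved_blocks = tibble::tibble(
               chrom = "chr1", start = c(1000L, 3000L), end = c(1400L, 3300L)))
}

test_that("the fixture bundle is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 99, L = 5000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the reference
  cfg2 <- small_cfg(seed = 100, L = 5000L)
  expect_false(identical(as.character(simulate_reference(cfg)$sequences),
                         as.character(simulate_reference(cfg2)$sequences)))
})

test_that("the reference is uniform i.i.d. A/C/G/T of the configured length", {
  cfg <- small_cfg(seed = 4, L = 40000L)
  ref <- simulate_reference(cfg)
  expect_equal(genome_index(ref)$length, 40000L)
  ch <- table(strsplit(get_sequence(ref, "chr1"), "")[[1]])
  # each base frequency within 3 binomial s.e. of 0.25
  se3 <- 3 * sqrt(0.25 * 0.75 / 40000)
  expect_true(all(abs(ch / 40000 - 0.25) < se3))
})

test_that("species divergence follows the JC69 substitution probability", {
  cfg <- small_cfg(seed = 12, L = 30000L)
  ref <- simulate_reference(cfg)
  sim <- simulate_species(ref, cfg)
  block_idx <- unlist(mapply(function(s, e) (s + 1):e,
                             cfg$conserved_blocks$start, cfg$conserved_blocks$end))
  for (i in seq_len(nrow(sim$distances))) {
    t <- sim$distances$distance[i]
    p_exp <- 0.75 * (1 - exp(-4 * t / 3))
    bl <- sim$blocks[sim$blocks$species == sim$distances$species[i], ]
    rc <- strsplit(bl$ref_aligned, "")[[1]]
    qc <- strsplit(bl$query_aligned, "")[[1]]
    # conserved blocks are copied verbatim in every species
    expect_true(all(rc[block_idx] == qc[block_idx]))
    # realised mismatch fraction outside blocks within 3 s.e. of p(t)
    out_idx <- setdiff(seq_along(rc), block_idx)
    p_obs <- mean(rc[out_idx] != qc[out_idx])
    se3 <- 3 * sqrt(p_exp * (1 - p_exp) / length(out_idx))
    expect_lt(abs(p_obs - p_exp), se3 + 1e-9)
  }
  # zero branch length means identical sequence
  cfg0 <- sim_config(seed = 5, chrom_lengths = c(chr1 = 2000L),
                     tree = "(ref:0,spA:0);",
                     conserved_blocks = tibble::tibble(
                       chrom = character(), start = integer(), end = integer()))
  sim0 <- simulate_species(simulate_reference(cfg0), cfg0)
  expect_identical(sim0$blocks$ref_aligned, sim0$blocks$query_aligned)
})

test_that("population variants follow the SNP rate and avoid conserved blocks", {
  cfg <- sim_config(seed = 21, chrom_lengths = c(chr1 = 100000L),
                    snp_rate = 0.01)
  ref <- simulate_reference(cfg)
  v <- simulate_population_variants(ref, cfg)
  block_bp <- sum(cfg$conserved_blocks$end - cfg$conserved_blocks$start)
  n_exp <- 0.01 * (100000 - block_bp)
  expect_lt(abs(nrow(v) - n_exp), 3 * sqrt(n_exp) + 1e-9)
  in_block <- mapply(function(p) any(p >= cfg$conserved_blocks$start &
                                     p < cfg$conserved_blocks$end), v$pos)
  expect_false(any(in_block))
  # REF alleles match the reference sequence
  ch <- strsplit(get_sequence(ref, "chr1"), "")[[1]]
  expect_identical(v$ref, ch[v$pos + 1])
  expect_false(any(v$ref == v$alt))
  # zero rate: no variants
  cfg0 <- sim_config(seed = 21, chrom_lengths = c(chr1 = 5000L), snp_rate = 0,
                     conserved_blocks = tibble::tibble(
                       chrom = character(), start = integer(), end = integer()))
  expect_equal(nrow(simulate_population_variants(simulate_reference(cfg0), cfg0)), 0L)
})

test_that("selection track and mask respect the conserved blocks", {
  cfg <- small_cfg(seed = 31)
  sel <- simulate_selection_track(cfg)$chr1
  block_idx <- unlist(mapply(function(s, e) (s + 1):e,
                             cfg$conserved_blocks$start, cfg$conserved_blocks$end))
  expect_true(all(sel[block_idx] == cfg$sel_conserved))
  expect_true(all(sel[-block_idx] == cfg$sel_background))

  mask <- simulate_mask(cfg)
  frac <- sum(mask$end - mask$start) / 20000
  expect_gt(frac, 0.8 * cfg$mask_fraction)
  expect_lt(frac, 2 * cfg$mask_fraction)
  # mask intervals never intersect blocks
  for (k in seq_len(nrow(mask))) {
    expect_equal(conscore:::interval_overlap_bp(
      mask$start[k], mask$end[k],
      cfg$conserved_blocks$start, cfg$conserved_blocks$end), 0L)
  }
  # intervals are sorted and non-overlapping
  expect_true(all(diff(mask$start) > 0))
  expect_true(all(mask$start[-1] >= mask$end[-nrow(mask)]))
})

test_that("fixture files parse back with the package's own readers", {
  cfg <- small_cfg(seed = 55, L = 8000L)
  dir <- withr::local_tempdir()
  fx <- simulate_fixture(cfg, dir)
  g <- read_fasta(fx$paths$reference)
  expect_equal(genome_index(g)$length, 8000L)
  tr <- read_newick(fx$paths$tree)
  expect_setequal(tr$tip.label, c("ref", names(fx$truth$branch_lengths)))
  blocks <- read_axt(fx$paths$axt[["spA"]], "spA")
  expect_equal(blocks$ref_end, 8000L)
  pos <- read_variant_positions(fx$paths$vcf, g)
  expect_true(all(diff(pos$pos) > 0))
  sel <- read_score_track(fx$paths$phylop, g)
  expect_equal(sort(unique(sel$chr1)), c(cfg$sel_background, cfg$sel_conserved))
  mask <- read_bed(fx$paths$mask, g)
  expect_true(nrow(mask) > 0)
})
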