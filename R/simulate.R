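# Synthetic fixtures with known ground truth: a random reference chromosome,
# query species diverged along a fixed tree under JC69, embedded
# zero-divergence ultraconserved blocks, Bernoulli population SNPs outside
# the blocks, a block-aware selection track and an accessibility mask. The
# whole bundle is deterministic under the configured seed.

#' Configuration for the synthetic fixture generator
#'
#' Defaults model a desk-scale version of a mosquito-style study system: one
#' 100-kb chromosome arm, six query species spanning reference distances from
#' 0.05 to 0.48 substitutions/site, three embedded ultraconserved blocks, a
#' 1% per-base population SNP rate outside the blocks and a 5% accessibility
#' mask.
#'
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it, so a fixture is fully reproducible (byte-identical files).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param tree Newick string with branch lengths; must contain `ref_name`.
#' @param ref_name Reference leaf name.
#' @param conserved_blocks Tibble (`chrom`, `start`, `end`, 0-based
#'   half-open) of ultraconserved blocks: zero divergence in every species
#'   and zero SNP rate. Default (`NULL`): three blocks at 20/50/80% of the
#'   first chromosome covering roughly 1.5% of it.
#' @param snp_rate Per-base Bernoulli SNP probability outside blocks.
#' @param mask_fraction Approximate fraction of each chromosome covered by
#'   the accessibility mask.
#' @param sel_conserved,sel_background Selection-score (phyloP CONACC style)
#'   values written inside and outside the blocks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 100000L),
                       tree = paste0(
                         "((ref:0.02,spA:0.03):0.03,(spB:0.05,(spC:0.10,",
                         "(spD:0.15,(spE:0.20,spF:0.23):0.05):0.05):0.05):0.05);"),
                       ref_name = "ref",
                       conserved_blocks = NULL,
                       snp_rate = 0.01,
                       mask_fraction = 0.05,
                       sel_conserved = 1.5,
                       sel_background = 0) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer")
  if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named")
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  if (snp_rate < 0 || snp_rate > 1) abort("`snp_rate` must lie in [0, 1]")
  if (mask_fraction < 0 || mask_fraction >= 1) abort("`mask_fraction` must lie in [0, 1)")
  if (is.null(conserved_blocks)) {
    # three ultraconserved blocks at 20/50/80% of the first chromosome,
    # 0.4-0.6% of its length each (600/500/400 bp on the default 100-kb arm)
    L <- chrom_lengths[[1]]
    conserved_blocks <- tibble(
      chrom = names(chrom_lengths)[1],
      start = as.integer(floor(L * c(0.20, 0.50, 0.80))),
      end = as.integer(floor(L * c(0.20, 0.50, 0.80)) +
                         pmax(50L, as.integer(L * c(0.006, 0.005, 0.004)))))
  }
  blocks <- as_tibble(conserved_blocks)
  for (chrom in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == chrom, ]
    L <- chrom_lengths[[chrom]]
    if (is.null(L)) abort(sprintf("block chromosome '%s' not in chrom_lengths", chrom))
    if (any(b$start < 0 | b$end > L | b$start >= b$end)) {
      abort("conserved blocks must lie within their chromosome")
    }
    o <- order(b$start)
    if (any(b$start[o][-1] < b$end[o][-nrow(b)])) {
      abort("conserved blocks must be disjoint")
    }
  }
  structure(
    list(seed = seed, chrom_lengths = chrom_lengths, tree = tree,
         ref_name = ref_name, conserved_blocks = blocks, snp_rate = snp_rate,
         mask_fraction = mask_fraction, sel_conserved = sel_conserved,
         sel_background = sel_background),
    class = "sim_config"
  )
}

# Run fn with a seed derived from the config seed and a small stage offset,
# restoring the caller's RNG state afterwards.
with_stage_seed <- function(config, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed + offset)
  fn()
}

block_positions <- function(config, chrom) {
  b <- config$conserved_blocks[config$conserved_blocks$chrom == chrom, ]
  if (nrow(b) == 0) return(integer())
  unlist(map2(b$start, b$end, function(s, e) s:(e - 1L))) + 1L   # 1-based index
}

#' Simulate the reference genome
#'
#' I.i.d. uniform A/C/G/T sequence for each configured chromosome.
#'
#' @param config A [sim_config()].
#' @return A `ref_genome` object.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config, 0L, function() {
    seqs <- vapply(names(config$chrom_lengths), function(chrom) {
      paste(sample(DNA_BASES, config$chrom_lengths[[chrom]], replace = TRUE),
            collapse = "")
    }, character(1))
    ref_genome(seqs)
  })
}

#' Simulate diverged query species as pairwise alignments
#'
#' Each query species mutates every non-block site of the reference
#' independently with the JC69 substitution probability
#' `p(t) = 3/4 (1 - exp(-4 t / 3))` at its patristic distance `t` from the
#' reference leaf; a substituted site takes one of the three other bases
#' uniformly. Ultraconserved blocks are copied verbatim. Each species is
#' emitted as a single collinear alignment block per chromosome.
#'
#' @param reference A `ref_genome` from [simulate_reference()].
#' @param config A [sim_config()].
#' @return A list with `blocks` (alignment tibble as from [read_axt()]),
#'   `tree` (the `phylo` object) and `distances` (tibble from
#'   [tree_distances()]).
#' @export
simulate_species <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- read_newick(text = config$tree)
  dists <- tree_distances(tree, config$ref_name)
  dists <- dists[order(dists$species), ]
  blocks <- with_stage_seed(config, 1L, function() {
    map_dfr(seq_len(nrow(dists)), function(i) {
      sp <- dists$species[i]
      t <- dists$distance[i]
      p_sub <- 0.75 * (1 - exp(-4 * t / 3))
      map_dfr(names(config$chrom_lengths), function(chrom) {
        L <- config$chrom_lengths[[chrom]]
        ch <- seq_chars(get_sequence(reference, chrom))
        hit <- which(stats::runif(L) < p_sub)
        hit <- setdiff(hit, block_positions(config, chrom))
        if (length(hit) > 0) {
          # substitute with one of the 3 other bases, uniformly
          shift <- sample.int(3L, length(hit), replace = TRUE)
          ch[hit] <- DNA_BASES[(match(ch[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
        }
        tibble(
          species = sp, ref_chrom = chrom,
          ref_start = 0L, ref_end = L,
          query_chrom = chrom, query_start = 0L, query_end = L,
          strand = "+", score = 0,
          ref_aligned = get_sequence(reference, chrom),
          query_aligned = paste(ch, collapse = "")
        )
      })
    })
  })
  list(blocks = blocks, tree = tree, distances = dists)
}

#' Simulate population variant positions
#'
#' Bernoulli(`snp_rate`) per base outside the ultraconserved blocks, rate 0
#' inside them.
#'
#' @param reference A `ref_genome`.
#' @param config A [sim_config()].
#' @return Tibble `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
simulate_population_variants <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config, 2L, function() {
    map_dfr(names(config$chrom_lengths), function(chrom) {
      L <- config$chrom_lengths[[chrom]]
      hit <- which(stats::runif(L) < config$snp_rate)
      hit <- setdiff(hit, block_positions(config, chrom))
      if (length(hit) == 0) {
        return(tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
      }
      ch <- seq_chars(get_sequence(reference, chrom))
      shift <- sample.int(3L, length(hit), replace = TRUE)
      alt <- DNA_BASES[(match(ch[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
      tibble(chrom = chrom, pos = hit - 1L, ref = ch[hit], alt = alt)
    })
  })
}

#' Simulate a per-base selection-score track
#'
#' Positive scores (`sel_conserved`) inside the ultraconserved blocks and a
#' background value (`sel_background`, default 0 = neutral) elsewhere,
#' mimicking a CONACC-style conservation/acceleration track.
#'
#' @param config A [sim_config()].
#' @return Named list of numeric vectors, one per chromosome.
#' @export
simulate_selection_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(setNames(names(config$chrom_lengths), names(config$chrom_lengths)),
         function(chrom) {
    v <- rep(config$sel_background, config$chrom_lengths[[chrom]])
    v[block_positions(config, chrom)] <- config$sel_conserved
    v
  })
}

#' Simulate an accessibility mask
#'
#' Draws random intervals (100-500 bp) until roughly `mask_fraction` of each
#' chromosome is covered, never intersecting the ultraconserved blocks, then
#' merges overlaps.
#'
#' @param config A [sim_config()].
#' @param avoid_blocks Set `FALSE` to allow mask intervals inside blocks.
#' @return Mask tibble `chrom`, `start`, `end`, sorted and non-overlapping.
#' @export
simulate_mask <- function(config, avoid_blocks = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config, 3L, function() {
    map_dfr(names(config$chrom_lengths), function(chrom) {
      L <- config$chrom_lengths[[chrom]]
      target <- config$mask_fraction * L
      if (target <= 0) {
        return(tibble(chrom = character(), start = integer(), end = integer()))
      }
      b <- config$conserved_blocks[config$conserved_blocks$chrom == chrom, ]
      starts <- integer(); ends <- integer()
      covered <- 0
      attempts <- 0L
      while (covered < target && attempts < 10000L) {
        attempts <- attempts + 1L
        len <- sample(100:500, 1L)
        s <- sample.int(L - len, 1L) - 1L
        e <- s + len
        if (avoid_blocks && nrow(b) > 0 &&
            interval_overlap_bp(s, e, b$start, b$end) > 0) next
        starts <- c(starts, s); ends <- c(ends, e)
        covered <- covered + len
      }
      merged <- merge_intervals(starts, ends)
      tibble(chrom = chrom, start = merged$start, end = merged$end)
    })
  })
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Emits `ref.fa`, one `<species>.axt` per query species, `tree.nwk`,
#' `variants.vcf`, `phylop.bedgraph`, `mask.bed` and `truth.json` (block
#' coordinates, branch lengths and the seed). Byte-identical for a given
#' configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the ground truth and all file paths.
#' @export
simulate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- simulate_reference(config)
  sim <- simulate_species(reference, config)
  variants <- simulate_population_variants(reference, config)
  sel <- simulate_selection_track(config)
  mask <- simulate_mask(config)

  paths <- list(
    reference = file.path(dir, "ref.fa"),
    tree = file.path(dir, "tree.nwk"),
    vcf = file.path(dir, "variants.vcf"),
    phylop = file.path(dir, "phylop.bedgraph"),
    mask = file.path(dir, "mask.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(reference, paths$reference)
  ape::write.tree(sim$tree, paths$tree)
  write_minimal_vcf(variants, genome_index(reference), paths$vcf)
  write_bedgraph(sel, paths$phylop)
  write_bed(mask, paths$mask)
  axt_paths <- setNames(
    file.path(dir, paste0(sim$distances$species, ".axt")),
    sim$distances$species
  )
  for (sp in sim$distances$species) {
    write_axt(sim$blocks[sim$blocks$species == sp, ], axt_paths[[sp]])
  }
  paths$axt <- axt_paths
  truth <- list(
    seed = config$seed,
    ref_name = config$ref_name,
    chrom_lengths = as.list(config$chrom_lengths),
    branch_lengths = setNames(as.list(sim$distances$distance),
                              sim$distances$species),
    conserved_blocks = config$conserved_blocks,
    snp_rate = config$snp_rate,
    mask_fraction = config$mask_fraction
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, paths = paths, config = config))
}

# Minimal single-sample-free VCF writer for the synthetic variants.
write_minimal_vcf <- function(variants, index, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", index$chrom, index$length), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, variants$pos + 1L,
                       variants$ref, variants$alt), con)
  }
  invisible(path)
}
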