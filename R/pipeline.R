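# End-to-end orchestration: read inputs, scan, build tracks, score and rank
# targets, and write a reproducible output bundle with a manifest.

#' Pipeline configuration
#'
#' @param reference Path to the reference FASTA.
#' @param axt Named character vector: species -> AXT path.
#' @param tree Optional Newick path; when absent, JC69 distances are
#'   estimated from the alignments.
#' @param vcf Optional VCF of population variants (no VCF: SNP density 0).
#' @param phylop Optional wiggle/bedGraph selection-score track (absent:
#'   neutral 0).
#' @param mask Optional BED accessibility mask.
#' @param scan A [scan_config()].
#' @param snp_window SNP-density window (bp, default 20).
#' @param scaling `"arm"` (default) or `"genome"` MinMax domain.
#' @param groups Named list of species subsets for windowed group-identity
#'   tracks.
#' @param group_window Window for group-identity tracks (bp, default 1e6).
#' @param region Optional target region `list(chrom=, start=, end=)`
#'   (0-based half-open); default: all chromosomes end to end.
#' @param top_k Ranked sites kept in the output table (default all).
#' @param snps_only Passed to [read_variant_positions()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, axt, tree = NULL, vcf = NULL,
                            phylop = NULL, mask = NULL,
                            scan = scan_config(), snp_window = 20L,
                            scaling = c("arm", "genome"), groups = list(),
                            group_window = 1e6, region = NULL, top_k = Inf,
                            snps_only = TRUE, out_dir = "conscore_out",
                            quiet = FALSE) {
  if (is.null(names(axt)) || any(!nzchar(names(axt)))) {
    abort("`axt` must be a named vector: species -> path")
  }
  scaling <- match.arg(scaling)
  stopifnot(inherits(scan, "scan_config"))
  if (length(groups) > 0) {
    unknown <- setdiff(unlist(groups), names(axt))
    if (length(unknown) > 0) {
      abort(sprintf("group species not among configured species: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(reference = reference, axt = axt, tree = tree, vcf = vcf,
         phylop = phylop, mask = mask, scan = scan,
         snp_window = as.integer(snp_window), scaling = scaling,
         groups = groups, group_window = group_window, region = region,
         top_k = top_k, snps_only = snps_only, out_dir = out_dir,
         quiet = quiet),
    class = "pipeline_config"
  )
}

pipe_msg <- function(config, stage, fmt, ...) {
  if (!isTRUE(config$quiet)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the conservation-scoring pipeline end to end
#'
#' Stages: read inputs; sliding-window identity scan per species; per-base
#' identity projection; phylogenetic distances (tree, or JC69 fallback from
#' the alignments); SNP-density, selection and conservation tracks; MinMax
#' scaling; windowed group-identity tracks; Cas9 site enumeration, scoring
#' and ranking. All declared outputs are written under `out_dir` along with
#' a JSON manifest (package version, configuration hash, per-stage counts).
#' A failing stage aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`elements`,
#'   `distances`, `tracks`, `group_identity`, `targets`, `manifest`) and
#'   output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  genome <- stage("read_reference", read_fasta(config$reference))
  idx <- genome_index(genome)
  pipe_msg(config, "read_reference", "%d chromosome(s), %d bp",
           nrow(idx), sum(idx$length))

  blocks <- stage("read_alignments", map_dfr(names(config$axt), function(sp) {
    read_axt(config$axt[[sp]], species = sp)
  }))
  species <- sort(names(config$axt))
  pipe_msg(config, "read_alignments", "%d block(s) from %d species",
           nrow(blocks), length(species))

  elements <- stage("scan", scan_conserved_elements(blocks, config$scan))
  pipe_msg(config, "scan", "%d conserved element(s)", nrow(elements))

  distances <- stage("distances", {
    if (!is.null(config$tree)) {
      tree <- read_newick(config$tree)
      missing <- setdiff(species, tree$tip.label)
      if (length(missing) > 0) {
        abort(sprintf("species not in tree: %s", paste(missing, collapse = ", ")))
      }
      ref_leaf <- setdiff(tree$tip.label, species)
      if (length(ref_leaf) != 1) {
        abort(sprintf("cannot identify the reference leaf (candidates: %s)",
                      paste(ref_leaf, collapse = ", ")))
      }
      tree_distances(tree, ref_leaf, species)
    } else {
      jc69_distance(blocks)[, c("species", "distance")]
    }
  })
  pipe_msg(config, "distances", "method: %s",
           if (is.null(config$tree)) "JC69 fallback" else "tree (patristic)")

  variants <- stage("variants", {
    if (is.null(config$vcf)) NULL
    else read_variant_positions(config$vcf, genome, snps_only = config$snps_only)
  })
  phylop <- stage("selection_track", {
    if (is.null(config$phylop)) NULL
    else read_score_track(config$phylop, genome, fill = 0)
  })
  mask <- stage("mask", {
    if (is.null(config$mask)) NULL else read_bed(config$mask, genome)
  })

  tracks <- stage("conservation", {
    lapply(setNames(idx$chrom, idx$chrom), function(chrom) {
      L <- idx$length[idx$chrom == chrom]
      I <- project_identity(elements, genome, chrom, species = species)
      In <- normalize_identity(I, distances)
      sigma <- if (is.null(variants)) rep(0, L) else {
        snp_density(variants$pos[variants$chrom == chrom], L,
                    window = config$snp_window)
      }
      p <- if (is.null(phylop)) rep(0, L) else phylop[[chrom]]
      tr <- conservation_score(In, sigma, p)
      tr$sigma <- sigma
      tr$identity <- I
      tr
    })
  })
  tracks <- stage("scaling", minmax_scale(tracks, domain = config$scaling))
  pipe_msg(config, "conservation", "%d arm track(s), scaling: %s",
           length(tracks), config$scaling)

  group_identity <- stage("group_identity", {
    if (length(config$groups) == 0) NULL
    else map_dfr(names(config$groups), function(g) {
      map_dfr(idx$chrom, function(chrom) {
        group_mean_identity(tracks[[chrom]]$identity, config$groups[[g]],
                            window = config$group_window) |>
          mutate(group = g, .before = 1)
      })
    })
  })

  targets <- stage("targets", {
    regions <- if (!is.null(config$region)) {
      list(config$region)
    } else {
      lapply(seq_len(nrow(idx)), function(i) {
        list(chrom = idx$chrom[i], start = 0L, end = idx$length[i])
      })
    }
    map_dfr(regions, function(r) {
      sites <- enumerate_cas9_sites(genome, r$chrom, r$start, r$end)
      score_sites(sites, tracks[[r$chrom]], mask)
    }) |> rank_sites(top_k = config$top_k)
  })
  pipe_msg(config, "targets", "%d ranked site(s)", nrow(targets))

  paths <- stage("write_outputs", {
    p <- list()
    p$elements <- file.path(config$out_dir, "elements.bed")
    write_elements_bed(elements, p$elements)
    p$distances <- file.path(config$out_dir, "distances.tsv")
    readr::write_tsv(distances, p$distances)
    p$sigma <- file.path(config$out_dir, "snp_density.bedgraph")
    write_bedgraph(lapply(tracks, `[[`, "sigma"), p$sigma)
    p$cs_raw <- file.path(config$out_dir, "cs_raw.bedgraph")
    write_bedgraph(lapply(tracks, `[[`, "cs_raw"), p$cs_raw)
    p$cs_scaled <- file.path(config$out_dir, "cs_scaled.bedgraph")
    write_bedgraph(lapply(tracks, `[[`, "cs_scaled"), p$cs_scaled)
    if (!is.null(group_identity)) {
      p$group_identity <- file.path(config$out_dir, "group_identity.tsv")
      readr::write_tsv(group_identity, p$group_identity)
    }
    p$targets <- file.path(config$out_dir, "targets.tsv")
    write_target_table(targets, p$targets)
    p
  })

  manifest <- list(
    package = "conscore",
    version = as.character(packageVersion("conscore")),
    config_hash = hash(config[setdiff(names(config), c("out_dir", "quiet"))]),
    species = species,
    chromosomes = setNames(as.list(idx$length), idx$chrom),
    counts = list(
      alignment_blocks = nrow(blocks),
      conserved_elements = nrow(elements),
      variant_positions = if (is.null(variants)) 0L else nrow(variants),
      target_sites = nrow(targets)
    ),
    scaling = config$scaling
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    elements = elements, distances = distances, tracks = tracks,
    group_identity = group_identity, targets = targets,
    manifest = manifest, paths = paths
  ))
}
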