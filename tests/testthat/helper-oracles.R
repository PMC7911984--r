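# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately use plain loops and direct per-window recounting so they share
# no code path with the package implementation.

make_block <- function(ref_aligned, query_aligned, species = "sp1",
                       ref_chrom = "chr1", ref_start = 0L) {
  ungapped <- nchar(gsub("-", "", ref_aligned, fixed = TRUE))
  tibble::tibble(
    species = species, ref_chrom = ref_chrom,
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_start + ungapped),
    query_chrom = ref_chrom, query_start = as.integer(ref_start),
    query_end = as.integer(ref_start + ungapped),
    strand = "+", score = 0,
    ref_aligned = toupper(ref_aligned), query_aligned = toupper(query_aligned)
  )
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Reference sequence mutated at given 1-based positions (to a different base).
mutate_seq <- function(seq, pos1) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos1) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

# Per-reference-position match indicator, by explicit column walk.
oracle_match_vector <- function(ref_aligned, query_aligned) {
  rc <- strsplit(ref_aligned, "")[[1]]
  qc <- strsplit(query_aligned, "")[[1]]
  m <- logical(0)
  for (k in seq_along(rc)) {
    if (rc[k] == "-") next
    m <- c(m, rc[k] %in% c("A", "C", "G", "T") &&
             qc[k] %in% c("A", "C", "G", "T") && rc[k] == qc[k])
  }
  m
}

# Exhaustive per-window match recount for one block.
oracle_window_counts <- function(ref_aligned, query_aligned, w) {
  m <- oracle_match_vector(ref_aligned, query_aligned)
  L <- length(m)
  if (w > L) return(integer(0))
  vapply(1:(L - w + 1), function(i) sum(m[i:(i + w - 1)]), integer(1))
}

# Exhaustive scan for one block and one (window, threshold) pair: qualifying
# windows merged into maximal runs by a linear sweep; identity = max inside.
oracle_scan_one <- function(block, w, th) {
  counts <- oracle_window_counts(block$ref_aligned, block$query_aligned, w)
  qual <- which(counts / w >= th - 1e-9)
  if (length(qual) == 0) {
    return(data.frame(start = integer(), end = integer(), identity = numeric()))
  }
  starts0 <- block$ref_start + qual - 1L   # 0-based genomic window starts
  runs <- list()
  cur_s <- starts0[1]; cur_e <- starts0[1] + w; cur_id <- counts[qual[1]] / w
  for (k in seq_along(starts0)[-1]) {
    s <- starts0[k]
    if (s < cur_e) {   # overlaps current run
      cur_e <- s + w
      cur_id <- max(cur_id, counts[qual[k]] / w)
    } else {
      runs[[length(runs) + 1]] <- c(cur_s, cur_e, cur_id)
      cur_s <- s; cur_e <- s + w; cur_id <- counts[qual[k]] / w
    }
  }
  runs[[length(runs) + 1]] <- c(cur_s, cur_e, cur_id)
  out <- do.call(rbind, runs)
  data.frame(start = out[, 1], end = out[, 2], identity = out[, 3])
}

# Brute-force two-strand Cas9 site scan by direct substring inspection.
oracle_cas9 <- function(seq, chrom = "seq") {
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (i in 0:(L - 23)) {
    site <- substr(seq, i + 1, i + 23)
    if (grepl("[^ACGT]", site)) next
    if (substr(site, 22, 23) == "GG") {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = i, end = i + 23, strand = "+",
        stringsAsFactors = FALSE)
    }
    if (substr(site, 1, 2) == "CC") {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = i, end = i + 23, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}

# Scalar per-position re-evaluation of the conservation model.
oracle_cs_scalar <- function(I, d, sigma, p) {
  m <- nrow(I); n <- ncol(I)
  out <- numeric(n)
  for (j in 1:n) {
    s <- 0
    for (i in 1:m) s <- s + I[i, j] * d[i]
    out[j] <- (s / m) * (1 - sigma[j]) / (1 + sigma[j]) * 2^p[j]
  }
  out
}

# Brute-force windowed SNP-density recount.
oracle_snp_density <- function(positions, L, w = 20) {
  left <- w %/% 2; right <- w - 1 - left
  out <- numeric(L)
  for (n in 0:(L - 1)) {
    lo <- max(0, n - left); hi <- min(L - 1, n + right)
    out[n + 1] <- sum(positions >= lo & positions <= hi) / (hi - lo + 1)
  }
  out
}
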