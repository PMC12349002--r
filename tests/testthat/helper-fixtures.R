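# Shared fixtures: tiny constructors and independent oracles.

# quick gene table: one chromosome per element of `sizes`, genes of 1 kb
# every 5 kb
toy_genes <- function(sizes, species = "toy", prefix = "g") {
  rows <- lapply(seq_along(sizes), function(i) {
    n <- sizes[[i]]
    chrom <- if (!is.null(names(sizes))) names(sizes)[i] else
      paste0("chr", i)
    tibble::tibble(
      gene_id = sprintf("%s_%s_%03d", prefix, chrom, seq_len(n)),
      chromosome = chrom,
      start = (seq_len(n) - 1L) * 5000L,
      end = (seq_len(n) - 1L) * 5000L + 1000L,
      strand = "+"
    )
  })
  gene_table(dplyr::bind_rows(rows), species = species)
}

# anchors tibble in the internal layout
toy_anchors <- function(rank_a, rank_b, chrom_a = "c1", chrom_b = "cA") {
  structure(
    tibble::tibble(
      gene_a = paste0("a", seq_along(rank_a)),
      gene_b = paste0("b", seq_along(rank_b)),
      chrom_a = chrom_a, chrom_b = chrom_b,
      rank_a = as.integer(rank_a), rank_b = as.integer(rank_b)
    ),
    class = c("anchors", class(tibble::tibble())),
    species_a = "a", species_b = "b"
  )
}

# independent exhaustive oracle for the best gap-limited monotone chain:
# depth-first enumeration over all legal chains, both orientations
chain_oracle_best <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  if (n == 0) return(0L)
  best <- 0L
  for (sgn in c(1L, -1L)) {
    rb <- sgn * rank_b
    extend <- function(last, len) {
      best <<- max(best, len)
      for (nxt in seq_len(n)) {
        if (rank_a[nxt] > rank_a[last] && rb[nxt] > rb[last] &&
            rank_a[nxt] - rank_a[last] <= max_gap &&
            rb[nxt] - rb[last] <= max_gap) {
          extend(nxt, len + 1L)
        }
      }
    }
    for (s in seq_len(n)) extend(s, 1L)
  }
  best
}

# synthetic synteny_blocks object from explicit spans (anchors only at the
# span ends; enough for span-based statistics)
blocks_from_spans <- function(spans, species_a = "a", species_b = "b") {
  rows <- purrr::pmap(spans, function(chrom_a, lo, hi, ...) {
    extra <- list(...)
    chrom_b <- extra$chrom_b %||% "t1"
    tibble::tibble(
      chrom_a = chrom_a, chrom_b = chrom_b, orientation = "+",
      n_pairs = hi - lo + 1L,
      anchors = list(tibble::tibble(
        gene_a = c("x", "y"), gene_b = c("u", "v"),
        chrom_a = chrom_a, chrom_b = chrom_b,
        rank_a = as.integer(c(lo, hi)), rank_b = c(0L, hi - lo)
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$block_id <- sprintf("B%04d", seq_len(nrow(out)))
  out <- out[, c("block_id", "chrom_a", "chrom_b", "orientation",
                 "n_pairs", "anchors")]
  structure(out, class = c("synteny_blocks", class(tibble::tibble())),
            species_a = species_a, species_b = species_b)
}

`%||%` <- rlang::`%||%`

# small simulated dataset shared by several tests
quiet_sim <- function(...) suppressWarnings(simulate_evolution(...))
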