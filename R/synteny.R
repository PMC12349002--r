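#' Place homologous gene pairs in gene-rank space
#'
#' Turns filtered homology pairs into dot-plot anchors: one row per pair
#' whose two genes both sit on chromosomes of their respective gene tables.
#' Pairs referencing genes absent from either table (e.g. scaffold-excluded
#' genes) are skipped; the skip count is stored in `attr(x, "n_skipped")`.
#'
#' @param genes_a,genes_b [gene_table()]s for the query and subject genome.
#'   Pass the same table twice for a self-comparison (the trivial i = j
#'   diagonal is then present and is removed later by block filtering).
#' @param pairs Homology tibble (`query_id`, `subject_id`, ...) with query
#'   ids drawn from `genes_a` and subject ids from `genes_b`.
#' @return An `anchors` tibble: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`.
#' @export
build_anchors <- function(genes_a, genes_b, pairs) {
  a <- select(genes_a, gene_a = "gene_id", chrom_a = "chromosome",
              rank_a = "rank")
  b <- select(as_tibble(genes_b), gene_b = "gene_id", chrom_b = "chromosome",
              rank_b = "rank")
  n_in <- nrow(distinct(pairs, .data$query_id, .data$subject_id))
  out <- pairs |>
    distinct(.data$query_id, .data$subject_id) |>
    inner_join(a, by = c(query_id = "gene_a"), keep = FALSE) |>
    rename(gene_a = "query_id") |>
    inner_join(b, by = c(subject_id = "gene_b"), keep = FALSE) |>
    rename(gene_b = "subject_id") |>
    select("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b") |>
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)
  out <- new_kf_tbl(out, "anchors")
  attr(out, "species_a") <- attr(genes_a, "species", exact = TRUE) %||% "a"
  attr(out, "species_b") <- attr(genes_b, "species", exact = TRUE) %||% "b"
  attr(out, "n_skipped") <- n_in - nrow(out)
  out
}

# Best monotone chain among anchors (ra, rb already oriented so both must
# strictly increase), gap-limited; score = anchor count. Tie-breaks: among
# equal scores prefer the chain with smaller ra span, then smaller starting
# ra. Implemented in C++ (src/chain.cpp) since this dominates run time.
best_chain_dp <- function(ra, rb, max_gap) {
  .best_chain_cpp(as.integer(ra), as.integer(rb), as.integer(max_gap))
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, blocks are extracted by iterated best-chain
#' dynamic programming: the score of a chain is its anchor count, a step is
#' legal iff both rank coordinates move strictly monotonically (increasing
#' for `+` blocks, rank_b decreasing for `-` blocks) and neither rank jumps
#' by more than `max_gap` genes. The highest-scoring chain (over both
#' orientations) is removed as a block and the search repeats until the best
#' remaining chain falls below `min_pairs`. Each anchor therefore belongs to
#' at most one block. Equal-score ties go to the chain with the smaller
#' rank_a span, then the smaller starting rank_a, then orientation `+`.
#'
#' @param anchors An anchors tibble from [build_anchors()].
#' @param max_gap Maximum rank gap (genes) between consecutive anchors
#'   (default 25).
#' @param min_pairs Minimum anchors per block (default 5).
#' @param self_mode Set for self-comparisons; recorded and used by
#'   [filter_blocks()] to drop identity-diagonal blocks.
#' @return A `synteny_blocks` tibble: one row per block with `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation`, `n_pairs` and a list-column
#'   `anchors` of per-block anchor tibbles ordered along the chain.
#' @export
chain_anchors <- function(anchors, max_gap = 25L, min_pairs = 5L,
                          self_mode = FALSE) {
  stopifnot(is_count(max_gap, 1L), is_count(min_pairs, 2L))
  groups <- anchors |>
    group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::group_split()
  rows <- list()
  for (g in groups) {
    remaining <- g
    repeat {
      if (nrow(remaining) == 0) break
      plus <- best_chain_dp(remaining$rank_a, remaining$rank_b, max_gap)
      minus <- best_chain_dp(remaining$rank_a, -remaining$rank_b, max_gap)
      pick <- if (minus$score > plus$score) {
        list(o = "-", c = minus)
      } else if (plus$score > minus$score) {
        list(o = "+", c = plus)
      } else if (plus$score == 0L) {
        NULL
      } else if (minus$span < plus$span ||
                 (minus$span == plus$span && minus$start < plus$start)) {
        list(o = "-", c = minus)
      } else {
        list(o = "+", c = plus)
      }
      if (is.null(pick) || pick$c$score < min_pairs) break
      chain <- remaining[pick$c$idx, , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble(
        chrom_a = chain$chrom_a[1], chrom_b = chain$chrom_b[1],
        orientation = pick$o, n_pairs = nrow(chain),
        anchors = list(as_tibble(chain))
      )
      remaining <- remaining[-pick$c$idx, , drop = FALSE]
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(chrom_a = character(), chrom_b = character(),
           orientation = character(), n_pairs = integer(),
           anchors = list())
  out <- out |>
    arrange(.data$chrom_a, .data$chrom_b, dplyr::desc(.data$n_pairs)) |>
    mutate(block_id = sprintf("B%04d", row_number()), .before = 1)
  out <- new_kf_tbl(out, "synteny_blocks")
  attr(out, "species_a") <- attr(anchors, "species_a", exact = TRUE) %||% "a"
  attr(out, "species_b") <- attr(anchors, "species_b", exact = TRUE) %||% "b"
  attr(out, "params") <- list(max_gap = max_gap, min_pairs = min_pairs,
                              self_mode = self_mode)
  out
}

#' Filter synteny blocks
#'
#' Drops blocks below the anchor-count threshold and, for self-comparisons,
#' blocks lying on the identity diagonal (same chromosome on both sides and
#' at least 90% of anchors with `rank_a == rank_b`), so that paralogy
#' statistics never count trivial self-matches.
#'
#' @param blocks A `synteny_blocks` tibble.
#' @param min_pairs Minimum anchors per retained block.
#' @param self_mode Apply the identity-diagonal rule. Defaults to the flag
#'   recorded at chaining time.
#' @return The filtered `synteny_blocks` tibble.
#' @export
filter_blocks <- function(blocks, min_pairs = 5L, self_mode = NULL) {
  params <- attr(blocks, "params", exact = TRUE)
  if (is.null(self_mode)) self_mode <- isTRUE(params$self_mode)
  keep <- blocks$n_pairs >= min_pairs
  if (self_mode && nrow(blocks) > 0) {
    diag_frac <- map_dbl(blocks$anchors, function(a) {
      mean(a$rank_a == a$rank_b & a$gene_a == a$gene_b)
    })
    keep <- keep & !(blocks$chrom_a == blocks$chrom_b & diag_frac >= 0.9)
  }
  out <- blocks[keep, , drop = FALSE]
  attributes(out)[c("species_a", "species_b", "params")] <-
    attributes(blocks)[c("species_a", "species_b", "params")]
  out
}

# rank interval [lo, hi] of each block on one side
block_spans <- function(blocks, side = c("a", "b")) {
  side <- match.arg(side)
  rk <- if (side == "a") "rank_a" else "rank_b"
  ch <- if (side == "a") "chrom_a" else "chrom_b"
  other <- if (side == "a") "chrom_b" else "chrom_a"
  if (nrow(blocks) == 0) {
    return(tibble(block_id = character(), chromosome = character(),
                  partner = character(), lo = integer(), hi = integer(),
                  n_pairs = integer()))
  }
  tibble(
    block_id = blocks$block_id,
    chromosome = blocks[[ch]],
    partner = blocks[[other]],
    lo = map_int(blocks$anchors, ~ min(.x[[rk]])),
    hi = map_int(blocks$anchors, ~ max(.x[[rk]])),
    n_pairs = blocks$n_pairs
  )
}

#' Per-chromosome synteny coverage
#'
#' For each (chromosome, partner chromosome) pair, the fraction of the
#' chromosome's genes lying inside the union of its blocks' anchor rank
#' spans.
#'
#' @param blocks A `synteny_blocks` tibble (side "a" is the reference by
#'   default).
#' @param genes The reference [gene_table()].
#' @param side Which side of the blocks the reference genome is on.
#' @return Tibble with `chromosome`, `partner`, `covered`, `n_genes`,
#'   `coverage` in `[0, 1]`.
#' @export
synteny_coverage <- function(blocks, genes, side = "a") {
  sizes <- chromosome_summary(genes)
  spans <- block_spans(blocks, side)
  if (nrow(spans) == 0) {
    return(tibble(chromosome = character(), partner = character(),
                  covered = integer(), n_genes = integer(),
                  coverage = double()))
  }
  spans |>
    group_by(.data$chromosome, .data$partner) |>
    summarise(covered = {
      ir <- IRanges::reduce(IRanges::IRanges(.data$lo, .data$hi))
      sum(IRanges::width(ir))
    }, .groups = "drop") |>
    inner_join(sizes, by = "chromosome") |>
    mutate(covered = pmin(.data$covered, .data$n_genes),
           coverage = .data$covered / .data$n_genes) |>
    select("chromosome", "partner", "covered", "n_genes", "coverage")
}

#' Classify chromosome-pair homology relations
#'
#' Labels every chromosome pair connected by at least one filtered block as
#' `whole`, `arm`, or `segmental` (`none` pairs are simply absent):
#' `whole` when reciprocal coverage reaches `theta_whole` both ways and the
#' two chromosomes are each other's top partner; `arm` when one chromosome's
#' blocks cover at least `theta_arm` of a single arm of the other (and the
#' chromosome itself is mostly explained by that partner); otherwise
#' `segmental`.
#'
#' @param blocks Filtered `synteny_blocks` between the two genomes.
#' @param genes_a,genes_b The two [gene_table()]s.
#' @param theta_whole,theta_arm Coverage thresholds. `theta_whole`
#'   defaults to 0.8: "homologous across the entire length" is read
#'   strictly, so a chromosome that is a 60/40 translocation mix of two
#'   ancestral chromosomes is not whole-related to either. `theta_arm`
#'   defaults to 0.6.
#' @param centromeres_a,centromeres_b Optional tibbles
#'   (`chromosome`, `centromere_rank`) enabling arm-level classification.
#' @param classify_arms Whether to attempt `arm` labels; requires both
#'   centromere tables, else a hard error.
#' @return Tibble `chrom_a`, `chrom_b`, `coverage_ab`, `coverage_ba`,
#'   `relation`.
#' @export
classify_homology <- function(blocks, genes_a, genes_b,
                              theta_whole = 0.8, theta_arm = 0.6,
                              centromeres_a = NULL, centromeres_b = NULL,
                              classify_arms = !is.null(centromeres_a)) {
  if (classify_arms && (is.null(centromeres_a) || is.null(centromeres_b))) {
    abort("arm classification requested but centromere ranks are missing")
  }
  cov_a <- synteny_coverage(blocks, genes_a, side = "a")
  cov_b <- synteny_coverage(blocks, genes_b, side = "b")
  if (nrow(cov_a) == 0) {
    return(tibble(chrom_a = character(), chrom_b = character(),
                  coverage_ab = double(), coverage_ba = double(),
                  relation = character()))
  }
  pairs <- cov_a |>
    rename(chrom_a = "chromosome", chrom_b = "partner",
           coverage_ab = "coverage") |>
    select("chrom_a", "chrom_b", "coverage_ab") |>
    inner_join(
      cov_b |>
        rename(chrom_b = "chromosome", chrom_a = "partner",
               coverage_ba = "coverage") |>
        select("chrom_a", "chrom_b", "coverage_ba"),
      by = c("chrom_a", "chrom_b")
    )
  top_a <- pairs |> group_by(.data$chrom_a) |>
    slice_max(.data$coverage_ab, n = 1, with_ties = FALSE) |> ungroup() |>
    select("chrom_a", top_b = "chrom_b")
  top_b <- pairs |> group_by(.data$chrom_b) |>
    slice_max(.data$coverage_ba, n = 1, with_ties = FALSE) |> ungroup() |>
    select("chrom_b", top_a = "chrom_a")
  pairs <- pairs |>
    left_join(top_a, by = "chrom_a") |>
    left_join(top_b, by = "chrom_b") |>
    mutate(whole = .data$coverage_ab >= theta_whole &
             .data$coverage_ba >= theta_whole &
             .data$top_b == .data$chrom_b & .data$top_a == .data$chrom_a)

  arm_flag <- rep(FALSE, nrow(pairs))
  if (classify_arms) {
    sizes_a <- chromosome_summary(genes_a)
    sizes_b <- chromosome_summary(genes_b)
    for (i in seq_len(nrow(pairs))) {
      if (pairs$whole[i]) next
      arm_flag[i] <-
        arm_concentrated(blocks, pairs$chrom_a[i], pairs$chrom_b[i],
                         centromeres_b, sizes_b, "b", theta_arm,
                         pairs$coverage_ab[i]) ||
        arm_concentrated(blocks, pairs$chrom_b[i], pairs$chrom_a[i],
                         centromeres_a, sizes_a, "a", theta_arm,
                         pairs$coverage_ba[i])
    }
  }
  pairs |>
    mutate(relation = dplyr::case_when(
      .data$whole ~ "whole",
      arm_flag ~ "arm",
      TRUE ~ "segmental"
    )) |>
    select("chrom_a", "chrom_b", "coverage_ab", "coverage_ba", "relation")
}

# Does chromosome `probe` cover >= theta of a single arm of `host` (host is
# on `host_side` of the blocks), with probe itself mostly explained?
arm_concentrated <- function(blocks, probe, host, centromeres_host,
                             sizes_host, host_side, theta, probe_cov) {
  cen <- centromeres_host$centromere_rank[centromeres_host$chromosome == host]
  if (length(cen) != 1) return(FALSE)
  n_host <- sizes_host$n_genes[sizes_host$chromosome == host]
  spans <- block_spans(blocks, host_side)
  spans <- spans[spans$chromosome == host & spans$partner == probe, ,
                 drop = FALSE]
  if (nrow(spans) == 0) return(FALSE)
  ir <- IRanges::reduce(IRanges::IRanges(spans$lo, spans$hi))
  arm_l <- IRanges::IRanges(0L, max(cen - 1L, 0L))
  arm_r <- IRanges::IRanges(cen, n_host - 1L)
  cov_l <- sum(IRanges::width(IRanges::intersect(ir, arm_l))) / max(cen, 1L)
  cov_r <- sum(IRanges::width(IRanges::intersect(ir, arm_r))) /
    max(n_host - cen, 1L)
  max(cov_l, cov_r) >= theta && probe_cov >= theta
}

#' Syntenic depth of a reference genome
#'
#' For every reference gene, the number of filtered blocks whose reference
#' rank span contains it. The modal nonzero depth, expressed `mode:1`,
#' diagnoses ploidy: a 2:1 profile of target-vs-reference blocks indicates
#' one whole-genome duplication in the target.
#'
#' @param blocks Filtered `synteny_blocks`; the reference genome is side "a".
#' @param reference The reference [gene_table()].
#' @return A `depth_profile` tibble (`chromosome`, `gene_id`, `rank`,
#'   `depth`) with attributes `modal_depth`, `modal_ratio`, and
#'   `no_signal` flag when all depths are zero.
#' @export
syntenic_depth <- function(blocks, reference) {
  spans <- block_spans(blocks, "a")
  prof <- reference |>
    select("chromosome", "gene_id", "rank") |>
    mutate(depth = 0L)
  if (nrow(spans) > 0) {
    counts <- prof |>
      left_join(spans, by = "chromosome", relationship = "many-to-many") |>
      filter(!is.na(.data$lo), .data$rank >= .data$lo,
             .data$rank <= .data$hi) |>
      count(.data$chromosome, .data$gene_id, name = "depth")
    prof <- prof |>
      select(-"depth") |>
      left_join(counts, by = c("chromosome", "gene_id")) |>
      mutate(depth = dplyr::coalesce(.data$depth, 0L))
  }
  nz <- prof$depth[prof$depth > 0]
  modal <- if (length(nz) == 0) NA_integer_ else {
    tab <- table(nz)
    as.integer(names(tab)[which.max(tab)])
  }
  out <- new_kf_tbl(prof, "depth_profile")
  attr(out, "modal_depth") <- modal
  attr(out, "modal_ratio") <- if (is.na(modal)) NA_character_ else
    paste0(modal, ":1")
  attr(out, "no_signal") <- is.na(modal)
  out
}
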