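# Karyotype painting: projecting a target genome onto ancestral
# proto-chromosomes through synteny blocks.

#' Chain synteny blocks between an ancestral karyotype and a target genome
#'
#' The ancestral pseudo-genome's genes are source-species genes, so the
#' homology tables between each source species and the target are reused
#' directly: pairs whose query is an ancestral gene become anchors on the
#' proto-chromosomes.
#'
#' @param agk An `ancestral_karyotype`.
#' @param target Target [gene_table()].
#' @param homologies Named list of homology tibbles keyed
#'   `"<species>|<species>"` (either direction); must cover every
#'   (source species, target species) pair, including the self pair when the
#'   target is itself a source species.
#' @param max_gap,min_pairs Chaining parameters.
#' @return Filtered `synteny_blocks` with proto-chromosomes on side "a".
#' @export
agk_target_blocks <- function(agk, target, homologies,
                              max_gap = 25L, min_pairs = 5L) {
  target_sp <- attr(target, "species") %||% "target"
  src_species <- unique(agk$source$source_species)
  agk_ids <- agk$genes$gene_id
  combined <- bind_rows(lapply(src_species, function(s) {
    h <- get_pair_homology(homologies, s, target_sp)
    filter(h, .data$query_id %in% agk_ids)
  }))
  anchors <- build_anchors(agk$genes, target, combined)
  self_mode <- identical(target_sp, "AGK")
  filter_blocks(chain_anchors(anchors, max_gap = max_gap,
                              min_pairs = min_pairs,
                              self_mode = self_mode),
                min_pairs = min_pairs)
}

#' Paint a target genome by proto-chromosome of origin
#'
#' Every target gene lying inside a block's target-side rank span takes that
#' block's proto-chromosome; when spans overlap, the block with more anchor
#' pairs wins. A light majority smoothing then absorbs isolated discordant
#' runs: a run shorter than 3 genes whose label disagrees with the majority
#' of the surrounding `smooth_window` genes is reassigned to that majority.
#' Genes outside every block stay `NA`.
#'
#' @param agk An `ancestral_karyotype` (proto-chromosomes on block side "a").
#' @param target Target [gene_table()].
#' @param blocks Filtered `synteny_blocks` between `agk` and `target`
#'   (e.g. from [agk_target_blocks()]).
#' @param smooth_window Width (genes) of the majority-smoothing window
#'   (default 30).
#' @return A `painting` tibble: `species`, `chromosome`, `gene_id`, `rank`,
#'   `proto`.
#' @export
project_karyotype <- function(agk, target, blocks, smooth_window = 30L) {
  spans <- block_spans(blocks, "b") |>
    rename(proto = "partner") |>
    mutate(weight = .data$n_pairs)
  prof <- target |>
    select("species", "chromosome", "gene_id", "rank") |>
    mutate(proto = NA_character_)
  if (nrow(spans) > 0) {
    hits <- prof |>
      select(-"proto") |>
      inner_join(spans, by = "chromosome", relationship = "many-to-many") |>
      filter(.data$rank >= .data$lo, .data$rank <= .data$hi) |>
      group_by(.data$chromosome, .data$gene_id) |>
      arrange(dplyr::desc(.data$weight), .data$block_id, .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      select("chromosome", "gene_id", "proto")
    prof <- prof |>
      select(-"proto") |>
      left_join(hits, by = c("chromosome", "gene_id"))
  }
  prof <- prof |>
    arrange(.data$chromosome, .data$rank) |>
    group_by(.data$chromosome) |>
    mutate(proto = smooth_labels(.data$proto, smooth_window)) |>
    ungroup()
  new_kf_tbl(prof, "painting")
}

# Majority smoothing of per-gene labels along one chromosome: runs shorter
# than 3 genes disagreeing with the window majority are absorbed.
smooth_labels <- function(labels, window) {
  n <- length(labels)
  if (n == 0 || window < 2) return(labels)
  r <- rle(ifelse(is.na(labels), "\r<NA>", labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- labels
  half <- max(1L, window %/% 2L)
  for (k in seq_along(r$lengths)) {
    if (r$lengths[k] >= 3L || r$values[k] == "\r<NA>") next
    lo <- max(1L, starts[k] - half)
    hi <- min(n, ends[k] + half)
    ctx <- labels[lo:hi]
    ctx <- ctx[!is.na(ctx)]
    if (length(ctx) == 0) next
    tab <- sort(table(ctx), decreasing = TRUE)
    maj <- names(tab)[1]
    if (!identical(maj, r$values[k]) &&
        tab[1] > r$lengths[k]) {
      out[starts[k]:ends[k]] <- maj
    }
  }
  out
}

#' Build the per-proto arm table from centromere ranks
#'
#' Splits each proto-chromosome at its centromere rank into a left arm `L`
#' (ranks below the centromere) and a right arm `R` (centromere rank and
#' above), measured in genes.
#'
#' @param agk An `ancestral_karyotype`.
#' @param centromeres Tibble `proto`, `centromere_rank`.
#' @return Tibble `proto`, `centromere_rank`, `len_L`, `len_R`, `n_genes`.
#' @export
arm_table <- function(agk, centromeres) {
  sizes <- chromosome_summary(agk$genes) |>
    rename(proto = "chromosome")
  missing <- setdiff(sizes$proto, centromeres$proto)
  if (length(missing) > 0) {
    abort(paste0("missing centromere rank for proto(s): ",
                 paste(missing, collapse = ", ")))
  }
  sizes |>
    inner_join(centromeres, by = "proto") |>
    mutate(len_L = pmin(pmax(.data$centromere_rank, 0L), .data$n_genes),
           len_R = .data$n_genes - .data$len_L) |>
    select("proto", "centromere_rank", "len_L", "len_R", "n_genes")
}

#' Assign synteny blocks to ancestral chromosome arms
#'
#' Each block goes to the arm containing the larger share of its ancestral
#' rank span (an exact 50/50 split goes left).
#'
#' @param blocks Filtered `synteny_blocks` with proto-chromosomes on side
#'   "a".
#' @param arms Arm table from [arm_table()].
#' @return Tibble `proto`, `arm` (`L`/`R`), `n_blocks`, plus per-block
#'   assignments in `attr(, "assignments")`.
#' @export
map_blocks_to_arms <- function(blocks, arms) {
  spans <- block_spans(blocks, "a") |>
    rename(proto = "chromosome")
  missing <- setdiff(unique(spans$proto), arms$proto)
  if (length(missing) > 0) {
    abort(paste0("missing centromere for proto(s): ",
                 paste(missing, collapse = ", ")))
  }
  asg <- spans |>
    inner_join(arms, by = "proto") |>
    mutate(
      left_share = pmax(0L, pmin(.data$hi, .data$centromere_rank - 1L) -
                          .data$lo + 1L),
      total = .data$hi - .data$lo + 1L,
      arm = ifelse(.data$left_share >= .data$total - .data$left_share,
                   "L", "R")
    ) |>
    select("block_id", "proto", "arm", "lo", "hi")
  counts <- asg |>
    count(.data$proto, .data$arm, name = "n_blocks")
  grid <- tidyr::expand_grid(proto = arms$proto, arm = c("L", "R")) |>
    left_join(counts, by = c("proto", "arm")) |>
    mutate(n_blocks = dplyr::coalesce(.data$n_blocks, 0L))
  attr(grid, "assignments") <- asg
  grid
}
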