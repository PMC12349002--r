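# Block-level statistics: collinearity degree, one-way ANOVA across
# comparisons, arm-length randomization test, and TE composition in blocks
# versus gene-rank flanks.

#' Collinearity degree of a block set
#'
#' The degree of collinearity is the ratio of collinear gene pairs to
#' syntenic blocks; longer, better-preserved blocks give higher degrees.
#'
#' @param blocks Filtered `synteny_blocks`.
#' @param comparison Label for the comparison (defaults to the species pair
#'   recorded on the blocks).
#' @return One-row tibble `comparison`, `n_gene_pairs`, `n_blocks`,
#'   `degree`; `degree` is `NA` (with a warning) when there are no blocks.
#' @export
collinearity_degree <- function(blocks, comparison = NULL) {
  if (is.null(comparison)) {
    comparison <- paste(attr(blocks, "species_a") %||% "a",
                        attr(blocks, "species_b") %||% "b", sep = "|")
  }
  n_blocks <- nrow(blocks)
  n_pairs <- sum(blocks$n_pairs)
  if (n_blocks == 0) {
    warn("no blocks: collinearity degree undefined")
    return(tibble(comparison = comparison, n_gene_pairs = 0L,
                  n_blocks = 0L, degree = NA_real_))
  }
  tibble(comparison = comparison, n_gene_pairs = n_pairs,
         n_blocks = n_blocks, degree = n_pairs / n_blocks)
}

#' One-way ANOVA on grouped degree values
#'
#' Classical one-way fixed-effects ANOVA (equal-variance F test) comparing
#' collinearity degrees (or any numeric values) across groups, with an
#' optional permutation p-value from label shuffles as a robustness
#' companion.
#'
#' @param data Data frame with one row per value.
#' @param value,group Columns (tidy-eval) holding the numeric values and
#'   group labels.
#' @param n_perm Number of label permutations (0 to skip).
#' @param seed RNG seed for the permutation p-value (required when
#'   `n_perm > 0`).
#' @return A `degree_anova` object (list with `statistic`, `df`, `p_value`,
#'   `perm_p`, `groups`); see [tidy()] and [glance()].
#' @export
anova_oneway <- function(data, value, group, n_perm = 0L, seed = NULL) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) {
    abort("anova_oneway needs at least two groups")
  }
  if (!any(table(g) >= 2)) {
    abort("anova_oneway needs at least one group with >= 2 values")
  }
  f_stat <- function(v, g) {
    m <- tapply(v, g, mean)
    n <- tapply(v, g, length)
    grand <- mean(v)
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum((v - m[g])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(v) - nlevels(g)
    if (ssw == 0 && ssb == 0) return(c(0, df1, df2))
    c((ssb / df1) / (ssw / df2), df1, df2)
  }
  g <- droplevels(g)
  fd <- f_stat(v, g)
  f <- fd[1]; df1 <- fd[2]; df2 <- fd[3]
  p <- if (f == 0 && all(v == v[1])) 1 else pf(f, df1, df2, lower.tail = FALSE)
  perm_p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) abort("permutation p-value requires a seed")
    perm_p <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        fp <- f_stat(v, sample(g))[1]
        if (fp >= f) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(statistic = f, df = c(df1 = df1, df2 = df2), p_value = p,
                 perm_p = perm_p, n_perm = n_perm,
                 groups = tibble(group = levels(g),
                                 n = as.integer(table(g)),
                                 mean = as.numeric(tapply(v, g, mean)))),
            class = "degree_anova")
}

#' Arm-length randomization test for block distribution
#'
#' Tests whether observed block counts per ancestral chromosome arm are
#' compatible with blocks landing on arms in proportion to arm length: under
#' the null each block falls on arm \eqn{a} with probability
#' \eqn{L_a / \sum L}, the statistic is the chi-square form
#' \eqn{\sum_a (O_a - E_a)^2 / E_a}, and the p-value is Monte-Carlo with the
#' +1 correction, so it is never exactly zero.
#'
#' @param counts Data frame with columns `arm`, `observed` (block counts)
#'   and `arm_length` (gene counts per arm; strictly positive).
#' @param n_sim Number of null simulations (default 10000).
#' @param seed Mandatory RNG seed.
#' @return An `arm_randomization` object (list with `table` including
#'   expected counts, `statistic`, `p_value`, `n_sim`, `seed`).
#' @export
arm_randomization_test <- function(counts, n_sim = 10000L, seed) {
  if (missing(seed)) abort("arm_randomization_test requires a seed")
  stopifnot(all(c("arm", "observed", "arm_length") %in% names(counts)))
  if (nrow(counts) < 2) abort("need at least two arms")
  if (any(counts$arm_length <= 0)) abort("arm lengths must be positive")
  n_total <- sum(counts$observed)
  if (n_total < 1) abort("need at least one observed block")
  p <- counts$arm_length / sum(counts$arm_length)
  expected <- n_total * p
  stat <- sum((counts$observed - expected)^2 / expected)
  p_value <- with_seed(seed, {
    sims <- rmultinom(n_sim, size = n_total, prob = p)
    sim_stat <- colSums((sims - expected)^2 / expected)
    (1 + sum(sim_stat >= stat)) / (n_sim + 1)
  })
  structure(list(
    table = counts |> mutate(expected = expected) |> as_tibble(),
    statistic = stat, p_value = p_value,
    n_sim = as.integer(n_sim), seed = as.integer(seed)
  ), class = "arm_randomization")
}

#' Transposable-element composition in blocks and their gene-rank flanks
#'
#' For every block, the bp span from its first to its last anchor gene is
#' the block region; the upstream and downstream flanks are the bp spans of
#' the `flank_genes` genes immediately before and after that gene span
#' (truncated at chromosome ends, with the truncation flagged). Per-class
#' percentages are computed on merged intervals clipped to the region, so
#' overlap within a class is never double-counted.
#'
#' @param blocks Filtered `synteny_blocks`.
#' @param te_intervals TE tibble from [read_te_intervals()] (same genome as
#'   the chosen block side).
#' @param genes [gene_table()] of that genome (rank-to-bp mapping).
#' @param flank_genes Flank width in genes (default 30).
#' @param side Which block side lives on this genome (`"a"` or `"b"`).
#' @return Tibble with one row per (region, TE class): `block_id`, `kind`
#'   (`block`/`flank_up`/`flank_down`), `chromosome`, `start`, `end`,
#'   `span`, `truncated`, `te_class`, `percent`.
#' @export
te_composition <- function(blocks, te_intervals, genes, flank_genes = 30L,
                           side = "a") {
  spans <- block_spans(blocks, side)
  if (nrow(spans) == 0) {
    return(tibble(block_id = character(), kind = character(),
                  chromosome = character(), start = integer(),
                  end = integer(), span = integer(), truncated = logical(),
                  te_class = character(), percent = double()))
  }
  classes <- c("Copia", "Gypsy", "LINE1", "Other")
  sizes <- chromosome_summary(genes)
  rows <- list()
  warned <- character()
  for (i in seq_len(nrow(spans))) {
    ch <- spans$chromosome[i]
    gch <- genes |> filter(.data$chromosome == ch) |> arrange(.data$rank)
    n <- nrow(gch)
    lo <- spans$lo[i]; hi <- spans$hi[i]
    regions <- list(
      block = c(lo, hi, FALSE),
      flank_up = c(max(0L, lo - flank_genes), lo - 1L, lo - flank_genes < 0),
      flank_down = c(hi + 1L, min(n - 1L, hi + flank_genes),
                     hi + flank_genes > n - 1L)
    )
    for (kind in names(regions)) {
      rg <- regions[[kind]]
      if (rg[1] > rg[2]) {
        rows[[length(rows) + 1L]] <- tibble(
          block_id = spans$block_id[i], kind = kind, chromosome = ch,
          start = NA_integer_, end = NA_integer_, span = 0L,
          truncated = TRUE, te_class = classes, percent = 0)
        next
      }
      bp0 <- gch$start[rg[1] + 1L]
      bp1 <- gch$end[rg[2] + 1L]
      span <- bp1 - bp0
      tch <- te_intervals |> filter(.data$chromosome == ch)
      if (nrow(tch) == 0 && !ch %in% warned) {
        warn(paste0("chromosome ", ch, " absent from TE annotation"))
        warned <- c(warned, ch)
      }
      pct <- map_dbl(classes, function(cl) {
        iv <- tch |> filter(.data$te_class == cl)
        if (nrow(iv) == 0) return(0)
        ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
        clip <- IRanges::restrict(ir, start = bp0 + 1L, end = bp1)
        100 * sum(IRanges::width(clip)) / span
      })
      rows[[length(rows) + 1L]] <- tibble(
        block_id = spans$block_id[i], kind = kind, chromosome = ch,
        start = bp0, end = bp1, span = span,
        truncated = as.logical(rg[3]), te_class = classes, percent = pct)
    }
  }
  bind_rows(rows)
}
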