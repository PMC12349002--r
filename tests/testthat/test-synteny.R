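# Anchor building, chaining, block filtering, coverage and depth.

test_that("anchors carry the gene tables' ranks and skips are counted", {
  ga <- toy_genes(c(c1 = 5), species = "A", prefix = "a")
  gb <- toy_genes(c(cX = 5), species = "B", prefix = "b")
  pairs <- tibble::tibble(
    query_id = c(ga$gene_id[1:3], "missing_gene"),
    subject_id = c(gb$gene_id[c(2, 1, 3)], gb$gene_id[1]),
    evalue = 1e-30, bitscore = 500
  )
  an <- build_anchors(ga, gb, pairs)
  expect_equal(nrow(an), 3L)
  expect_equal(attr(an, "n_skipped"), 1L)
  expect_equal(an$rank_b[an$gene_a == ga$gene_id[1]], 1L)
})

test_that("perfect diagonals chain into single oriented blocks", {
  plus <- chain_anchors(toy_anchors(0:4, 0:4), max_gap = 5, min_pairs = 5)
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$orientation, "+")
  expect_equal(plus$n_pairs, 5L)

  minus <- chain_anchors(toy_anchors(0:4, 10 - (0:4)), max_gap = 5,
                         min_pairs = 5)
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$orientation, "-")
  expect_equal(minus$n_pairs, 5L)
})

test_that("first extracted chain matches the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:13, 1)
    g <- sample(3:8, 1)
    ra <- sample.int(30, n, replace = TRUE)
    rb <- sample.int(30, n, replace = TRUE)
    bl <- chain_anchors(toy_anchors(ra, rb), max_gap = g, min_pairs = 2)
    got <- if (nrow(bl) == 0) 1L else max(bl$n_pairs)
    want <- chain_oracle_best(ra, rb, g)
    # blocks below min_pairs = 2 are not emitted; oracle floor is 1
    expect_equal(max(got, 1L), max(want, 1L),
                 info = sprintf("rep %d seed state", rep))
  }
})

test_that("anchors are conserved: each belongs to at most one block", {
  set.seed(7)
  an <- toy_anchors(sample.int(40, 30, TRUE), sample.int(40, 30, TRUE))
  bl <- chain_anchors(an, max_gap = 6, min_pairs = 2)
  used <- dplyr::bind_rows(bl$anchors)
  key <- paste(used$rank_a, used$rank_b, used$gene_a)
  expect_false(any(duplicated(key)))
  expect_true(all(paste(used$rank_a, used$rank_b) %in%
                    paste(an$rank_a, an$rank_b)))
})

test_that("reversing rank_b flips orientations and nothing else", {
  set.seed(13)
  an <- toy_anchors(sample.int(50, 25, TRUE), sample.int(50, 25, TRUE))
  bl <- chain_anchors(an, max_gap = 8, min_pairs = 3)
  an_rev <- an
  an_rev$rank_b <- max(an$rank_b) - an$rank_b
  bl_rev <- chain_anchors(an_rev, max_gap = 8, min_pairs = 3)
  expect_equal(sort(bl$n_pairs), sort(bl_rev$n_pairs))
  flip <- c("+" = "-", "-" = "+")
  ord <- function(b) b[order(b$n_pairs, vapply(b$anchors,
                                               function(a) min(a$rank_a),
                                               integer(1))), ]
  expect_equal(unname(flip[ord(bl)$orientation]),
               ord(bl_rev)$orientation)
})

test_that("filtering drops short blocks and self-diagonals", {
  an <- toy_anchors(c(0:3, 10:19), c(0:3, 10:19))
  bl <- chain_anchors(an, max_gap = 5, min_pairs = 2)
  expect_equal(sort(bl$n_pairs), c(4L, 10L))
  kept <- filter_blocks(bl, min_pairs = 5)
  expect_equal(kept$n_pairs, 10L)

  # self-comparison: identity diagonal dropped under self_mode
  self_an <- structure(
    tibble::tibble(gene_a = paste0("g", 1:10), gene_b = paste0("g", 1:10),
                   chrom_a = "c1", chrom_b = "c1",
                   rank_a = 0:9, rank_b = 0:9),
    class = c("anchors", class(tibble::tibble())))
  sbl <- chain_anchors(self_an, max_gap = 5, min_pairs = 5,
                       self_mode = TRUE)
  expect_equal(nrow(filter_blocks(sbl, min_pairs = 5)), 0L)
})

test_that("coverage fractions follow the anchor span unions", {
  g <- toy_genes(c(c1 = 200))
  full <- blocks_from_spans(tibble::tibble(chrom_a = "c1", lo = 0L,
                                           hi = 199L))
  expect_equal(synteny_coverage(full, g)$coverage, 1)

  none <- full[0, ]
  expect_equal(nrow(synteny_coverage(none, g)), 0L)

  two <- blocks_from_spans(tibble::tibble(chrom_a = "c1",
                                          lo = c(0L, 100L),
                                          hi = c(49L, 149L)))
  expect_equal(synteny_coverage(two, g)$coverage, 0.5)

  # monotonicity: adding a block never decreases coverage
  more <- blocks_from_spans(tibble::tibble(chrom_a = "c1",
                                           lo = c(0L, 100L, 160L),
                                           hi = c(49L, 149L, 170L)))
  expect_gte(synteny_coverage(more, g)$coverage,
             synteny_coverage(two, g)$coverage)
})

test_that("chromosome relations classify as whole / arm / segmental", {
  ga <- toy_genes(c(c1 = 100), species = "A", prefix = "a")
  gb <- toy_genes(c(t1 = 100), species = "B", prefix = "b")
  whole <- blocks_from_spans(tibble::tibble(chrom_a = "c1", lo = 0L,
                                            hi = 99L, chrom_b = "t1"))
  whole$anchors <- lapply(whole$anchors, function(a) {
    a$rank_b <- c(0L, 99L); a
  })
  rel <- classify_homology(whole, ga, gb)
  expect_equal(rel$relation, "whole")

  seg <- blocks_from_spans(tibble::tibble(chrom_a = "c1", lo = 10L,
                                          hi = 15L, chrom_b = "t1"))
  expect_equal(classify_homology(seg, ga, gb)$relation, "segmental")

  # fission product: 50-gene chromosome matching the left arm of a
  # 100-gene chromosome whose centromere sits at rank 50
  gfis <- toy_genes(c(f1 = 50), species = "F", prefix = "f")
  armbl <- blocks_from_spans(tibble::tibble(chrom_a = "f1", lo = 0L,
                                            hi = 49L, chrom_b = "t1"))
  armbl$anchors <- lapply(armbl$anchors, function(a) {
    a$rank_b <- c(0L, 49L); a
  })
  cen_b <- tibble::tibble(chromosome = "t1", centromere_rank = 50L)
  cen_a <- tibble::tibble(chromosome = "f1", centromere_rank = 25L)
  rel2 <- classify_homology(armbl, gfis, gb, centromeres_a = cen_a,
                            centromeres_b = cen_b)
  expect_equal(rel2$relation, "arm")
  expect_error(
    classify_homology(armbl, gfis, gb, classify_arms = TRUE),
    "centromere")
})

test_that("syntenic depth counts covering blocks and reports the mode", {
  g <- toy_genes(c(c1 = 100))
  bl <- blocks_from_spans(tibble::tibble(
    chrom_a = "c1", lo = c(0L, 0L, 50L), hi = c(99L, 49L, 99L)))
  d <- syntenic_depth(bl, g)
  expect_equal(unique(d$depth), 2L)
  expect_equal(attr(d, "modal_ratio"), "2:1")

  d0 <- syntenic_depth(bl[0, ], g)
  expect_true(all(d0$depth == 0L))
  expect_true(attr(d0, "no_signal"))
})
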