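# Two-round reconstruction, consolidation, representative selection,
# painting and arm mapping.

toy_links_empty <- function() tibble::tibble(
  species = character(), chromosome = character(), lo = integer(),
  hi = integer(), partner_species = character(),
  partner_chromosome = character(), plo = integer(), phi = integer(),
  n_pairs = integer(), block_uid = character())

rel_row <- function(sa, ca, sb, cb, relation = "whole") {
  tibble::tibble(species_a = sa, chrom_a = ca, species_b = sb, chrom_b = cb,
                 coverage_ab = 0.95, coverage_ba = 0.95, relation = relation)
}

test_that("whole-chromosome relations seed unified protos", {
  rel <- dplyr::bind_rows(
    rel_row("A", "c1", "B", "x1"), rel_row("A", "c2", "B", "x2"),
    rel_row("A", "c3", "B", "x3"), rel_row("B", "x1", "C", "y1"))
  seeds <- seed_round1(rel, c("A", "B", "C"))
  expect_equal(dplyr::n_distinct(seeds$proto), 3L)
  # transitively shared chromosome joins one seed
  p1 <- seeds$proto[seeds$species == "A" & seeds$chromosome == "c1"]
  expect_equal(seeds$proto[seeds$species == "C" & seeds$chromosome == "y1"],
               p1)
  expect_equal(nrow(seed_round1(rel[0, ], c("A", "B"))), 0L)
})

test_that("conflicting seed unification is a hard error", {
  rel <- dplyr::bind_rows(
    rel_row("A", "c1", "B", "x1"), rel_row("A", "c2", "B", "x1"))
  expect_error(seed_round1(rel, c("A", "B")), "conflicting")
})

test_that("an internal inversion does not break whole-chromosome seeding", {
  cfg <- sim_config(species = c("s1", "s2"), n_protos = 3,
                    genes_per_chromosome = c(80, 100),
                    n_inversions = 2, n_translocations = 0,
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0, p_spurious = 0, seed = 5)
  ds <- quiet_sim(cfg)
  hom <- lapply(ds$homologies, filter_homology)
  h <- hom[["s1|s2"]]
  an <- build_anchors(ds$genomes$s1, ds$genomes$s2, h)
  fb <- filter_blocks(chain_anchors(an))
  rel <- classify_homology(fb, ds$genomes$s1, ds$genomes$s2) |>
    dplyr::mutate(species_a = "s1", species_b = "s2")
  seeds <- seed_round1(rel, c("s1", "s2"))
  expect_equal(dplyr::n_distinct(seeds$proto), 3L)
})

test_that("consolidation merges on 2-species support without contradiction", {
  # protos P001 (pieces in A,B) and P002 (whole in C,D) carry the same
  # ancestral content: direct homology across >= 2 species pairs
  membership <- tibble::tibble(
    proto = c("P001", "P001", "P002", "P002"),
    species = c("A", "B", "C", "D"),
    chromosome = c("a9", "b9", "c9", "d9"),
    round = c(1L, 1L, 1L, 1L),
    start_rank = 0L, end_rank = c(99L, 99L, 99L, 99L))
  link <- function(s, c, ps, pc) tibble::tibble(
    species = s, chromosome = c, lo = 0L, hi = 99L,
    partner_species = ps, partner_chromosome = pc, plo = 0L, phi = 99L,
    n_pairs = 50L, block_uid = paste(s, c, ps, pc))
  genomes <- list(A = toy_genes(c(a9 = 100), "A", "A"),
                  B = toy_genes(c(b9 = 100), "B", "B"),
                  C = toy_genes(c(c9 = 100), "C", "C"),
                  D = toy_genes(c(d9 = 100), "D", "D"))
  links <- dplyr::bind_rows(
    link("A", "a9", "C", "c9"), link("C", "c9", "A", "a9"),
    link("B", "b9", "D", "d9"), link("D", "d9", "B", "b9"))
  out <- consolidate(membership, links, c("A", "B", "C", "D"), genomes)
  expect_equal(dplyr::n_distinct(out$proto), 1L)
  expect_equal(nrow(attr(out, "merges")), 1L)

  # one species pair only: not merged
  out1 <- consolidate(membership,
                      dplyr::bind_rows(link("A", "a9", "C", "c9"),
                                       link("C", "c9", "A", "a9")),
                      c("A", "B", "C", "D"), genomes)
  expect_equal(dplyr::n_distinct(out1$proto), 2L)

  # contradiction: a species carries both protos as near-whole
  # chromosomes apart
  memb2 <- dplyr::bind_rows(membership, tibble::tibble(
    proto = c("P001", "P002"), species = c("E", "E"),
    chromosome = c("e1", "e2"), round = 1L,
    start_rank = 0L, end_rank = 99L))
  genomes$E <- toy_genes(c(e1 = 100, e2 = 100), "E", "E")
  out2 <- consolidate(memb2, links, c("A", "B", "C", "D", "E"), genomes)
  expect_equal(dplyr::n_distinct(out2$proto), 2L)
})

test_that("representatives maximize continuity with documented tie-breaks", {
  membership <- tibble::tibble(
    proto = "P001", region = "P001",
    species = c("A", "B"), chromosome = c("a1", "b1"),
    round = 1L, start_rank = 0L, end_rank = c(99L, 99L))
  genomes <- list(A = toy_genes(c(a1 = 100), "A", "A"),
                  B = toy_genes(c(b1 = 100), "B", "B"))
  mk_links <- function(n_ab, n_ba) dplyr::bind_rows(
    tibble::tibble(species = "A", chromosome = "a1", lo = 0L, hi = 99L,
                   partner_species = "B", partner_chromosome = "b1",
                   plo = 0L, phi = 99L, n_pairs = n_ab, block_uid = "k1"),
    tibble::tibble(species = "B", chromosome = "b1", lo = 0L, hi = 99L,
                   partner_species = "A", partner_chromosome = "a1",
                   plo = 0L, phi = 99L, n_pairs = n_ba, block_uid = "k1"))
  # higher continuity (more anchors over the same span) wins
  agk <- select_representatives(membership, mk_links(90L, 60L), genomes)
  expect_equal(agk$segments$species, "A")
  # equal continuity: lexicographic (species, chromosome)
  agk2 <- select_representatives(membership, mk_links(80L, 80L), genomes)
  expect_equal(agk2$segments$species, "A")
})

test_that("protos are named AGK1, AGK2, ... by descending gene count", {
  membership <- tibble::tibble(
    proto = c("P001", "P002"), region = c("P001", "P002"),
    species = "A", chromosome = c("small", "big"),
    round = 1L, start_rank = 0L, end_rank = c(499L, 699L))
  genomes <- list(A = toy_genes(c(small = 500, big = 700), "A", "A"))
  agk <- select_representatives(membership, toy_links_empty(), genomes)
  expect_equal(agk$segments$proto[agk$segments$chromosome == "big"], "AGK1")
  expect_equal(agk$segments$proto[agk$segments$chromosome == "small"],
               "AGK2")
})

test_that("raising min_species never adds a round-2 assignment", {
  cfg <- sim_config(species = paste0("sp", 1:4), n_protos = 6,
                    genes_per_chromosome = c(120, 200), seed = 77)
  ds <- quiet_sim(cfg)
  hom <- lapply(ds$homologies, filter_homology)
  builders <- paste0("sp", 1:4)
  agk3 <- build_ancestral_karyotype(ds$genomes[builders], hom,
                                    species_order = builders,
                                    min_species = 3)
  agk4 <- build_ancestral_karyotype(ds$genomes[builders], hom,
                                    species_order = builders,
                                    min_species = 4)
  # the support rule governs assignment to existing protos: every
  # chromosome assigned by voting under the stricter bar is also assigned
  # under the looser one
  asg <- function(a) {
    pr <- a$provenance
    unique(paste(pr$species, pr$chromosome)[pr$event == "round2_assign"])
  }
  expect_true(all(asg(agk4) %in% asg(agk3)))
})

test_that("reconstruction is deterministic", {
  cfg <- sim_config(species = paste0("sp", 1:3), n_protos = 4,
                    genes_per_chromosome = c(80, 120), seed = 21)
  ds <- quiet_sim(cfg)
  hom <- lapply(ds$homologies, filter_homology)
  a1 <- build_ancestral_karyotype(ds$genomes, hom)
  a2 <- build_ancestral_karyotype(ds$genomes, hom)
  expect_identical(a1$segments, a2$segments)
  expect_identical(as.data.frame(a1$genes), as.data.frame(a2$genes))
})

test_that("a fused chromosome is painted in two proto colors", {
  cfg <- sim_config(species = c("ref", "fus"), n_protos = 4,
                    genes_per_chromosome = c(100, 140),
                    n_inversions = 0, n_translocations = 0,
                    n_fusions = c(0L, 1L),
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0, p_spurious = 0, seed = 9)
  ds <- quiet_sim(cfg)
  hom <- lapply(ds$homologies, filter_homology)
  agk <- as_ancestral_karyotype(ds$genomes$ref)
  bl <- agk_target_blocks(agk, ds$genomes$fus, hom)
  p <- project_karyotype(agk, ds$genomes$fus, bl)
  seg <- painting_segments(p) |> dplyr::filter(!is.na(proto))
  # 4 proto-chromosomes and one fusion leave 3 descendant chromosomes
  per_chrom <- seg |> dplyr::count(chromosome)
  expect_equal(sort(per_chrom$n), c(1, 1, 2))
  fused <- per_chrom$chromosome[per_chrom$n == 2]
  two <- seg[seg$chromosome == fused, ]
  expect_equal(two$start_rank[2], two$end_rank[1] + 1L)
})

test_that("a target with zero homology paints fully NA", {
  g <- toy_genes(c(c1 = 60), species = "ref")
  t <- toy_genes(c(z1 = 60), species = "far", prefix = "z")
  agk <- as_ancestral_karyotype(g)
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = double(), bitscore = double())
  bl <- agk_target_blocks(agk, t, setNames(list(empty), "ref|far"))
  p <- project_karyotype(agk, t, bl)
  expect_true(all(is.na(p$proto)))
})

test_that("blocks map to ancestral arms by majority span with L ties", {
  g <- toy_genes(c(c1 = 100), species = "ref")
  agk <- as_ancestral_karyotype(g)
  arms <- arm_table(agk, tibble::tibble(proto = "AGK1",
                                        centromere_rank = 50L))
  expect_equal(arms$len_L, 50L)
  expect_equal(arms$len_R, 50L)
  bl <- blocks_from_spans(tibble::tibble(
    chrom_a = "AGK1",
    lo = c(0L, 30L, 40L, 60L),
    hi = c(20L, 79L, 59L, 99L)))
  res <- map_blocks_to_arms(bl, arms)
  asg <- attr(res, "assignments")
  # 30-79 is 20 left / 30 right -> R; 40-59 splits 10/10 -> L
  expect_equal(asg$arm, c("L", "R", "L", "R"))
  expect_equal(sum(res$n_blocks), nrow(bl))
  expect_error(
    map_blocks_to_arms(bl, arms[0, ]), "centromere")
})
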