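# Forward simulator: events, determinism, replay, bookkeeping, noise and
# TE landscape calibration; recovery scoring.

test_that("zero events leave the descendant identical to the ancestor", {
  cfg <- sim_config(species = "s1", n_protos = 3,
                    genes_per_chromosome = c(50, 60),
                    n_inversions = 0, n_translocations = 0,
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0, p_spurious = 0, seed = 1)
  ds <- quiet_sim(cfg)
  anc_order <- ds$maps$uid[order(ds$maps$gene_id)]
  g <- ds$genomes$s1
  expect_equal(nrow(g), nrow(ds$ancestor))
  # per-chromosome gene order of lineage uids matches an ancestor
  # chromosome exactly
  truth <- ds$truth
  by_chrom <- split(truth$true_proto, g$chromosome[match(truth$gene_id,
                                                         g$gene_id)])
  expect_true(all(vapply(by_chrom, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("whole-genome duplication without loss doubles the gene count", {
  cfg <- sim_config(species = "w", n_protos = 3,
                    genes_per_chromosome = c(40, 60),
                    n_inversions = 0, n_translocations = 0,
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0, p_spurious = 0,
                    wgd_species = "w", seed = 2)
  ds <- quiet_sim(cfg)
  expect_equal(nrow(ds$genomes$w), 2L * nrow(ds$ancestor))
  expect_equal(length(unique(ds$genomes$w$chromosome)),
               2L * length(unique(ds$ancestor$chromosome)))
})

test_that("the same config and seed give identical datasets", {
  cfg <- sim_config(species = paste0("s", 1:2), n_protos = 3,
                    genes_per_chromosome = c(40, 80), seed = 33)
  a <- quiet_sim(cfg)
  b <- quiet_sim(cfg)
  expect_identical(lapply(a$genomes, as.data.frame),
                   lapply(b$genomes, as.data.frame))
  expect_identical(a$homologies, b$homologies)
  expect_identical(a$te, b$te)
})

test_that("replaying the event log reproduces every descendant exactly", {
  cfg <- sim_config(species = paste0("s", 1:3), n_protos = 4,
                    genes_per_chromosome = c(60, 100),
                    n_fissions = 1, n_fusions = 1,
                    wgd_species = "s2", seed = 8)
  ds <- quiet_sim(cfg)
  for (sp in cfg$species) {
    expect_identical(as.data.frame(replay_events(ds, sp)),
                     as.data.frame(ds$genomes[[sp]]),
                     info = sp)
  }
})

test_that("gene counts obey the per-branch bookkeeping identity", {
  cfg <- sim_config(species = c("a", "b"), n_protos = 4,
                    genes_per_chromosome = c(80, 120),
                    wgd_species = "b", loss_fraction = 0.1,
                    gain_fraction = 0.05, seed = 12)
  ds <- quiet_sim(cfg)
  n_anc <- nrow(ds$ancestor)
  for (sp in cfg$species) {
    evs <- ds$events[ds$events$species == sp, ]
    losses <- sum(vapply(evs$event[evs$type == "loss"], function(e)
      sum(lengths(e$positions)), integer(1)))
    gains <- sum(vapply(evs$event[evs$type == "gain"], function(e)
      nrow(e$insertions), integer(1)))
    base <- if (sp %in% cfg$wgd_species) 2L * n_anc else n_anc
    expect_equal(nrow(ds$genomes[[sp]]), base - losses + gains)
  }
})

test_that("elementary events transform gene order as documented", {
  st <- list(c1 = tibble::tibble(uid = 1:10, anc_proto = "A01",
                                 gene_len = 1000L, strand = "+"),
             c2 = tibble::tibble(uid = 11:16, anc_proto = "A02",
                                 gene_len = 1000L, strand = "+"))
  inv <- apply_event(st, list(type = "inversion", chrom = "c1",
                              from = 3L, to = 7L))
  expect_equal(inv$c1$uid, c(1, 2, 7, 6, 5, 4, 3, 8, 9, 10))
  expect_equal(inv$c1$strand[3:7], rep("-", 5))
  expect_equal(inv$c2$uid, 11:16)

  fis <- apply_event(st, list(type = "fission", chrom = "c1", k = 4L))
  expect_equal(nrow(fis$c1.1), 4L)
  expect_equal(nrow(fis$c1.2), 6L)
  expect_null(fis$c1)

  fus <- apply_event(st, list(type = "fusion", chrom = "c2",
                              chrom2 = "c1"))
  expect_equal(fus$c2$uid, c(11:16, 1:10))
  expect_null(fus$c1)

  tr <- apply_event(st, list(type = "translocation", chrom = "c1",
                             chrom2 = "c2", k1 = 8L, k2 = 2L))
  expect_equal(tr$c1$uid, c(1:8, 13:16))
  expect_equal(tr$c2$uid, c(11, 12, 9, 10))

  expect_error(apply_event(st, list(type = "inversion", chrom = "c1",
                                    from = 5L, to = 5L)), "illegal")
})

test_that("missing-pair noise matches p_missing within two percent", {
  cfg <- sim_config(species = c("x", "y"), n_protos = 8,
                    genes_per_chromosome = c(350, 450),
                    n_inversions = 0, n_translocations = 0,
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0.1, p_spurious = 0, seed = 44)
  ds <- quiet_sim(cfg)
  n_true <- nrow(ds$genomes$x)
  expect_gt(n_true, 2000)
  kept <- nrow(ds$homologies[["x|y"]])
  expect_lt(abs(kept / n_true - 0.9), 0.02)
})

test_that("TE landscape matches configured intensity and multiplier", {
  cfg <- sim_config(species = "t", n_protos = 20,
                    genes_per_chromosome = c(400, 400),
                    n_inversions = 0, n_translocations = 0,
                    loss_fraction = 0, gain_fraction = 0,
                    p_missing = 0, p_spurious = 0,
                    te_intensity = c(Copia = 6, Gypsy = 10, LINE1 = 20,
                                     Other = 4),
                    line1_multiplier = 4,
                    designated_per_chromosome = 1,
                    designated_genes = 100, seed = 55)
  ds <- quiet_sim(cfg)
  g <- ds$genomes$t
  te <- ds$te$t
  genome_bp <- sum(chromosome_summary(g)$length)
  expect_gt(genome_bp, 1e7)  # law-of-large-numbers scale
  # genome-wide per-class insert counts close to lambda * Mbp (LINE1 has
  # the designated extra on top)
  n_gypsy <- sum(te$te_class == "Gypsy")
  expect_lt(abs(n_gypsy / (10 * genome_bp / 1e6) - 1), 0.15)

  # density inside designated windows vs outside estimates the multiplier
  des <- ds$designated
  l1 <- te[te$te_class == "LINE1", ]
  des_bp <- 0; des_n <- 0
  for (i in seq_len(nrow(des))) {
    gch <- g[g$chromosome == des$chromosome[i], ]
    bp0 <- gch$start[gch$rank == des$start_rank[i]]
    bp1 <- gch$end[gch$rank == des$end_rank[i]]
    des_bp <- des_bp + (bp1 - bp0)
    des_n <- des_n + sum(l1$chromosome == des$chromosome[i] &
                           l1$start >= bp0 & l1$start < bp1)
  }
  out_n <- nrow(l1) - des_n
  out_bp <- genome_bp - des_bp
  ratio <- (des_n / des_bp) / (out_n / out_bp)
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("recovery scoring behaves at the extremes", {
  truth <- tibble::tibble(species = "s",
                          gene_id = sprintf("g%03d", 1:120),
                          true_proto = rep(c("A01", "A02", "A03"),
                                           each = 40))
  perfect <- structure(tibble::tibble(
    species = "s", chromosome = rep(c("c1", "c2", "c3"), each = 40),
    gene_id = truth$gene_id, rank = rep(0:39, 3),
    proto = rep(c("AGK2", "AGK3", "AGK1"), each = 40)
  ), class = c("painting", class(tibble::tibble())))
  agk <- as_ancestral_karyotype(
    toy_genes(c(c1 = 40, c2 = 40, c3 = 40), species = "ref"))
  rr <- evaluate_recovery(agk, perfect, truth)
  expect_equal(rr$painting_accuracy, 1)
  expect_equal(rr$partition_agreement, 1)
  expect_equal(rr$unpainted_fraction, 0)

  # uniformly random labels: adjusted Rand index near zero
  aris <- vapply(1:20, function(s) {
    set.seed(s)
    rnd <- perfect
    rnd$proto <- sample(c("AGK1", "AGK2", "AGK3"), 120, replace = TRUE)
    evaluate_recovery(agk, rnd, truth)$partition_agreement
  }, numeric(1))
  expect_lt(max(abs(aris)), 0.05 + max(abs(aris)) * 0)  # each |ARI| small
  expect_lt(mean(abs(aris)), 0.05)

  # species mismatch is a hard error
  bad <- perfect
  bad$species <- "other"
  expect_error(evaluate_recovery(agk, bad, truth), "not in truth")
})
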