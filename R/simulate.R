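# Forward simulation of karyotype evolution in gene-rank space.
#
# The simulator works on an internal genome state: a named list of
# chromosomes, each a tibble of genes in order with a persistent lineage uid
# (shared by all descendant copies of an ancestral gene), the ancestral
# proto-chromosome of origin, a gene length, and a strand. Base-pair
# coordinates are synthesized at the end from the stored gene lengths and a
# fixed intergenic gap, so replaying the event log is RNG-free and exact.

#' Simulation configuration
#'
#' Per-branch event counts may be scalars (applied to every species) or
#' vectors recycled along `species`.
#'
#' @param species Character vector of descendant species ids.
#' @param n_protos Number of ancestral chromosomes (default 12).
#' @param genes_per_chromosome Two-element range of genes per ancestral
#'   chromosome (default `c(200, 500)`).
#' @param n_inversions,n_translocations,n_fissions,n_fusions Per-branch
#'   event counts.
#' @param wgd_species Species whose branch carries a whole-genome
#'   duplication.
#' @param loss_fraction,gain_fraction Per-branch gene turnover fractions.
#' @param p_missing,p_spurious Homology-noise probabilities: each true pair
#'   is dropped with `p_missing`; `round(p_spurious * n_true)` spurious
#'   pairs are added.
#' @param intergenic_bp Fixed intergenic gap used to lay out bp coordinates.
#' @param te_intensity Named per-class TE insertion intensity (elements per
#'   Mbp) for `Copia`, `Gypsy`, `LINE1`, `Other`.
#' @param te_lengths Named per-class mean element length (bp).
#' @param line1_multiplier LINE1 intensity multiplier inside designated
#'   windows.
#' @param designated_per_chromosome Number of designated elevated-LINE1 gene
#'   windows per chromosome (default 0).
#' @param designated_genes Genes per designated window.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = paste0("sp", 1:5),
                       n_protos = 12L,
                       genes_per_chromosome = c(200L, 500L),
                       n_inversions = 5L, n_translocations = 1L,
                       n_fissions = 0L, n_fusions = 0L,
                       wgd_species = character(0),
                       loss_fraction = 0.05, gain_fraction = 0.02,
                       p_missing = 0.02, p_spurious = 0.02,
                       intergenic_bp = 3000L,
                       te_intensity = c(Copia = 6, Gypsy = 10, LINE1 = 8,
                                        Other = 4),
                       te_lengths = c(Copia = 5000, Gypsy = 6000,
                                      LINE1 = 3000, Other = 800),
                       line1_multiplier = 1,
                       designated_per_chromosome = 0L,
                       designated_genes = 100L,
                       seed) {
  if (missing(seed)) abort("sim_config requires a seed")
  stopifnot(
    is_count(n_protos, 1L), length(genes_per_chromosome) == 2,
    loss_fraction >= 0, loss_fraction <= 1,
    gain_fraction >= 0, p_missing >= 0, p_missing <= 1, p_spurious >= 0,
    all(wgd_species %in% species)
  )
  rec <- function(x) rep_len(x, length(species))
  structure(list(
    species = species, n_protos = as.integer(n_protos),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_inversions = rec(n_inversions),
    n_translocations = rec(n_translocations),
    n_fissions = rec(n_fissions), n_fusions = rec(n_fusions),
    wgd_species = wgd_species,
    loss_fraction = rec(loss_fraction), gain_fraction = rec(gain_fraction),
    p_missing = p_missing, p_spurious = p_spurious,
    intergenic_bp = as.integer(intergenic_bp),
    te_intensity = te_intensity, te_lengths = te_lengths,
    line1_multiplier = line1_multiplier,
    designated_per_chromosome = as.integer(designated_per_chromosome),
    designated_genes = as.integer(designated_genes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# ---- state helpers ---------------------------------------------------------

state_from_tables <- function(chrom_list) chrom_list

state_n_genes <- function(state) sum(map_int(state, nrow))

#' Apply one rearrangement event to a genome state
#'
#' The genome state is a named list of chromosomes, each a tibble of genes
#' in order (columns `uid`, `anc_proto`, `gene_len`, `strand`). Positions in
#' event parameters are 1-based gene indices at the time of the event.
#' Supported events: `inversion` (reverse an index interval, flipping
#' strands), `translocation` (reciprocal swap of two terminal segments),
#' `fission` (split after index `k`), `fusion` (append chromosome `chrom2`
#' to `chrom`), `wgd` (duplicate every chromosome, suffixing the copy with
#' `"w"`), `loss` (delete listed indices), `gain` (insert novel genes).
#'
#' @param state Genome state (named list of gene tibbles).
#' @param event A list with `type` and type-specific parameters.
#' @return The new genome state.
#' @export
apply_event <- function(state, event) {
  type <- event$type
  if (type == "inversion") {
    ch <- state[[event$chrom]]
    i <- event$from; j <- event$to
    if (is.null(ch) || i < 1 || j > nrow(ch) || i >= j) {
      abort("illegal inversion parameters")
    }
    seg <- ch[j:i, ]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    state[[event$chrom]] <- bind_rows(
      if (i > 1) ch[1:(i - 1), ], seg,
      if (j < nrow(ch)) ch[(j + 1):nrow(ch), ])
  } else if (type == "translocation") {
    c1 <- state[[event$chrom]]; c2 <- state[[event$chrom2]]
    k1 <- event$k1; k2 <- event$k2
    if (is.null(c1) || is.null(c2) || k1 < 1 || k1 >= nrow(c1) ||
        k2 < 1 || k2 >= nrow(c2)) {
      abort("illegal translocation parameters")
    }
    state[[event$chrom]] <- bind_rows(c1[1:k1, ], c2[(k2 + 1):nrow(c2), ])
    state[[event$chrom2]] <- bind_rows(c2[1:k2, ], c1[(k1 + 1):nrow(c1), ])
  } else if (type == "fission") {
    ch <- state[[event$chrom]]
    k <- event$k
    if (is.null(ch) || k < 1 || k >= nrow(ch)) {
      abort("illegal fission parameters")
    }
    state[[paste0(event$chrom, ".1")]] <- ch[1:k, ]
    state[[paste0(event$chrom, ".2")]] <- ch[(k + 1):nrow(ch), ]
    state[[event$chrom]] <- NULL
  } else if (type == "fusion") {
    c1 <- state[[event$chrom]]; c2 <- state[[event$chrom2]]
    if (is.null(c1) || is.null(c2)) abort("illegal fusion parameters")
    state[[event$chrom]] <- bind_rows(c1, c2)
    state[[event$chrom2]] <- NULL
  } else if (type == "wgd") {
    copies <- state
    names(copies) <- paste0(names(state), "w")
    state <- c(state, copies)
  } else if (type == "loss") {
    for (ch in names(event$positions)) {
      pos <- event$positions[[ch]]
      keep <- setdiff(seq_len(nrow(state[[ch]])), pos)
      state[[ch]] <- state[[ch]][keep, ]
    }
    state <- state[map_int(state, nrow) > 0]
  } else if (type == "gain") {
    ins <- event$insertions
    for (i in seq_len(nrow(ins))) {
      ch <- state[[ins$chrom[i]]]
      pos <- ins$pos[i]  # insert before this 1-based index (n+1 appends)
      new_row <- tibble(uid = NA_integer_, anc_proto = NA_character_,
                        gene_len = ins$gene_len[i], strand = "+")
      state[[ins$chrom[i]]] <- bind_rows(
        if (pos > 1) ch[1:(pos - 1), ], new_row,
        if (pos <= nrow(ch)) ch[pos:nrow(ch), ])
    }
  } else {
    abort(paste0("unknown event type: ", type))
  }
  state
}

# sample one branch's events, mutating state; returns list(state, events)
simulate_branch <- function(state, species, cfg, idx) {
  events <- list()
  push <- function(ev) {
    ev$species <- species
    events[[length(events) + 1L]] <<- ev
    state <<- apply_event(state, ev)
  }
  pick_chrom <- function(min_genes = 2L) {
    ok <- names(state)[map_int(state, nrow) >= min_genes]
    if (length(ok) == 0) return(NULL)
    ok[sample.int(length(ok), 1)]
  }
  if (species %in% cfg$wgd_species) push(list(type = "wgd"))
  for (i in seq_len(cfg$n_translocations[idx])) {
    chs <- names(state)[map_int(state, nrow) >= 2]
    if (length(chs) < 2) break
    pr <- sample(chs, 2)
    push(list(type = "translocation", chrom = pr[1], chrom2 = pr[2],
              k1 = sample.int(nrow(state[[pr[1]]]) - 1L, 1),
              k2 = sample.int(nrow(state[[pr[2]]]) - 1L, 1)))
  }
  for (i in seq_len(cfg$n_fissions[idx])) {
    ch <- pick_chrom(2L)
    if (is.null(ch)) break
    push(list(type = "fission", chrom = ch,
              k = sample.int(nrow(state[[ch]]) - 1L, 1)))
  }
  for (i in seq_len(cfg$n_fusions[idx])) {
    if (length(state) < 2) break
    pr <- sample(names(state), 2)
    push(list(type = "fusion", chrom = pr[1], chrom2 = pr[2]))
  }
  for (i in seq_len(cfg$n_inversions[idx])) {
    ch <- pick_chrom(2L)
    if (is.null(ch)) break
    n <- nrow(state[[ch]])
    ij <- sort(sample.int(n, 2))
    if (ij[1] == ij[2]) next
    push(list(type = "inversion", chrom = ch, from = ij[1], to = ij[2]))
  }
  n_loss <- round(cfg$loss_fraction[idx] * state_n_genes(state))
  if (n_loss > 0) {
    sizes <- map_int(state, nrow)
    flat <- rep(names(state), sizes)
    sel <- sample.int(length(flat), n_loss)
    positions <- lapply(names(state), function(ch) {
      offs <- cumsum(c(0, sizes))[match(ch, names(state))]
      sort(sel[flat[sel] == ch] - offs)
    })
    names(positions) <- names(state)
    positions <- positions[map_int(positions, length) > 0]
    push(list(type = "loss", positions = positions))
  }
  n_gain <- round(cfg$gain_fraction[idx] * state_n_genes(state))
  if (n_gain > 0) {
    sizes <- map_int(state, nrow)
    chs <- sample(names(state), n_gain, replace = TRUE,
                  prob = sizes / sum(sizes))
    push(list(type = "gain", insertions = tibble(
      chrom = chs,
      pos = map_int(chs, ~ sample.int(nrow(state[[.x]]) + 1L, 1)),
      gene_len = sample(800:5000, n_gain, replace = TRUE)
    )))
  }
  list(state = state, events = events)
}

# finalize a state into a public gene table + lineage map
finalize_genome <- function(state, species, intergenic_bp) {
  sizes <- map_int(state, nrow)
  ord <- order(-sizes, names(state))
  state <- state[ord]
  new_names <- paste0("chr", seq_along(state))
  rows <- list()
  for (i in seq_along(state)) {
    ch <- state[[i]]
    start <- cumsum(c(0L, head(ch$gene_len + intergenic_bp, -1)))
    rows[[i]] <- ch |>
      mutate(chromosome = new_names[i],
             start = as.integer(start),
             end = as.integer(start + .data$gene_len))
  }
  flat <- bind_rows(rows) |>
    mutate(gene_id = sprintf("%s_g%05d", species, row_number()))
  genes <- gene_table(
    flat |> select("gene_id", "chromosome", "start", "end", "strand"),
    species = species)
  map <- flat |> select("gene_id", "uid", "anc_proto") |>
    mutate(species = species)
  list(genes = genes, map = map)
}

# noisy homology table between two finalized genomes (by lineage uid)
sim_homology_pair <- function(map_a, map_b, p_missing, p_spurious,
                              self = FALSE) {
  a <- map_a |> filter(!is.na(.data$uid)) |>
    select(query_id = "gene_id", uid = "uid")
  b <- map_b |> filter(!is.na(.data$uid)) |>
    select(subject_id = "gene_id", uid = "uid")
  true_pairs <- inner_join(a, b, by = "uid",
                           relationship = "many-to-many") |>
    select("query_id", "subject_id")
  if (self) {
    ident <- true_pairs$query_id == true_pairs$subject_id
    paralogs <- true_pairs[!ident, ]
    identity <- tibble(query_id = map_a$gene_id,
                       subject_id = map_a$gene_id)
    keep <- runif(nrow(paralogs)) >= p_missing
    true_kept <- bind_rows(identity, paralogs[keep, ])
  } else {
    keep <- runif(nrow(true_pairs)) >= p_missing
    true_kept <- true_pairs[keep, ]
  }
  n_spur <- round(p_spurious * nrow(true_kept))
  spurious <- if (n_spur > 0) {
    tibble(query_id = sample(map_a$gene_id, n_spur, replace = TRUE),
           subject_id = sample(map_b$gene_id, n_spur, replace = TRUE))
  } else {
    tibble(query_id = character(), subject_id = character())
  }
  n_t <- nrow(true_kept)
  bind_rows(
    true_kept |> mutate(evalue = 10^-runif(n_t, 40, 180),
                        bitscore = round(runif(n_t, 300, 1500), 1)),
    spurious |> mutate(evalue = 10^-runif(n_spur, 6, 15),
                       bitscore = round(runif(n_spur, 60, 150), 1))
  ) |>
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)
}

# TE landscape for one finalized genome
sim_te <- function(genes, cfg, designated) {
  sizes <- chromosome_summary(genes)
  classes <- names(cfg$te_intensity)
  rows <- list()
  for (i in seq_len(nrow(sizes))) {
    ch <- sizes$chromosome[i]
    L <- sizes$length[i] + cfg$intergenic_bp
    for (cl in classes) {
      lam <- cfg$te_intensity[[cl]] * L / 1e6
      n <- rpois(1, lam)
      if (n > 0) {
        st <- as.integer(floor(runif(n, 0, L)))
        len <- as.integer(pmax(50, round(cfg$te_lengths[[cl]] *
                                           runif(n, 0.7, 1.3))))
        rows[[length(rows) + 1L]] <- tibble(
          chromosome = ch, start = st, end = st + len, te_class = cl)
      }
    }
    # elevated LINE1 inside designated windows
    des <- designated[designated$chromosome == ch, , drop = FALSE]
    m <- cfg$line1_multiplier
    if (nrow(des) > 0 && m > 1) {
      gch <- genes[genes$chromosome == ch, ]
      for (j in seq_len(nrow(des))) {
        bp0 <- gch$start[gch$rank == des$start_rank[j]]
        bp1 <- gch$end[gch$rank == des$end_rank[j]]
        W <- bp1 - bp0
        n <- rpois(1, (m - 1) * cfg$te_intensity[["LINE1"]] * W / 1e6)
        if (n > 0) {
          st <- as.integer(floor(runif(n, bp0, bp1)))
          len <- as.integer(pmax(50, round(cfg$te_lengths[["LINE1"]] *
                                             runif(n, 0.7, 1.3))))
          rows[[length(rows) + 1L]] <- tibble(
            chromosome = ch, start = st, end = st + len,
            te_class = "LINE1")
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chromosome = character(), start = integer(),
                  end = integer(), te_class = character()))
  }
  bind_rows(rows) |> arrange(.data$chromosome, .data$start)
}

#' Simulate karyotype evolution from a known ancestor
#'
#' Builds an ancestor of `n_protos` chromosomes, evolves one descendant per
#' species along a star tree (event order per branch: whole-genome
#' duplication, translocations, fissions, fusions, inversions, loss, gain),
#' and emits everything the reconstruction pipeline consumes: gene tables,
#' noisy homology tables for every species pair (plus each species against
#' itself and against the ancestor), TE interval sets, a replayable event
#' log, and the truth painting. Deterministic given the config seed; public
#' gene ids encode nothing about the truth.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `ancestor`, `genomes`, `homologies`,
#'   `te`, `designated`, `truth`, `events`, `maps`, `config`.
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    # ancestor
    n_genes_per <- sample(seq(cfg$genes_per_chromosome[1],
                              cfg$genes_per_chromosome[2]),
                          cfg$n_protos, replace = TRUE)
    anc_state <- list()
    uid0 <- 0L
    for (k in seq_len(cfg$n_protos)) {
      nm <- sprintf("A%02d", k)
      anc_state[[nm]] <- tibble(
        uid = uid0 + seq_len(n_genes_per[k]),
        anc_proto = nm,
        gene_len = sample(800:5000, n_genes_per[k], replace = TRUE),
        strand = sample(c("+", "-"), n_genes_per[k], replace = TRUE)
      )
      uid0 <- uid0 + n_genes_per[k]
    }
    anc_fin <- finalize_ancestor(anc_state, cfg$intergenic_bp)

    genomes <- list(); maps <- list(); events <- list(); te <- list()
    designated_all <- list()
    for (idx in seq_along(cfg$species)) {
      sp <- cfg$species[idx]
      br <- simulate_branch(anc_state, sp, cfg, idx)
      fin <- finalize_genome(br$state, sp, cfg$intergenic_bp)
      genomes[[sp]] <- fin$genes
      maps[[sp]] <- fin$map
      events[[sp]] <- br$events
      des <- pick_designated(fin$genes, cfg)
      designated_all[[sp]] <- des |> mutate(species = sp)
      te[[sp]] <- sim_te(fin$genes, cfg, des)
    }

    homologies <- list()
    for (i in seq_along(cfg$species)) {
      for (j in seq_along(cfg$species)) {
        if (j < i) next
        a <- cfg$species[i]; b <- cfg$species[j]
        homologies[[pair_key(a, b)]] <- sim_homology_pair(
          maps[[a]], maps[[b]], cfg$p_missing, cfg$p_spurious,
          self = i == j)
      }
    }
    for (sp in cfg$species) {
      homologies[[pair_key("ancestor", sp)]] <- sim_homology_pair(
        anc_fin$map, maps[[sp]], cfg$p_missing, cfg$p_spurious)
    }

    truth <- bind_rows(maps) |>
      select("species", "gene_id", true_proto = "anc_proto")
    ev_tbl <- tibble(
      species = unlist(map(events, ~ map_chr(.x, "species"))) %||%
        character(),
      type = unlist(map(events, ~ map_chr(.x, "type"))) %||% character(),
      event = unname(do.call(c, c(events, list(list()))))
    )
    structure(list(
      ancestor = anc_fin$genes,
      genomes = genomes,
      homologies = homologies,
      te = te,
      designated = bind_rows(designated_all),
      truth = truth,
      events = ev_tbl,
      maps = bind_rows(maps),
      config = cfg
    ), class = "sim_dataset")
  })
}

finalize_ancestor <- function(anc_state, intergenic_bp) {
  rows <- list()
  for (nm in names(anc_state)) {
    ch <- anc_state[[nm]]
    start <- cumsum(c(0L, head(ch$gene_len + intergenic_bp, -1)))
    rows[[nm]] <- ch |>
      mutate(chromosome = nm, start = as.integer(start),
             end = as.integer(start + .data$gene_len))
  }
  flat <- bind_rows(rows) |>
    mutate(gene_id = sprintf("anc_g%05d", row_number()))
  genes <- gene_table(
    flat |> select("gene_id", "chromosome", "start", "end", "strand"),
    species = "ancestor")
  map <- flat |> select("gene_id", "uid", "anc_proto") |>
    mutate(species = "ancestor")
  list(genes = genes, map = map)
}

# spaced designated elevated-LINE1 gene windows
pick_designated <- function(genes, cfg) {
  if (cfg$designated_per_chromosome < 1) {
    return(tibble(chromosome = character(), start_rank = integer(),
                  end_rank = integer()))
  }
  w <- cfg$designated_genes
  margin <- 40L
  sizes <- chromosome_summary(genes)
  rows <- list()
  for (i in seq_len(nrow(sizes))) {
    n <- sizes$n_genes[i]
    slot <- w + 2L * margin
    k <- min(cfg$designated_per_chromosome, n %/% slot)
    if (k < 1) next
    starts <- margin + (seq_len(k) - 1L) * slot +
      as.integer(floor(runif(k, 0, max(1, slot - w - 2L * margin + 1L))))
    rows[[i]] <- tibble(chromosome = sizes$chromosome[i],
                        start_rank = starts, end_rank = starts + w - 1L)
  }
  if (length(rows) == 0) {
    return(tibble(chromosome = character(), start_rank = integer(),
                  end_rank = integer()))
  }
  bind_rows(rows)
}

#' Replay a species' event log from the ancestor
#'
#' @param dataset A `sim_dataset`.
#' @param species Species id.
#' @return The replayed [gene_table()]; identical to
#'   `dataset$genomes[[species]]`.
#' @export
replay_events <- function(dataset, species) {
  cfg <- dataset$config
  anc <- dataset$ancestor
  state <- lapply(split(seq_len(nrow(anc)), anc$chromosome), function(ix) {
    g <- anc[ix, ]
    g <- g[order(g$rank), ]
    tibble(uid = match(g$gene_id, dataset$ancestor$gene_id),
           anc_proto = g$chromosome,
           gene_len = g$end - g$start, strand = g$strand)
  })
  # restore lineage uids from the ancestor map
  amap <- dataset$maps
  evs <- dataset$events |> filter(.data$species == !!species)
  for (i in seq_len(nrow(evs))) {
    state <- apply_event(state, evs$event[[i]])
  }
  finalize_genome(state, species, cfg$intergenic_bp)$genes
}
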