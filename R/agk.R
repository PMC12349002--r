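# Two-round ancestral karyotype reconstruction.
#
# Round 1 seeds proto-chromosomes from whole-chromosome homology relations
# between divergent species pairs (inversions do not affect seeding because
# relations are coverage-based). Round 2 assigns residual chromosomes to
# protos supported consistently by at least `min_species` species, founding
# new protos where residual chromosomes of enough species are collinear only
# with each other. Candidate protos are then consolidated when two or more
# species co-localize them on a single chromosome without contradiction, and
# one representative segment per proto region is selected by anchor
# continuity. Protos are finally named by descending gene count.

# ---- union-find ------------------------------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

# ---- evidence tables -------------------------------------------------------

# Flatten per-pair filtered blocks into a directed link table: one row per
# (block, direction), giving the rank span on the focal side and the partner.
flatten_links <- function(pair_blocks) {
  rows <- list()
  for (key in names(pair_blocks)) {
    fb <- pair_blocks[[key]]
    if (nrow(fb) == 0) next
    sp_a <- attr(fb, "species_a"); sp_b <- attr(fb, "species_b")
    sa <- block_spans(fb, "a"); sb <- block_spans(fb, "b")
    rows[[length(rows) + 1L]] <- tibble(
      species = sp_a, chromosome = sa$chromosome,
      lo = sa$lo, hi = sa$hi,
      partner_species = sp_b, partner_chromosome = sb$chromosome,
      plo = sb$lo, phi = sb$hi, n_pairs = sa$n_pairs,
      block_uid = paste0(key, "/", sa$block_id)
    )
    rows[[length(rows) + 1L]] <- tibble(
      species = sp_b, chromosome = sb$chromosome,
      lo = sb$lo, hi = sb$hi,
      partner_species = sp_a, partner_chromosome = sa$chromosome,
      plo = sa$lo, phi = sa$hi, n_pairs = sb$n_pairs,
      block_uid = paste0(key, "/", sa$block_id)
    )
  }
  if (length(rows) == 0) {
    return(tibble(species = character(), chromosome = character(),
                  lo = integer(), hi = integer(),
                  partner_species = character(),
                  partner_chromosome = character(), plo = integer(),
                  phi = integer(), n_pairs = integer(),
                  block_uid = character()))
  }
  bind_rows(rows)
}

# ---- round 1 ---------------------------------------------------------------

#' Seed proto-chromosomes from whole-chromosome homology relations
#'
#' Every `whole` relation between two species joins its two chromosomes into
#' one seed; seeds sharing a chromosome are unified transitively. A seed that
#' would contain two different chromosomes of the same species indicates
#' conflicting whole-chromosome evidence and is a hard error.
#'
#' @param relations Tibble with columns `species_a`, `species_b`, `chrom_a`,
#'   `chrom_b`, `relation` (as produced by [classify_homology()] plus the
#'   species ids).
#' @param species_order Builder species in priority order; relations
#'   involving other species are ignored.
#' @return Membership tibble `proto`, `species`, `chromosome`, `round`
#'   (all round 1), with provisional proto ids.
#' @export
seed_round1 <- function(relations, species_order) {
  whole <- relations |>
    filter(.data$relation == "whole",
           .data$species_a %in% species_order,
           .data$species_b %in% species_order)
  if (nrow(whole) == 0) {
    return(tibble(proto = character(), species = character(),
                  chromosome = character(), round = integer()))
  }
  node_a <- paste(whole$species_a, whole$chrom_a, sep = "\r")
  node_b <- paste(whole$species_b, whole$chrom_b, sep = "\r")
  nodes <- sort(unique(c(node_a, node_b)))
  uf <- uf_new(length(nodes))
  ia <- match(node_a, nodes); ib <- match(node_b, nodes)
  for (k in seq_along(ia)) uf <- uf_union(uf, ia[k], ib[k])
  comp <- vapply(seq_along(nodes), function(i) uf_find(uf, i), integer(1))
  parts <- do.call(rbind, strsplit(nodes, "\r", fixed = TRUE))
  members <- tibble(species = parts[, 1], chromosome = parts[, 2],
                    comp = comp)
  conflicts <- members |>
    count(.data$comp, .data$species) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    bad <- members |> filter(.data$comp %in% conflicts$comp) |>
      arrange(.data$comp, .data$species, .data$chromosome)
    abort(paste0(
      "conflicting whole-chromosome seed unification: one seed would ",
      "contain multiple chromosomes of the same species: ",
      paste(paste(bad$species, bad$chromosome, sep = ":"), collapse = ", ")))
  }
  comp_ids <- sort(unique(members$comp))
  members |>
    mutate(proto = sprintf("P%03d", match(.data$comp, comp_ids)),
           round = 1L) |>
    arrange(.data$proto, match(.data$species, species_order),
            .data$chromosome) |>
    select("proto", "species", "chromosome", "round")
}

# ---- round 2 ---------------------------------------------------------------

# total overlap (genes) between interval [lo, hi] and a set of intervals
interval_overlap <- function(lo, hi, los, his) {
  if (length(los) == 0) return(0L)
  sum(pmax(0L, pmin(hi, his) - pmax(lo, los) + 1L))
}

#' Assign residual chromosome segments to proto-chromosomes (round 2)
#'
#' After round-1 seeds are masked out, the unexplained parts of every
#' remaining chromosome are assigned at segment level: the hull of the block
#' spans linking a chromosome to one proto's members becomes a new member
#' segment of that proto, provided the evidence involves at least
#' `min_species` distinct species (the chromosome's own species counts as
#' one). A chromosome can therefore contribute different segments to
#' different protos, as translocation or fusion products do. Segments whose
#' proto links conflict (overlapping hulls claimed by two protos) are
#' reported and left unassigned. Finally, residual segments linked only to
#' each other found a new proto when their connected component spans at
#' least `min_species` species.
#'
#' @param seeds Round-1 membership tibble from [seed_round1()].
#' @param links Directed block-link table (internal; built from the filtered
#'   pairwise block sets).
#' @param genomes Named list of builder [gene_table()]s.
#' @param species_order Builder species in priority order.
#' @param min_species Support bar (default 3 species).
#' @return Membership tibble `proto`, `species`, `chromosome`, `round`,
#'   `start_rank`, `end_rank` (one row per member segment), with attributes
#'   `unassigned` and `provenance`.
#' @export
assign_round2 <- function(seeds, links, genomes, species_order,
                          min_species = 3L) {
  all_chroms <- bind_rows(lapply(species_order, function(s) {
    chromosome_summary(genomes[[s]]) |> mutate(species = s)
  })) |>
    arrange(match(.data$species, species_order), .data$chromosome)
  membership <- seeds |>
    left_join(all_chroms, by = c("species", "chromosome")) |>
    mutate(start_rank = 0L, end_rank = .data$n_genes - 1L) |>
    select("proto", "species", "chromosome", "round", "start_rank",
           "end_rank")
  links <- links |>
    filter(.data$species %in% species_order,
           .data$partner_species %in% species_order)
  prov <- list()

  # fraction of a link's span lying outside the assigned segments of its
  # own chromosome / overlapping a proto segment on the partner chromosome
  link_outside <- function(lk, memb) {
    map_dbl(seq_len(nrow(lk)), function(i) {
      seg <- memb[memb$species == lk$species[i] &
                    memb$chromosome == lk$chromosome[i], , drop = FALSE]
      ov <- interval_overlap(lk$lo[i], lk$hi[i], seg$start_rank,
                             seg$end_rank)
      1 - ov / (lk$hi[i] - lk$lo[i] + 1L)
    })
  }
  link_proto <- function(lk, memb) {
    map_chr(seq_len(nrow(lk)), function(i) {
      seg <- memb[memb$species == lk$partner_species[i] &
                    memb$chromosome == lk$partner_chromosome[i], ,
                  drop = FALSE]
      if (nrow(seg) == 0) return(NA_character_)
      w <- lk$phi[i] - lk$plo[i] + 1L
      ov <- pmax(0L, pmin(lk$phi[i], seg$end_rank) -
                   pmax(lk$plo[i], seg$start_rank) + 1L)
      best <- which.max(ov)
      if (ov[best] >= 0.5 * w) seg$proto[best] else NA_character_
    })
  }

  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(all_chroms))) {
      s <- all_chroms$species[i]; ch <- all_chroms$chromosome[i]
      own <- membership[membership$species == s &
                          membership$chromosome == ch, , drop = FALSE]
      if (any(own$round == 1L)) next  # seeded whole
      lk <- links |>
        filter(.data$species == s, .data$chromosome == ch)
      if (nrow(lk) == 0) next
      lk <- lk[link_outside(lk, membership) >= 0.5, , drop = FALSE]
      if (nrow(lk) == 0) next
      lk$partner_proto <- link_proto(lk, membership)
      lk <- lk |>
        filter(!is.na(.data$partner_proto), .data$partner_species != s)
      if (nrow(lk) == 0) next
      votes <- lk |>
        group_by(.data$partner_proto) |>
        summarise(n_sp = dplyr::n_distinct(.data$partner_species),
                  lo = min(.data$lo), hi = max(.data$hi),
                  anchors = sum(.data$n_pairs), .groups = "drop") |>
        mutate(support = .data$n_sp + 1L) |>
        filter(.data$support >= min_species,
               !.data$partner_proto %in% own$proto) |>
        arrange(dplyr::desc(.data$support), dplyr::desc(.data$anchors),
                .data$partner_proto)
      if (nrow(votes) == 0) next
      acc_lo <- own$start_rank; acc_hi <- own$end_rank
      for (v in seq_len(nrow(votes))) {
        w <- votes$hi[v] - votes$lo[v] + 1L
        ov <- interval_overlap(votes$lo[v], votes$hi[v], acc_lo, acc_hi)
        if (ov < 0.5 * w) {
          membership <- bind_rows(membership, tibble(
            proto = votes$partner_proto[v], species = s, chromosome = ch,
            round = 2L, start_rank = votes$lo[v], end_rank = votes$hi[v]))
          acc_lo <- c(acc_lo, votes$lo[v]); acc_hi <- c(acc_hi, votes$hi[v])
          prov[[length(prov) + 1L]] <- tibble(
            event = "round2_assign", species = s, chromosome = ch,
            proto = votes$partner_proto[v],
            detail = paste0("support=", votes$support[v], " span=",
                            votes$lo[v], "-", votes$hi[v]))
          changed <- TRUE
        } else {
          prov[[length(prov) + 1L]] <- tibble(
            event = "round2_conflict", species = s, chromosome = ch,
            proto = votes$partner_proto[v],
            detail = "overlapping claim by competing proto")
        }
      }
    }
    if (!changed) break
  }

  # new protos from residual segments linked only to each other
  repeat {
    out_self <- link_outside(links, membership)
    swapped <- links |>
      rename(species = "partner_species", chromosome = "partner_chromosome",
             lo = "plo", hi = "phi", partner_species = "species",
             partner_chromosome = "chromosome", plo = "lo", phi = "hi")
    out_partner <- link_outside(swapped, membership)
    res <- links[out_self >= 0.5 & out_partner >= 0.5 &
                   links$species != links$partner_species, , drop = FALSE]
    if (nrow(res) == 0) break
    keys <- unique(c(paste(res$species, res$chromosome),
                     paste(res$partner_species, res$partner_chromosome)))
    uf <- uf_new(length(keys))
    ii <- match(paste(res$species, res$chromosome), keys)
    jj <- match(paste(res$partner_species, res$partner_chromosome), keys)
    for (k in seq_along(ii)) uf <- uf_union(uf, ii[k], jj[k])
    comp <- vapply(seq_along(keys), function(i) uf_find(uf, i), integer(1))
    key_sp <- sub(" .*$", "", keys)
    made_one <- FALSE
    next_id <- max(c(0L, as.integer(sub("^P", "",
                                        unique(membership$proto))))) + 1L
    for (cp in sort(unique(comp))) {
      sel <- which(comp == cp)
      if (dplyr::n_distinct(key_sp[sel]) < min_species) {
        prov[[length(prov) + 1L]] <- tibble(
          event = "round2_unassigned", species = NA_character_,
          chromosome = paste(keys[sel], collapse = ","),
          proto = NA_character_,
          detail = paste0("species support ",
                          dplyr::n_distinct(key_sp[sel]), " < ",
                          min_species))
        next
      }
      pid <- sprintf("P%03d", next_id); next_id <- next_id + 1L
      made_one <- TRUE
      for (ky in keys[sel]) {
        s <- sub(" .*$", "", ky); ch <- sub("^[^ ]+ ", "", ky)
        span <- res |> filter(.data$species == s, .data$chromosome == ch)
        span2 <- res |> filter(.data$partner_species == s,
                               .data$partner_chromosome == ch)
        lo <- min(c(span$lo, span2$plo)); hi <- max(c(span$hi, span2$phi))
        membership <- bind_rows(membership, tibble(
          proto = pid, species = s, chromosome = ch, round = 2L,
          start_rank = lo, end_rank = hi))
      }
      prov[[length(prov) + 1L]] <- tibble(
        event = "round2_new_proto", species = NA_character_,
        chromosome = NA_character_, proto = pid,
        detail = paste(keys[sel], collapse = ","))
    }
    if (!made_one) break
  }

  covered <- membership |>
    group_by(.data$species, .data$chromosome) |>
    summarise(cov = sum(.data$end_rank - .data$start_rank + 1L),
              .groups = "drop")
  unassigned <- all_chroms |>
    left_join(covered, by = c("species", "chromosome")) |>
    mutate(cov = dplyr::coalesce(.data$cov, 0L)) |>
    filter(.data$cov < 0.5 * .data$n_genes) |>
    select("species", "chromosome")
  attr(membership, "unassigned") <- unassigned
  attr(membership, "provenance") <-
    if (length(prov)) bind_rows(prov) else tibble(
      event = character(), species = character(), chromosome = character(),
      proto = character(), detail = character())
  membership
}

# ---- consolidation ---------------------------------------------------------

#' Consolidate partial proto-chromosomes
#'
#' Two candidate protos are merged into one ancestral chromosome when their
#' member segments are directly homologous — block evidence connecting a
#' member segment of one to a member segment of the other — across at least
#' two distinct species pairs, and no contradiction exists: a species
#' carrying the two protos as different near-whole chromosomes shows they
#' were ancestrally distinct, and blocks that merely sit next to each other
#' on a rearranged junction chromosome are not merge evidence. Merged protos
#' keep their original pieces as separate regions for representative
#' selection.
#'
#' @param membership Membership tibble (rounds 1-2).
#' @param links Directed block-link table.
#' @param species_order Builder species.
#' @param genomes Named list of builder [gene_table()]s (used to decide
#'   which member chromosomes count as whole-chromosome evidence).
#' @return `membership` with a `region` column (the pre-merge proto id) and
#'   merged `proto` ids; merge events in `attr(, "merges")`.
#' @export
consolidate <- function(membership, links, species_order, genomes) {
  membership$region <- membership$proto
  protos <- sort(unique(membership$proto))
  if (length(protos) < 2) {
    attr(membership, "merges") <- tibble(proto_a = character(),
                                         proto_b = character())
    return(membership)
  }
  # annotate every directed link with the protos its two spans belong to
  # (a span must overlap a member segment by >= 50% to count)
  seg_all <- membership |>
    select("proto", "species", "chromosome", "start_rank", "end_rank")
  own_proto <- links |>
    mutate(.row = row_number()) |>
    inner_join(seg_all, by = c("species", "chromosome"),
               relationship = "many-to-many") |>
    mutate(w = .data$hi - .data$lo + 1L,
           ov = pmax(0L, pmin(.data$hi, .data$end_rank) -
                       pmax(.data$lo, .data$start_rank) + 1L)) |>
    filter(.data$ov >= 0.5 * .data$w) |>
    distinct(.data$.row, own = .data$proto)
  partner_proto <- links |>
    mutate(.row = row_number()) |>
    inner_join(seg_all, by = c(partner_species = "species",
                               partner_chromosome = "chromosome"),
               relationship = "many-to-many") |>
    mutate(w = .data$phi - .data$plo + 1L,
           ov = pmax(0L, pmin(.data$phi, .data$end_rank) -
                       pmax(.data$plo, .data$start_rank) + 1L)) |>
    filter(.data$ov >= 0.5 * .data$w) |>
    distinct(.data$.row, prt = .data$proto)
  direct <- links |>
    mutate(.row = row_number()) |>
    inner_join(own_proto, by = ".row", relationship = "many-to-many") |>
    inner_join(partner_proto, by = ".row", relationship = "many-to-many") |>
    filter(.data$own != .data$prt)
  # a chromosome counts as whole-chromosome evidence for a proto only when
  # the proto's segments cover most of it; a minor translocated fragment is
  # a rearrangement product, not proof the two protos were distinct
  sizes <- bind_rows(lapply(species_order, function(s) {
    chromosome_summary(genomes[[s]]) |> mutate(species = s)
  }))
  msz <- membership |>
    inner_join(sizes, by = c("species", "chromosome")) |>
    group_by(.data$proto, .data$species, .data$chromosome, .data$n_genes) |>
    summarise(cov = sum(.data$end_rank - .data$start_rank + 1L),
              .groups = "drop") |>
    filter(.data$cov >= 0.8 * .data$n_genes)
  hosts <- split(paste(msz$species, msz$chromosome), msz$proto)
  hosts <- lapply(protos, function(p) unique(hosts[[p]]))
  names(hosts) <- protos
  # contradiction: some species carries the two protos as near-whole
  # chromosomes apart (and neither of those chromosomes hosts both)
  contradicted <- function(i, j) {
    hi_ <- hosts[[i]]; hj_ <- hosts[[j]]
    both <- intersect(hi_, hj_)
    only_i <- setdiff(hi_, both); only_j <- setdiff(hj_, both)
    length(intersect(sub(" .*$", "", only_i),
                     sub(" .*$", "", only_j))) > 0
  }
  cand <- list()
  for (i in seq_along(protos)) {
    for (j in seq_along(protos)) {
      if (j <= i) next
      dd <- direct |>
        filter((.data$own == protos[i] & .data$prt == protos[j]) |
                 (.data$own == protos[j] & .data$prt == protos[i]))
      n_sp_pairs <- dd |>
        mutate(k = ifelse(.data$species < .data$partner_species,
                          paste(.data$species, .data$partner_species),
                          paste(.data$partner_species, .data$species))) |>
        distinct(.data$k) |>
        nrow()
      if (n_sp_pairs < 2) next
      if (contradicted(i, j)) next
      cand[[length(cand) + 1L]] <- tibble(i = i, j = j,
                                          support = n_sp_pairs)
    }
  }
  uf <- uf_new(length(protos))
  merges <- list()
  if (length(cand) > 0) {
    cand <- bind_rows(cand) |>
      arrange(dplyr::desc(.data$support), .data$i, .data$j)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      # refuse a merge whose transitive closure would join a contradicted
      # pair of protos
      trial <- uf_union(uf, i, j)
      roots <- vapply(seq_along(protos), function(k) uf_find(trial, k),
                      integer(1))
      ok <- TRUE
      for (a in seq_along(protos)) {
        for (b in seq_along(protos)) {
          if (b <= a || roots[a] != roots[b]) next
          if (contradicted(a, b)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        uf <- trial
        merges[[length(merges) + 1L]] <- tibble(proto_a = protos[i],
                                                proto_b = protos[j])
      }
    }
  }
  root <- vapply(seq_along(protos), function(i) uf_find(uf, i), integer(1))
  merged_id <- protos[root]
  membership$proto <- merged_id[match(membership$proto, protos)]
  attr(membership, "merges") <-
    if (length(merges)) bind_rows(merges) else
      tibble(proto_a = character(), proto_b = character())
  membership
}

# ---- representative selection ---------------------------------------------

#' Select representative segments and finalize the ancestral karyotype
#'
#' Within each proto region carrying candidates from several species, the
#' segment with the highest continuity (anchors in the segment divided by
#' its rank span) is kept; ties go to the segment with more anchors, then to
#' the lexicographically first (species, chromosome). Proto ids are then
#' assigned by descending gene count (`AGK1` is the largest), and the
#' ancestral gene list is the concatenation of representative segments with
#' their source-species provenance.
#'
#' @param membership Membership tibble with `region` column
#'   (from [consolidate()]).
#' @param links Directed block-link table.
#' @param genomes Named list of builder [gene_table()]s.
#' @return An `ancestral_karyotype` object: list with `segments` (one row
#'   per representative segment), `members`, `genes` (the ancestral
#'   pseudo-genome as a [gene_table()]), `source` (per ancestral gene its
#'   source species/chromosome/rank), and `provenance`.
#' @export
select_representatives <- function(membership, links, genomes) {
  if (nrow(membership) == 0) abort("no proto-chromosome candidates to select from")
  regions <- membership |>
    distinct(.data$proto, .data$region)
  seg_rows <- list()
  for (r in seq_len(nrow(regions))) {
    cand <- membership |>
      filter(.data$proto == regions$proto[r],
             .data$region == regions$region[r])
    if (nrow(cand) == 0) abort("proto region with zero candidates")
    others <- paste(cand$species, cand$chromosome)
    score <- purrr::pmap(cand, function(species, chromosome, start_rank,
                                        end_rank, ...) {
      lk <- links |>
        filter(.data$species == !!species, .data$chromosome == !!chromosome,
               paste(.data$partner_species, .data$partner_chromosome) %in%
                 setdiff(others, paste(!!species, !!chromosome)),
               .data$lo <= !!end_rank, .data$hi >= !!start_rank)
      n_anchors <- sum(lk$n_pairs)
      span <- end_rank - start_rank + 1L
      list(n_anchors = n_anchors, span = span,
           continuity = n_anchors / span)
    })
    cand$n_anchors <- map_dbl(score, "n_anchors")
    cand$continuity <- map_dbl(score, "continuity")
    # only candidates covering (almost) the full region extent compete on
    # continuity; a short dense fragment must not displace a full segment
    span_max <- max(cand$end_rank - cand$start_rank + 1L)
    best <- cand |>
      filter(.data$end_rank - .data$start_rank + 1L >= 0.8 * span_max) |>
      arrange(dplyr::desc(.data$continuity), dplyr::desc(.data$n_anchors),
              .data$species, .data$chromosome) |>
      slice(1)
    n_genes <- genomes[[best$species]] |>
      filter(.data$chromosome == best$chromosome,
             .data$rank >= best$start_rank, .data$rank <= best$end_rank) |>
      nrow()
    seg_rows[[r]] <- best |>
      mutate(n_genes = n_genes) |>
      select("proto", "region", "species", "chromosome", "start_rank",
             "end_rank", "round", "n_genes", "continuity")
  }
  segments <- bind_rows(seg_rows)
  # name protos by descending gene count
  totals <- segments |>
    group_by(.data$proto) |>
    summarise(gene_count = sum(.data$n_genes),
              key = paste0(first(.data$species), first(.data$chromosome)),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$gene_count), .data$key) |>
    mutate(agk = paste0("AGK", row_number()))
  relabel <- setNames(totals$agk, totals$proto)
  segments$proto <- unname(relabel[segments$proto])
  membership$proto <- unname(relabel[membership$proto])
  segments <- segments |>
    group_by(.data$proto) |>
    arrange(dplyr::desc(.data$n_genes), .by_group = TRUE) |>
    ungroup() |>
    arrange(as.integer(sub("^AGK", "", .data$proto)))

  # ancestral pseudo-genome: concatenate representative segments
  gene_rows <- list()
  src_rows <- list()
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    g <- genomes[[sg$species]] |>
      filter(.data$chromosome == sg$chromosome,
             .data$rank >= sg$start_rank, .data$rank <= sg$end_rank) |>
      arrange(.data$rank)
    if (nrow(g) == 0) next
    offset0 <- min(g$start)
    gene_rows[[i]] <- tibble(
      gene_id = g$gene_id, chromosome = sg$proto,
      start = g$start - offset0, end = g$end - offset0,
      strand = g$strand, seg_index = i
    )
    src_rows[[i]] <- tibble(
      gene_id = g$gene_id, source_species = sg$species,
      source_chromosome = sg$chromosome, source_rank = g$rank
    )
  }
  genes_raw <- bind_rows(gene_rows)
  # lay segments of one proto end to end with a fixed 10 kb joint
  genes_raw <- genes_raw |>
    group_by(.data$chromosome) |>
    arrange(.data$seg_index, .data$start, .by_group = TRUE) |>
    mutate(offset = {
      seg_len <- tapply(.data$end, .data$seg_index, max)
      seg_ids <- as.integer(names(seg_len))
      offs <- cumsum(c(0, head(seg_len + 10000L, -1)))
      offs[match(.data$seg_index, seg_ids)]
    }) |>
    ungroup() |>
    mutate(start = .data$start + .data$offset,
           end = .data$end + .data$offset) |>
    select(-"offset", -"seg_index")
  agk_genes <- gene_table(genes_raw, species = "AGK")
  out <- structure(list(
    segments = segments,
    members = membership,
    genes = agk_genes,
    source = bind_rows(src_rows),
    provenance = attr(membership, "provenance", exact = TRUE) %||% tibble()
  ), class = "ancestral_karyotype")
  out
}

# ---- orchestrator ----------------------------------------------------------

#' Reconstruct an ancestral karyotype from multiple genomes
#'
#' Runs the full two-round reconstruction: pairwise anchor building and
#' block chaining over every pair of builder species, whole-chromosome
#' relation classification, round-1 seeding, round-2 residual assignment,
#' consolidation, and representative selection.
#'
#' @param genomes Named list of [gene_table()]s.
#' @param homologies Named list of filtered homology tibbles keyed
#'   `"<speciesA>|<speciesB>"` (query ids from the first species). Either
#'   direction may be supplied for a pair.
#' @param species_order Builder species in priority order (default: all of
#'   `names(genomes)`).
#' @param max_gap,min_pairs Chaining parameters (see [chain_anchors()]).
#' @param theta_whole,theta_arm Relation thresholds (see
#'   [classify_homology()]).
#' @param min_species Round-2 support bar.
#' @return An `ancestral_karyotype`; see [select_representatives()]. The
#'   per-pair filtered blocks are attached as `attr(, "pair_blocks")` for
#'   reuse (e.g. painting diagnostics).
#' @export
build_ancestral_karyotype <- function(genomes, homologies,
                                      species_order = names(genomes),
                                      max_gap = 25L, min_pairs = 5L,
                                      theta_whole = 0.8, theta_arm = 0.6,
                                      min_species = 3L) {
  stopifnot(all(species_order %in% names(genomes)))
  pairs <- utils::combn(species_order, 2, simplify = FALSE)
  pair_blocks <- list()
  relations <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    h <- get_pair_homology(homologies, a, b)
    anc <- build_anchors(genomes[[a]], genomes[[b]], h)
    fb <- filter_blocks(chain_anchors(anc, max_gap = max_gap,
                                      min_pairs = min_pairs),
                        min_pairs = min_pairs)
    pair_blocks[[pair_key(a, b)]] <- fb
    rel <- classify_homology(fb, genomes[[a]], genomes[[b]],
                             theta_whole = theta_whole,
                             theta_arm = theta_arm)
    if (nrow(rel) > 0) {
      relations[[pair_key(a, b)]] <- rel |>
        mutate(species_a = a, species_b = b)
    }
  }
  relations <- if (length(relations)) bind_rows(relations) else
    tibble(chrom_a = character(), chrom_b = character(),
           coverage_ab = double(), coverage_ba = double(),
           relation = character(), species_a = character(),
           species_b = character())
  links <- flatten_links(pair_blocks)
  seeds <- seed_round1(relations, species_order)
  membership <- assign_round2(seeds, links, genomes, species_order,
                              min_species = min_species)
  membership <- consolidate(membership, links, species_order, genomes)
  agk <- select_representatives(membership, links, genomes)
  attr(agk, "pair_blocks") <- pair_blocks
  attr(agk, "relations") <- relations
  agk
}

# fetch a pair's homology table, swapping direction if stored the other way
get_pair_homology <- function(homologies, a, b) {
  k1 <- pair_key(a, b); k2 <- pair_key(b, a)
  if (!is.null(homologies[[k1]])) return(homologies[[k1]])
  if (!is.null(homologies[[k2]])) {
    h <- homologies[[k2]]
    return(h |>
             rename(query_id = "subject_id", subject_id = "query_id") |>
             select("query_id", "subject_id", dplyr::everything()))
  }
  abort(paste0("no homology table for species pair ", a, " / ", b))
}

#' Treat a single genome as an ancestral karyotype
#'
#' Each chromosome becomes one proto-chromosome (named by descending gene
#' count), with the genome itself as the representative source. Useful as a
#' reference karyotype for painting and for self-projection checks.
#'
#' @param genes A [gene_table()].
#' @return An `ancestral_karyotype`.
#' @export
as_ancestral_karyotype <- function(genes) {
  sizes <- chromosome_summary(genes) |>
    arrange(dplyr::desc(.data$n_genes), .data$chromosome) |>
    mutate(proto = paste0("AGK", row_number()))
  membership <- sizes |>
    mutate(species = attr(genes, "species") %||% "genome",
           round = 1L, start_rank = 0L, end_rank = .data$n_genes - 1L,
           region = .data$proto) |>
    select("proto", "species", "chromosome", "round", "start_rank",
           "end_rank", "region")
  genomes <- list(genes)
  names(genomes) <- membership$species[1]
  select_representatives(membership, flatten_links(list()), genomes)
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("<ancestral_karyotype> ", nrow(distinct(x$segments, .data$proto)),
      " proto-chromosomes, ", nrow(x$genes), " genes\n", sep = "")
  print(x$segments, n = 20)
  invisible(x)
}
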