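# Bespoke tab-separated on-disk formats for blocks and paintings.
# Blocks: two comment header lines, then per block one ">"-prefixed header
# line (block_id, chrom_a, chrom_b, orientation, n_pairs) followed by exactly
# n_pairs anchor lines (gene_a, gene_b, rank_a, rank_b).

#' Write synteny blocks to a tab-separated file
#'
#' @param blocks A `synteny_blocks` tibble.
#' @param path Output path.
#' @return `path`, invisibly. [read_synteny_blocks()] reproduces the object
#'   exactly.
#' @export
write_synteny_blocks <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# karyoforge blocks v1",
    paste0("# species_a=", attr(blocks, "species_a") %||% "a",
           "\tspecies_b=", attr(blocks, "species_b") %||% "b")
  ), con)
  for (i in seq_len(nrow(blocks))) {
    writeLines(paste(">", paste(blocks$block_id[i], blocks$chrom_a[i],
                                blocks$chrom_b[i], blocks$orientation[i],
                                blocks$n_pairs[i], sep = "\t"), sep = ""), con)
    a <- blocks$anchors[[i]]
    writeLines(paste(a$gene_a, a$gene_b, a$rank_a, a$rank_b, sep = "\t"), con)
  }
  invisible(path)
}

#' Read synteny blocks written by [write_synteny_blocks()]
#'
#' @param path Path to a block file.
#' @return A `synteny_blocks` tibble.
#' @export
read_synteny_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^# species_a=", lines)]
  sp_a <- "a"; sp_b <- "b"
  if (length(meta) == 1) {
    f <- strsplit(sub("^# ", "", meta), "\t")[[1]]
    sp_a <- sub("^species_a=", "", f[1])
    sp_b <- sub("^species_b=", "", f[2])
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^>", lines[i])) {
      abort(paste0("expected block header at line ", i, " of ", path))
    }
    h <- strsplit(sub("^>", "", lines[i]), "\t")[[1]]
    n <- as.integer(h[5])
    if (i + n > length(lines) ||
        any(grepl("^>", lines[seq_len(n) + i]))) {
      abort(paste0("truncated block ", h[1], ": expected ", n,
                   " anchor lines"))
    }
    af <- strsplit(lines[seq_len(n) + i], "\t")
    rows[[length(rows) + 1L]] <- tibble(
      block_id = h[1], chrom_a = h[2], chrom_b = h[3], orientation = h[4],
      n_pairs = n,
      anchors = list(tibble(
        gene_a = map_chr(af, 1), gene_b = map_chr(af, 2),
        chrom_a = h[2], chrom_b = h[3],
        rank_a = as.integer(map_chr(af, 3)),
        rank_b = as.integer(map_chr(af, 4))
      ))
    )
    i <- i + n + 1L
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(block_id = character(), chrom_a = character(),
           chrom_b = character(), orientation = character(),
           n_pairs = integer(), anchors = list())
  out <- new_kf_tbl(out, "synteny_blocks")
  attr(out, "species_a") <- sp_a
  attr(out, "species_b") <- sp_b
  out
}

#' Write a karyotype painting as segment lines
#'
#' One line per maximal run of a single proto-chromosome assignment:
#' species, chromosome, start rank, end rank (inclusive), proto id, and the
#' number of genes supporting the run. Unpainted gaps are emitted with the
#' sentinel proto id `NA`.
#'
#' @param painting A `painting` tibble from [project_karyotype()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_painting <- function(painting, path) {
  seg <- painting_segments(painting)
  readr::write_tsv(seg, path, col_names = TRUE, na = "NA")
  invisible(path)
}

#' Read a painting segment file written by [write_painting()]
#'
#' @param path Path to a painting file.
#' @return Segment tibble (`species`, `chromosome`, `start_rank`,
#'   `end_rank`, `proto`, `n_genes`).
#' @export
read_painting_segments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species = readr::col_character(),
                    chromosome = readr::col_character(),
                    start_rank = readr::col_integer(),
                    end_rank = readr::col_integer(),
                    proto = readr::col_character(),
                    n_genes = readr::col_integer()
                  ))
}

#' Collapse a per-gene painting into maximal segments
#'
#' @param painting A `painting` tibble (`species`, `chromosome`, `rank`,
#'   `proto`).
#' @return One row per maximal run of a single `proto` value (including `NA`
#'   runs) with its rank range and gene count.
#' @export
painting_segments <- function(painting) {
  painting |>
    arrange(.data$species, .data$chromosome, .data$rank) |>
    group_by(.data$species, .data$chromosome) |>
    mutate(
      .p = dplyr::coalesce(.data$proto, "\r<NA>"),
      run = cumsum(.data$.p != lag(.data$.p, default = "\r<START>"))
    ) |>
    group_by(.data$species, .data$chromosome, .data$run) |>
    summarise(start_rank = min(.data$rank), end_rank = max(.data$rank),
              proto = first(.data$proto), n_genes = dplyr::n(),
              .groups = "drop") |>
    select("species", "chromosome", "start_rank", "end_rank", "proto",
           "n_genes")
}
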