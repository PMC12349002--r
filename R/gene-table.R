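#' Build a gene table from gene model records
#'
#' A gene table is the coordinate system for all synteny work: one row per
#' gene model, ordered by position, with a 0-based `rank` column giving each
#' gene's order index within its chromosome. Internally all base-pair
#' coordinates are 0-based half-open regardless of the input format.
#'
#' @param genes A data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, and optionally `strand` (defaults to `"+"`).
#' @param species Species identifier attached to every row.
#' @param chromosomes Optional character vector of chromosome ids to keep;
#'   genes on any other sequence (e.g. unplaced scaffolds) are dropped and the
#'   dropped count is recorded in the `n_excluded` attribute.
#' @return A tibble of class `gene_table` with columns `species`,
#'   `chromosome`, `gene_id`, `start`, `end`, `strand`, `rank`, sorted by
#'   `(chromosome, start)`. Ranks within each chromosome are consecutive
#'   `0..n-1`.
#' @export
gene_table <- function(genes, species = "genome", chromosomes = NULL) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chromosome", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("`genes` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "+")

  n_excluded <- 0L
  if (!is.null(chromosomes)) {
    keep <- genes$chromosome %in% chromosomes
    n_excluded <- sum(!keep)
    genes <- genes[keep, , drop = FALSE]
  }
  if (nrow(genes) > 0) {
    bad <- which(!(genes$start < genes$end))
    if (length(bad) > 0) {
      abort(paste0("start must be < end for every gene; first offender: ",
                   genes$gene_id[bad[1]]))
    }
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup) > 0) {
      abort(paste0("duplicate gene_id: ", dup[1]))
    }
  }

  out <- genes |>
    mutate(
      species = species,
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    ) |>
    arrange(.data$chromosome, .data$start) |>
    group_by(.data$chromosome) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("species", "chromosome", "gene_id", "start", "end",
           "strand", "rank")
  out <- new_kf_tbl(out, "gene_table")
  attr(out, "species") <- species
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read gene models from GFF3 or BED into a gene table
#'
#' Parsing of the standard formats is delegated to [rtracklayer::import()];
#' a light pre-scan first checks field counts so that a malformed record is
#' reported with its line number. For GFF3, features of type `gene` are used
#' (all features if the file has none typed `gene`), identified by their `ID`
#' attribute. Inputs are expected to carry one model per gene (splice
#' variants pre-collapsed).
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param chromosomes Optional chromosome id whitelist; genes on other
#'   sequences (scaffolds) are excluded and counted.
#' @param species Species id stored in the table.
#' @return A [gene_table()] tibble; the number of excluded scaffold genes is
#'   in `attr(x, "n_excluded")`.
#' @export
read_gene_table <- function(path, format = c("gff3", "bed"),
                            chromosomes = NULL, species = "genome") {
  format <- match.arg(format)
  prescan_tabular(path, format)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    warn(paste0("no records in ", path, "; returning empty gene table"))
    return(gene_table(
      tibble(gene_id = character(), chromosome = character(),
             start = integer(), end = integer(), strand = character()),
      species = species, chromosomes = chromosomes
    ))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  df <- as_tibble(as.data.frame(gr))
  if (format == "gff3") {
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- filter(df, .data$type == "gene")
    }
    ids <- if ("ID" %in% names(df)) df$ID else df$Name
    if (is.null(ids) || anyNA(ids)) {
      abort("GFF3 gene features must carry unique ID attributes")
    }
    df$gene_id <- as.character(ids)
  } else {
    if (!"name" %in% names(df) || anyNA(df$name)) {
      abort("BED records must carry a name field (column 4) for the gene id")
    }
    df$gene_id <- as.character(df$name)
  }
  genes <- tibble(
    gene_id = df$gene_id,
    chromosome = as.character(df$seqnames),
    # GRanges is 1-based closed; internal convention is 0-based half-open
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
  gt <- gene_table(genes, species = species, chromosomes = chromosomes)
  if (attr(gt, "n_excluded") > 0) {
    inform(paste0(attr(gt, "n_excluded"),
                  " gene(s) on sequences outside the chromosome list excluded"))
  }
  gt
}

# Field-count / numeric pre-scan that names the offending line number.
prescan_tabular <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "gff3") {
      if (length(f) != 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
          is.na(suppressWarnings(as.integer(f[5])))) {
        abort(paste0("malformed GFF3 record at line ", i, " of ", path))
      }
    } else if (format == "bed") {
      if (length(f) < 3 || is.na(suppressWarnings(as.integer(f[2]))) ||
          is.na(suppressWarnings(as.integer(f[3])))) {
        abort(paste0("malformed BED record at line ", i, " of ", path))
      }
    }
  }
  invisible(TRUE)
}

#' Per-chromosome gene counts of a gene table
#'
#' @param genes A [gene_table()].
#' @return A tibble with `chromosome`, `n_genes`, and `length` (bp span to
#'   the last gene end).
#' @export
chromosome_summary <- function(genes) {
  genes |>
    group_by(.data$chromosome) |>
    summarise(n_genes = dplyr::n(), length = max(.data$end), .groups = "drop")
}
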