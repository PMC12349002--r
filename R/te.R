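#' Normalize transposable-element class labels
#'
#' Repeat annotations come with heterogeneous class strings
#' (`"LTR/Copia"`, `"LINE/L1"`, ...). These are folded case-insensitively
#' onto the four canonical labels used throughout the package: `Copia`,
#' `Gypsy`, `LINE1`, and `Other`.
#'
#' @param x Character vector of raw class labels.
#' @return Character vector over `{Copia, Gypsy, LINE1, Other}`.
#' @export
normalize_te_class <- function(x) {
  lx <- tolower(x)
  dplyr::case_when(
    grepl("copia", lx) ~ "Copia",
    grepl("gypsy", lx) ~ "Gypsy",
    grepl("l1", lx) | grepl("line-1", lx) | grepl("line1", lx) ~ "LINE1",
    TRUE ~ "Other"
  )
}

#' Read transposable-element intervals from GFF3 or BED
#'
#' The repeat class is taken from the BED name column or, for GFF3, from the
#' feature type (falling back on the `ID`/`Name` attribute), then normalized
#' with [normalize_te_class()]. Records with `start >= end` are rejected with
#' a warning rather than an error, since repeat annotations routinely carry
#' a few degenerate rows.
#'
#' @inheritParams read_gene_table
#' @return A tibble with `chromosome`, `start`, `end` (0-based half-open),
#'   `te_class`.
#' @export
read_te_intervals <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  prescan_tabular(path, format)
  # drop degenerate records up front (rtracklayer refuses whole files for them)
  lines <- readLines(path, warn = FALSE)
  is_rec <- !grepl("^#", lines) & nzchar(trimws(lines))
  bad_rec <- vapply(seq_along(lines), function(i) {
    if (!is_rec[i]) return(FALSE)
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (format == "gff3") as.integer(f[4]) > as.integer(f[5])
    else as.integer(f[2]) >= as.integer(f[3])
  }, logical(1))
  if (any(bad_rec)) {
    warn(paste0(sum(bad_rec), " TE interval(s) with start >= end rejected"))
    path <- tempfile(fileext = paste0(".", format))
    writeLines(lines[!bad_rec], path)
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0) {
    return(tibble(chromosome = character(), start = integer(),
                  end = integer(), te_class = character()))
  }
  label <- if (format == "bed") {
    df$name
  } else if ("type" %in% names(df) && !all(as.character(df$type) %in% c("", NA))) {
    as.character(df$type)
  } else {
    df$ID %||% df$Name
  }
  out <- tibble(
    chromosome = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    te_class = normalize_te_class(as.character(label))
  )
  out[out$start < out$end, , drop = FALSE]
}
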