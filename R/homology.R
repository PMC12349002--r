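#' Read and filter a tabular protein-homology table
#'
#' Consumes standard 12-column aligner tabular output (query, subject, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' The alignment itself is assumed done upstream; this reader only applies
#' the E-value cutoff, collapses duplicate (query, subject) lines to the
#' best-scoring one, and caps hits per query.
#'
#' @param path Path to the tabular file (no header).
#' @param evalue_max Maximum E-value retained (default `1e-5`).
#' @param top_k Hits kept per query, ranked by bitscore (default 5). Ties in
#'   bitscore at the boundary are all kept, so the result is deterministic.
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
read_homology <- function(path, evalue_max = 1e-5, top_k = 5L) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  evalue = double(), bitscore = double()))
  }
  if (ncol(raw) < 12) {
    abort("homology table must have >= 12 tab-separated columns (outfmt-6 style)")
  }
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  bs <- suppressWarnings(as.numeric(raw[[12]]))
  if (anyNA(ev) || anyNA(bs)) {
    bad <- which(is.na(ev) | is.na(bs))[1]
    abort(paste0("non-numeric evalue/bitscore at data line ", bad))
  }
  pairs <- tibble(query_id = raw[[1]], subject_id = raw[[2]],
                  evalue = ev, bitscore = bs)
  filter_homology(pairs, evalue_max = evalue_max, top_k = top_k)
}

#' Apply E-value and top-k filtering to in-memory homology pairs
#'
#' @param pairs Tibble with `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @inheritParams read_homology
#' @return Filtered tibble, sorted by query then descending bitscore.
#' @export
filter_homology <- function(pairs, evalue_max = 1e-5, top_k = 5L) {
  stopifnot(is_count(top_k, min = 1L))
  pairs <- as_tibble(pairs)[pairs$evalue <= evalue_max, , drop = FALSE]
  if (nrow(pairs) == 0) return(pairs)
  ord <- order(pairs$query_id, -pairs$bitscore, pairs$subject_id)
  pairs <- pairs[ord, , drop = FALSE]
  # exact duplicates collapse to the best-scoring line (first after sort)
  pairs <- pairs[!duplicated(paste(pairs$query_id, pairs$subject_id,
                                   sep = "\r")), , drop = FALSE]
  # per query keep the top_k by bitscore, retaining boundary ties
  grp <- cumsum(!duplicated(pairs$query_id))
  pos <- sequence(rle(grp)$lengths)
  thr <- rep(-Inf, max(grp))
  kth <- pos == top_k
  thr[grp[kth]] <- pairs$bitscore[kth]
  pairs[pairs$bitscore >= thr[grp], , drop = FALSE]
}
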