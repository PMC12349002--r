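# Scoring recovery of a simulated ancestor by the reconstruction pipeline.

#' Score recovery of a simulated ancestral karyotype
#'
#' Compares paintings of simulated descendants against the simulator's truth
#' painting. Because inferred proto ids are arbitrary labels, they are first
#' matched to true ancestral chromosomes greedily by overlap (largest
#' contingency cell first); painting accuracy is then the fraction of
#' painted genes whose matched proto equals the truth. Genes gained after
#' the ancestor (truth `NA`) are excluded from every denominator.
#'
#' @param agk The inferred `ancestral_karyotype`.
#' @param paintings A `painting` tibble covering one or more species, or a
#'   list of them.
#' @param truth Truth painting tibble (`species`, `gene_id`, `true_proto`).
#' @return A `recovery_report`: list with `inferred_proto_count`,
#'   `true_proto_count`, `painting_accuracy`, `partition_agreement`
#'   (adjusted Rand index), `unpainted_fraction`, and the `proto_map` used.
#' @export
evaluate_recovery <- function(agk, paintings, truth) {
  if (is.list(paintings) && !is.data.frame(paintings)) {
    paintings <- bind_rows(paintings)
  }
  missing_sp <- setdiff(unique(paintings$species), unique(truth$species))
  if (length(missing_sp) > 0) {
    abort(paste0("species in painting but not in truth: ",
                 paste(missing_sp, collapse = ", ")))
  }
  joined <- paintings |>
    inner_join(truth, by = c("species", "gene_id"))
  if (nrow(joined) < nrow(paintings)) {
    abort("painting contains genes absent from the truth table")
  }
  eligible <- joined |> filter(!is.na(.data$true_proto))
  painted <- eligible |> filter(!is.na(.data$proto))
  unpainted_fraction <- 1 - nrow(painted) / max(1L, nrow(eligible))

  proto_map <- greedy_label_match(painted$proto, painted$true_proto)
  acc <- if (nrow(painted) == 0) 0 else {
    mean(unname(proto_map[painted$proto]) == painted$true_proto,
         na.rm = FALSE)
  }
  ari <- if (nrow(painted) < 2) NA_real_ else {
    mclust::adjustedRandIndex(painted$proto, painted$true_proto)
  }
  inferred <- dplyr::n_distinct(agk$segments$proto)
  structure(list(
    inferred_proto_count = inferred,
    true_proto_count = dplyr::n_distinct(eligible$true_proto),
    painting_accuracy = acc,
    partition_agreement = ari,
    unpainted_fraction = unpainted_fraction,
    proto_map = proto_map
  ), class = "recovery_report")
}

# greedy maximum matching of label sets by contingency overlap
greedy_label_match <- function(labels, truth) {
  if (length(labels) == 0) return(setNames(character(), character()))
  tab <- table(labels, truth)
  map <- setNames(rep(NA_character_, nrow(tab)), rownames(tab))
  while (any(tab > 0)) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    map[rownames(tab)[ij[1]]] <- colnames(tab)[ij[2]]
    tab[ij[1], ] <- -1
    tab[, ij[2]] <- -1
  }
  map
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n",
      "  protos inferred/true: ", x$inferred_proto_count, "/",
      x$true_proto_count, "\n",
      "  painting accuracy:    ", round(x$painting_accuracy, 4), "\n",
      "  adjusted Rand index:  ", round(x$partition_agreement, 4), "\n",
      "  unpainted fraction:   ", round(x$unpainted_fraction, 4), "\n",
      sep = "")
  invisible(x)
}
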