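# broom-style tidiers for fitted result objects.

#' @rdname anova_oneway
#' @param x A `degree_anova` object.
#' @param ... Unused.
#' @method tidy degree_anova
#' @export
tidy.degree_anova <- function(x, ...) {
  x$groups
}

#' @rdname anova_oneway
#' @method glance degree_anova
#' @export
glance.degree_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = unname(x$df["df1"]),
         df2 = unname(x$df["df2"]), p_value = x$p_value,
         perm_p = x$perm_p, n_perm = x$n_perm)
}

#' @rdname arm_randomization_test
#' @param x An `arm_randomization` object.
#' @param ... Unused.
#' @method tidy arm_randomization
#' @export
tidy.arm_randomization <- function(x, ...) {
  x$table
}

#' @rdname arm_randomization_test
#' @method glance arm_randomization
#' @export
glance.arm_randomization <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_sim = x$n_sim,
         seed = x$seed)
}

#' @rdname select_representatives
#' @param x An `ancestral_karyotype`.
#' @param ... Unused.
#' @method tidy ancestral_karyotype
#' @export
tidy.ancestral_karyotype <- function(x, ...) {
  x$segments
}

#' @rdname select_representatives
#' @method glance ancestral_karyotype
#' @export
glance.ancestral_karyotype <- function(x, ...) {
  tibble(n_protos = dplyr::n_distinct(x$segments$proto),
         n_segments = nrow(x$segments),
         n_genes = nrow(x$genes),
         n_source_species = dplyr::n_distinct(x$source$source_species))
}

#' @rdname evaluate_recovery
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(inferred_proto_count = x$inferred_proto_count,
         true_proto_count = x$true_proto_count,
         painting_accuracy = x$painting_accuracy,
         partition_agreement = x$partition_agreement,
         unpainted_fraction = x$unpainted_fraction)
}

#' @rdname syntenic_depth
#' @param x A `depth_profile`.
#' @param ... Unused.
#' @method glance depth_profile
#' @export
glance.depth_profile <- function(x, ...) {
  tibble(modal_depth = attr(x, "modal_depth"),
         modal_ratio = attr(x, "modal_ratio"),
         no_signal = attr(x, "no_signal"),
         mean_depth = mean(x$depth),
         covered_fraction = mean(x$depth > 0))
}
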