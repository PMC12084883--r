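# broom-style accessors for fitted/result objects

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, n_x = length(x$x),
         n_y = length(x$y), statistic = x$statistic, p = x$p,
         significant = x$significant, method = x$method)
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' @export
tidy.tailscope_de <- function(x, ...) as_tibble(x)

#' @export
glance.tailscope_de <- function(x, ...) {
  called <- if ("called" %in% names(x)) x$called else rep(NA, nrow(x))
  tibble(n_features = nrow(x),
         n_tested = sum(!is.na(x$padj)),
         n_called = sum(called, na.rm = TRUE),
         n_up = sum(called & x$log2fc > 0, na.rm = TRUE),
         n_down = sum(called & x$log2fc < 0, na.rm = TRUE))
}

#' @export
tidy.polya_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.polya_comparison <- function(x, ...) {
  tibble(n_tested = nrow(x), n_significant = sum(x$significant),
         n_longer = sum(x$significant & x$delta > 0),
         n_shorter = sum(x$significant & x$delta < 0))
}

#' @export
tidy.monoa_correlation <- function(x, ...) x$pairs

#' @export
glance.monoa_correlation <- function(x, ...) {
  tibble(n_mirnas = x$n, pearson_r = x$r, p = x$p)
}

#' @export
tidy.interaction_set <- function(x, ...) as_tibble(x)

#' @export
glance.interaction_set <- function(x, ...) {
  n <- nrow(x)
  tibble(n_interactions = n,
         n_mirnas = dplyr::n_distinct(x$mirna),
         n_genes = dplyr::n_distinct(x$gene),
         frac_negative = if (n > 0) mean(x$sign_class == "negative") else NA_real_,
         frac_positive = if (n > 0) mean(x$sign_class == "positive") else NA_real_,
         frac_undefined = if (n > 0) mean(x$sign_class == "undefined") else NA_real_,
         mode = attr(x, "mode") %||% NA_character_)
}

#' @export
tidy.tail_composition <- function(x, ...) {
  mutate(x$by_length, sample_id = attr(x, "sample_id"))
}

#' @export
glance.isomir_profile <- function(x, ...) {
  tibble(sample_id = attr(x, "sample_id"), genotype = attr(x, "genotype"),
         n_isomirs = nrow(x), n_mirnas = dplyr::n_distinct(x$mirna),
         n_assigned = attr(x, "n_assigned"),
         n_unassigned = attr(x, "n_unassigned"),
         n_dropped = nrow(attr(x, "dropped")))
}
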