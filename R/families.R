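#' Aggregate an OTU table to family-level relative abundances
#'
#' Sums counts over the taxa of each family and converts to per-sample
#' proportions. Taxa missing from the taxonomy map are pooled as
#' `"Other"`. Optionally keeps only the top families by mean abundance,
#' folding the remainder into `"Other"`.
#'
#' @param table OTU table (wide tibble or matrix).
#' @param taxonomy Tibble mapping `taxon` to `family` (non-empty).
#' @param top_n Optional number of families to keep by mean relative
#'   abundance; the rest are pooled as `"Other"`.
#' @return Long tibble `sample_id`, `family`, `proportion`; proportions sum
#'   to 1 within each sample.
#' @export
family_profile <- function(table, taxonomy, top_n = NULL) {
  if (is.null(taxonomy) || nrow(taxonomy) == 0) abort("empty taxonomy")
  stopifnot(all(c("taxon", "family") %in% names(taxonomy)))
  m <- otu_matrix(table)
  if (any(rowSums(m) == 0)) abort("sample with zero total count")
  fam <- taxonomy$family[match(colnames(m), taxonomy$taxon)]
  fam[is.na(fam)] <- "Other"
  prof <- otu_tibble(m) |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon", values_to = "count") |>
    dplyr::mutate(family = fam[match(.data$taxon, colnames(m))]) |>
    dplyr::group_by(.data$sample_id, .data$family) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "family", "proportion")
  if (!is.null(top_n)) {
    keep <- prof |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(mean_prop = mean(.data$proportion)) |>
      dplyr::arrange(dplyr::desc(.data$mean_prop)) |>
      dplyr::slice_head(n = top_n) |>
      dplyr::pull("family")
    prof <- prof |>
      dplyr::mutate(family = ifelse(.data$family %in% keep,
                                    .data$family, "Other")) |>
      dplyr::group_by(.data$sample_id, .data$family) |>
      dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
  }
  prof
}

#' Per-family two-group comparison of relative abundances
#'
#' Welch two-sample t-test of each family's relative abundance between two
#' sample groups, with the 95 % confidence interval on the difference of
#' means (group_b minus group_a). P-values are reported raw, without
#' multiplicity correction; apply [stats::p.adjust()] downstream if a
#' corrected screen is wanted.
#'
#' @param profile Long family profile from [family_profile()].
#' @param metadata Tibble with `sample_id` and `group` columns.
#' @param group_a,group_b Group labels to compare; each must have at least
#'   two samples.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return Tibble per family: `family`, `mean_a`, `mean_b`,
#'   `mean_difference` (b - a), `conf_low`, `conf_high`, `t_statistic`,
#'   `p_value`.
#' @export
group_difference <- function(profile, metadata, group_a, group_b,
                             conf_level = 0.95) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  meta <- metadata |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    dplyr::distinct(.data$sample_id, .data$group)
  # families absent from a sample count as proportion zero, not missing
  df <- tidyr::expand_grid(
    family = unique(profile$family),
    sample_id = meta$sample_id
  ) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::left_join(profile, by = c("family", "sample_id")) |>
    dplyr::mutate(proportion = dplyr::coalesce(.data$proportion, 0))
  n_by_group <- df |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(n_by_group) < 2 || any(n_by_group$n < 2)) {
    abort("each group needs at least 2 samples")
  }
  df |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(function(d, key) {
      xa <- d$proportion[d$group == group_a]
      xb <- d$proportion[d$group == group_b]
      if (sd(xa) == 0 && sd(xb) == 0) {
        delta <- mean(xb) - mean(xa)
        return(tibble::tibble(mean_a = mean(xa), mean_b = mean(xb),
                              mean_difference = delta, conf_low = delta,
                              conf_high = delta, t_statistic = NA_real_,
                              p_value = if (delta == 0) 1 else NA_real_))
      }
      tt <- t.test(xb, xa, conf.level = conf_level) # Welch by default
      tibble::tibble(mean_a = mean(xa), mean_b = mean(xb),
                     mean_difference = unname(tt$estimate[1] - tt$estimate[2]),
                     conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                     t_statistic = unname(tt$statistic), p_value = tt$p.value)
    }) |>
    dplyr::ungroup()
}
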