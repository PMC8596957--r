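#' Run a complete study: balances, rankings and community statistics
#'
#' Orchestrates the end-to-end analysis of a multi-reactor experiment:
#' balances every reactor, ranks the reactors (maximum ethanol yield,
#' maximum consumption, maximum peak current), and, when a community
#' experiment is supplied, computes the alpha-diversity panel, Bray-Curtis
#' distances, NMDS ordination, PERMANOVA on the group labels, the
#' family-level profile and the per-family pre/post comparison. The report
#' is a pure function of its inputs and `seed`; reactor order does not
#' affect its content.
#'
#' @param batches Reactor batch table (see [make_benchmark_fixture()]).
#' @param community Optional community experiment, a list with `table`,
#'   `metadata` and optionally `tree` and `taxonomy` (as returned by
#'   [make_community()]).
#' @param seed Integer seed forwarded to the seeded community stages.
#' @param n_permutations PERMANOVA permutations (default 9999).
#' @return Object of class `study_report`: `balance` (per-reactor summary
#'   tibble, sorted by reactor id), `rankings` (one-row tibble naming the
#'   argmax reactors), and `community` (list of result tables or `NULL`).
#'   [tidy()] returns the balance table, [glance()] the rankings.
#' @examples
#' run_study(make_benchmark_fixture())
#' @export
run_study <- function(batches, community = NULL, seed = 1,
                      n_permutations = 9999) {
  bal <- balance_all(batches) |> dplyr::arrange(.data$reactor_id)

  peak_per_reactor <- purrr::pmap_dbl(batches, function(...) {
    row <- list(...)
    if (!is.null(row$trace)) {
      find_current_peak(row$trace)$peak_current
    } else if (!is.null(row$peak_current)) {
      as.numeric(row$peak_current)
    } else {
      NA_real_
    }
  })
  names(peak_per_reactor) <- batches$reactor_id
  argmax <- function(vals, ids) {
    if (all(is.na(vals))) NA_character_ else ids[which.max(vals)]
  }
  rankings <- tibble::tibble(
    max_yield_reactor = argmax(bal$yield_ethanol, bal$reactor_id),
    max_yield = suppressWarnings(max(bal$yield_ethanol, na.rm = TRUE)),
    max_consumption_reactor = argmax(bal$consumption_pct, bal$reactor_id),
    max_consumption_pct = suppressWarnings(max(bal$consumption_pct, na.rm = TRUE)),
    max_peak_reactor = argmax(unname(peak_per_reactor[bal$reactor_id]),
                              bal$reactor_id),
    max_peak_current = if (all(is.na(peak_per_reactor))) NA_real_ else
      max(peak_per_reactor, na.rm = TRUE)
  )

  comm <- NULL
  if (!is.null(community)) {
    tab <- community$table
    meta <- dplyr::arrange(community$metadata, .data$sample_id)
    alpha <- alpha_diversity(tab, tree = community$tree)
    d <- bray_curtis(tab)
    ord <- nmds_ordination(d, k = 2, seed = seed)
    grp <- meta$group[match(attr(d, "Labels"), meta$sample_id)]
    perm <- permanova(d, grp, n_permutations = n_permutations, seed = seed)
    prof <- diff_tab <- NULL
    if (!is.null(community$taxonomy)) {
      prof <- family_profile(tab, community$taxonomy)
      grp_levels <- unique(meta$group)
      if (length(grp_levels) == 2 &&
          all(table(meta$group) >= 2)) {
        diff_tab <- group_difference(prof, meta, grp_levels[1], grp_levels[2])
      }
    }
    comm <- list(alpha = alpha, distances = d, ordination = ord,
                 permanova = perm, family_profile = prof,
                 group_difference = diff_tab)
  }

  structure(list(balance = bal, rankings = rankings, community = comm,
                 seed = seed, version = as.character(utils::packageVersion("fermbal"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d reactor(s)%s\n", nrow(x$balance),
              if (is.null(x$community)) "" else ", with community analysis"))
  cat(sprintf("  max ethanol yield: %s (%.3f mol/mol)\n",
              x$rankings$max_yield_reactor, x$rankings$max_yield))
  cat(sprintf("  max consumption:   %s (%.1f %%)\n",
              x$rankings$max_consumption_reactor, x$rankings$max_consumption_pct))
  if (!is.na(x$rankings$max_peak_reactor)) {
    cat(sprintf("  max peak current:  %s (%.3g A)\n",
                x$rankings$max_peak_reactor, x$rankings$max_peak_current))
  }
  if (!is.null(x$community)) {
    cat(sprintf("  PERMANOVA: R2 = %.3f, p = %.4g (%d permutations)\n",
                x$community$permanova$r_squared, x$community$permanova$p_value,
                x$community$permanova$n_permutations))
  }
  invisible(x)
}

#' @export
tidy.study_report <- function(x, ...) dplyr::select(x$balance, -"report")

#' @export
glance.study_report <- function(x, ...) x$rankings
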