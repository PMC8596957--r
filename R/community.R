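#' Coerce an OTU table to a counts matrix
#'
#' The package stores OTU tables as wide tibbles: a `sample_id` column
#' followed by one integer column per taxon. `otu_matrix()` converts this
#' (or an already-numeric matrix) to a samples-by-taxa matrix with sample
#' row names, validating non-negativity and unique sample identifiers.
#'
#' @param table Wide tibble (`sample_id` + taxon columns) or numeric matrix.
#' @return Numeric matrix, samples in rows.
#' @export
otu_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else {
    stopifnot(is.data.frame(table), "sample_id" %in% names(table))
    m <- as.matrix(table[setdiff(names(table), "sample_id")])
    rownames(m) <- table$sample_id
  }
  if (any(m < 0)) abort("OTU counts must be non-negative")
  if (anyDuplicated(rownames(m))) abort("sample identifiers must be unique")
  m
}

otu_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads, the standard normalisation before alpha-diversity comparison.
#' Samples whose total is below `depth` are dropped with a warning.
#'
#' @param table OTU table (wide tibble or matrix; see [otu_matrix()]).
#' @param depth Target reads per sample (> 0). Defaults to the smallest
#'   sample total.
#' @param seed Integer seed; subsampling is reproducible under it.
#' @return Rarefied table in the same wide-tibble form.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1) {
  m <- otu_matrix(table)
  totals <- rowSums(m)
  depth <- depth %||% min(totals)
  if (depth <= 0) abort("rarefaction depth must be > 0")
  drop <- totals < depth
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " sample(s) below depth ", depth))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no sample reaches the rarefaction depth")
  withr_seed(seed)
  # vegan warns whenever the smallest positive count exceeds 1, which is
  # routine for aggregated OTU tables; that check is not informative here
  r <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  otu_tibble(r)
}

# local seed scope so package randomness does not disturb the caller's RNG
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  invisible(old)
}

#' Shannon diversity of one count vector
#'
#' -sum(p_i * log(p_i)) over positive proportions, in the given log base.
#' Base 2 is the package default (stated explicitly in every report
#' because conventions differ between pipelines).
#'
#' @param counts Non-negative count vector with at least one positive entry.
#' @param base Logarithm base (default 2).
#' @return Shannon index (>= 0).
#' @examples
#' shannon_index(c(5, 5, 5, 5)) # log2(4) = 2
#' @export
shannon_index <- function(counts, base = 2) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (sum(counts) == 0) abort("all-zero sample has no diversity")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 richness estimate
#'
#' Abundance-based richness estimator from singleton and doubleton counts.
#' The default bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1)) is
#' defined even when no doubletons are observed; the classic form
#' S_obs + F1^2 / (2 F2) is available via `bias_corrected = FALSE`.
#'
#' @param counts Non-negative integer count vector.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness; always >= the observed richness.
#' @examples
#' chao1_index(c(rep(1, 4), rep(2, 2), rep(5, 4))) # 10 + 4*3/6 = 12
#' @export
chao1_index <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts != round(counts))) abort("Chao1 needs integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2 # classic form falls back when F2 = 0
  }
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the observed taxa;
#' by default the path to the root is included (the "whole tree" reading),
#' toggleable via `include_root`.
#'
#' @param tree `ape::phylo` tree whose tips are (a superset of) the taxa.
#' @param present_taxa Character vector of observed taxa (non-empty, all
#'   tips of `tree`).
#' @param include_root Include the root path (default `TRUE`).
#' @return Branch-length sum (>= 0).
#' @export
faith_pd <- function(tree, present_taxa, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(present_taxa) == 0) abort("no taxa present")
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("taxa not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) {
    # resolve a basal polytomy with zero-length edges; branch lengths, and
    # hence PD, are unchanged
    tree <- ape::multi2di(tree)
  }
  comm <- matrix(as.integer(tree$tip.label %in% present_taxa), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  as.numeric(picante::pd(comm, tree, include.root = include_root)$PD)
}

#' Per-sample alpha-diversity panel
#'
#' Computes the four standard alpha-diversity measures for every sample of
#' an OTU table: Shannon index, observed species, Chao1 and (when a tree
#' is supplied) Faith's PD.
#'
#' @param table OTU table (wide tibble or matrix).
#' @param tree Optional `phylo` tree covering the table's taxa.
#' @param base Shannon log base (default 2).
#' @param include_root Passed to [faith_pd()].
#' @return Tibble with one row per sample: `sample_id`, `shannon`,
#'   `observed_species`, `chao1`, `faith_pd` (NA without a tree).
#' @export
alpha_diversity <- function(table, tree = NULL, base = 2, include_root = TRUE) {
  m <- otu_matrix(table)
  purrr::map_dfr(rownames(m), function(s) {
    x <- m[s, ]
    tibble::tibble(
      sample_id = s,
      shannon = shannon_index(x, base = base),
      observed_species = sum(x > 0),
      chao1 = chao1_index(x),
      faith_pd = if (is.null(tree)) NA_real_ else
        faith_pd(tree, names(x)[x > 0], include_root = include_root)
    )
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y) on raw counts.
#'
#' @param table OTU table with at least two samples; every sample must have
#'   a positive total.
#' @return A `dist` object (symmetric, zero diagonal, values in \[0, 1\]).
#' @export
bray_curtis <- function(table) {
  m <- otu_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (any(rowSums(m) == 0)) abort("sample with zero total count")
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS with monotone regression and random restarts,
#' keeping the best solution; deterministic under `seed`.
#'
#' @param distances A `dist` object.
#' @param k Number of ordination dimensions (default 2; must be smaller
#'   than the number of samples).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 20).
#' @param tol Convergence tolerance on stress (default 1e-6).
#' @param max_iter Maximum iterations per start (default 300).
#' @return Object of class `nmds_ordination` with `points` (tibble of
#'   sample coordinates, centred), `stress` (final stress-1, in \[0, 1\]),
#'   `k`, `seed`, `converged`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
nmds_ordination <- function(distances, k = 2, seed = 1, n_restarts = 20,
                            tol = 1e-6, max_iter = 300) {
  stopifnot(inherits(distances, "dist"))
  n <- attr(distances, "Size")
  if (k >= n) abort("k must be smaller than the number of samples")
  withr_seed(seed)
  fit <- withCallingHandlers(
    vegan::metaMDS(distances, k = k, try = n_restarts,
                   trymax = n_restarts, trace = 0,
                   sfgrmin = tol, maxit = max_iter, wascores = FALSE),
    warning = function(w) {
      # a perfectly embeddable configuration is a success, not a problem
      if (grepl("stress is (nearly) zero", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  ids <- attr(distances, "Labels") %||% as.character(seq_len(n))
  structure(list(
    points = dplyr::bind_cols(
      tibble::tibble(sample_id = ids),
      tibble::as_tibble(pts, .name_repair = ~ paste0("NMDS", seq_len(k)))
    ),
    stress = fit$stress, # monoMDS stress-1, reported as a fraction
    k = k, seed = seed, n_restarts = n_restarts,
    converged = fit$converged
  ), class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("<nmds_ordination> k = %d, stress-1 = %.4f (%d samples)\n",
              x$k, x$stress, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n_samples = nrow(x$points),
                 seed = x$seed, converged = isTRUE(x$converged))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared dissimilarities of a distance matrix between and
#' within groups and tests the between-group fraction (R^2) with a
#' permutation test on the pseudo-F statistic (Adonis). The permutation
#' p-value is (number of permuted F >= observed F + 1) / (n + 1).
#'
#' @param distances A `dist` object.
#' @param groups Group label per sample (>= 2 groups, each non-empty).
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed for the permutations.
#' @return One-row tibble: `r_squared`, `pseudo_f`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`.
#' @export
permanova <- function(distances, groups, n_permutations = 9999, seed = 1) {
  stopifnot(inherits(distances, "dist"))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 groups")
  if (length(groups) != attr(distances, "Size")) {
    abort("one group label per sample required")
  }
  withr_seed(seed)
  fit <- vegan::adonis2(distances ~ groups, permutations = n_permutations)
  tibble::tibble(
    r_squared = fit$R2[1],
    pseudo_f = fit$F[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = n_permutations,
    df_between = fit$Df[1],
    df_within = fit$Df[2]
  )
}
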