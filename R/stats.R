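# Inferential layer: Bray-Curtis, PERMANOVA, PLS-DA, univariate scans,
# trajectory-marker correlation.

#' Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over nonnegative abundance
#' vectors; the canonical community-distance input to PERMANOVA. Computed
#' with [vegan::vegdist()]. Pairs of all-zero samples have an undefined
#' distance and are flagged.
#'
#' @param matrix samples x features matrix of nonnegative values.
#' @return A `dist` object; attribute `undefined_pairs` lists any sample
#'   pairs where both rows are all zero (their entry is `NaN`).
#' @export
bray_curtis <- function(matrix) {
  if (any(matrix < 0)) stop("Bray-Curtis requires nonnegative values")
  d <- suppressWarnings(vegan::vegdist(matrix, method = "bray"))
  zero <- which(rowSums(matrix) == 0)
  undef <- if (length(zero) >= 2) t(utils::combn(rownames(matrix)[zero], 2))
           else NULL
  if (!is.null(undef)) warning("all-zero sample pair(s): distance undefined")
  attr(d, "undefined_pairs") <- undef
  d
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from among- vs within-group sums of squared distances (the
#' one-factor adonis form),
#' \eqn{F = (SS_A/(k-1)) / (SS_W/(n-k))} with
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}.
#' Sample labels are permuted freely (no strata); the p-value is
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param dist a `dist` or square symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations number of label permutations.
#' @param seed integer seed making the permutations reproducible.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `ss_among`, `ss_within`, `df`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = 1L) {
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2)) stop("singleton group: every group needs >= 2 samples")
  k <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_for(groups)
  exceed <- with_local_seed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(i) f_for(sample(groups)) >= f_obs, logical(1)))
  })
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 ss_among = ss_total - ss_within_for(groups),
                 ss_within = ss_within_for(groups),
                 df = c(among = k - 1, within = n - k)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Partial least squares discriminant analysis (NIPALS)
#'
#' Supervised projection maximizing covariance between the (centered,
#' optionally unit-scaled) feature matrix and a centered one-hot encoding of
#' the group labels. Components are extracted sequentially by NIPALS with
#' deflation of X between components. Constant features are dropped with a
#' warning. Loadings (the normalized X-weights) rank each feature's
#' contribution to group separation.
#'
#' @param matrix samples x features.
#' @param groups two-level (or more) factor, >= 2 samples per group.
#' @param n_components number of latent components
#'   (<= min(samples, features)).
#' @param scale unit-variance scale the features (default TRUE).
#' @return list of class `plsda_fit`: `scores` (samples x components),
#'   `loadings` (features x components, the normalized weights),
#'   `x_loadings` (deflation loadings), `explained_variance`, `groups`,
#'   `dropped_features`.
#' @export
plsda_fit <- function(matrix, groups, n_components = 2, scale = TRUE) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  if (n_components > min(dim(matrix)))
    stop("n_components must be <= min(samples, features)")
  x <- as.matrix(matrix)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x, center = TRUE, scale = if (scale) sds else FALSE)
  y <- stats::model.matrix(~ groups - 1)
  y <- scale(y, center = TRUE, scale = FALSE)
  n_feat <- ncol(x)
  ss_x_total <- sum(x^2)
  scores <- matrix(0, nrow(x), n_components)
  weights <- matrix(0, n_feat, n_components,
                    dimnames = list(colnames(x), NULL))
  ploads <- matrix(0, n_feat, n_components,
                   dimnames = list(colnames(x), NULL))
  expl <- numeric(n_components)
  xd <- x; yd <- y
  for (h in seq_len(n_components)) {
    u <- yd[, which.max(apply(yd, 2, stats::var)), drop = TRUE]
    w <- t_old <- NULL
    for (iter in 1:500) {
      w <- crossprod(xd, u); w <- w / sqrt(sum(w^2))
      t_h <- xd %*% w
      c_h <- crossprod(yd, t_h) / sum(t_h^2)
      u <- yd %*% c_h / sum(c_h^2)
      if (!is.null(t_old) && sum((t_h - t_old)^2) < 1e-12 * sum(t_h^2)) break
      t_old <- t_h
    }
    p_h <- crossprod(xd, t_h) / sum(t_h^2)
    xd <- xd - t_h %*% t(p_h)
    yd <- yd - t_h %*% t(c_h)
    scores[, h] <- t_h
    weights[, h] <- w
    ploads[, h] <- p_h
    expl[h] <- sum((t_h %*% t(p_h))^2) / ss_x_total
  }
  dimnames(scores) <- list(rownames(matrix),
                           paste0("comp", seq_len(n_components)))
  colnames(weights) <- colnames(ploads) <- colnames(scores)
  structure(list(scores = scores, loadings = weights, x_loadings = ploads,
                 explained_variance = expl, groups = groups,
                 dropped_features = dropped),
            class = "plsda_fit")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`): order-preserving, never decreases a
#' p-value.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate feature scan with FDR correction
#'
#' Per-feature two-sample Wilcoxon rank-sum (Mann-Whitney) test between the
#' two groups (midranks for ties; exact p for small tie-free samples, normal
#' approximation with tie correction otherwise), followed by
#' Benjamini-Hochberg adjustment across the whole scan. Direction is the
#' sign of the median difference. Note the two-sample rank-sum test is used
#' for independent WT/KO groups; the signed-rank test applies only to
#' paired designs.
#'
#' @param matrix samples x features.
#' @param groups two-level factor aligned with rows.
#' @return data.frame: `feature_id`, `statistic` (rank-sum W), `raw_p`,
#'   `adjusted_p`, `direction` (`"higher-in-KO"`, `"higher-in-WT"`, or
#'   `NA` for all-tied features, for generic labels `higher-in-<level2>`
#'   etc.).
#' @export
feature_scan <- function(matrix, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("feature_scan requires exactly two groups")
  lv <- levels(groups)
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[groups == lv[1], j]
    y <- matrix[groups == lv[2], j]
    if (length(unique(c(x, y))) == 1L) {
      return(data.frame(feature_id = colnames(matrix)[j], statistic = NA_real_,
                        raw_p = 1, direction = NA_character_,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    md <- stats::median(y) - stats::median(x)
    dir <- if (md > 0) paste0("higher-in-", lv[2])
           else if (md < 0) paste0("higher-in-", lv[1])
           else NA_character_
    data.frame(feature_id = colnames(matrix)[j],
               statistic = unname(wt$statistic), raw_p = wt$p.value,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$raw_p)
  out[, c("feature_id", "statistic", "raw_p", "adjusted_p", "direction")]
}

#' Spearman correlation between a sweep trajectory and an inflammation marker
#'
#' Pools `(mouse, week)` pairs of focal-locus frequency and marker level —
#' optionally restricted to one genotype — and computes Spearman's rank
#' correlation. Weeks where the locus was not called are treated as
#' frequency 0 (below detection); pairs with a missing marker are dropped.
#'
#' @param freq_series data.frame `mouse_id`, `week`, `frequency` for the
#'   focal locus.
#' @param marker_series data.frame `mouse_id`, `week`, `marker_per_gram`
#'   (plus optional `genotype`).
#' @param scope `"all-mice"` or `"KO-only"` (requires a `genotype` column in
#'   `marker_series`).
#' @return list: `rho`, `p_value`, `n_pairs`, `scope`.
#' @export
trajectory_correlation <- function(freq_series, marker_series,
                                   scope = c("all-mice", "KO-only")) {
  scope <- match.arg(scope)
  mk <- marker_series
  if (scope == "KO-only") {
    if (is.null(mk$genotype)) stop("KO-only scope needs a genotype column")
    mk <- mk[mk$genotype == "KO", , drop = FALSE]
  }
  merged <- merge(mk, freq_series[, c("mouse_id", "week", "frequency")],
                  by = c("mouse_id", "week"), all.x = TRUE)
  merged$frequency[is.na(merged$frequency)] <- 0
  merged <- merged[!is.na(merged$marker_per_gram), , drop = FALSE]
  if (nrow(merged) < 3) stop("need >= 3 (mouse, week) pairs")
  ct <- suppressWarnings(stats::cor.test(merged$frequency,
                                         merged$marker_per_gram,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = nrow(merged), scope = scope)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value
#' (`stats::kruskal.test`); degenerate all-tied input returns H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups).
#' @return list: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
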