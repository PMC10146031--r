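# Evaluation machinery deciding whether information scale correction
# improved cross-dataset comparability: Bray-Curtis dissimilarity, NMDS
# ordination, Procrustes superimposition with a permutation test, the
# pre-treatment medoid, the per-sample correction effectiveness dE
# (d(m, post) - d(m, pre); negative = the sample converged toward the
# pre-treatment medoid), and the group-level mean effectiveness E-bar.

#' Bray-Curtis dissimilarity between samples of an abundance table
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y)`.
#'
#' @param table ASV x sample count matrix.
#' @return a symmetric `dist`-convertible matrix with zero diagonal and the
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table)[cs == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(table), method = "bray"))
  diag(d) <- 0
  d
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimization with monotone regression on dissimilarity
#' ranks, taking the best of `n_starts` random starts. Deterministic for a
#' given seed.
#'
#' @param d symmetric distance matrix (with sample ids as dimnames).
#' @param k embedding dimension.
#' @param n_starts number of random starts.
#' @param seed integer RNG seed (`NULL` = current stream).
#' @return list of class `isc_ordination` with `points` (n x k), `stress`
#'   (Kruskal stress-1, as a fraction in `[0, 1]`) and `ids`.
#' @export
nmds_ordinate <- function(d, k = 2L, n_starts = 20L, seed = NULL) {
  dm <- as.matrix(d)
  if (nrow(dm) < 4L) stop("NMDS needs at least 4 samples")
  fit <- with_seed(seed,
    vegan::metaMDS(stats::as.dist(dm), k = k, try = n_starts,
                   trymax = n_starts, trace = 0, autotransform = FALSE,
                   wascores = FALSE))
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge in ", n_starts, " starts; ",
            "best configuration returned")
  structure(list(points = unname(fit$points), stress = fit$stress,
                 ids = rownames(dm)),
            class = "isc_ordination")
}

#' Symmetric Procrustes superimposition with a permutation test
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' optimal rotation comes from the singular value decomposition of `X'Y`,
#' and the goodness-of-fit is `M2 = 1 - (sum of singular values)^2` (0 =
#' perfect congruence). The permutation p-value is
#' `(1 + #{permuted M2 <= observed}) / (1 + permutations)` under row
#' permutations of `Y`.
#'
#' @param X,Y `isc_ordination` objects or n x 2 coordinate matrices with
#'   matching rows.
#' @param permutations number of row permutations.
#' @param seed integer RNG seed (`NULL` = current stream).
#' @return list of class `isc_procrustes` with `M2`, `p`, `X` (the scaled
#'   reference configuration) and `Yrot` (the target configuration rotated
#'   and scaled onto it).
#' @export
procrustes_fit <- function(X, Y, permutations = 999L, seed = NULL) {
  xm <- if (inherits(X, "isc_ordination")) X$points else as.matrix(X)
  ym <- if (inherits(Y, "isc_ordination")) Y$points else as.matrix(Y)
  if (nrow(xm) != nrow(ym))
    stop("configurations have different numbers of rows")
  norm_conf <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  m2_of <- function(x0, y0) {
    sv <- svd(crossprod(x0, y0))$d
    max(1 - sum(sv)^2, 0)
  }
  x0 <- norm_conf(xm)
  y0 <- norm_conf(ym)
  s <- svd(crossprod(x0, y0))
  rot <- s$v %*% t(s$u)
  M2 <- max(1 - sum(s$d)^2, 0)
  p <- with_seed(seed, {
    perm <- vapply(seq_len(permutations), function(i) {
      m2_of(x0, y0[sample.int(nrow(y0)), , drop = FALSE])
    }, numeric(1))
    (1 + sum(perm <= M2)) / (1 + permutations)
  })
  structure(list(M2 = M2, p = p, X = x0,
                 Yrot = sum(s$d) * y0 %*% rot),
            class = "isc_procrustes")
}

#' @export
print.isc_procrustes <- function(x, ...) {
  cat(sprintf("Procrustes: M2 = %.6g, permutation p = %.4g\n", x$M2, x$p))
  invisible(x)
}

#' Medoid of a point configuration (PAM with k = 1)
#'
#' @param points n x d coordinate matrix.
#' @return the index of the point minimizing the sum of Euclidean distances
#'   to all points (ties go to the lowest index).
#' @export
medoid <- function(points) {
  m <- as.matrix(points)
  if (nrow(m) < 1L) stop("medoid of an empty configuration")
  d <- as.matrix(stats::dist(m))
  unname(which.min(colSums(d)))
}

#' Per-sample correction effectiveness
#'
#' `delta_e = d(m, a) - d(m, b)` with Euclidean distances in the shared
#' (Procrustes-aligned) ordination space: `m` the pre-treatment medoid,
#' `b` the sample's pre-treatment position, `a` its post-treatment position.
#' Negative values mean the sample moved toward the medoid, i.e. similarity
#' improved after correction.
#'
#' @param m,a,b coordinate vectors (same dimension).
#' @return numeric scalar.
#' @export
delta_e <- function(m, a, b) {
  sqrt(sum((m - a)^2)) - sqrt(sum((m - b)^2))
}

#' Mean correction effectiveness between two groups
#'
#' `E-bar(g1, g2) = mean(dE_g1) - mean(dE_g2)`; negative values are read as
#' improved similarity.
#'
#' @param dE_g1,dE_g2 per-sample `delta_e` vectors of the two groups.
#' @return numeric scalar.
#' @export
mean_effectiveness <- function(dE_g1, dE_g2) {
  stopifnot(length(dE_g1) > 0L, length(dE_g2) > 0L)
  mean(dE_g1) - mean(dE_g2)
}

#' One-sample t-test of the effectiveness vector against zero
#'
#' Two-sided. Zero-variance vectors take a degenerate path: p = 1 when the
#' mean is 0, else p = 0 (flagged with a warning).
#'
#' @param dE vector of per-sample `delta_e` values (length >= 3).
#' @return the two-sided p-value.
#' @export
test_delta_e <- function(dE) {
  stopifnot(length(dE) >= 3L)
  if (stats::sd(dE) == 0) {
    if (mean(dE) == 0) return(1)
    warning("zero-variance effectiveness vector with nonzero mean")
    return(0)
  }
  stats::t.test(dE, mu = 0)$p.value
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, ".", ""))))
}

#' Pairwise group-effectiveness matrix
#'
#' For every ordered group pair (rows are g1): `E-bar` via
#' [mean_effectiveness()] and a Welch two-sample t-test between the two
#' `delta_e` vectors; stars encode `*** p<0.001`, `** p<0.01`, `* p<0.05`,
#' `. p<0.1`. Groups with fewer than 3 samples are excluded with a warning.
#' Holm adjustment of the p-values is optional.
#'
#' @param groups named list: group id -> `delta_e` vector.
#' @param p_adjust adjust p-values by Holm's method?
#' @return list with matrices `E` (antisymmetric), `p` and `stars`.
#' @export
pairwise_matrix <- function(groups, p_adjust = FALSE) {
  n <- vapply(groups, length, integer(1))
  if (any(n < 3L)) {
    warning("excluding group(s) with < 3 samples: ",
            paste(names(groups)[n < 3L], collapse = ", "))
    groups <- groups[n >= 3L]
  }
  g <- names(groups)
  if (length(g) < 2L) stop("need at least 2 groups with >= 3 samples")
  E <- matrix(0, length(g), length(g), dimnames = list(g, g))
  P <- matrix(1, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i == j) next
    E[i, j] <- mean_effectiveness(groups[[i]], groups[[j]])
    P[i, j] <- tryCatch(stats::t.test(groups[[i]], groups[[j]])$p.value,
                        error = function(e)  # both groups degenerate
                          if (E[i, j] == 0) 1 else 0)
  }
  if (p_adjust) {
    off <- row(P) != col(P)
    P[off] <- stats::p.adjust(P[off], method = "holm")
  }
  list(E = E, p = P, stars = matrix(p_stars(P), nrow(P),
                                    dimnames = dimnames(P)))
}

#' Correlation between window-length difference and effectiveness
#'
#' Spearman correlation, across unordered group pairs, between the absolute
#' amplicon-length difference of the two groups' windows and `E-bar` of the
#' pair oriented longer-minus-shorter (so a negative correlation means
#' larger scale differences were corrected more strongly).
#'
#' @param lengths named numeric vector: group id -> amplicon window length.
#' @param pair_matrix output of [pairwise_matrix()].
#' @return list with `rho`, `p` and the per-pair data.frame `pairs`.
#' @export
length_effect_correlation <- function(lengths, pair_matrix) {
  g <- rownames(pair_matrix$E)
  stopifnot(all(g %in% names(lengths)))
  pr <- t(utils::combn(g, 2L))
  if (nrow(pr) < 3L) stop("need at least 3 group pairs")
  dl <- abs(lengths[pr[, 1L]] - lengths[pr[, 2L]])
  ebar <- vapply(seq_len(nrow(pr)), function(i) {
    a <- pr[i, 1L]; b <- pr[i, 2L]
    if (lengths[a] >= lengths[b]) pair_matrix$E[a, b] else
      pair_matrix$E[b, a]
  }, numeric(1))
  if (stats::sd(ebar) == 0)
    stop("effectiveness is constant across pairs; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(dl, ebar, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       pairs = data.frame(g1 = pr[, 1L], g2 = pr[, 2L],
                          dlength = unname(dl), ebar = ebar))
}

#' Evaluate information scale correction for paired pre/post tables
#'
#' The pre- and post-correction samples are ordinated by NMDS on
#' Bray-Curtis dissimilarities, the pre-treatment medoid is located, and
#' per-sample effectiveness `delta_e = d(medoid, post) - d(medoid, pre)` is
#' computed with Euclidean distances. Columns of `table_pre` and
#' `table_post` must be the same samples in the same order, counted in one
#' common ASV space.
#'
#' With `ordination = "joint"` (the default) all pre and post columns are
#' ordinated together, so both configurations share one space and `delta_e`
#' uses the joint coordinates directly; the Procrustes statistic is
#' computed between the pre- and post-sample subconfigurations. With
#' `ordination = "separate"` each arm is ordinated on its own and the two
#' configurations are merged by Procrustes, with `delta_e` measured in the
#' aligned space. The separate mode degenerates when the pre-correction
#' table splits the samples into groups with disjoint ASV support (all
#' between-group dissimilarities saturate at 1 and a zero-stress ordination
#' collapses each group to a point), which is precisely the situation a
#' scale-discordant dataset pair creates; the joint ordination anchors the
#' arms through the unchanged samples and is therefore the default.
#'
#' @param table_pre,table_post ASV x sample count matrices.
#' @param groups optional factor/character of group labels per sample.
#' @param ordination `"joint"` or `"separate"` (see Details).
#' @param n_starts,permutations,seed see [nmds_ordinate()] and
#'   [procrustes_fit()].
#' @return list of class `isc_evaluation` with the pre/post configurations
#'   (`X`, `Y`), the Procrustes result, `medoid_id`, the named `delta_e`
#'   vector, the convergence fraction (share of samples with
#'   `delta_e < 0`), the one-sample t-test p-value, and (when `groups` is
#'   given) per-group `delta_e` vectors plus the pairwise matrix.
#' @export
evaluate_correction <- function(table_pre, table_post, groups = NULL,
                                ordination = c("joint", "separate"),
                                n_starts = 20L, permutations = 999L,
                                seed = NULL) {
  ordination <- match.arg(ordination)
  stopifnot(identical(colnames(table_pre), colnames(table_post)),
            identical(rownames(table_pre), rownames(table_post)))
  with_seed(seed, {
    n <- ncol(table_pre)
    if (ordination == "joint") {
      comb <- cbind(table_pre, table_post)
      colnames(comb) <- c(paste0(colnames(table_pre), "|pre"),
                          paste0(colnames(table_post), "|post"))
      ord <- nmds_ordinate(bray_curtis(comb), n_starts = n_starts)
      X <- ord$points[seq_len(n), , drop = FALSE]
      Y <- ord$points[n + seq_len(n), , drop = FALSE]
      pr <- procrustes_fit(X, Y, permutations = permutations)
      ords <- list(joint = ord)
    } else {
      ord_pre <- nmds_ordinate(bray_curtis(table_pre), n_starts = n_starts)
      ord_post <- nmds_ordinate(bray_curtis(table_post),
                                n_starts = n_starts)
      pr <- procrustes_fit(ord_pre, ord_post, permutations = permutations)
      X <- pr$X
      Y <- pr$Yrot
      ords <- list(pre = ord_pre, post = ord_post)
    }
    m_idx <- medoid(X)
    m <- X[m_idx, ]
    dE <- vapply(seq_len(n), function(i)
      delta_e(m, a = Y[i, ], b = X[i, ]), numeric(1))
    names(dE) <- colnames(table_pre)
    out <- c(ords,
             list(X = X, Y = Y, procrustes = pr,
                  medoid_id = colnames(table_pre)[m_idx], delta_e = dE,
                  convergence = mean(dE < 0), p_delta_e = test_delta_e(dE)))
    if (!is.null(groups)) {
      out$group_delta_e <- split(dE, groups)
      out$pairwise <- pairwise_matrix(out$group_delta_e)
    }
    structure(out, class = "isc_evaluation")
  })
}

#' @export
print.isc_evaluation <- function(x, ...) {
  cat(sprintf("ISC evaluation over %d samples\n", length(x$delta_e)))
  cat(sprintf("  Procrustes M2 = %.6g (permutation p = %.4g)\n",
              x$procrustes$M2, x$procrustes$p))
  cat(sprintf("  mean delta_e = %.4g (t-test p = %.4g)\n",
              mean(x$delta_e), x$p_delta_e))
  cat(sprintf("  convergence: %.1f%% of samples moved toward the medoid\n",
              100 * x$convergence))
  invisible(x)
}
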