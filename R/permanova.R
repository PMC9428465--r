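#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = 1 - 2 * sum(min(u_i, v_i)) / sum(u_i + v_i)`: 0 for identical
#' communities, 1 for communities with disjoint taxon support.
#'
#' @param mat Non-negative matrix, communities in rows, taxa in columns.
#' @return Symmetric dissimilarity matrix with zero diagonal. Pairs of
#'   all-zero rows are undefined (`NaN`, with a warning).
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop_input("bray_curtis requires non-negative values")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(mat[i, ] + mat[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) {
        NaN
      } else {
        1 - 2 * sum(pmin(mat[i, ], mat[j, ])) / denom
      }
    }
  }
  if (any(is.nan(d))) {
    warning("dissimilarity undefined for pair(s) of all-zero communities",
      call. = FALSE
    )
  }
  d
}

## Gower-centered inner-product matrix of a squared distance matrix:
## G = -(1/2) J D^2 J with J the centering projector. tr(G) is the total
## sum of squared distances / n.
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

permanova_f <- function(g, hat, rank_x) {
  n <- nrow(g)
  ## tr(H G) = sum(H * G) for symmetric H, G
  ss_model <- sum(hat * g)
  ss_total <- sum(diag(g))
  ss_res <- ss_total - ss_model
  df1 <- rank_x - 1
  df2 <- n - rank_x
  list(
    f = (ss_model / df1) / (ss_res / df2),
    df = c(between = df1, within = df2),
    ss = c(model = ss_model, residual = ss_res, total = ss_total)
  )
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a distance matrix with respect to a predictor using the
#' trace form of the pseudo-F statistic: the squared distances are
#' Gower-centered and projected onto the predictor's model matrix, giving
#' `F = (SS_model / df1) / (SS_residual / df2)`. Significance comes from
#' permuting observation labels: `p = (1 + #(F_perm >= F_obs)) /
#' (1 + n_perm)`. The predictor may be a grouping factor (the usual
#' treatment comparison) or a continuous covariate (regression on the
#' distance matrix, 1 model df).
#'
#' With `method = "exhaustive"` every distinct relabelling is enumerated
#' (all label permutations; feasible for small n) and the p-value is the
#' exact proportion of relabellings with `F >= F_obs`, counting the
#' observed one.
#'
#' @param d Distance matrix (square symmetric matrix or `dist`).
#' @param groups Grouping factor (>= 2 groups of >= 2) or numeric
#'   covariate.
#' @param n_perm Number of Monte-Carlo permutations; default 999.
#' @param seed Integer seed for the permutations.
#' @param method `"monte-carlo"` (default) or `"exhaustive"`.
#' @return An object of class `"permanova_result"`: list with `pseudo_f`,
#'   `df` (between, within), `p_perm`, `n_perm`, `ss`, and `method`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      method = c("monte-carlo", "exhaustive")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n) {
    stop_input("groups length (%d) must match distance matrix size (%d)",
      length(groups), n
    )
  }
  if (any(!is.finite(d))) stop_input("distance matrix has undefined entries")

  continuous <- is.numeric(groups) && !is.factor(groups)
  if (!continuous) {
    groups <- factor(groups)
    sizes <- table(groups)
    if (nlevels(groups) < 2) stop_input("need >= 2 groups")
    if (any(sizes < 2)) {
      stop_input(
        "singleton group(s): %s",
        paste(names(sizes)[sizes < 2], collapse = ", ")
      )
    }
    x <- stats::model.matrix(~groups)
  } else {
    x <- cbind(1, groups)
  }
  rank_x <- qr(x)$rank
  hat <- x %*% solve(crossprod(x)) %*% t(x)
  g <- gower_center(d)
  obs <- permanova_f(g, hat, rank_x)

  if (method == "exhaustive") {
    if (n > 9) stop_input("exhaustive enumeration is limited to n <= 9")
    perms <- all_permutations(n)
    f_all <- vapply(seq_len(nrow(perms)), function(i) {
      idx <- perms[i, ]
      permanova_f(g[idx, idx], hat, rank_x)$f
    }, numeric(1))
    p <- mean(f_all >= obs$f - 1e-12)
    n_used <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        permanova_f(g[idx, idx], hat, rank_x)$f
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= obs$f - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }

  structure(
    list(
      pseudo_f = obs$f, df = obs$df, p_perm = p, n_perm = n_used,
      ss = obs$ss, method = method
    ),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.3f, p = %.4g (%s, %d permutations)\n",
    x$df[["between"]], x$df[["within"]], x$pseudo_f, x$p_perm,
    x$method, x$n_perm
  ))
  invisible(x)
}

## All n! row permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Runs [permanova()] on every pair of groups and multiplies each raw
#' permutation p-value by the number of pairs (capped at 1), the
#' Bonferroni guard against inflated type-I error from multiple
#' comparisons.
#'
#' @inheritParams permanova
#' @return A tibble with columns `group1`, `group2`, `pseudo_f`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  pairs <- combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  rows <- purrr::map(seq_len(n_pairs), function(j) {
    sel <- groups %in% pairs[, j]
    res <- permanova(
      d[sel, sel], droplevels(groups[sel]),
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + j
    )
    tibble::tibble(
      group1 = pairs[1, j], group2 = pairs[2, j],
      pseudo_f = res$pseudo_f, p_raw = res$p_perm,
      p_adj = min(res$p_perm * n_pairs, 1)
    )
  })
  dplyr::bind_rows(rows)
}

#' Principal components analysis of community composition
#'
#' Column-centered, unscaled PCA of a replicate x taxon relative-abundance
#' matrix (proportions share a scale, so no standardisation). The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param mat Matrix of relative abundances, replicates in rows.
#' @return List with `scores` (replicate x component), `loadings`
#'   (taxon x component, orthonormal columns), and `var_explained`
#'   (fraction per component, non-increasing). A zero-variance matrix
#'   yields zero scores and zero variance explained.
#' @export
pca_composition <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop_input("pca_composition needs >= 2 replicates and >= 2 taxa")
  }
  centered <- scale(mat, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var == 0) {
    k <- min(dim(mat))
    return(list(
      scores = matrix(0, nrow(mat), k),
      loadings = diag(ncol(mat))[, seq_len(k), drop = FALSE],
      var_explained = rep(0, k)
    ))
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  list(
    scores = sweep(pc$x, 2, flip, `*`),
    loadings = sweep(pc$rotation, 2, flip, `*`),
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  )
}
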