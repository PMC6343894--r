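#' Kruskal-Wallis rank test
#'
#' Hand-implemented Kruskal-Wallis test with mid-ranks for ties and the
#' standard tie correction. For `N` observations in `k` groups with group
#' rank means \eqn{\bar R_i},
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \tfrac{N+1}{2})^2}
#' divided by the tie-correction factor
#' \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)} over tie group sizes `t`. When all
#' values are tied the statistic is defined as 0 (p = 1). The p-value uses
#' the chi-squared upper tail with `k - 1` degrees of freedom.
#'
#' @param x Numeric response vector.
#' @param g Grouping vector (coerced to factor) of the same length.
#' @return An object of class `llp_stat` with fields `statistic`, `df`,
#'   `p_value`, `method`, `n` (per-group sizes).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(1:3, each = 3)) # H = 7.2
#' @export
kruskal_wallis <- function(x, g) {
  if (length(x) != length(g)) stop_invalid("'x' and 'g' must have equal length")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g[keep]))
  k <- nlevels(g)
  if (k < 2L) stop_invalid("need at least 2 groups")
  n_i <- table(g)
  if (any(n_i == 0L)) stop_invalid("every group needs at least one observation")
  N <- length(x)
  r <- rank(x)  # mid-ranks for ties
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0  # all observations tied
  } else {
    H <- H / C
  }
  p <- if (H == 0 && C <= 0) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(
    list(statistic = H, df = k - 1L, p_value = p,
         method = "Kruskal-Wallis rank test",
         n = as.integer(n_i), groups = levels(g)),
    class = "llp_stat"
  )
}

#' @export
print.llp_stat <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  chi-squared(%d) = %.3f, p = %.3f\n", x$df, x$statistic, x$p_value))
  cat("  group sizes:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Nemenyi pairwise rank contrasts
#'
#' All-pairs post-hoc contrasts on joint mid-ranks following a
#' Kruskal-Wallis test. Two variants:
#' \describe{
#'   \item{`chisq`}{statistic for pair (i, j):
#'     \eqn{(\bar R_i - \bar R_j)^2 / [\frac{N(N+1)}{12}(1/n_i + 1/n_j)]},
#'     p from the chi-squared upper tail with `k - 1` df.}
#'   \item{`tukey`}{\eqn{q = |\bar R_i - \bar R_j| /
#'     \sqrt{\frac{N(N+1)}{24}(1/n_i + 1/n_j)}}, p from the studentized
#'     range distribution with `k` groups and infinite df.}
#' }
#'
#' @inheritParams kruskal_wallis
#' @param variant `"chisq"` (default; contrasts reported as chi-squared
#'   statistics) or `"tukey"`.
#' @return An object of class `nemenyi_test`: a data frame of all unordered
#'   group pairs with columns `group1`, `group2`, `statistic`, `p_value`,
#'   plus attributes `variant` and `df`.
#' @export
nemenyi_pairwise <- function(x, g, variant = c("chisq", "tukey")) {
  variant <- match.arg(variant)
  if (length(x) != length(g)) stop_invalid("'x' and 'g' must have equal length")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g[keep]))
  k <- nlevels(g)
  if (k < 3L) stop_invalid("Nemenyi contrasts need at least 3 groups")
  n_i <- table(g)
  if (any(n_i == 0L)) stop_invalid("every group needs at least one observation")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- rbar[[i]] - rbar[[j]]
    inv <- 1 / n_i[[i]] + 1 / n_i[[j]]
    if (variant == "chisq") {
      stat <- d^2 / ((N * (N + 1) / 12) * inv)
      p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    } else {
      stat <- abs(d) / sqrt((N * (N + 1) / 24) * inv)
      p <- stats::ptukey(stat, nmeans = k, df = Inf, lower.tail = FALSE)
    }
    c(stat = stat, p = p)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = res["stat", ], p_value = res["p", ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, variant = variant, df = k - 1L,
            class = c("nemenyi_test", "data.frame"))
}

#' @export
print.nemenyi_test <- function(x, ...) {
  cat("Nemenyi pairwise contrasts (", attr(x, "variant"), " variant)\n", sep = "")
  df <- as.data.frame(x)
  df$statistic <- report_round(df$statistic, 3)
  df$p_value <- report_round(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Correspondence analysis of a contingency table
#'
#' Chi-square-metric ordination of a non-negative frequency table, computed
#' from first principles: with correspondence matrix \eqn{P = X/N}, row and
#' column masses `r`, `c`, the matrix of standardized residuals
#' \deqn{S = D_r^{-1/2} (P - r c^\top) D_c^{-1/2}}
#' is decomposed by SVD. Principal inertias are the squared singular
#' values; their sum (the total inertia) equals the Pearson chi-squared
#' statistic of the table divided by `N`, and each axis explains its share
#' of it. Row and column scores are reported in principal coordinates
#' (symmetric scaling), which reproduce the chi-squared distances among row
#' (and column) profiles.
#'
#' @param tab Matrix-like contingency table of non-negative counts with at
#'   least 2 rows and 2 columns and no all-zero margin.
#' @return An object of class `ca_result`: list with `row_scores`,
#'   `col_scores` (principal coordinates, one column per axis),
#'   `principal_inertias`, `proportion`, `cumulative`, `total_inertia`,
#'   `degenerate` (`TRUE` when the table is rank 1 under independence, i.e.
#'   total inertia 0, in which case proportions are `NA`).
#' @examples
#' tab <- rbind(c(10, 2, 4), c(3, 12, 5))
#' correspondence_analysis(tab)$proportion # single axis: 1
#' @export
correspondence_analysis <- function(tab) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || any(tab < 0) || anyNA(tab))
    stop_invalid("'tab' must be a non-negative numeric matrix")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_invalid("contingency table needs at least 2 rows and 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("all-zero row or column margin; drop it before analysis")
  N <- sum(tab)
  P <- tab / N
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  K <- min(nrow(tab), ncol(tab)) - 1L  # trivial dimension removed
  d <- sv$d[seq_len(K)]
  inertias <- d^2
  total <- sum(sv$d^2)
  degenerate <- total < 1e-12
  prop <- if (degenerate) rep(NA_real_, K) else inertias / total
  row_scores <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(K), drop = FALSE] %*% diag(d, K)
  col_scores <- diag(1 / sqrt(cc)) %*% sv$v[, seq_len(K), drop = FALSE] %*% diag(d, K)
  dimnames(row_scores) <- list(rownames(tab), paste0("CA", seq_len(K)))
  dimnames(col_scores) <- list(colnames(tab), paste0("CA", seq_len(K)))
  structure(
    list(row_scores = row_scores,
         col_scores = col_scores,
         principal_inertias = inertias,
         proportion = prop,
         cumulative = if (degenerate) rep(NA_real_, K) else cumsum(prop),
         total_inertia = total,
         degenerate = degenerate,
         n = N),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis\n")
  if (x$degenerate) {
    cat("  degenerate table: total inertia 0 (rows proportional)\n")
  } else {
    cat(sprintf("  total inertia: %.4f (= chi-squared / N)\n", x$total_inertia))
    for (i in seq_along(x$principal_inertias))
      cat(sprintf("  axis %d: inertia %.4f (%.1f%%, cumulative %.1f%%)\n",
                  i, x$principal_inertias[i], 100 * x$proportion[i],
                  100 * x$cumulative[i]))
  }
  invisible(x)
}

#' Distance-based permutational multivariate ANOVA
#'
#' Partitions the total sum of squared Euclidean distances among
#' observations into sequential components for one or more factors, with
#' significance assessed by permuting raw observations. Computed via the
#' Gower-centred inner-product matrix `G` of the distance matrix: for hat
#' matrix `H` of a model, the explained sum of squares is `tr(H G H)`, and
#' sequential terms are differences between nested models. The pseudo-F for
#' each term is its mean square over the residual mean square; the
#' permutation p-value is `(number of permuted F >= observed F + 1) /
#' (n_permutations + 1)`, so p is never reported below
#' `1/(n_permutations + 1)`.
#'
#' The observed pseudo-F is deterministic (the seed affects only the
#' permutation p-value). With a single response column the one-factor
#' pseudo-F equals the classical one-way ANOVA F.
#'
#' @param response Numeric matrix (observations x variables) or vector.
#' @param factors A factor, or data frame of factors (terms entered
#'   sequentially in column order).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `permanova`: a list with an ANOVA-style table
#'   (`terms`: Df, SumOfSqs, F, p_value), `total_ss`, `n_permutations`.
#' @export
permanova <- function(response, factors, n_permutations = 999, seed = NULL) {
  Y <- as.matrix(response)
  if (!is.numeric(Y)) stop_invalid("'response' must be numeric")
  if (is.data.frame(factors)) {
    fdf <- factors
  } else {
    fdf <- data.frame(factor = factors)
  }
  fdf[] <- lapply(fdf, factor)
  n <- nrow(Y)
  if (any(vapply(fdf, length, integer(1)) != n))
    stop_invalid("factors must match the number of observations")
  if (!is_count(n_permutations) || n_permutations < 1)
    stop_invalid("'n_permutations' must be a positive integer")

  # Gower-centred inner-product matrix from Euclidean distances
  D2 <- as.matrix(stats::dist(Y))^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J

  # sequential hat matrices for nested models (intercept, +term1, +term2, ...)
  hats <- list(matrix(1 / n, n, n))
  X <- matrix(1, n, 1)
  for (j in seq_along(fdf)) {
    X <- cbind(X, stats::model.matrix(~ fdf[[j]])[, -1, drop = FALSE])
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[j + 1L]] <- tcrossprod(Q)
  }
  H_full <- hats[[length(hats)]]
  df_terms <- integer(length(fdf))
  for (j in seq_along(fdf))
    df_terms[j] <- round(sum(diag(hats[[j + 1L]])) - sum(diag(hats[[j]])))
  df_res <- n - as.integer(round(sum(diag(H_full))))
  if (df_res < 1L)
    stop_invalid("no residual degrees of freedom (a factor level with a single ",
                 "observation, or a saturated model)")

  ss_fun <- function(Gm) {
    ss_terms <- vapply(seq_along(fdf), function(j)
      sum((hats[[j + 1L]] - hats[[j]]) * Gm), numeric(1))
    ss_res <- sum((diag(n) - H_full) * Gm)
    list(terms = ss_terms, res = ss_res)
  }
  obs <- ss_fun(G)
  F_obs <- (obs$terms / df_terms) / (obs$res / df_res)

  exceed <- integer(length(fdf))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      perm <- ss_fun(G[p, p])
      F_perm <- (perm$terms / df_terms) / (perm$res / df_res)
      exceed <- exceed + (F_perm >= F_obs)
    }
  })
  p_values <- (exceed + 1) / (n_permutations + 1)

  terms_tab <- data.frame(
    term = c(names(fdf), "Residual", "Total"),
    Df = c(df_terms, df_res, n - 1L),
    SumOfSqs = c(obs$terms, obs$res, sum(diag(G))),
    F = c(F_obs, NA, NA),
    p_value = c(p_values, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(terms = terms_tab,
         total_ss = sum(diag(G)),
         n_permutations = n_permutations,
         method = "PERMANOVA (Euclidean distance, sequential SS)"),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(x$method, "-", x$n_permutations, "permutations\n")
  tab <- x$terms
  tab$SumOfSqs <- report_round(tab$SumOfSqs, 3)
  tab$F <- report_round(tab$F, 3)
  tab$p_value <- report_round(tab$p_value, 3)
  print(tab, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Tidy a fitted statistics object into a flat data frame
#'
#' @param x An `llp_stat`, `nemenyi_test`, `ca_result` or `permanova`
#'   object.
#' @param label Optional label stored in the `response` column.
#' @return Data frame with columns `method`, `response`, `term`,
#'   `statistic`, `df`, `p_value`.
#' @export
tidy_stat <- function(x, label = NA_character_) {
  if (inherits(x, "llp_stat")) {
    data.frame(method = "kruskal_wallis", response = label, term = "treatment",
               statistic = x$statistic, df = x$df, p_value = x$p_value,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "nemenyi_test")) {
    data.frame(method = paste0("nemenyi_", attr(x, "variant")), response = label,
               term = paste(x$group1, x$group2, sep = "-"),
               statistic = x$statistic, df = attr(x, "df"), p_value = x$p_value,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "permanova")) {
    tt <- x$terms[!x$terms$term %in% c("Residual", "Total"), , drop = FALSE]
    data.frame(method = "permanova", response = label, term = tt$term,
               statistic = tt$F, df = tt$Df, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "ca_result")) {
    data.frame(method = "correspondence_analysis", response = label,
               term = paste0("axis", seq_along(x$principal_inertias)),
               statistic = x$principal_inertias,
               df = NA_integer_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    stop_invalid("unsupported object for tidy_stat")
  }
}
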