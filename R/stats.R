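# Nonparametric cohort statistics: Mann-Whitney U (exact by enumeration for
# small samples, normal approximation with tie correction otherwise),
# Spearman rank correlation (exact by permutation for small n), and
# per-family Benjamini-Hochberg FDR adjustment.

#' Mann-Whitney U test
#'
#' The statistic is `U = min(U_a, U_b)` computed from midranks. In exact
#' mode the two-sided p-value is the fraction of all `choose(n_a+n_b, n_a)`
#' group labelings whose folded statistic `min(U_a, U_b)` is at most the
#' observed one (the folding counts both tails). In approximate mode a
#' normal approximation with tie correction and continuity correction is
#' used. `auto` picks exact when `n_a + n_b <= 16`.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return One-row tibble: `statistic` (U), `p_value`, `method`,
#'   `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a == 0L || n_b == 0L) {
    rlang::abort("Both groups must be non-empty.", class = "hippomorph_stats_error")
  }
  if (mode == "auto") mode <- if (n_a + n_b <= 16L) "exact" else "approx"
  pooled <- c(group_a, group_b)
  r <- rank(pooled) # midranks
  u_obs <- u_min_from_ranks(r, seq_len(n_a), n_a, n_b)
  if (mode == "exact") {
    combos <- utils::combn(n_a + n_b, n_a)
    stats_all <- apply(combos, 2, function(ix) u_min_from_ranks(r, ix, n_a, n_b))
    p <- mean(stats_all <= u_obs + 1e-9)
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
    }
  }
  tibble::tibble(
    statistic = u_obs, p_value = min(p, 1), method = paste0("mann_whitney_", mode),
    n_a = n_a, n_b = n_b
  )
}

u_min_from_ranks <- function(r, idx_a, n_a, n_b) {
  ua <- sum(r[idx_a]) - n_a * (n_a + 1) / 2
  min(ua, n_a * n_b - ua)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks. In exact mode (auto for
#' `n <= 8`) the two-sided p-value is the fraction of all `n!` permutations
#' of one variable with `|rho|` at least the observed value; otherwise the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3` after removing
#'   pairs with missing values).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return One-row tibble: `statistic` (rho), `p_value`, `method`, `n`.
#' @export
spearman_rho <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    rlang::abort("Spearman correlation needs at least 3 complete pairs.",
      class = "hippomorph_stats_error"
    )
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    rlang::abort("Constant input: rho is undefined.", class = "hippomorph_stats_error")
  }
  if (mode == "auto") mode <- if (n <= 8L) "exact" else "approx"
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (mode == "exact") {
    perms <- permutations_all(n)
    rho_perm <- as.vector(stats::cor(rx, matrix(ry[perms], nrow = n)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-9)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  tibble::tibble(
    statistic = rho, p_value = p, method = paste0("spearman_", mode), n = n
  )
}

# All permutations of 1..n as an n x n! index matrix (n <= 8 in practice).
permutations_all <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    ins <- rbind(sub, n) # row n holds the new element; insert it at position k
    ins <- ins[append(seq_len(n - 1L), n, after = k - 1L), , drop = FALSE]
    out[, col + seq_len(ncol(sub))] <- ins
    col <- col + ncol(sub)
  }
  out
}

#' Benjamini-Hochberg adjustment within one family
#'
#' Step-up FDR adjustment (`adjusted_(i) = min_{j >= i} (m/j) p_(j)`,
#' capped at 1), applied to one analysis family at a time and mapped back
#' to the input order. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1].", class = "hippomorph_stats_error")
  }
  stats::p.adjust(p, method = "BH")
}
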