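#' Single-factor PERMANOVA on a distance matrix
#'
#' Partitions the squared-distance variance by a grouping factor:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, \eqn{SS_{within}} is the
#' analogous per-group sum, \eqn{R^2 = SS_{between} / SS_{total}}, and the
#' pseudo-F statistic is tested by permuting group labels. The permutation
#' p-value uses the \eqn{(1 + b) / (1 + n_{perm})} estimator, so it can never
#' be zero and has granularity 1/1000 at the conventional 999 permutations.
#' With \code{n_perm = "exact"} all label permutations are enumerated and the
#' p-value is the exact fraction (identity included) with
#' \eqn{F_{perm} \ge F_{obs}}.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param groups grouping labels, one per sample (>= 2 groups).
#' @param n_perm number of permutations (default 999), or \code{"exact"}.
#' @param seed integer seed for the permutations.
#' @return an object of class \code{permanova_result}: list with
#'   \code{r_squared}, \code{p_value}, \code{f_observed}, \code{df},
#'   \code{n_permutations}.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2) stop("need at least two groups")
  d2 <- dm^2

  ss_stats <- function(g) {
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx, drop = FALSE]
        ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    c(ss_t, ss_w)
  }
  a <- length(unique(groups))
  obs <- ss_stats(groups)
  ss_total <- obs[1]; ss_within <- obs[2]
  ss_between <- ss_total - ss_within
  r2 <- if (ss_total > 0) ss_between / ss_total else 0
  f_obs <- (ss_between / (a - 1)) / (ss_within / (n - a))

  f_of <- function(g) {
    s <- ss_stats(g)
    ((s[1] - s[2]) / (a - 1)) / (s[2] / (n - a))
  }

  if (identical(n_perm, "exact")) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1, function(idx) f_of(groups[idx]))
    p <- mean(fs >= f_obs - 1e-12)
    np <- nrow(perms)
  } else {
    fs <- with_seed(seed, replicate(n_perm, f_of(sample(groups))))
    p <- (1 + sum(fs >= f_obs - 1e-12)) / (n_perm + 1)
    np <- n_perm
  }
  structure(list(r_squared = r2, p_value = p, f_observed = f_obs,
                 df = c(between = a - 1, within = n - a),
                 n_permutations = np),
            class = "permanova_result")
}

all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8 samples")
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    r <- 0
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(k)) {
        r <- r + 1
        out[r, ] <- append(perms[i, ], k, after = pos - 1)
      }
    }
    perms <- out
  }
  perms
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.3f, F = %.3f, p = %.4g (%d permutations)\n",
              x$r_squared, x$f_observed, x$p_value, x$n_permutations))
  invisible(x)
}
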