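#' Group means and standard deviations of a per-tree metric
#'
#' @param data Per-tree data frame with a grouping column (`"palm"` /
#'   `"dicot"`) and the metric of interest.
#' @param metric Column name (string) of the metric.
#' @param group Column name of the group label (default `"group"`).
#' @return A tibble, one row per group: `group`, `mean`, `sd`, `n`; `sd` is
#'   `NA` (flagged with a warning) for single-member groups.
#' @examples
#' d <- tibble::tibble(group = c("palm", "palm", "dicot", "dicot", "dicot"),
#'                     theta_t = c(0.673, 0.728, 0.459, 0.391, 0.485))
#' group_means(d, "theta_t")
#' @export
group_means <- function(data, metric, group = "group") {
  check_columns(data, c(metric, group), "data")
  vals <- data[[metric]]
  if (any(!nzchar(data[[group]])) || anyNA(data[[group]]))
    stop("group labels must be complete", call. = FALSE)
  out <- data |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sd = sd_or_na(.data[[metric]]),
                     n = dplyr::n(),
                     .by = dplyr::all_of(group))
  if (!all(c("palm", "dicot") %in% out[[group]]))
    stop("both groups must be non-empty", call. = FALSE)
  if (any(is.na(out$sd)))
    warning("sd undefined for single-member group(s)", call. = FALSE)
  tibble::as_tibble(out)
}

#' One-sample t-test of one group against the other group's mean
#'
#' Tests whether the values of one group (typically the larger dicot group)
#' differ from the other group's mean treated as the hypothesised value —
#' the small-sample design used when one group has too few members for a
#' two-sample test.
#'
#' @param values Numeric vector (>= 2 values, nonzero variance).
#' @param mu Hypothesised mean (the reference group's mean).
#' @return A one-row tibble `estimate`, `t_statistic`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu)
  tibble::tibble(estimate = unname(tt$estimate),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Permutation test on the difference in group means
#'
#' Two-sided permutation test with the difference in group means as the
#' statistic. Group labels are permuted uniformly; the p-value is the
#' proportion of permuted absolute differences at least as large as the
#' observed one, counting the observed arrangement (so p > 0 always). When
#' the number of distinct label arrangements is at most `n_perm`, the test
#' enumerates all of them exactly instead of sampling — at the study's
#' sample sizes (2 palms vs 5 dicots, 21 arrangements) the test is exact.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param n_perm Monte-Carlo iterations when enumeration is infeasible
#'   (default 5000).
#' @param seed Integer seed for the Monte-Carlo path.
#' @return A one-row tibble `observed_diff`, `p_value`, `n_permutations`,
#'   `exhaustive`.
#' @examples
#' permutation_test(c(0, 0), c(1, 1, 1)) # exact p = 0.1
#' @export
permutation_test <- function(x, y, n_perm = 5000, seed = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  obs <- mean(x) - mean(y)
  n_arrangements <- choose(n, nx)
  if (n_arrangements <= n_perm) {
    idx <- utils::combn(n, nx)
    diffs <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    return(tibble::tibble(observed_diff = obs, p_value = p,
                          n_permutations = n_arrangements,
                          exhaustive = TRUE))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  diffs <- replicate(n_perm, {
    i <- sample.int(n, nx)
    mean(pooled[i]) - mean(pooled[-i])
  })
  p <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  tibble::tibble(observed_diff = obs, p_value = p,
                 n_permutations = n_perm, exhaustive = FALSE)
}

#' Full palm-vs-dicot contrast for one metric
#'
#' Convenience wrapper running [group_means()], [one_sample_t()] (dicot
#' values against the palm mean) and [permutation_test()] for one per-tree
#' metric column.
#'
#' @inheritParams group_means
#' @param n_perm,seed Passed to [permutation_test()].
#' @return A one-row tibble: `metric`, `palm_mean`, `palm_sd`, `dicot_mean`,
#'   `dicot_sd`, `t_statistic`, `t_p_value`, `perm_p_value`,
#'   `n_permutations`, `exhaustive`.
#' @export
group_contrast <- function(data, metric, group = "group", n_perm = 5000,
                           seed = NULL) {
  gm <- group_means(data, metric, group)
  palm <- data[[metric]][data[[group]] == "palm"]
  dicot <- data[[metric]][data[[group]] == "dicot"]
  tt <- one_sample_t(dicot, mean(palm))
  pt <- permutation_test(palm, dicot, n_perm = n_perm, seed = seed)
  tibble::tibble(
    metric = metric,
    palm_mean = gm$mean[gm[[group]] == "palm"],
    palm_sd = gm$sd[gm[[group]] == "palm"],
    dicot_mean = gm$mean[gm[[group]] == "dicot"],
    dicot_sd = gm$sd[gm[[group]] == "dicot"],
    t_statistic = tt$t_statistic,
    t_p_value = tt$p_value,
    perm_p_value = pt$p_value,
    n_permutations = pt$n_permutations,
    exhaustive = pt$exhaustive)
}
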