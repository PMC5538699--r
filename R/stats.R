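#' Compare profile errors across reconstruction variants
#'
#' Kruskal-Wallis rank test (with tie correction) across model variants,
#' followed by all-pairs Tukey-Kramer comparisons on rank sums (the Nemenyi
#' procedure, using the studentized range distribution). The rank-based
#' post-hoc matches the nonparametric omnibus test; a parametric Tukey test
#' on raw errors would contradict it.
#'
#' @param rmse_table data frame with columns `subject`, `variant`, `rmse`
#'   (or any value column named by `value`)
#' @param value name of the value column
#' @return a `model_comparison` object: list with `kw` (htest), `posthoc`
#'   tibble of pairwise comparisons, `table` the input, `means` per-variant
#'   summary
#' @export
compare_models <- function(rmse_table, value = "rmse") {
  stopifnot(all(c("variant", value) %in% names(rmse_table)))
  x <- rmse_table[[value]]
  gname <- factor(rmse_table$variant, levels = unique(rmse_table$variant))
  if (nlevels(gname) < 2L) stop("need at least 2 variants", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate test: all values identical", call. = FALSE)
  kw <- stats::kruskal.test(x, gname)
  posthoc <- nemenyi_posthoc(x, gname)
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(variant = gname, value = x), .data$variant),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    median = stats::median(.data$value), n = dplyr::n(), .groups = "drop")
  structure(list(kw = kw, posthoc = posthoc, table = rmse_table,
                 means = means, value = value),
            class = "model_comparison")
}

# All-pairs Nemenyi comparisons on joint ranks: the difference of mean ranks
# is referred to the studentized range distribution (Tukey-Kramer form, which
# accommodates unequal group sizes).
nemenyi_posthoc <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  k <- nlevels(g)
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2L)
  out <- apply(pairs, 2L, function(p) {
    i <- p[1L]; j <- p[2L]
    se <- sqrt(n * (n + 1) / 24 * (1 / ns[[i]] + 1 / ns[[j]]))
    stat <- abs(mr[[i]] - mr[[j]]) / se
    p_adj <- stats::ptukey(stat, nmeans = k, df = Inf, lower.tail = FALSE)
    c(stat = stat, p = p_adj)
  })
  tibble::tibble(variant_a = pairs[1L, ], variant_b = pairs[2L, ],
                 mean_rank_a = as.numeric(mr[pairs[1L, ]]),
                 mean_rank_b = as.numeric(mr[pairs[2L, ]]),
                 statistic = out["stat", ], p_value = out["p", ])
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (Kruskal-Wallis + Nemenyi post-hoc)\n")
  cat(sprintf("  H = %.3f, df = %d, p = %.4g\n",
              unname(x$kw$statistic), unname(x$kw$parameter), x$kw$p.value))
  print(x$means)
  cat("Pairwise (Tukey-Kramer on rank sums):\n")
  print(x$posthoc, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_models
#' @param x a `model_comparison`
#' @param ... unused
#' @export
tidy.model_comparison <- function(x, ...) x$posthoc

#' @rdname compare_models
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(statistic = unname(x$kw$statistic),
                 df = unname(x$kw$parameter),
                 p_value = x$kw$p.value,
                 n = nrow(x$table),
                 k = nrow(x$means))
}
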