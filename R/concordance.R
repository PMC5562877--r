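#' Reduce any change product to a binary change flag
#'
#' Label maps pass through (`label == direction`); fractional maps flag any
#' strictly non-zero signed delta in the requested direction, matching the
#' convention that any non-zero tree-cover change counts as change when
#' products are compared pixel-wise.
#'
#' @param map A `change_map` or `fraction_change`.
#' @param direction `"loss"` or `"gain"`.
#' @return Logical matrix of change flags.
#' @export
to_binary_change <- function(map, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  if (inherits(map, "change_map")) {
    map$label == if (direction == "loss") 1L else 2L
  } else if (inherits(map, "fraction_change")) {
    if (direction == "loss") map$delta < 0 else map$delta > 0
  } else {
    stop("`map` must be a change_map or fraction_change", call. = FALSE)
  }
}

#' Pixel-level agreement across datasets
#'
#' Counts, per pixel, how many datasets flag change in the given direction.
#' The count is banded into the conventional categories: 0 none, 1-2 low
#' agreement, 3-4 high agreement, with 4 additionally marking full
#' agreement.
#'
#' @param flags List of logical matrices (one per dataset, same shape).
#' @param direction `"loss"` or `"gain"` (metadata only).
#' @return An `agreement_map`: integer `count` matrix, the `direction`, and
#'   the number of datasets.
#' @export
agreement_count <- function(flags, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  if (length(flags) == 0) stop("no datasets supplied", call. = FALSE)
  dims <- lapply(flags, dim)
  if (length(unique(dims)) != 1L) {
    stop("all datasets must share one grid", call. = FALSE)
  }
  count <- Reduce(`+`, lapply(flags, function(m) {
    matrix(as.integer(m), nrow(m))
  }))
  structure(list(count = count, direction = direction,
                 n_datasets = length(flags)),
            class = "agreement_map")
}

#' Band agreement counts into categories
#' @param counts Integer vector or matrix of agreement counts.
#' @return Factor (same shape flattened) with levels `none`, `low`, `high`.
#' @export
agreement_category <- function(counts) {
  cut(as.vector(counts), breaks = c(-0.5, 0.5, 2.5, 4.5),
      labels = c("none", "low", "high"))
}

#' @export
print.agreement_map <- function(x, ...) {
  cat(sprintf("<agreement_map:%s> %d datasets\n", x$direction, x$n_datasets))
  print(table(agreement_category(x$count)))
  invisible(x)
}

#' Tidy an agreement map
#' @param x An `agreement_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `count`, `category`, `full`.
#' @method as_tibble agreement_map
#' @export
as_tibble.agreement_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$count)), times = ncol(x$count)),
    col = rep(seq_len(ncol(x$count)), each = nrow(x$count)),
    count = as.vector(x$count),
    category = agreement_category(x$count),
    full = as.vector(x$count) == x$n_datasets
  )
}

#' Per-dataset composition of agreement levels
#'
#' For each dataset, among the pixels that dataset flags, the percentage
#' sitting at each agreement level (1..n datasets); rows per dataset sum
#' to 100.
#'
#' @param agreement An [agreement_count()] result.
#' @param flags The same named list of logical matrices that built it.
#' @return Tibble `(dataset, level, pct)`.
#' @export
agreement_composition <- function(agreement, flags) {
  if (is.null(names(flags))) {
    names(flags) <- paste0("dataset", seq_along(flags))
  }
  purrr::imap(flags, function(m, nm) {
    lv <- agreement$count[m]
    tibble::tibble(dataset = nm,
                   level = seq_len(agreement$n_datasets),
                   pct = if (length(lv) == 0) {
                     rep(NA_real_, agreement$n_datasets)
                   } else {
                     100 * tabulate(lv, nbins = agreement$n_datasets) /
                       length(lv)
                   })
  }) |>
    dplyr::bind_rows()
}

#' Pearson correlation with a 90%-level t-test flag
#'
#' Sample Pearson r between two provincial coverage vectors, with
#' significance judged by `t = r * sqrt((n - 2) / (1 - r^2))` against the
#' two-sided Student-t critical value at `alpha` with `n - 2` degrees of
#' freedom. A zero-variance input leaves r undefined and not significant.
#'
#' @param x,y Numeric vectors (provincial coverage percentages), length
#'   >= 3; pairs with an NA in either vector are dropped.
#' @param alpha Two-sided significance level (default 0.10, the 90% level).
#' @return One-row tibble `(r, n, t, df, significant)`.
#' @export
pearson_cor <- function(x, y, alpha = 0.10) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, n = n, t = NA_real_,
                          df = n - 2, significant = FALSE))
  }
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  crit <- stats::qt(1 - alpha / 2, df = n - 2)
  tibble::tibble(r = r, n = n, t = t, df = n - 2,
                 significant = is.finite(t) && abs(t) > crit ||
                   !is.finite(t))
}

#' Weighted Pearson correlation
#'
#' Pearson correlation computed from weighted means, variances and
#' covariance (weights normalized to sum 1), used to weight provincial
#' change relationships by provincial forest area so large-forest provinces
#' dominate. With equal weights it reduces exactly to the plain Pearson r.
#' Significance uses the Kish effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)` with `df = n_eff - 2` in the same t-test
#' as [pearson_cor()].
#'
#' @param x,y Numeric vectors; pairs with NA in x, y or w are dropped.
#' @param w Non-negative weights (e.g. provincial forest areas); scale-free.
#' @param alpha Two-sided significance level (default 0.10).
#' @return One-row tibble `(r, n, n_eff, t, df, significant)`.
#' @export
weighted_pearson <- function(x, y, w, alpha = 0.10) {
  keep <- stats::complete.cases(x, y, w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("weights must not all be zero", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  vx <- sum(wn * (x - mx)^2); vy <- sum(wn * (y - my)^2)
  cxy <- sum(wn * (x - mx) * (y - my))
  n_eff <- 1 / sum(wn^2)
  if (vx == 0 || vy == 0) {
    return(tibble::tibble(r = NA_real_, n = n, n_eff = n_eff, t = NA_real_,
                          df = n_eff - 2, significant = FALSE))
  }
  r <- cxy / sqrt(vx * vy)
  df <- n_eff - 2
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  crit <- stats::qt(1 - alpha / 2, df = df)
  tibble::tibble(r = r, n = n, n_eff = n_eff, t = t, df = df,
                 significant = abs(t) > crit)
}

#' Pairwise provincial correlation matrix across datasets
#'
#' Builds the symmetric dataset-by-dataset Pearson correlation matrix of a
#' provincial change metric, with a companion significance mask at the 90%
#' level. Provinces are matched by ID across datasets; pairs are
#' pairwise-complete. Datasets lacking the metric (all NA — e.g. an
#' inventory that only reports net change when loss is requested) simply
#' yield NA cells.
#'
#' @param data Long tibble with columns `dataset`, `province_id`, `value`
#'   and, when `weighted = TRUE`, `weight`.
#' @param weighted Use [weighted_pearson()] instead of [pearson_cor()]?
#' @param alpha Two-sided significance level.
#' @return A `cor_matrix`: `r` (matrix), `significant` (logical matrix),
#'   `n` (pair counts). Tidy with [tidy.cor_matrix()].
#' @export
correlation_matrix <- function(data, weighted = FALSE, alpha = 0.10) {
  stopifnot(all(c("dataset", "province_id", "value") %in% names(data)))
  if (weighted && !"weight" %in% names(data)) {
    stop("`weighted = TRUE` needs a `weight` column", call. = FALSE)
  }
  wide <- data |>
    dplyr::select(dplyr::any_of(c("dataset", "province_id", "value"))) |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "value")
  ds <- setdiff(names(wide), "province_id")
  k <- length(ds)
  r <- matrix(NA_real_, k, k, dimnames = list(ds, ds))
  sig <- matrix(FALSE, k, k, dimnames = list(ds, ds))
  npair <- matrix(0L, k, k, dimnames = list(ds, ds))
  wts <- NULL
  if (weighted) {
    wtab <- data |>
      dplyr::distinct(.data$province_id, .data$weight)
    wts <- wtab$weight[match(wide$province_id, wtab$province_id)]
  }
  for (i in seq_len(k)) {
    r[i, i] <- 1; sig[i, i] <- TRUE
    npair[i, i] <- sum(!is.na(wide[[ds[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- wide[[ds[i]]]; y <- wide[[ds[j]]]
      ok <- if (weighted) stats::complete.cases(x, y, wts) else
        stats::complete.cases(x, y)
      npair[i, j] <- npair[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      res <- if (weighted) weighted_pearson(x, y, wts, alpha = alpha) else
        pearson_cor(x, y, alpha = alpha)
      r[i, j] <- r[j, i] <- res$r
      sig[i, j] <- sig[j, i] <- isTRUE(res$significant)
    }
  }
  structure(list(r = r, significant = sig, n = npair,
                 weighted = weighted, alpha = alpha),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("<cor_matrix%s> alpha = %g\n",
              if (x$weighted) " (weighted)" else "", x$alpha))
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a correlation matrix into long form
#' @param x A `cor_matrix`.
#' @param ... Unused.
#' @return Tibble `(dataset1, dataset2, r, significant, n)`, upper triangle
#'   plus diagonal.
#' @method tidy cor_matrix
#' @export
tidy.cor_matrix <- function(x, ...) {
  ds <- rownames(x$r)
  idx <- which(upper.tri(x$r, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    dataset1 = ds[idx[, 1]], dataset2 = ds[idx[, 2]],
    r = x$r[idx], significant = x$significant[idx], n = as.integer(x$n[idx])
  )
}
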