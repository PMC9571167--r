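index_digits <- c(arearatio_R = 1, arearatio_L = 1, ARI = 1,
                  ang_tangent = 2, ppd = 2, pci = 2)

#' Per-group index summaries
#'
#' Mean, sample (n-1) standard deviation, minimum and maximum of each gait
#' index, per group, from a table of per-subject records. A display label
#' using the conventional rounding (1 decimal for area ratios and ARI, 2 for
#' the tangent angle, PPD and PCI; half away from zero) is included alongside
#' the unrounded values.
#'
#' @param records Data frame with columns `subject_id`, `group`, and index
#'   columns among `arearatio_R`, `arearatio_L`, `ARI`, `ang_tangent`,
#'   `ppd`, `pci`.
#' @param group Optional single group to summarise; default all groups.
#' @return Tibble with one row per group x index: `group`, `index`, `mean`,
#'   `sd`, `min`, `max`, `n`, `label`.
#' @examples
#' summarize_group(gait_index_table())
#' @export
summarize_group <- function(records, group = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.null(group)) records <- records[records$group %in% group, ]
  if (nrow(records) < 2) abort("need at least 2 records", class = "gaitpolar_format_error")
  idx_cols <- intersect(names(index_digits), names(records))
  if (!length(idx_cols)) abort("no index columns found", class = "gaitpolar_format_error")
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(idx_cols), names_to = "index", values_to = "value")
  if (any(!is.finite(long$value))) abort("indices must be finite", class = "gaitpolar_format_error")
  long |>
    dplyr::group_by(.data$group, .data$index) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = {
      d <- index_digits[.data$index]
      sprintf("%.*f ± %.*f", d, round_half_away(.data$mean, d), d, round_half_away(.data$sd, d))
    }) |>
    dplyr::mutate(index = factor(.data$index, levels = idx_cols)) |>
    dplyr::arrange(.data$group, .data$index) |>
    dplyr::mutate(index = as.character(.data$index))
}

#' Exact Mann-Whitney U test
#'
#' Two-sided rank-sum test. For tie-free samples the p-value is exact: the
#' null distribution of U over all \eqn{\binom{n_1+n_2}{n_1}} labelings
#' (obtained from the exact Wilcoxon distribution) gives
#' \eqn{p = \min\{1,\; 2\min(P(U \le u), P(U \ge u))\}}. With ties, or when
#' the arrangement count exceeds `max_arrangements`, midranks are used with
#' the tie-corrected normal approximation (continuity-corrected).
#'
#' @param x,y Numeric samples.
#' @param max_arrangements Largest labeling count for which the exact
#'   distribution is used (default 1e6).
#' @return One-row tibble: `U` (for `x` relative to `y`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_exact(c(5, 6, 7), c(1, 2, 3))
#' @export
mann_whitney_exact <- function(x, y, max_arrangements = 1e6) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) abort("empty sample", class = "gaitpolar_format_error")
  if (any(!is.finite(c(x, y)))) abort("missing or non-finite values", class = "gaitpolar_format_error")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y)) # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_free <- !any(duplicated(c(x, y)))
  if (tie_free && choose(n1 + n2, n1) <= max_arrangements) {
    u_all <- 0:(n1 * n2)
    d <- dwilcox(u_all, n1, n2)
    p_le <- sum(d[u_all <= U])
    p_ge <- sum(d[u_all >= U])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(U = U, p_value = p, method = method)
}

#' Compare healthy and stroke groups across all indices
#'
#' Summarises each index per group, tests each with the exact Mann-Whitney U
#' test, flags indices on which the two groups separate cleanly (group
#' ranges disjoint, and the decision threshold — where one exists — lying
#' between them), and reports the stroke-to-healthy ratio of ARI group
#' means.
#'
#' @param records Per-subject index table with a `group` column containing
#'   `"healthy"` and `"stroke"` (see [gait_index_table()] for the packaged
#'   reference table).
#' @param ari_threshold,ppd_threshold ARI / PPD decision thresholds in
#'   percent (defaults 10 and 10).
#' @param angtangent_cutoff Tangent-angle cutoff in radians (default 0.155,
#'   the midpoint of the 0.15-0.16 rad band).
#' @param alpha Significance level echoed in the report (default 0.05).
#' @return Object of class `gait_group_comparison`: list with `summary`
#'   (per-group stats), `tests` (per-index U, p, separation flag,
#'   threshold), `ari_mean_ratio`, `thresholds`, `alpha`. Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @examples
#' cmp <- compare_groups(gait_index_table())
#' glance(cmp)
#' @export
compare_groups <- function(records, ari_threshold = 10, ppd_threshold = 10,
                           angtangent_cutoff = 0.155, alpha = 0.05) {
  records <- tibble::as_tibble(records)
  for (g in c("healthy", "stroke")) {
    if (sum(records$group == g) < 2) {
      abort(paste0("group '", g, "' needs at least 2 records"), class = "gaitpolar_format_error")
    }
  }
  summary <- summarize_group(records)
  thresholds <- c(ARI = ari_threshold, ppd = ppd_threshold,
                  ang_tangent = angtangent_cutoff)
  idx_cols <- intersect(names(index_digits), names(records))
  tests <- purrr::map_dfr(idx_cols, function(ix) {
    h <- records[[ix]][records$group == "healthy"]
    s <- records[[ix]][records$group == "stroke"]
    mw <- mann_whitney_exact(s, h)
    thr <- unname(thresholds[ix])
    disjoint <- max(h) < min(s)
    sep <- disjoint && (is.na(thr) || (max(h) < thr && thr < min(s)))
    tibble::tibble(
      index = ix,
      healthy_max = max(h), stroke_min = min(s),
      threshold = if (length(thr)) thr else NA_real_,
      separated = sep,
      U = mw$U, p_value = mw$p_value, method = mw$method,
      significant = mw$p_value < alpha
    )
  })
  ratio <- with(summary, mean[group == "stroke" & index == "ARI"] /
                         mean[group == "healthy" & index == "ARI"])
  structure(
    list(summary = summary, tests = tests,
         ari_mean_ratio = ratio,
         thresholds = thresholds, alpha = alpha),
    class = "gait_group_comparison"
  )
}

#' @export
print.gait_group_comparison <- function(x, ...) {
  cat("<gait_group_comparison>\n\nPer-group summaries (mean ± SD):\n")
  wide <- tidyr::pivot_wider(x$summary[c("group", "index", "label")],
                             names_from = "index", values_from = "label")
  print(as.data.frame(wide), row.names = FALSE)
  cat("\nIndex tests (stroke vs healthy):\n")
  print(as.data.frame(x$tests), row.names = FALSE, digits = 4)
  cat(sprintf("\nARI stroke/healthy mean ratio: %.1f; significance level %.2f\n",
              round_half_away(x$ari_mean_ratio, 1), x$alpha))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `gait_group_comparison`.
#' @param ... Unused.
#' @export
tidy.gait_group_comparison <- function(x, ...) x$tests

#' @rdname compare_groups
#' @export
glance.gait_group_comparison <- function(x, ...) {
  tibble::tibble(
    ari_mean_ratio = x$ari_mean_ratio,
    ari_separated = x$tests$separated[x$tests$index == "ARI"],
    p_ari = x$tests$p_value[x$tests$index == "ARI"],
    p_ppd = x$tests$p_value[x$tests$index == "ppd"],
    p_pci = x$tests$p_value[x$tests$index == "pci"],
    alpha = x$alpha
  )
}

#' Packaged per-subject reference index table
#'
#' The per-subject gait indices for the 8 healthy adults and 4 stroke
#' patients of the reference cohort (area ratios, ARI, tangent angle, PPD,
#' PCI), as published; shipped as a plain TSV in `inst/extdata`.
#'
#' @return Tibble with 12 rows.
#' @export
gait_index_table <- function() {
  path <- system.file("extdata", "reference_indices.tsv", package = "gaitpolar", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Packaged per-subject continuous gait-phase table
#'
#' Per-subject mean and SD of the estimated per-cycle phase span (rad) for
#' the reference cohort.
#'
#' @return Tibble with 12 rows: `subject_id`, `group`, `phase_mean`,
#'   `phase_sd`.
#' @export
gait_phase_table <- function() {
  path <- system.file("extdata", "reference_phase.tsv", package = "gaitpolar", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
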