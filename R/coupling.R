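# The central statistic: per-category correlation between pairwise dN/dS
# and pair-mean codon deviation coefficient, plus selection summaries.

#' Coupling between selection strength and codon usage bias
#'
#' Per gene category, the rank correlation (Spearman by default) between
#' pairwise dN/dS and pair-mean CDC, with a two-sided p-value and a
#' Bonferroni-adjusted p across categories. Pairs with undefined omega are
#' excluded; categories with fewer than 3 usable pairs are reported with an
#' undefined correlation rather than raising an error.
#'
#' @param pairs_df Data.frame with columns `pair_id`, `category`, `omega`,
#'   `pair_cdc` (one row per ortholog pair).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data.frame of class `coupling_result` (`category`, `n_pairs`,
#'   `rho`, `p`, `p_adj`, `method`).
#' @export
coupling_analysis <- function(pairs_df, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  usable <- pairs_df[!is.na(pairs_df$omega) & !is.na(pairs_df$pair_cdc), ,
                     drop = FALSE]
  cats <- unique(pairs_df$category)
  rows <- lapply(cats, function(ct) {
    g <- usable[usable$category == ct, , drop = FALSE]
    if (nrow(g) < 3L || stats::sd(g$pair_cdc) == 0 || stats::sd(g$omega) == 0) {
      return(data.frame(category = ct, n_pairs = nrow(g), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct_res <- suppressWarnings(
      stats::cor.test(g$pair_cdc, g$omega, method = method,
                      alternative = "two.sided", exact = FALSE))
    data.frame(category = ct, n_pairs = nrow(g),
               rho = unname(ct_res$estimate), p = ct_res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out$method <- method
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Summarise selection results by group
#'
#' Median omega over pairs with a defined estimate, counts of fast-evolving
#' pairs (omega > 1), and the number of undefined estimates, per group.
#'
#' @param selection Data.frame with an `omega` column and the grouping
#'   column named by `group_key`.
#' @param group_key Column name to group by (e.g. category or site).
#' @return Data.frame (`group`, `median_omega`, `n_fast`, `n_total`,
#'   `n_undefined`).
#' @export
summarize_selection <- function(selection, group_key = "category") {
  if (nrow(selection) == 0L) stop("empty selection table")
  groups <- split(selection, selection[[group_key]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    omg <- groups[[g]]$omega
    data.frame(group = g,
               median_omega = stats::median(omg, na.rm = TRUE),
               n_fast = sum(omg > 1, na.rm = TRUE),
               n_total = length(omg),
               n_undefined = sum(is.na(omg)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run selection + codon-bias analysis over a community's ortholog pairs
#'
#' For every evolved ortholog pair: NG86 dN/dS (via protein alignment and
#' codon back-threading) and pair-mean CDC, joined with the pair category.
#'
#' @param community A `synthetic_community`, or a list of `evolved_pair`
#'   objects plus a matching truth table via `truth`.
#' @param truth Optional data.frame (`pair_id`, `category`, ...) when
#'   `community` is a bare pair list.
#' @return Data.frame with one row per pair: `pair_id`, `category`,
#'   `omega`, `dn`, `ds`, `pair_cdc`, `selection_class`, plus the truth
#'   columns `omega_true` and `cub_strength` when available.
#' @export
analyze_pairs <- function(community, truth = NULL) {
  if (inherits(community, "synthetic_community")) {
    pairs <- community$pairs
    truth <- community$ortholog_truth
  } else {
    pairs <- community
    if (is.null(truth)) {
      truth <- data.frame(pair_id = sprintf("pair_%04d", seq_along(pairs)),
                          category = "core", stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sel <- dnds_pair(p$cds_a, p$cds_b)
    data.frame(pair_id = truth$pair_id[i],
               category = truth$category[i],
               omega = sel$omega, dn = sel$dN, ds = sel$dS,
               pair_cdc = pair_mean_cdc(p$cds_a, p$cds_b),
               selection_class = classify_selection(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  extra <- intersect(c("omega_true", "cub_strength"), names(truth))
  for (col in extra) out[[col]] <- truth[[col]]
  out
}

#' Scatter plot of the selection-vs-codon-bias coupling
#'
#' One panel per gene category: pairwise dN/dS against pair-mean CDC.
#'
#' @param pairs_df Output of [analyze_pairs()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `pairs_df`.
#' @export
plot_coupling <- function(pairs_df, ...) {
  usable <- pairs_df[!is.na(pairs_df$omega), , drop = FALSE]
  cats <- unique(usable$category)
  old <- graphics::par(mfrow = c(1, length(cats)))
  on.exit(graphics::par(old))
  for (ct in cats) {
    g <- usable[usable$category == ct, ]
    graphics::plot(g$pair_cdc, g$omega, xlab = "pair-mean CDC",
                   ylab = "dN/dS", main = ct, pch = 19,
                   col = "steelblue", ...)
  }
  invisible(pairs_df)
}
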