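#' One-way ANOVA with Tukey HSD post hoc over per-synapse measurements
#'
#' Each synapse is one observation (matching per-synapse dot plots).
#' Unbalanced groups use the Tukey-Kramer studentized-range procedure
#' (the harmonic-mean-style adjustment built into \code{stats::TukeyHSD}).
#' Unadjusted pairwise pooled-t p-values are reported alongside for
#' reference; calls are made at \code{alpha}.
#'
#' @param values numeric per-synapse measurements (PI, clearance ratio, ...).
#' @param group group labels, same length.
#' @param alpha significance level for the calls (default 0.05).
#' @return list: \code{F}, \code{p}, \code{df}, \code{table} (one row per
#'   pair: diff, lwr, upr, p_adj, p_unadj, significant), \code{alpha},
#'   \code{method}.
#' @export
anovaTukey <- function(values, group, alpha = 0.05) {
  if (length(values) != length(group)) stop("values and group must align")
  if (any(!is.finite(values))) stop("values must be finite")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (length(values) < 3) stop("need total n >= 3")
  ns <- table(group)
  if (any(ns == 1))
    stop("groups with n = 1 cannot enter Tukey HSD: ",
         paste(names(ns)[ns == 1], collapse = ", "))
  fit <- stats::aov(values ~ group)
  ss <- summary(fit)[[1]]
  totalSS <- sum((values - mean(values))^2)
  degenerate <- totalSS <= 1e-10 * max(1, mean(values)^2) * length(values)
  if (degenerate) {
    Fval <- 0; pval <- 1
    pairs <- utils::combn(levels(group), 2)
    tab <- data.frame(
      pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, lwr = 0, upr = 0, p_adj = 1, p_unadj = 1,
      significant = FALSE)
  } else {
    Fval <- ss[1, "F value"]; pval <- ss[1, "Pr(>F)"]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pt <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    lookup <- function(i, j) {
      if (i %in% rownames(pt) && j %in% colnames(pt) &&
          !is.na(pt[i, j])) pt[i, j] else NA_real_
    }
    unadj <- vapply(rownames(tk), function(nm) {
      gg <- strsplit(nm, "-", fixed = TRUE)[[1]]
      v <- c(lookup(gg[1], gg[2]), lookup(gg[2], gg[1]))
      v[!is.na(v)][1]
    }, numeric(1))
    tab <- data.frame(
      pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
      upr = tk[, "upr"], p_adj = tk[, "p adj"], p_unadj = unadj,
      significant = tk[, "p adj"] < alpha, row.names = NULL)
  }
  list(F = Fval, p = pval,
       df = c(between = nlevels(group) - 1,
              within = length(values) - nlevels(group)),
       table = tab, alpha = alpha,
       method = "one-way ANOVA + Tukey HSD (Tukey-Kramer for unbalanced n)")
}

#' Fold induction of exosomal reporter secretion
#'
#' Exosomal reporter signals (e.g. GFP-CD63 western blot band intensity)
#' are normalized by the matching cell-lysate reporter level; fold
#' induction is the stimulated over unstimulated ratio of these
#' normalized signals:
#' \code{(exoStim / cellStim) / (exoUnstim / cellUnstim)}. The result is
#' invariant to rescaling all four signals by one positive constant.
#'
#' @param exoStim,cellStim stimulated exosome and cell-lysate signals, > 0.
#' @param exoUnstim,cellUnstim unstimulated counterparts, > 0.
#' @param group optional pair of group labels; must match.
#' @return fold induction (vectorized).
#' @examples
#' exosomeFoldInduction(6, 2, 2, 2)  # 3
#' @export
exosomeFoldInduction <- function(exoStim, cellStim, exoUnstim, cellUnstim,
                                 group = NULL) {
  if (!is.null(group) && length(unique(group)) != 1)
    stop("stimulated and unstimulated measurements must share a group label")
  sig <- c(exoStim, cellStim, exoUnstim, cellUnstim)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("signals must be positive (zero denominators are not allowed)")
  (exoStim / cellStim) / (exoUnstim / cellUnstim)
}

#' Dot plot of per-synapse measurements by group
#'
#' Mirrors per-synapse dot plots with the group mean marked. Requires
#' ggplot2.
#'
#' @param values numeric measurements.
#' @param group group labels.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plotGroupDots <- function(values, group, ylab = "PI") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(group = factor(group), value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, color = "red") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
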