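#' Squared Pearson correlation with significance stars
#'
#' r^2 with the conventional star coding of the correlation test p-value:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param x,y Numeric vectors (n >= 3, neither constant).
#' @return List with `r2`, `r`, `p_value`, `stars`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r2 = r^2, r = r, p_value = ct$p.value,
       stars = p_stars(ct$p.value), n = length(x))
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r2`, `p_value` (slope test), `stars`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  p <- co["x", "Pr(>|t|)"]
  list(slope = co["x", "Estimate"], slope_se = co["x", "Std. Error"],
       intercept = co["(Intercept)", "Estimate"],
       intercept_se = co["(Intercept)", "Std. Error"],
       r2 = summary(fit)$r.squared, p_value = p, stars = p_stars(p),
       n = length(x))
}

#' One-way ANOVA with Tukey compact-letter display
#'
#' Fits a one-way ANOVA, computes all pairwise comparisons by the Tukey
#' studentized-range (HSD) test, and summarises them as compact letters by
#' the insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`. Letters are assigned in
#' ascending-mean order starting at "a".
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor); >= 2 groups with >= 2
#'   values each.
#' @param alpha Family-wise significance level for the HSD test.
#' @return Data frame (one row per group, ascending mean): `group`, `n`,
#'   `mean`, `se`, `letters`.
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  df <- data.frame(value = values, group = groups)
  means <- tapply(df$value, df$group, mean)
  ses <- tapply(df$value, df$group, function(v) stats::sd(v) / sqrt(length(v)))
  ns <- as.integer(table(df$group))

  lv <- levels(groups)[order(means)]  # ascending-mean order
  if (all(tapply(df$value, df$group, stats::sd) < .Machine$double.eps^0.5) ||
      stats::sd(df$value) == 0) {
    warning("degenerate within-group variance: all groups share letter 'a'")
    letters_by_group <- stats::setNames(rep("a", length(lv)), lv)
  } else {
    fit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pmat <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
    for (pair in rownames(tk)) {
      gg <- strsplit(pair, "-", fixed = TRUE)[[1]]
      sig <- tk[pair, "p adj"] <= alpha
      pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- sig
    }
    letters_by_group <- insert_absorb_letters(pmat, lv)
  }
  out <- data.frame(group = lv, n = ns[order(means)],
                    mean = unname(sort(means)),
                    se = unname(ses[order(means)]),
                    letters = unname(letters_by_group[lv]))
  rownames(out) <- NULL
  out
}

# Insert-and-absorb compact letters from a logical significance matrix
# (TRUE = significantly different). `order_lv` fixes the ascending-mean
# order used both for processing and for naming letters.
insert_absorb_letters <- function(sig, order_lv) {
  sets <- list(order_lv)  # start: one letter containing every group
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    g1 <- order_lv[pairs[p, 1]]; g2 <- order_lv[pairs[p, 2]]
    new_sets <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {           # insert: split the offending set
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j))
        keep[i] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # name letters by the lowest-mean group each set contains
  first_idx <- vapply(sets, function(s) min(match(s, order_lv)), numeric(1))
  sets <- sets[order(first_idx)]
  out <- stats::setNames(rep("", length(order_lv)), order_lv)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Paired treatment/control summaries
#'
#' For measurements made on paired sites (e.g. a moisture-exposed patch
#' and the untreated opposite cheek of the same fruit), computes per-time
#' treatment and control means with SEs and the mean within-pair
#' difference (treatment minus control).
#'
#' @param data Data frame with columns `value`, `treatment` (logical or a
#'   two-level factor where the first level is control), `pair` (pairing
#'   key), and optionally `time`.
#' @return Data frame, one row per time point (single row if no `time`):
#'   `time`, `n_pairs`, `mean_treatment`, `se_treatment`, `mean_control`,
#'   `se_control`, `mean_paired_diff`, `se_paired_diff`.
#' @export
paired_effect <- function(data) {
  need <- c("value", "treatment", "pair")
  if (!all(need %in% names(data)))
    stop("`data` needs columns ", paste(need, collapse = ", "))
  trt <- if (is.logical(data$treatment)) data$treatment
         else factor(data$treatment) == levels(factor(data$treatment))[2]
  tm <- if ("time" %in% names(data)) data$time else rep(0, nrow(data))
  se <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else 0
  out <- lapply(sort(unique(tm)), function(tp) {
    sub_t <- data$value[tm == tp & trt]; id_t <- data$pair[tm == tp & trt]
    sub_c <- data$value[tm == tp & !trt]; id_c <- data$pair[tm == tp & !trt]
    miss <- c(setdiff(id_t, id_c), setdiff(id_c, id_t))
    if (length(miss))
      stop("unpaired record(s) at time ", tp, ": pair ",
           paste(unique(miss), collapse = ", "))
    if (anyDuplicated(id_t) || anyDuplicated(id_c))
      stop("duplicated pair key at time ", tp)
    diff <- sub_t[order(id_t)] - sub_c[order(id_c)]
    data.frame(time = tp, n_pairs = length(diff),
               mean_treatment = mean(sub_t), se_treatment = se(sub_t),
               mean_control = mean(sub_c), se_control = se(sub_c),
               mean_paired_diff = mean(diff), se_paired_diff = se(diff))
  })
  do.call(rbind, out)
}
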