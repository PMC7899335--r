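## Group-comparison statistics implemented from first principles (sums of
## squares, studentized-range and multivariate-t tail probabilities), so
## every figure-style comparison in the pipeline is reproducible without a
## statistics GUI. Base R supplies only the distribution functions
## (pt, pf, ptukey); the test statistics themselves are computed here.

check_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("'groups' must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, function(v) {
    if (!is.numeric(v) || length(v) < min_n)
      stopf("each group needs >= %d numeric values", min_n)
  })
  groups
}

#' Two-sample t test
#'
#' Classical two-sided Student's t with pooled variance by default; Welch's
#' unequal-variance form behind a flag. When both groups have zero variance
#' and equal means the statistic is taken as 0 with p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch-Satterthwaite form (default `FALSE`).
#' @return A list with `t`, `df`, `p`, `mean_diff`.
#' @export
t_test2 <- function(a, b, welch = FALSE) {
  check_flag(welch, "welch")
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (d == 0) return(list(t = 0, df = na + nb - 2, p = 1, mean_diff = 0))
    return(list(t = sign(d) * Inf, df = na + nb - 2, p = 0, mean_diff = d))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t <- d / sqrt(se2)
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = d)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`. With all values identical the
#' statistic is 0 and p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A list with `F`, `df_between`, `df_within`, `p`, `mse` (the
#'   within-group mean square) and `group_means`.
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  mse <- ssw / df2
  f <- if (ssw == 0 && ssb == 0) 0 else if (ssw == 0) Inf else
    (ssb / df1) / mse
  p <- if (f == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df_between = df1, df_within = df2, p = p, mse = mse,
       group_means = means, n = n)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group differences tested against the studentized-range
#' distribution with the one-way ANOVA error term; unequal group sizes use
#' the Tukey-Kramer standard error
#' `sqrt(MSE / 2 * (1 / n_i + 1 / n_j))`.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame of pairs: `group1`, `group2`, `diff`, `q` (studentized
#'   range statistic), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  av <- anova_oneway(groups)
  k <- length(groups)
  df <- av$df_within
  nm <- names(groups)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    d <- av$group_means[i] - av$group_means[j]
    se <- sqrt(av$mse / 2 * (1 / av$n[i] + 1 / av$n[j]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    p <- if (q == 0) 1 else
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = nm[i], group2 = nm[j], diff = unname(d),
               q = unname(q), p_adj = unname(p))
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

## Cache of Monte-Carlo null samples for the Dunnett max-|t| statistic,
## keyed by group sizes, error df, draw count and seed.
.dunnett_cache <- new.env(parent = emptyenv())

dunnett_null_sample <- function(n, df, n_mc, seed) {
  key <- paste(c(n, df, n_mc, seed), collapse = "_")
  got <- get0(key, envir = .dunnett_cache)
  if (!is.null(got)) return(got)
  k <- length(n) # first entry is the control group
  maxt <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_mc * k), n_mc, k)
    m <- sweep(m, 2L, sqrt(n), "/") # group means, unit error variance
    s <- sqrt(stats::rchisq(n_mc, df) / df)
    tt <- abs(m[, -1L, drop = FALSE] - m[, 1L]) /
      outer(s, sqrt(1 / n[-1L] + 1 / n[1L]))
    apply(tt, 1L, max)
  })
  assign(key, maxt, envir = .dunnett_cache)
  maxt
}

#' Dunnett many-to-one comparisons
#'
#' Each treatment group is compared with the control using the one-way
#' ANOVA error term; the family-wise adjustment uses the null distribution
#' of the maximum absolute Dunnett t, obtained by Monte-Carlo simulation of
#' the multivariate t (group means and a shared error variance drawn under
#' the null; 100,000 draws with a fixed internal seed, cached per design).
#'
#' @param groups Named list of numeric vectors.
#' @param control Name of the control group.
#' @param alpha Family-wise significance level.
#' @param n_mc Monte-Carlo draws for the null distribution.
#' @param mc_seed Seed of the Monte-Carlo null (fixed for reproducibility;
#'   does not touch the caller's RNG).
#' @return A list with `comparisons` (data frame: group, diff, t, p_adj,
#'   significant) and `crit` (the alpha-level critical value of max |t|).
#' @export
dunnett <- function(groups, control, alpha = 0.05, n_mc = 100000L,
                    mc_seed = 20090L) {
  groups <- check_groups(groups)
  if (!control %in% names(groups))
    stopf("control group '%s' not present", control)
  groups <- c(groups[control], groups[names(groups) != control])
  av <- anova_oneway(groups)
  n <- lengths(groups)
  df <- av$df_within
  se <- sqrt(av$mse * (1 / n[-1L] + 1 / n[1L]))
  d <- av$group_means[-1L] - av$group_means[1L]
  t <- ifelse(se == 0, ifelse(d == 0, 0, Inf), d / se)
  maxt <- dunnett_null_sample(n, df, n_mc, mc_seed)
  p <- vapply(abs(t), function(ti)
    if (ti == 0) 1 else mean(maxt >= ti), 0)
  crit <- stats::quantile(maxt, 1 - alpha, names = FALSE)
  comp <- data.frame(group = names(groups)[-1L], diff = unname(d),
                     t = unname(t), p_adj = unname(p),
                     significant = unname(p) < alpha)
  rownames(comp) <- NULL
  list(comparisons = comp, crit = crit, df = df, control = control)
}

#' Two-way repeated-measures ANOVA
#'
#' Univariate mixed-design ANOVA with one between-unit factor (genotype)
#' and one within-unit factor (time). Units must have complete timepoint
#' grids; missing cells are an error (no imputation). The between effect is
#' tested against the unit-within-group mean square, the within and
#' interaction effects against the unit-by-time residual. No sphericity
#' correction by default; `gg = TRUE` applies the Greenhouse-Geisser
#' epsilon to the within-effect degrees of freedom.
#'
#' @param data Data frame in long format.
#' @param value,unit,between,within Column names of the response, the unit
#'   (worm) identifier, the between factor and the within factor.
#' @param gg Apply the Greenhouse-Geisser correction (default `FALSE`).
#' @return Data frame with rows `between`, `within`, `interaction`:
#'   `SS`, `df`, `MS`, `F`, `p` (plus `df_error`, and `epsilon` when
#'   `gg = TRUE`).
#' @export
rm_anova_two_way <- function(data, value, unit, between, within, gg = FALSE) {
  check_flag(gg, "gg")
  y <- data[[value]]; u <- as.character(data[[unit]])
  g <- as.character(data[[between]]); w <- as.character(data[[within]])
  if (anyNA(y)) stopf("missing response values")
  times <- sort(unique(w)); b <- length(times)
  units <- unique(u); N <- length(units)
  if (nrow(data) != N * b || any(table(u) != b) ||
      any(table(u, w) != 1L))
    stopf("incomplete design: every unit needs exactly one value per timepoint")
  unit_group <- tapply(g, u, function(x) x[1L])
  if (any(tapply(g, u, function(x) length(unique(x)) != 1L)))
    stopf("unit assigned to more than one between-group level")
  a <- length(unique(g))
  if (a < 2L) stopf("need >= 2 between-group levels")
  grand <- mean(y)
  unit_mean <- tapply(y, u, mean)
  group_mean <- tapply(y, g, mean)
  time_mean <- tapply(y, w, mean)
  cell_mean <- tapply(y, list(g, w), mean)
  n_g <- table(unit_group) # units per group

  ss_between <- b * sum(n_g * (group_mean[names(n_g)] - grand)^2)
  ss_subj_within <- b * sum((unit_mean - group_mean[unit_group[names(unit_mean)]])^2)
  ss_time <- N * sum((time_mean - grand)^2)
  gl <- rownames(cell_mean); tl <- colnames(cell_mean)
  ss_int <- sum(vapply(seq_along(gl), function(i) {
    sum(n_g[gl[i]] * (cell_mean[i, ] - group_mean[gl[i]] -
                        time_mean[tl] + grand)^2)
  }, 0))
  fit <- cell_mean[cbind(match(g, gl), match(w, tl))] +
    unit_mean[u] - group_mean[g]
  ss_err <- sum((y - fit)^2)

  df_a <- a - 1L; df_sa <- N - a
  df_b <- b - 1L; df_int <- (a - 1L) * (b - 1L); df_e <- (N - a) * (b - 1L)
  ms <- c(ss_between / df_a, ss_time / df_b, ss_int / df_int)
  ms_sa <- ss_subj_within / df_sa
  ms_e <- ss_err / df_e
  f <- c(if (ms_sa == 0) 0 else ms[1L] / ms_sa,
         if (ms_e == 0) 0 else ms[2L] / ms_e,
         if (ms_e == 0) 0 else ms[3L] / ms_e)
  eps <- 1
  if (gg && b > 2L) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance
    wide <- matrix(NA_real_, N, b, dimnames = list(units, times))
    wide[cbind(match(u, units), match(w, times))] <- y
    centered <- do.call(rbind, lapply(unique(unit_group), function(gr) {
      rows <- wide[unit_group[units] == gr, , drop = FALSE]
      sweep(rows, 2L, colMeans(rows))
    }))
    S <- crossprod(centered) / (N - a)
    Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
    lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > max(lam) * 1e-12]
    eps <- sum(lam)^2 / ((b - 1) * sum(lam^2))
    eps <- min(max(eps, 1 / (b - 1)), 1)
  }
  p <- c(if (f[1L] == 0) 1 else stats::pf(f[1L], df_a, df_sa, lower.tail = FALSE),
         if (f[2L] == 0) 1 else
           stats::pf(f[2L], df_b * eps, df_e * eps, lower.tail = FALSE),
         if (f[3L] == 0) 1 else
           stats::pf(f[3L], df_int * eps, df_e * eps, lower.tail = FALSE))
  out <- data.frame(
    effect = c("between", "within", "interaction"),
    SS = c(ss_between, ss_time, ss_int),
    df = c(df_a, df_b, df_int),
    df_error = c(df_sa, df_e, df_e),
    MS = ms, F = f, p = p)
  if (gg) out$epsilon <- eps
  attr(out, "SS_subjects_within") <- ss_subj_within
  attr(out, "SS_error") <- ss_err
  out
}
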