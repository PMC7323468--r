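#' Two-way repeated-measures ANOVA (muscle x level)
#'
#' Within-subject two-factor ANOVA of one metric from a level table, with
#' each effect tested against its subject-by-factor interaction error
#' stratum (muscle vs subject:muscle, level vs subject:level, interaction
#' vs subject:muscle:level). Subjects with missing cells are dropped (with
#' a count recorded in the result); remaining incompleteness is an error
#' naming the offending subjects. When both an effect and its error
#' stratum have (numerically) zero variance the F ratio is undefined and
#' the p-value is reported as 1.
#'
#' No sphericity correction is applied by default;
#' `correction = "greenhouse-geisser"` adjusts the level and interaction
#' degrees of freedom by the Greenhouse-Geisser epsilon.
#'
#' @param table level table: data.frame with columns subject, muscle,
#'   level and the metric.
#' @param metric column name to analyse (e.g. "volume_ml").
#' @param alpha significance threshold for the post hoc flags.
#' @param posthoc also run [sidakPosthoc()] per level.
#' @param correction "none" (default) or "greenhouse-geisser".
#' @return an [AnovaResult-class].
#' @export
rmAnova <- function(table, metric, alpha = 0.05, posthoc = TRUE,
                    correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  dat <- completeTable(table, metric)
  y <- dat$data[[metric]]
  df <- data.frame(y = y,
                   subject = factor(dat$data$subject),
                   muscle = factor(dat$data$muscle, levels = MUSCLES),
                   level = factor(dat$data$level, levels = LEVELS))
  if (nlevels(df$subject) < 3L)
    stop("at least 3 complete subjects are required")
  if (stats::sd(df$y) < .Machine$double.eps^0.5 * (1 + mean(abs(df$y)))) {
    # degenerate: no variance anywhere, every F undefined, report p = 1
    effects <- data.frame(
      effect = c("muscle", "level", "muscle:level"), F = NaN,
      df1 = c(1, 5, 5), df2 = (nlevels(df$subject) - 1) * c(1, 5, 5), p = 1)
  } else {
    fit <- stats::aov(y ~ muscle * level + Error(subject / (muscle * level)),
                      data = df)
    effects <- extractEffects(fit)
  }
  if (correction == "greenhouse-geisser")
    effects <- applyGG(effects, df)
  ph <- if (posthoc)
    sidakPosthoc(dat$data, metric, alpha = alpha) else emptyPosthoc()
  new("AnovaResult", metric = metric, effects = effects, posthoc = ph,
      alpha = alpha, nSubjects = nlevels(df$subject),
      nDropped = dat$nDropped, correction = correction)
}

completeTable <- function(table, metric) {
  need <- c("subject", "muscle", "level", metric)
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "))
  tb <- table[, need]
  tb <- tb[is.finite(tb[[metric]]), ]
  cnt <- stats::aggregate(tb[[metric]], by = list(subject = tb$subject),
                          FUN = length)
  full <- 12L
  bad <- cnt$subject[cnt$x < full]
  over <- cnt$subject[cnt$x > full]
  if (length(over))
    stop("duplicated cells for subjects: ", paste(over, collapse = ", "))
  nDropped <- length(bad)
  if (nDropped) {
    message("dropping ", nDropped,
            " subject(s) with missing cells: ", paste(bad, collapse = ", "))
    tb <- tb[!(tb$subject %in% bad), ]
  }
  if (!nrow(tb)) stop("no complete subjects remain")
  # verify balance cell-by-cell
  tabc <- table(tb$muscle, tb$level)
  if (length(unique(as.vector(tabc))) != 1L)
    stop("design is unbalanced after dropping incomplete subjects")
  list(data = tb, nDropped = as.integer(nDropped))
}

extractEffects <- function(fit) {
  sm <- summary(fit)
  pick <- function(stratum, term) {
    st <- sm[[paste0("Error: ", stratum)]]
    if (is.null(st)) return(NULL)
    tt <- st[[1]]
    i <- match(term, trimws(rownames(tt)))
    j <- match("Residuals", trimws(rownames(tt)))
    if (is.na(i) || is.na(j)) return(NULL)
    msE <- tt[j, "Mean Sq"]
    msT <- tt[i, "Mean Sq"]
    Fv <- tt[i, "F value"]
    pv <- tt[i, "Pr(>F)"]
    if (!is.finite(Fv) || !is.finite(msE) || msE <= 0) {
      # zero-variance degenerate case: undefined F reported as p = 1
      Fv <- if (is.finite(msT) && msT == 0) NaN else Inf
      pv <- if (is.nan(Fv)) 1 else 0
    }
    data.frame(F = Fv, df1 = tt[i, "Df"], df2 = tt[j, "Df"], p = pv)
  }
  rows <- rbind(
    cbind(effect = "muscle", pick("subject:muscle", "muscle")),
    cbind(effect = "level", pick("subject:level", "level")),
    cbind(effect = "muscle:level", pick("subject:muscle:level",
                                        "muscle:level")))
  rownames(rows) <- NULL
  rows
}

# Greenhouse-Geisser epsilon from the subject x cell matrix of each
# within-subject effect, applied to the level and interaction terms
# (muscle has 2 levels: epsilon is identically 1).
applyGG <- function(effects, df) {
  eps <- function(Y) {
    S <- stats::cov(Y)
    k <- ncol(S)
    C <- stats::contr.helmert(k)
    C <- C %*% diag(1 / sqrt(colSums(C^2)), k - 1L, k - 1L)
    E <- t(C) %*% S %*% C
    sum(diag(E))^2 / ((k - 1) * sum(E^2))
  }
  cellMatrix <- function(fac) {
    wide <- tapply(df$y, list(df$subject, fac), mean)
    wide
  }
  gg <- c(muscle = 1,
          level = eps(cellMatrix(df$level)),
          `muscle:level` = eps(cellMatrix(interaction(df$muscle, df$level))))
  for (i in seq_len(nrow(effects))) {
    e <- gg[[effects$effect[i]]]
    if (is.finite(e) && is.finite(effects$F[i])) {
      effects$df1[i] <- effects$df1[i] * e
      effects$df2[i] <- effects$df2[i] * e
      effects$p[i] <- stats::pf(effects$F[i], effects$df1[i],
                                effects$df2[i], lower.tail = FALSE)
    }
  }
  effects
}

emptyPosthoc <- function() data.frame(
  level = character(), mean_diff = numeric(), t = numeric(),
  df = numeric(), p_raw = numeric(), p_sidak = numeric(),
  significant = logical())

#' Sidak adjustment of p-values
#'
#' `p_adj = 1 - (1 - p)^m`; monotone in p and bounded above by
#' `min(1, m p)`.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values.
#' @examples
#' sidakAdjust(0.01, m = 6)  # 1 - 0.99^6 = 0.05852
#' @export
sidakAdjust <- function(p, m = length(p)) 1 - (1 - p)^m

#' Per-level Sidak-adjusted post hoc comparisons
#'
#' At each vertebral level, a paired t test of multifidus minus erector
#' spinae across subjects; p-values are Sidak-adjusted for the family of
#' six levels. Exact ties (zero within-pair variance) are reported with
#' p = 1.
#'
#' @param table level table (see [rmAnova()]).
#' @param metric column to compare.
#' @param alpha significance threshold for the flags.
#' @param m family size for the adjustment (default 6, one test per
#'   level).
#' @return data.frame with level, mean_diff (multifidus - erector
#'   spinae), t, df, p_raw, p_sidak, significant.
#' @export
sidakPosthoc <- function(table, metric, alpha = 0.05, m = 6L) {
  dat <- completeTable(table, metric)$data
  out <- emptyPosthoc()
  for (lv in LEVELS) {
    sub <- dat[dat$level == lv, ]
    wide <- merge(sub[sub$muscle == "multifidus", c("subject", metric)],
                  sub[sub$muscle == "erector_spinae", c("subject", metric)],
                  by = "subject", suffixes = c(".mf", ".es"))
    dif <- wide[[paste0(metric, ".mf")]] - wide[[paste0(metric, ".es")]]
    if (stats::sd(dif) < .Machine$double.eps^0.5 * max(1, mean(abs(dif)))) {
      tt <- list(statistic = c(t = NaN), parameter = c(df = length(dif) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(dif)
    }
    out <- rbind(out, data.frame(
      level = lv, mean_diff = mean(dif), t = unname(tt$statistic),
      df = unname(tt$parameter), p_raw = tt$p.value,
      p_sidak = min(1, sidakAdjust(tt$p.value, m)),
      significant = min(1, sidakAdjust(tt$p.value, m)) < alpha))
  }
  out
}

#' Repeated-measures ANCOVA with fat fraction as covariate
#'
#' Re-runs the muscle-by-level analysis of a metric with the cell-level
#' fat signal fraction entered as a continuous covariate in every error
#' stratum, and reports whether each effect's significance flag matches
#' the plain repeated-measures result. Used as a sensitivity analysis:
#' when diffusion differences merely track fat content, adjusting for the
#' covariate removes them.
#'
#' @param table level table containing the metric and a `fat_fraction`
#'   column.
#' @param metric column to analyse.
#' @param alpha significance threshold.
#' @param posthoc also run the per-level post hoc on the
#'   covariate-residualised metric.
#' @return an [AnovaResult-class]; the `effects` table gains columns
#'   `p_unadjusted` and `agrees` (TRUE where the significance decision
#'   matches [rmAnova()]).
#' @export
ancovaFatCovariate <- function(table, metric, alpha = 0.05, posthoc = TRUE) {
  if (!"fat_fraction" %in% names(table))
    stop("table must contain a fat_fraction column")
  dat <- completeTable(table, metric)
  base <- rmAnova(table, metric, alpha = alpha, posthoc = posthoc)
  dd <- dat$data
  dd$fat_fraction <- table$fat_fraction[match(
    paste(dd$subject, dd$muscle, dd$level),
    paste(table$subject, table$muscle, table$level))]
  if (any(!is.finite(dd$fat_fraction)))
    stop("fat_fraction missing for some analysed cells")
  df <- data.frame(y = dd[[metric]], cov = dd$fat_fraction,
                   subject = factor(dd$subject),
                   muscle = factor(dd$muscle, levels = MUSCLES),
                   level = factor(dd$level, levels = LEVELS))
  covConstant <- stats::sd(df$cov) < .Machine$double.eps^0.5
  fit <- if (covConstant)
    stats::aov(y ~ muscle * level + Error(subject / (muscle * level)),
               data = df)
  else
    stats::aov(y ~ cov + muscle * level + Error(subject / (muscle * level)),
               data = df)
  effects <- extractEffects(fit)
  effects$p_unadjusted <- base@effects$p[match(effects$effect,
                                               base@effects$effect)]
  effects$agrees <- (effects$p < alpha) ==
    (effects$p_unadjusted < alpha)
  ph <- emptyPosthoc()
  if (posthoc) {
    # residualise the metric on the covariate, then compare per level
    res <- stats::resid(stats::lm(y ~ cov, data = df))
    dd2 <- dd
    dd2[[metric]] <- res + mean(df$y)
    ph <- sidakPosthoc(dd2, metric, alpha = alpha)
    ph$agrees <- ph$significant == base@posthoc$significant
  }
  new("AnovaResult", metric = paste0(metric, " | fat_fraction"),
      effects = effects, posthoc = ph, alpha = alpha,
      nSubjects = base@nSubjects, nDropped = dat$nDropped,
      correction = "none")
}
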