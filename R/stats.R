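# Grade-group association statistics: dichotomization, Spearman vs grade
# group, Mann-Whitney class comparison, Benjamini-Hochberg correction, and
# the two-way ANOVA site screen.

#' Dichotomize a grade group into aggressiveness classes
#'
#' Grade group 1 is the low-aggressive class; grade groups 2-5 are the
#' intermediate/high class.
#'
#' @param gradeGroup integer vector with values in 1..5.
#' @return character vector, `"low"` or `"int_high"`.
#' @examples
#' dichotomize(c(1, 2, 5))
#' @export
dichotomize <- function(gradeGroup) {
  if (any(!gradeGroup %in% 1:5)) stop("grade group out of range 1..5")
  ifelse(gradeGroup == 1, "low", "int_high")
}

#' Spearman correlation of a feature with grade group
#'
#' Tie-corrected rho (Pearson correlation of midranks) with a two-sided p
#' value from the t approximation. A constant feature is degenerate: rho 0,
#' p 1, `degenerate = TRUE`.
#'
#' @param feature numeric vector.
#' @param grades integer grade groups, same length, spanning >= 2 values.
#' @return list with `rho`, `p`, `degenerate`.
#' @export
spearmanVsGrade <- function(feature, grades) {
  stopifnot(length(feature) == length(grades), length(feature) >= 3)
  if (length(unique(grades)) < 2) stop("grades span a single value")
  if (length(unique(feature)) < 2)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  rho <- stats::cor(rank(feature), rank(grades))
  n <- length(feature)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Two-tailed Mann-Whitney U test
#'
#' U with midrank tie handling. The p value is exact (enumeration over all
#' group labelings, correct under ties) when the combined sample size is at
#' most `exactMax`, and uses the normal approximation with continuity and
#' tie correction otherwise.
#'
#' @param x,y numeric samples of the two groups (both nonempty).
#' @param exactMax combined-size bound for the exact branch (default 12).
#' @return list with `U` (for `x` relative to `y`), `p`.
#' @examples
#' mwuTest(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
#' @export
mwuTest <- function(x, y, exactMax = 12) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  if (n <= exactMax) {
    combs <- utils::combn(n, nx)
    Us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tieAdj)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
  }
  list(U = U, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate;
#' significance is decided on the adjusted values at the chosen level.
#'
#' @param pvals numeric vector of p values in \[0, 1\].
#' @return numeric vector of adjusted values (monotone, capped at 1).
#' @export
bhAdjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Association table of all features with aggressiveness
#'
#' For every feature column: Spearman rho with grade group (1-5) and its p,
#' the two-tailed Mann-Whitney p for low versus intermediate/high, and the
#' BH-adjusted q values (each statistic's p family corrected jointly over
#' all features).
#'
#' @param table a feature data.frame with metadata columns `grade_group`
#'   and feature columns `features`.
#' @param features character vector of feature column names (default: the
#'   canonical 51-name registry).
#' @param alpha significance level on adjusted values (default 0.05).
#' @return data.frame with columns feature, rho, p_rho, U, p_u, q_rho, q_u,
#'   sig_rho, sig_u.
#' @export
associationTable <- function(table, features = featureNames(), alpha = 0.05) {
  cls <- dichotomize(table$grade_group)
  res <- lapply(features, function(f) {
    v <- table[[f]]
    sp <- spearmanVsGrade(v, table$grade_group)
    mw <- mwuTest(v[cls == "low"], v[cls == "int_high"])
    data.frame(feature = f, rho = sp$rho, p_rho = sp$p, U = mw$U,
               p_u = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_rho <- bhAdjust(out$p_rho)
  out$q_u <- bhAdjust(out$p_u)
  out$sig_rho <- out$q_rho < alpha
  out$sig_u <- out$q_u < alpha
  out
}

#' Two-way ANOVA site screen
#'
#' Screens each feature for institution effects before classification. Each
#' feature is log transformed (with a positivity shift `x - min + 1` when
#' any value is <= 0) and fit by two-way ANOVA with factors site and
#' aggressiveness class. Type-II tests: the site-by-class interaction is
#' the full-versus-additive comparison; the site main effect is the
#' class-only-versus-additive comparison. A feature is dropped when either
#' is significant at `alpha`. Sites contributing a single tumor are merged
#' out of the screen with a warning.
#'
#' @param table feature data.frame with `site_id`, `grade_group` and
#'   feature columns.
#' @param features feature column names (default: full registry present in
#'   the table).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns feature, p_site, p_interaction, keep,
#'   reason.
#' @export
anovaSiteScreen <- function(table, features = NULL, alpha = 0.05) {
  if (is.null(features))
    features <- intersect(featureNames(), colnames(table))
  cls <- factor(dichotomize(table$grade_group), levels = c("low", "int_high"))
  site <- factor(table$site_id)
  small <- names(which(table(site) < 2))
  if (length(small) > 0) {
    warning("site(s) with a single tumor merged out of the ANOVA screen: ",
            paste(small, collapse = ", "))
    keepRows <- !site %in% small
    table <- table[keepRows, , drop = FALSE]
    cls <- droplevels(cls[keepRows])
    site <- droplevels(site[keepRows])
  }
  bothClasses <- vapply(levels(site), function(s)
    length(unique(cls[site == s])) == 2, TRUE)
  if (sum(bothClasses) < 2)
    stop("need >= 2 sites with both classes represented")
  res <- lapply(features, function(f) {
    y <- table[[f]]
    if (min(y) <= 0) y <- y - min(y) + 1
    ly <- log(y)
    if (stats::var(ly) == 0) {
      return(data.frame(feature = f, p_site = 1, p_interaction = 1,
                        keep = TRUE, reason = "constant",
                        stringsAsFactors = FALSE))
    }
    full <- stats::lm(ly ~ site * cls)
    add <- stats::lm(ly ~ site + cls)
    mcls <- stats::lm(ly ~ cls)
    # type-II F tests with the full-model residual mean square as the
    # denominator
    rssFull <- sum(stats::residuals(full)^2)
    dfFull <- stats::df.residual(full)
    mse <- rssFull / dfFull
    ssInt <- sum(stats::residuals(add)^2) - rssFull
    dfInt <- stats::df.residual(add) - dfFull
    ssSite <- sum(stats::residuals(mcls)^2) - sum(stats::residuals(add)^2)
    dfSite <- stats::df.residual(mcls) - stats::df.residual(add)
    pInt <- if (dfInt > 0 && mse > 0)
      stats::pf(ssInt / dfInt / mse, dfInt, dfFull, lower.tail = FALSE) else NA
    pSite <- if (dfSite > 0 && mse > 0)
      stats::pf(ssSite / dfSite / mse, dfSite, dfFull, lower.tail = FALSE) else NA
    if (is.na(pInt)) pInt <- 1
    if (is.na(pSite)) pSite <- 1
    drop <- pInt < alpha || pSite < alpha
    data.frame(feature = f, p_site = pSite, p_interaction = pInt,
               keep = !drop,
               reason = if (!drop) "" else if (pInt < alpha)
                 "site x class interaction" else "site main effect",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
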