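#' Goodman-Kruskal gamma with asymptotic significance
#'
#' gamma = (C - D) / (C + D) over all point pairs, where C and D count the
#' concordant and discordant pairs and ties (in either variable) are
#' excluded from both counts. Significance uses the asymptotic normal
#' approximation z = gamma * sqrt((C + D) / (n (1 - gamma^2))), two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(gamma, C, D, z, p).
#' @examples
#' goodmanKruskalGamma(1:5, c(2, 3, 1, 5, 6))
#' @export
goodmanKruskalGamma <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  C <- 0L
  D <- 0L
  for (i in seq_len(n - 1L)) {
    dx <- x[i] - x[(i + 1L):n]
    dy <- y[i] - y[(i + 1L):n]
    s <- sign(dx) * sign(dy)
    C <- C + sum(s > 0)
    D <- D + sum(s < 0)
  }
  if (C + D == 0L) {
    stop("gamma is undefined: all pairs are tied")
  }
  gamma <- (C - D) / (C + D)
  z <- if (abs(gamma) >= 1) {
    Inf
  } else {
    abs(gamma) * sqrt((C + D) / (n * (1 - gamma^2)))
  }
  list(gamma = gamma, C = C, D = D, z = z, p = 2 * pnorm(-z))
}

#' Spearman and Kendall rank correlations with significance
#'
#' Spearman uses midranks for ties; Kendall defaults to tau-b (the tie-
#' corrected form computed by \code{stats::cor.test}) and can be switched to
#' tau-a, for which ties simply reduce the numerator.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param kendall "tau_b" (default) or "tau_a".
#' @return list(spearman_R, p_R, kendall_tau, p_tau, kendall_variant).
#' @export
rankCorrelations <- function(x, y, kendall = c("tau_b", "tau_a")) {
  kendall <- match.arg(kendall)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("rank correlation is undefined for a constant vector")
  }
  sp <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)
  )
  if (kendall == "tau_b") {
    kt <- suppressWarnings(
      cor.test(x, y, method = "kendall", exact = FALSE)
    )
    tau <- unname(kt$estimate)
    p_tau <- kt$p.value
  } else {
    n <- length(x)
    C <- 0L
    D <- 0L
    for (i in seq_len(n - 1L)) {
      s <- sign(x[i] - x[(i + 1L):n]) * sign(y[i] - y[(i + 1L):n])
      C <- C + sum(s > 0)
      D <- D + sum(s < 0)
    }
    tau <- (C - D) / (n * (n - 1) / 2)
    z <- tau / sqrt((4 * n + 10) / (9 * n * (n - 1)))
    p_tau <- 2 * pnorm(-abs(z))
  }
  list(
    spearman_R = unname(sp$estimate), p_R = sp$p.value,
    kendall_tau = tau, p_tau = p_tau, kendall_variant = kendall
  )
}

#' Pearson correlation with linear regression and 95\% confidence band
#'
#' Least-squares regression of y on x with the pointwise confidence band of
#' the mean response, as drawn in predicted-vs-measured affinity scatter
#' plots.
#'
#' @param x,y numeric vectors of equal length >= 3; x must not be constant.
#' @param conf band confidence level, default 0.95.
#' @return list(r, p, slope, intercept, band) where band is a data.frame
#'   (x, fit, lwr, upr) evaluated at the sorted observed x.
#' @export
pearsonWithRegression <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < 2L) {
    stop("regression is undefined for constant x")
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  xs <- sort(unique(x))
  pr <- predict(fit, newdata = data.frame(x = xs),
                interval = "confidence", level = conf)
  list(
    r = unname(ct$estimate), p = ct$p.value,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    band = data.frame(x = xs, fit = pr[, "fit"], lwr = pr[, "lwr"],
                      upr = pr[, "upr"])
  )
}

#' Convert paired affinities to the relative (per-variant delta) scale
#'
#' Each variant must be present with exactly one ancestral and one minor
#' point; the output has one row per variant with minor-minus-ancestral
#' deltas of both the predicted and the measured affinity (the natural
#' reading of comparing alleles on a relative natural-log scale; on a log
#' scale the difference is the log fold change).
#'
#' @param pairs data.frame with columns id, allele ("ancestral"/"minor"),
#'   predicted, measured.
#' @return data.frame(id, predicted, measured) of deltas.
#' @export
toRelativeScale <- function(pairs) {
  stopifnot(all(c("id", "allele", "predicted", "measured") %in% names(pairs)))
  ids <- unique(pairs$id)
  out <- lapply(ids, function(v) {
    sub <- pairs[pairs$id == v, ]
    anc <- sub[sub$allele == "ancestral", ]
    mino <- sub[sub$allele == "minor", ]
    if (nrow(anc) != 1L || nrow(mino) != 1L) {
      stop(sprintf(
        "variant '%s' needs exactly one ancestral and one minor point", v
      ))
    }
    data.frame(
      id = v,
      predicted = mino$predicted - anc$predicted,
      measured = mino$measured - anc$measured,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Full concordance battery for predicted vs measured affinities
#'
#' Computes the four coefficients reported for predicted-vs-measured
#' affinity comparisons: Pearson r (with regression line and confidence
#' band), Spearman R, Kendall tau and Goodman-Kruskal gamma, each with its
#' significance level.
#'
#' @param predicted,measured numeric vectors (ln-units), length >= 3.
#' @param conf confidence level of the regression band.
#' @return list(r, p_r, slope, intercept, band, spearman_R, p_R,
#'   kendall_tau, p_tau, gamma, p_gamma, n).
#' @export
concordanceStats <- function(predicted, measured, conf = 0.95) {
  pear <- pearsonWithRegression(predicted, measured, conf = conf)
  ranks <- rankCorrelations(predicted, measured)
  gk <- goodmanKruskalGamma(predicted, measured)
  list(
    r = pear$r, p_r = pear$p, slope = pear$slope,
    intercept = pear$intercept, band = pear$band,
    spearman_R = ranks$spearman_R, p_R = ranks$p_R,
    kendall_tau = ranks$kendall_tau, p_tau = ranks$p_tau,
    gamma = gk$gamma, p_gamma = gk$p,
    n = length(predicted)
  )
}

#' Scatter plot of predicted vs measured affinities
#'
#' Base-graphics scatter with the regression line and its confidence band,
#' ancestral alleles as filled and minor alleles as open circles.
#'
#' @param pairs data.frame with columns id, allele, predicted, measured.
#' @param main plot title.
#' @return the \code{\link{concordanceStats}} list, invisibly.
#' @export
plotConcordance <- function(pairs, main = "Predicted vs measured -ln KD") {
  st <- concordanceStats(pairs$predicted, pairs$measured)
  pch <- ifelse(pairs$allele == "ancestral", 19, 1)
  graphics::plot(pairs$predicted, pairs$measured, pch = pch,
       xlab = "predicted -ln KD (ln-units)",
       ylab = "measured -ln KD (ln-units)", main = main)
  graphics::lines(st$band$x, st$band$fit)
  graphics::lines(st$band$x, st$band$lwr, lty = 2)
  graphics::lines(st$band$x, st$band$upr, lty = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "r = %.2f, R = %.2f, tau = %.2f, gamma = %.2f",
    st$r, st$spearman_R, st$kendall_tau, st$gamma
  ))
  invisible(st)
}
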