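# Independent brute-force oracles and fixture builders. These deliberately
# use naive character-by-character loops so they share no code path with the
# package's vectorised implementations.

BASES <- c("a", "c", "g", "t")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# promoter-like GC-rich background, so embedded TATA contexts dominate the
# scan the way they do in real proximal promoters
random_promoter_bg <- function(n) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
}

# combined score of one window (admissibility ignored), naive path
oracle_window_score <- function(s, i0, coeffs, pwm, slideVals, bendVals) {
  W <- coeffs@windowLength
  win <- substr(s, i0 + 1L, i0 + W)
  pb <- oracle_pwm_best(pwmWeights(pwm), win)
  coeffs@intercept +
    coeffs@weightSlide * oracle_dinuc_mean(win, slideVals) +
    coeffs@weightPwm * pb$score +
    coeffs@weightBend * oracle_dinuc_mean(win, bendVals)
}

# naive best-placement PWM score: enumerate every placement
oracle_pwm_best <- function(weights, window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  w <- ncol(weights)
  best <- -Inf
  bestoff <- NA_integer_
  for (o in 0:(length(chars) - w)) {
    sc <- 0
    for (j in seq_len(w)) sc <- sc + unname(weights[chars[o + j], j])
    if (sc > best) {
      best <- sc
      bestoff <- o
    }
  }
  list(score = best, offset = bestoff)
}

oracle_dinuc_mean <- function(window, values) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  tot <- 0
  for (k in seq_len(length(chars) - 1L)) {
    tot <- tot + values[[paste0(chars[k], chars[k + 1])]]
  }
  tot / (length(chars) - 1L)
}

# naive window-max affinity: enumerate every window and placement
oracle_affinity <- function(s, coeffs, pwm, slideVals, bendVals) {
  L <- nchar(s)
  W <- coeffs@windowLength
  weights <- pwmWeights(pwm)
  best <- -Inf
  beststart <- NA_integer_
  any_adm <- FALSE
  for (i0 in 0:(L - W)) {
    win <- substr(s, i0 + 1L, i0 + W)
    pb <- oracle_pwm_best(weights, win)
    if (length(coeffs@scanRegion) == 2L) {
      mid <- i0 + pb$offset + 7 - L
      if (mid < coeffs@scanRegion[1] || mid > coeffs@scanRegion[2]) next
    }
    any_adm <- TRUE
    sc <- coeffs@intercept +
      coeffs@weightSlide * oracle_dinuc_mean(win, slideVals) +
      coeffs@weightPwm * pb$score +
      coeffs@weightBend * oracle_dinuc_mean(win, bendVals)
    if (sc > best) {
      best <- sc
      beststart <- i0 - L
    }
  }
  if (!any_adm) return(NULL)
  list(mean = best, start = beststart)
}

# all-pairs concordant/discordant counts
oracle_pair_counts <- function(x, y) {
  n <- length(x)
  C <- 0L
  D <- 0L
  tx <- 0L
  ty <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1L
        ty <- ty + 1L
      } else if (dx == 0) {
        tx <- tx + 1L
      } else if (dy == 0) {
        ty <- ty + 1L
      } else if (dx * dy > 0) {
        C <- C + 1L
      } else {
        D <- D + 1L
      }
    }
  }
  list(C = C, D = D, tx = tx, ty = ty, n0 = n * (n - 1L) / 2L)
}

oracle_gamma <- function(x, y) {
  pc <- oracle_pair_counts(x, y)
  (pc$C - pc$D) / (pc$C + pc$D)
}

oracle_tau_b <- function(x, y) {
  pc <- oracle_pair_counts(x, y)
  (pc$C - pc$D) / sqrt((pc$n0 - pc$tx) * (pc$n0 - pc$ty))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# 90-bp promoter with a variant context embedded so that the first ref base
# sits at the requested TSS-relative position; uniqueness enforced
promoter_with_context <- function(flank5, ref, flank3, anchor_pos,
                                  seed = 1L, gene = "FIX") {
  ctx <- paste0(flank5, ref, flank3)
  set.seed(seed)
  for (try in 1:200) {
    bg <- random_promoter_bg(90L)
    i0 <- anchor_pos + 90L          # 0-based index of first ref base
    start0 <- i0 - 10L
    stopifnot(start0 >= 0L, start0 + nchar(ctx) <= 90L)
    s <- paste0(
      substr(bg, 1L, start0), ctx,
      substr(bg, start0 + nchar(ctx) + 1L, 90L)
    )
    hits <- gregexpr(ctx, s, fixed = TRUE)[[1]]
    if (length(hits) == 1L && hits[1] != -1L) {
      return(PromoterSequence(gene, s))
    }
  }
  stop("could not embed a unique context")
}

il1b_variant <- function() {
  VariantSpec("rs1143627", "ttttgaaagc", "c", "t", "ataaaaacag")
}
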