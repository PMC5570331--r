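#' Repeated-measures ANOVA with Huynh-Feldt correction and generalized eta^2
#'
#' Univariate within-subject decomposition for fully repeated designs with
#' one or more within factors. For every effect (main effects and all
#' interactions) the sums of squares are obtained by projecting each
#' subject's cell means onto orthonormal contrasts of the effect; the error
#' stratum is the subject-by-effect interaction. Sphericity is quantified by
#' the Greenhouse-Geisser estimate from the sample covariance of the
#' contrast scores, converted to the Huynh-Feldt estimate and clipped at 1;
#' corrected p values use epsilon-scaled degrees of freedom. Effects with a
#' single numerator degree of freedom (2-level factors) have epsilon = 1 by
#' construction. The generalized eta squared of an effect is its SS divided
#' by (its SS + the sum of all error SS in the design), the convention for
#' purely within-subject designs with no measured between factors.
#'
#' Subjects with incomplete cells are removed listwise (reported via the
#' `n_removed` attribute). Replicated subject-cell observations are averaged
#' into cell means first.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject-identifier column.
#' @param alpha Significance level carried into the result (default 0.05).
#' @return Data frame of class `rm_anova` with one row per effect:
#'   `effect`, `df_num`, `df_den`, `F`, `epsilon_hf`, `p_uncorrected`,
#'   `p_corrected`, `eta2_g`.
#' @examples
#' d <- expand.grid(subject = factor(1:8), task = factor(1:4))
#' d$score <- rnorm(nrow(d)) + as.numeric(d$task) / 2
#' rm_anova(d, "score", "task", "subject")
#' @export
rm_anova <- function(data, dv, within, subject, alpha = 0.05) {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  for (f in c(within, subject)) data[[f]] <- factor(data[[f]])
  # cell means per subject x within-cell
  cell <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  agg <- stats::aggregate(data[[dv]],
                          by = list(subject = data[[subject]], cell = cell),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "cell",
                         direction = "wide")
  cells <- levels(cell)
  colnames(wide)[-1] <- sub("^x\\.", "", colnames(wide)[-1])
  complete <- stats::complete.cases(wide[, cells, drop = FALSE])
  n_removed <- sum(!complete)
  Y <- as.matrix(wide[complete, cells, drop = FALSE])
  n <- nrow(Y)
  if (n < 2) stop("inference error: fewer than 2 complete subjects")
  if (stats::var(as.vector(Y)) == 0) {
    stop("degenerate-data error: dependent variable has zero variance")
  }
  levs <- lapply(within, function(f) levels(data[[f]]))
  names(levs) <- within
  nlev <- vapply(levs, length, integer(1))

  # orthonormal contrast rows per factor, plus the unit mean vector
  contr <- lapply(nlev, function(p) {
    M <- stats::contr.helmert(p)            # p x (p-1)
    t(qr.Q(qr(M)))                          # (p-1) x p, orthonormal rows
  })
  unitv <- lapply(nlev, function(p) matrix(1 / sqrt(p), 1, p))

  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)

  ss_total <- sum((Y - mean(Y))^2)
  # first pass: SS per effect and its error stratum
  res <- lapply(effects, function(eff) {
    M <- Reduce(kronecker, lapply(within, function(f) {
      if (f %in% eff) contr[[f]] else unitv[[f]]
    }))
    Z <- Y %*% t(M)                         # n x k contrast scores
    k <- nrow(M)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    if ((ss_eff + ss_err) < 1e-12 * ss_total) {
      # numerically null stratum (dv constant over this effect)
      ss_eff <- 0; ss_err <- 0
    }
    if (k == 1 || ss_err == 0) {
      gg <- 1; hf <- 1
    } else {
      S <- stats::cov(Z)
      gg <- sum(diag(S))^2 / (k * sum(S^2))
      hf <- min(1, (n * k * gg - 2) / (k * (n - 1 - k * gg)))
    }
    list(effect = paste(eff, collapse = ":"), k = k,
         ss_eff = ss_eff, ss_err = ss_err, gg = gg, hf = hf)
  })
  total_err <- sum(vapply(res, function(r) r$ss_err, numeric(1)))
  out <- do.call(rbind, lapply(res, function(r) {
    df1 <- r$k
    df2 <- (n - 1) * r$k
    Fv <- if (r$ss_eff == 0) 0 else (r$ss_eff / df1) / (r$ss_err / df2)
    data.frame(effect = r$effect, df_num = df1, df_den = df2, F = Fv,
               epsilon_hf = r$hf,
               p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               p_corrected = stats::pf(Fv, df1 * r$hf, df2 * r$hf,
                                       lower.tail = FALSE),
               eta2_g = if (r$ss_eff == 0 && total_err == 0) 0
                        else r$ss_eff / (r$ss_eff + total_err),
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_subjects") <- n
  attr(out, "n_removed") <- n_removed
  attr(out, "alpha") <- alpha
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Cohen's d for paired or two-sample comparisons
#'
#' Paired: mean difference divided by the SD of the differences. Two-sample:
#' mean difference divided by the pooled SD. A zero SD yields `NA` with a
#' warning rather than an infinite effect size.
#'
#' @param x,y Numeric samples (paired: equal length).
#' @param design `"paired"` or `"two_sample"`.
#' @return Cohen's d (scalar), possibly `NA`.
#' @export
cohens_d <- function(x, y, design = c("paired", "two_sample")) {
  design <- match.arg(design)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (design == "paired") {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    s <- stats::sd(d)
    if (s == 0) {
      warning("zero SD of differences: Cohen's d undefined")
      return(NA_real_)
    }
    mean(d) / s
  } else {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
    if (sp == 0) {
      warning("zero pooled SD: Cohen's d undefined")
      return(NA_real_)
    }
    (mean(x) - mean(y)) / sp
  }
}

#' A-priori power of a one-way repeated-measures design
#'
#' Uses the conventional noncentral-F formulation for a within factor with
#' `m` levels measured on `n` subjects: noncentrality
#' `lambda = f^2 * n * m / (1 - rho)`, where `f` is Cohen's effect size and
#' `rho` the assumed correlation between factor levels; power is the upper
#' tail of the noncentral F at the central critical value, with degrees of
#' freedom `(m - 1) * epsilon` and `(n - 1) * (m - 1) * epsilon`.
#'
#' @param n Number of subjects (>= 2).
#' @param m Number of within-factor levels (>= 2).
#' @param f Cohen's f effect size (>= 0).
#' @param rho Assumed correlation between factor levels, in `[0, 1)`
#'   (default 0.5).
#' @param alpha Test level (default 0.05).
#' @param epsilon Assumed nonsphericity in `(0, 1]` (default 1, sphericity,
#'   matching conventional a-priori power tools).
#' @return Achieved power in `[0, 1]`. With `f = 0` this equals `alpha`.
#' @examples
#' rm_power(n = 40, m = 4, f = 0.25, rho = 0.5)  # > 0.95
#' @export
rm_power <- function(n, m, f, rho = 0.5, alpha = 0.05, epsilon = 1) {
  stopifnot(n >= 2, m >= 2, f >= 0, rho >= 0, rho < 1,
            alpha > 0, alpha < 1, epsilon > 0, epsilon <= 1)
  lambda <- f^2 * n * m / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Paired or two-sample t test with Cohen's d
#'
#' Thin wrapper around [stats::t.test()] that also reports the matching
#' Cohen's d, mirroring how such comparisons are conventionally reported.
#'
#' @inheritParams cohens_d
#' @return Data frame with `t`, `df`, `p`, `d`.
#' @export
t_test_d <- function(x, y, design = c("paired", "two_sample")) {
  design <- match.arg(design)
  tt <- stats::t.test(x, y, paired = design == "paired",
                      var.equal = design == "two_sample")
  d <- suppressWarnings(cohens_d(x, y, design))
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = d)
}
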