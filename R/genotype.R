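# Zygosity classification (heterozygous vs homozygous) and carrier-fraction
# estimation from the normalized depth / normalized mismatch features of a
# confirmed indel.

#' Extract classifier features at indel positions
#'
#' The normalized depth is read at the indel position itself; the normalized
#' gated mismatch is the maximum within `w_f` bp, because the mismatch signal
#' peaks at the indel boundary rather than at its centre.
#'
#' @param profiles Normalized `indel_profiles`.
#' @param positions Indel positions (confirmed or truth).
#' @param w_f Search half-width for the mismatch peak (default 5, the
#'   detector window).
#' @return A tibble with `position`, `d_hat`, `m1_hat`.
#' @export
indel_features <- function(profiles, positions, w_f = 5) {
  if (!"m1_hat" %in% names(profiles)) abort("profiles must be normalized")
  T <- nrow(profiles)
  positions <- as.integer(positions)
  stopifnot(all(positions >= 1), all(positions <= T))
  m1_peak <- vapply(positions, function(p) {
    max(profiles$m1_hat[max(1L, p - w_f):min(T, p + w_f)])
  }, numeric(1))
  tibble(position = positions, d_hat = profiles$d_hat[positions],
         m1_hat = m1_peak)
}

#' Fit the two-feature linear discriminant for zygosity
#'
#' Fisher linear discriminant with pooled covariance on
#' `(d_hat, m1_hat)`, separating heterozygous (~50% of reads carry the
#' indel) from homozygous (~100%) indels. The decision is the sign of
#' `intercept + w_d * d_hat + w_m * m1_hat` (positive = homozygous); exact
#' ties are called heterozygous, the conservative choice.
#'
#' @param data Tibble with columns `d_hat`, `m1_hat` and `zygosity`
#'   (`"heterozygous"`/`"homozygous"`, or fractions 0.5/1).
#' @return A `zygosity_model`.
#' @export
fit_zygosity <- function(data) {
  data <- as_tibble(data)
  z <- normalize_zygosity(data$zygosity)
  x <- as.matrix(data[, c("d_hat", "m1_hat")])
  if (any(!is.finite(x))) abort("features must be finite")
  lev <- c("heterozygous", "homozygous")
  if (!all(lev %in% z) || min(table(z)) < 2) {
    abort("need at least 2 examples of each zygosity class")
  }
  mu <- rbind(colMeans(x[z == lev[1], , drop = FALSE]),
              colMeans(x[z == lev[2], , drop = FALSE]))
  n1 <- sum(z == lev[1]); n2 <- sum(z == lev[2])
  s1 <- stats::cov(x[z == lev[1], , drop = FALSE])
  s2 <- stats::cov(x[z == lev[2], , drop = FALSE])
  # pooled within-class scatter over total n: invariant to duplicating the
  # training set (the unbiased n - 2 denominator is not)
  sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2)
  w <- tryCatch(solve(sp, mu[2, ] - mu[1, ]), error = function(e) {
    warn("pooled covariance is singular; adding a ridge jitter")
    solve(sp + diag(1e-8 * (1 + mean(diag(sp))), 2), mu[2, ] - mu[1, ])
  })
  intercept <- -sum(w * (mu[1, ] + mu[2, ]) / 2) + log(n2 / n1)
  model <- structure(
    list(coef = c(intercept = unname(intercept), d_hat = unname(w[1]),
                  m1_hat = unname(w[2])),
         means = mu, pooled_cov = sp, n = c(n1, n2), levels = lev),
    class = "zygosity_model")
  model
}

normalize_zygosity <- function(z) {
  if (is.numeric(z)) {
    out <- ifelse(z >= 0.75, "homozygous", "heterozygous")
  } else {
    out <- as.character(z)
  }
  if (!all(out %in% c("heterozygous", "homozygous"))) {
    abort("zygosity must be heterozygous/homozygous (or fractions 0.5 / 1)")
  }
  out
}

#' Classify indels as heterozygous or homozygous
#'
#' @param model A fitted [fit_zygosity()] model.
#' @param data Tibble with `d_hat`, `m1_hat`.
#' @return `data` with `.score` (signed discriminant value) and `.zygosity`
#'   appended.
#' @export
classify_zygosity <- function(model, data) {
  stopifnot(inherits(model, "zygosity_model"))
  data <- as_tibble(data)
  co <- unname(model$coef)
  score <- co[1] + co[2] * data$d_hat + co[3] * data$m1_hat
  data$.score <- unname(score)
  data$.zygosity <- ifelse(score > 0, "homozygous", "heterozygous")
  data
}

#' @export
print.zygosity_model <- function(x, ...) {
  cat("<zygosity_model> homozygous iff",
      sprintf("%.3g + %.3g * d_hat + %.3g * m1_hat > 0\n",
              x$coef[1], x$coef[2], x$coef[3]))
  invisible(x)
}

#' @method tidy zygosity_model
#' @export
tidy.zygosity_model <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @method glance zygosity_model
#' @export
glance.zygosity_model <- function(x, ...) {
  tibble(n = sum(x$n), n_heterozygous = x$n[1], n_homozygous = x$n[2])
}

#' Fit the logistic carrier-fraction model
#'
#' Models the fraction p of cells carrying the indel as
#' `logit(p) = alpha + beta * d_hat + delta * m1_hat`, fitted by
#' quasi-likelihood logistic regression (the responses are fractions in
#' (0, 1], not counts). On spike-in training data the depth coefficient is
#' negative and the mismatch coefficient positive: a deeper depth drop and a
#' stronger edge-mismatch peak both indicate a larger carrier fraction.
#'
#' @param data Tibble with `d_hat`, `m1_hat` and `fraction` in (0, 1].
#' @return A `fraction_model` wrapping the glm fit.
#' @export
fit_fraction <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("d_hat", "m1_hat", "fraction") %in% names(data)))
  if (any(data$fraction <= 0 | data$fraction > 1)) {
    abort("fractions must lie in (0, 1]")
  }
  if (length(unique(data$fraction)) < 2) {
    abort("need at least 2 distinct spike fractions to fit")
  }
  if (stats::sd(data$d_hat) == 0 && stats::sd(data$m1_hat) == 0) {
    abort("degenerate design: both features are constant")
  }
  fit <- glm(fraction ~ d_hat + m1_hat, data = data,
             family = quasibinomial())
  structure(list(fit = fit, coef = coef(fit)), class = "fraction_model")
}

#' Estimate the carrier fraction of indels
#'
#' @param model A fitted [fit_fraction()] model.
#' @param data Tibble with `d_hat`, `m1_hat`.
#' @return `data` with `.fraction_hat` in (0, 1) appended.
#' @export
estimate_fraction <- function(model, data) {
  stopifnot(inherits(model, "fraction_model"))
  data <- as_tibble(data)
  data$.fraction_hat <- unname(predict(model$fit, newdata = data,
                                       type = "response"))
  data
}

#' @export
print.fraction_model <- function(x, ...) {
  cat("<fraction_model> logit(p) =",
      sprintf("%.3g + %.3g * d_hat + %.3g * m1_hat\n",
              x$coef[1], x$coef[2], x$coef[3]))
  invisible(x)
}

#' @method tidy fraction_model
#' @export
tidy.fraction_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("alpha", "beta", "delta"), estimate = unname(s[, 1]),
         std.error = unname(s[, 2]))
}

#' @method glance fraction_model
#' @export
glance.fraction_model <- function(x, ...) {
  tibble(n = length(x$fit$residuals), deviance = x$fit$deviance,
         df.residual = x$fit$df.residual)
}

# repeated random-split protocols ----------------------------------------

#' Repeated 50/50 split evaluation of the zygosity classifier
#'
#' Splits the labelled feature set in half at random, fits the discriminant
#' on one half, scores the other, and repeats. Reports the mean test
#' misclassification percentage.
#'
#' @param data Labelled feature tibble (see [fit_zygosity()]).
#' @param n_splits Number of random splits (default 100).
#' @param seed Integer seed.
#' @return A list with `mean_error_pct` and the per-split errors.
#' @export
zygosity_split_error <- function(data, n_splits = 100, seed = 1) {
  data <- as_tibble(data)
  data$zygosity <- normalize_zygosity(data$zygosity)
  n <- nrow(data)
  errs <- withr::with_seed(seed, {
    vapply(seq_len(n_splits), function(i) {
      repeat {
        train <- sample.int(n, floor(n / 2))
        if (length(unique(data$zygosity[train])) == 2 &&
            min(table(data$zygosity[train])) >= 2) break
      }
      m <- fit_zygosity(data[train, ])
      pred <- classify_zygosity(m, data[-train, ])
      mean(pred$.zygosity != data$zygosity[-train])
    }, numeric(1))
  })
  list(mean_error_pct = 100 * mean(errs), errors = errs)
}

#' Repeated 50/50 split evaluation of the fraction estimator
#'
#' @param data Feature tibble with `fraction` (see [fit_fraction()]).
#' @param n_splits Number of random splits (default 100).
#' @param seed Integer seed.
#' @return A list with `mae_pct` (mean absolute error in percentage points),
#'   `per_class` (a tibble of per-fraction MAEs), and per-split values.
#' @export
fraction_split_error <- function(data, n_splits = 100, seed = 1) {
  data <- as_tibble(data)
  n <- nrow(data)
  res <- withr::with_seed(seed, {
    purrr::map(seq_len(n_splits), function(i) {
      repeat {
        train <- sample.int(n, floor(n / 2))
        if (length(unique(data$fraction[train])) >= 2) break
      }
      m <- fit_fraction(data[train, ])
      pred <- estimate_fraction(m, data[-train, ])
      tibble(fraction = data$fraction[-train],
             abs_err = abs(pred$.fraction_hat - data$fraction[-train]))
    })
  })
  all <- bind_rows(res)
  list(
    mae_pct = 100 * mean(all$abs_err),
    per_class = all |>
      group_by(.data$fraction) |>
      summarise(mae_pct = 100 * mean(.data$abs_err), .groups = "drop"),
    split_mae_pct = vapply(res, function(d) 100 * mean(d$abs_err), numeric(1))
  )
}
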