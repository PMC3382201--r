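#' Weighted node degrees of a cohort
#'
#' The weighted degree of a node is the sum of the weights of all edges
#' incident to it (its row sum). Degrees are returned per subject and node in
#' subject-major order, zeros retained, so a cohort of S subjects and N nodes
#' yields S x N values.
#'
#' @param stack a [subject_stack()].
#' @return data.frame with columns `subject`, `node`, `degree`; the `degree`
#'   column in row order is the subject-major sample.
#' @export
weighted_degrees <- function(stack) {
  stack <- validate_subject_stack(stack)
  n <- n_nodes(stack)
  out <- do.call(rbind, lapply(seq_along(stack$matrices), function(k) {
    data.frame(subject = stack$subject_ids[k], node = seq_len(n),
               degree = rowSums(stack$matrices[[k]]))
  }))
  rownames(out) <- NULL
  out
}

# Distribution-fit container ------------------------------------------------

new_distribution_fit <- function(family, params, support_bound, loglik,
                                 ks_distance, n_used) {
  structure(list(family = family, params = params,
                 support_bound = support_bound, loglik = loglik,
                 ks_distance = ks_distance, n_used = as.integer(n_used)),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("distribution_fit: %s (%s); KS = %.4f; n_used = %d; support bound = %g\n",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$ks_distance, x$n_used, x$support_bound))
  invisible(x)
}

#' Kolmogorov-Smirnov distance between a sample and a fitted CDF
#'
#' Supremum gap between the sample's empirical CDF and `cdf`, evaluated with
#' the standard one-sample formula at the sorted sample points.
#'
#' @param x numeric sample.
#' @param cdf vectorized cumulative distribution function.
#' @return numeric in \[0, 1\].
#' @export
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  fx <- cdf(x)
  max(pmax(seq_len(n) / n - fx, fx - (seq_len(n) - 1L) / n))
}

#' Full-sample maximum-likelihood fits (normal, gamma)
#'
#' Normal parameters are the closed-form MLEs (population-form sigma). The
#' gamma fit is restricted to strictly positive values (zero has no gamma
#' density) and maximized numerically via [MASS::fitdistr()]; its `n_used`
#' reflects the restriction.
#'
#' @param sample numeric vector of non-negative values (zeros allowed).
#' @param family `"normal"` or `"gamma"`.
#' @return a `distribution_fit`.
#' @export
fit_full <- function(sample, family = c("normal", "gamma")) {
  family <- match.arg(family)
  stopifnot(length(sample) > 0)
  if (family == "normal") {
    mu <- mean(sample)
    sigma <- sqrt(mean((sample - mu)^2))
    if (sigma == 0) stop("degenerate sample: zero variance")
    return(new_distribution_fit(
      "normal", c(mean = mu, sd = sigma), support_bound = 0,
      loglik = sum(stats::dnorm(sample, mu, sigma, log = TRUE)),
      ks_distance = ks_distance(sample, function(q) stats::pnorm(q, mu, sigma)),
      n_used = length(sample)))
  }
  x <- sample[sample > 0]
  if (!length(x)) stop("domain error: gamma fit requires positive values")
  if (stats::var(x) == 0) stop("degenerate sample: zero variance")
  # moment start, then MLE
  s0 <- mean(x)^2 / stats::var(x)
  fit <- MASS::fitdistr(x, "gamma",
                        start = list(shape = s0, rate = s0 / mean(x)),
                        lower = c(1e-10, 1e-10))
  shape <- unname(fit$estimate["shape"]); rate <- unname(fit$estimate["rate"])
  new_distribution_fit(
    "gamma", c(shape = shape, scale = 1 / rate), support_bound = 0,
    loglik = unname(fit$loglik),
    ks_distance = ks_distance(x, function(q) stats::pgamma(q, shape, rate)),
    n_used = length(x))
}

#' Histogram mode of a sample
#'
#' Center of the most populated histogram bin under Freedman-Diaconis binning;
#' ties are broken toward the smaller bin center. A sample with zero
#' interquartile range (or a single value) returns its median.
#'
#' @param sample numeric vector.
#' @return numeric scalar, the mode estimate.
#' @export
sample_mode <- function(sample) {
  stopifnot(length(sample) > 0)
  iqr <- stats::IQR(sample)
  if (iqr == 0 || length(unique(sample)) == 1L) return(stats::median(sample))
  h <- 2 * iqr / length(sample)^(1 / 3)
  breaks <- seq(min(sample), max(sample) + h, by = h)
  counts <- graphics::hist(sample, breaks = breaks, plot = FALSE, right = FALSE)
  centers <- counts$mids
  centers[which.max(counts$counts)] # which.max takes the first (smaller) on ties
}

#' Shifted-exponential fit to the sample tail
#'
#' Maximum-likelihood exponential fit to the values strictly above
#' `left_bound`: the rate is the reciprocal of the mean excess. The KS distance
#' compares the tail-restricted empirical CDF with the fitted conditional CDF.
#'
#' @param sample numeric vector.
#' @param left_bound left edge of the fitted tail.
#' @return a `distribution_fit` with parameters `rate` and `left_bound`.
#' @export
fit_exponential_tail <- function(sample, left_bound) {
  x <- sample[sample > left_bound]
  if (length(x) < 10L)
    stop("insufficient data: fewer than 10 values above the left bound")
  rate <- 1 / mean(x - left_bound)
  new_distribution_fit(
    "exponential", c(rate = rate, left_bound = left_bound),
    support_bound = left_bound,
    loglik = sum(stats::dexp(x - left_bound, rate, log = TRUE)),
    ks_distance = ks_distance(x, function(q) stats::pexp(q - left_bound, rate)),
    n_used = length(x))
}

#' Pareto (power-law) fit with automatic lower bound
#'
#' Continuous-Pareto maximum likelihood with data-driven selection of the
#' left bound `x_min`: every distinct positive sample value is scanned as a
#' candidate bound, the tail exponent is the closed-form MLE
#' `alpha = 1 + n_tail / sum(log(x / x_min))`, and the bound minimizing the KS
#' distance between the tail empirical CDF and the fitted Pareto CDF is
#' selected. Candidates leaving fewer than `min_tail` tail points are skipped.
#'
#' @param sample numeric vector; needs at least 25 distinct positive values
#'   unless `x_min` is forced.
#' @param x_min optional forced lower bound (skips the scan).
#' @param min_tail smallest admissible tail size during the scan (default 10).
#' @return a `distribution_fit` with parameters `alpha` and `x_min`.
#' @export
fit_powerlaw <- function(sample, x_min = NULL, min_tail = 10L) {
  x <- sort(sample[sample > 0])
  if (is.null(x_min)) {
    if (length(unique(x)) < 25L)
      stop("insufficient data: need at least 25 distinct positive values")
    cand <- unique(x)
    cand <- cand[vapply(cand, function(b) sum(x >= b), integer(1)) >= min_tail]
    if (!length(cand)) stop("insufficient data: no candidate x_min leaves a tail")
    best <- NULL
    for (b in cand) {
      f <- .pareto_tail_fit(x, b)
      if (is.null(f)) next
      if (is.null(best) || f$ks < best$ks) best <- f
    }
    if (is.null(best)) stop("degenerate tail: all tail values equal at every candidate bound")
  } else {
    best <- .pareto_tail_fit(x, x_min)
    if (is.null(best)) stop("degenerate tail: all tail values equal")
  }
  new_distribution_fit(
    "powerlaw", c(alpha = best$alpha, x_min = best$x_min),
    support_bound = best$x_min, loglik = best$loglik,
    ks_distance = best$ks, n_used = best$n)
}

.pareto_tail_fit <- function(x_sorted, b) {
  tail <- x_sorted[x_sorted >= b]
  n <- length(tail)
  if (n < 2L) return(NULL)
  slog <- sum(log(tail / b))
  if (slog <= 0) return(NULL)       # all tail values equal the bound
  alpha <- 1 + n / slog
  cdf <- function(q) 1 - (b / q)^(alpha - 1)
  list(alpha = alpha, x_min = b, n = n,
       ks = ks_distance(tail, cdf),
       loglik = n * log(alpha - 1) + n * (alpha - 1) * log(b) - alpha * sum(log(tail)))
}

#' Fit and rank all four candidate degree distributions
#'
#' Runs the normal and gamma full-sample fits, the shifted-exponential fit to
#' the right of the histogram mode ([sample_mode()]), and the Pareto fit with
#' scanned `x_min`, then ranks the fits by ascending KS distance. Tail fits are
#' evaluated on their restricted support (their KS distances compare the
#' tail-restricted empirical CDF against the fitted conditional CDF), so the
#' `support` column must be consulted when interpreting the ranking: a tail-only
#' family describes only the portion of the sample above its bound, whereas the
#' normal fit covers the complete sample. A family whose fit fails is reported
#' with `NA` distance rather than aborting the comparison.
#'
#' @param sample numeric vector of non-negative values.
#' @return data.frame with columns `family`, `ks_distance`, `support`
#'   (`"full"`/`"tail"`), `support_bound`, `n_used`, `params` (list column),
#'   ordered by `ks_distance`; failed fits sort last. The fit objects are
#'   attached as attribute `fits`.
#' @export
compare_fits <- function(sample) {
  stopifnot(length(sample) > 0, all(sample >= 0))
  mode_est <- sample_mode(sample)
  fits <- list(
    normal      = function() fit_full(sample, "normal"),
    gamma       = function() fit_full(sample, "gamma"),
    exponential = function() fit_exponential_tail(sample, mode_est),
    powerlaw    = function() fit_powerlaw(sample))
  res <- lapply(fits, function(f) tryCatch(f(), error = function(e) e))
  ok <- !vapply(res, inherits, logical(1), "error")
  tab <- data.frame(
    family = names(res),
    ks_distance = vapply(res, function(f) if (inherits(f, "error")) NA_real_ else f$ks_distance, numeric(1)),
    support = c("full", "full", "tail", "tail"),
    support_bound = vapply(res, function(f) if (inherits(f, "error")) NA_real_ else f$support_bound, numeric(1)),
    n_used = vapply(res, function(f) if (inherits(f, "error")) NA_integer_ else f$n_used, integer(1)),
    error = vapply(res, function(f) if (inherits(f, "error")) conditionMessage(f) else "", character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$ks_distance, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- res[ok]
  tab
}

#' Empirical vs fitted-normal quantile table
#'
#' Pairs of (empirical quantile, fitted-normal quantile) at percentiles 1..99,
#' for Q-Q assessment of the normal fit.
#'
#' @param sample numeric vector.
#' @param fit a normal `distribution_fit` (from [fit_full()]).
#' @return data.frame with columns `percentile`, `empirical`, `fitted`.
#' @export
quantile_report <- function(sample, fit) {
  stopifnot(inherits(fit, "distribution_fit"), fit$family == "normal")
  pr <- seq_len(99) / 100
  data.frame(percentile = 100 * pr,
             empirical = unname(stats::quantile(sample, probs = pr)),
             fitted = stats::qnorm(pr, fit$params["mean"], fit$params["sd"]))
}
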