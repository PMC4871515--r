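# The five approximate probabilistic model-checking algorithms. Each decides
# a query P_cmp_theta[psi] from a stream of per-trace Boolean outcomes
# (psi evaluated on independent simulation traces):
#
#   blackbox_check       fixed n; one-sided binomial p-values for H0 and H1
#                        at the boundary theta; the hypothesis with the
#                        smaller p-value (less supported by the data) is
#                        rejected; exact ties fall back to x/n cmp theta.
#   chernoff_check       fixed n = ceil((4/eps^2) * ln(2/delta)) so that
#                        P[|x/n - p| > eps] < delta; decides x/n cmp theta.
#   sprt_check           Wald's sequential probability ratio test of
#                        p >= theta+h against p <= theta-h with type I/II
#                        error bounds alpha/beta; data-dependent n.
#   bayes_estimate_check Beta-Binomial posterior mean/variance; consumes
#                        outcomes until posterior variance < threshold.
#   bayes_factor_check   posterior odds B = P(H0|data)/P(H1|data) from the
#                        Beta posterior CDF at theta; stops at B > T
#                        (holds) or B < 1/T (does not hold).
#
# The checkers are deterministic given the outcome sequence; all
# stochasticity lives in trace generation.

cmp_is_upper <- function(cmp) cmp %in% c(">", ">=")

new_verdict <- function(holds, estimate, n_total, n_true, confidence,
                        method) {
  structure(
    list(holds = holds, estimate = estimate, n_total = n_total,
         n_true = n_true, n_false = n_total - n_true,
         confidence = confidence, method = method),
    class = "mstmc_verdict")
}

#' @export
print.mstmc_verdict <- function(x, ...) {
  cat(sprintf("<verdict:%s> holds=%s estimate=%s n=%d (true %d / false %d)\n",
              x$method, x$holds,
              if (is.null(x$estimate)) "-" else format(x$estimate),
              x$n_total, x$n_true, x$n_false))
  if (length(x$confidence))
    cat("  confidence:", paste(names(x$confidence), "=",
                               vapply(x$confidence, format, character(1)),
                               collapse = ", "), "\n")
  invisible(x)
}

check_query_arg <- function(q) {
  if (!inherits(q, "pblmstl_query"))
    abort_parameter("q must be a pblmstl_query (see parse_query)")
  q
}

# --- outcome providers ------------------------------------------------------

#' Outcome providers
#'
#' A provider is a closure stream of Boolean outcomes (one per simulation
#' trace). \code{outcome_provider} wraps a fixed logical vector;
#' \code{trace_outcome_provider} evaluates a query lazily over a list of
#' traces; \code{generator_outcome_provider} invokes an external command
#' that must write exactly one new MSTML file per invocation into
#' \code{dir}, then evaluates the query on it (the on-demand generation
#' contract).
#'
#' @param outcomes Logical vector.
#' @return A function \code{()} returning \code{TRUE}/\code{FALSE}, or
#'   \code{NULL} when exhausted.
#' @export
outcome_provider <- function(outcomes) {
  outcomes <- as.logical(outcomes)
  if (anyNA(outcomes)) abort_parameter("outcomes must be TRUE/FALSE")
  i <- 0L
  function() {
    if (i >= length(outcomes)) return(NULL)
    i <<- i + 1L
    outcomes[[i]]
  }
}

#' @rdname outcome_provider
#' @param traces List of \code{mst_trace} objects (or paths to MSTML files,
#'   loaded lazily).
#' @param q Parsed \code{pblmstl_query}.
#' @param g \code{ma_graph}.
#' @param registry \code{spatial_registry}.
#' @param locf Passed to the evaluator.
#' @export
trace_outcome_provider <- function(traces, q, g,
                                   registry = default_spatial_registry(),
                                   locf = FALSE) {
  check_query_arg(q)
  i <- 0L
  function() {
    if (i >= length(traces)) return(NULL)
    i <<- i + 1L
    tr <- traces[[i]]
    if (is.character(tr)) tr <- read_mstml(tr, registry)
    evaluate_query_on_trace(q, tr, g, registry, locf)
  }
}

#' @rdname outcome_provider
#' @param command External command line; invoked as
#'   \code{command <dir>} and required to create exactly one new MSTML
#'   file in \code{dir} per invocation.
#' @param dir Watched output directory.
#' @param timeout Seconds to allow per invocation.
#' @export
generator_outcome_provider <- function(command, dir, q, g,
                                       registry = default_spatial_registry(),
                                       locf = FALSE, timeout = 300) {
  check_query_arg(q)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  function() {
    before <- list.files(dir, pattern = "\\.(xml|mstml)$")
    status <- system2(command, args = shQuote(dir), timeout = timeout)
    if (!identical(status, 0L))
      abort_sample(sprintf("trace generator '%s' failed with status %s",
                           command, status))
    after <- list.files(dir, pattern = "\\.(xml|mstml)$")
    fresh <- setdiff(after, before)
    if (length(fresh) != 1L)
      abort_sample(sprintf(
        "trace generator must create exactly one new MSTML file, found %d",
        length(fresh)))
    tr <- read_mstml(file.path(dir, fresh), registry)
    evaluate_query_on_trace(q, tr, g, registry, locf)
  }
}

draw_n <- function(provider, n, method) {
  out <- logical(0)
  for (i in seq_len(n)) {
    v <- provider()
    if (is.null(v))
      abort_sample(sprintf(
        "%s needs %d outcomes but the provider was exhausted after %d",
        method, n, length(out)))
    out <- c(out, v)
  }
  out
}

# --- probabilistic black-box ------------------------------------------------

#' Probabilistic black-box check
#'
#' Fixed-sample hypothesis test from \code{n >= 1} Boolean outcomes. With
#' \code{x} successes, the p-value of each hypothesis is the binomial tail
#' at the boundary \code{theta} in the direction of the opposing
#' hypothesis; the hypothesis with the smaller p-value is rejected and its
#' rival holds. An exact tie falls back to the point estimate
#' \code{x/n cmp theta}. Both p-values are reported.
#'
#' @param outcomes Logical vector (or an outcome provider plus \code{n}).
#' @param q \code{pblmstl_query}.
#' @param n Number of outcomes to draw when \code{outcomes} is a provider.
#' @return An \code{mstmc_verdict} with confidence components
#'   \code{p_value_h0} and \code{p_value_h1}.
#' @export
blackbox_check <- function(outcomes, q, n = NULL) {
  check_query_arg(q)
  if (is.function(outcomes)) outcomes <- draw_n(outcomes, n, "blackbox_check")
  outcomes <- as.logical(outcomes)
  n <- length(outcomes)
  if (n < 1L) abort_sample("black-box check needs at least one outcome")
  x <- sum(outcomes)
  theta <- q$theta
  upper_tail <- stats::pbinom(x - 1L, n, theta, lower.tail = FALSE) # P[X >= x]
  lower_tail <- stats::pbinom(x, n, theta)                          # P[X <= x]
  if (cmp_is_upper(q$cmp)) {
    pv_h0 <- lower_tail   # evidence against H0: p cmp-above theta is small x
    pv_h1 <- upper_tail
  } else {
    pv_h0 <- upper_tail
    pv_h1 <- lower_tail
  }
  holds <- if (pv_h0 == pv_h1) {
    apply_comparator(q$cmp, x / n, theta)
  } else {
    pv_h0 > pv_h1   # reject the hypothesis with the smaller p-value
  }
  new_verdict(holds, x / n, n, x,
              c(p_value_h0 = pv_h0, p_value_h1 = pv_h1), "blackbox")
}

# --- Chernoff-Hoeffding -----------------------------------------------------

#' Chernoff-Hoeffding sample size and estimate check
#'
#' \code{chernoff_sample_size} returns \code{ceiling((4 / epsilon^2) *
#' log(2 / delta))} (natural log): with that many i.i.d. outcomes the
#' estimate \code{x/n} deviates from the true probability by more than
#' \code{epsilon} with probability below \code{delta}.
#'
#' @param epsilon Half-width of the estimation error band, in (0, 1).
#' @param delta Failure probability bound, in (0, 1).
#' @return Positive integer.
#' @examples
#' chernoff_sample_size(0.1, 0.05)  # 1476
#' @export
chernoff_sample_size <- function(epsilon, delta) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon >= 1)
    abort_parameter("epsilon must lie in (0, 1)")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    abort_parameter("delta must lie in (0, 1)")
  as.integer(ceiling((4 / epsilon^2) * log(2 / delta)))
}

#' @rdname chernoff_sample_size
#' @param provider Outcome provider (or logical vector; extra outcomes
#'   beyond the required sample size are ignored).
#' @param q \code{pblmstl_query}.
#' @return \code{chernoff_check}: an \code{mstmc_verdict}; the estimate is
#'   \code{x/n}, the verdict \code{estimate cmp theta}, the confidence the
#'   pair (epsilon, delta).
#' @export
chernoff_check <- function(provider, epsilon, delta, q) {
  check_query_arg(q)
  n <- chernoff_sample_size(epsilon, delta)
  if (!is.function(provider)) provider <- outcome_provider(provider)
  outcomes <- draw_n(provider, n, "chernoff_check")
  x <- sum(outcomes)
  est <- x / n
  new_verdict(apply_comparator(q$cmp, est, q$theta), est, n, x,
              c(epsilon = epsilon, delta = delta), "chernoff")
}

# --- sequential probability ratio test --------------------------------------

#' Wald's sequential probability ratio test
#'
#' Tests \code{p >= theta + half_width} against \code{p <= theta -
#' half_width} (the indifference region is \code{(theta - half_width,
#' theta + half_width)}). After each outcome the log likelihood ratio is
#' updated; the upper hypothesis is accepted when it reaches
#' \code{log((1-beta)/alpha)}, the lower when it falls to
#' \code{log(beta/(1-alpha))}. The verdict is mapped back through the
#' query comparator: for \code{P > theta} / \code{P >= theta} the property
#' holds iff the upper hypothesis is accepted, for \code{P < theta} /
#' \code{P <= theta} iff the lower one is.
#'
#' @param provider Outcome provider or logical vector.
#' @param alpha,beta Upper bounds on type I / type II error probability.
#' @param half_width Indifference-region half-width; must satisfy
#'   \code{0 < half_width < min(theta, 1 - theta)}.
#' @param q \code{pblmstl_query}.
#' @param max_n Safety cap on the number of outcomes drawn.
#' @return An \code{mstmc_verdict} with confidence components
#'   \code{log_lr}, \code{alpha}, \code{beta}, \code{half_width}.
#' @export
sprt_check <- function(provider, alpha, beta, half_width, q,
                       max_n = 1e6) {
  check_query_arg(q)
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      abort_parameter(sprintf("%s must lie in (0, 1)", nm))
  }
  theta <- q$theta
  if (!is.numeric(half_width) || half_width <= 0 ||
      half_width >= min(theta, 1 - theta))
    abort_parameter("half_width must satisfy 0 < half_width < min(theta, 1 - theta)")
  if (!is.function(provider)) provider <- outcome_provider(provider)
  p1 <- theta + half_width
  p0 <- theta - half_width
  upper_bound <- log((1 - beta) / alpha)
  lower_bound <- log(beta / (1 - alpha))
  log_lr <- 0
  n <- 0L
  x <- 0L
  decision <- NA_character_
  while (n < max_n) {
    v <- provider()
    if (is.null(v))
      abort_sample(sprintf(
        "SPRT undecided after %d outcomes (log likelihood ratio %.4f)",
        n, log_lr))
    n <- n + 1L
    x <- x + as.integer(v)
    log_lr <- log_lr +
      if (v) log(p1 / p0) else log((1 - p1) / (1 - p0))
    if (log_lr >= upper_bound) { decision <- "upper"; break }
    if (log_lr <= lower_bound) { decision <- "lower"; break }
  }
  if (is.na(decision))
    abort_sample(sprintf("SPRT undecided after max_n = %d outcomes", max_n))
  holds <- if (cmp_is_upper(q$cmp)) decision == "upper" else decision == "lower"
  new_verdict(holds, x / n, n, x,
              c(log_lr = log_lr, alpha = alpha, beta = beta,
                half_width = half_width), "sprt")
}

# --- Bayesian mean/variance estimation --------------------------------------

#' Bayesian estimate check
#'
#' Beta-Binomial estimation: starting from a \code{Beta(prior_alpha,
#' prior_beta)} prior, outcomes are consumed until the posterior variance
#' drops below \code{variance_threshold} (the prior alone may already
#' satisfy the rule, giving \code{n = 0}). The estimate is the posterior
#' mean; the verdict compares it with the query threshold.
#'
#' @param provider Outcome provider or logical vector.
#' @param prior_alpha,prior_beta Beta prior parameters (> 0).
#' @param variance_threshold Posterior-variance stopping threshold (> 0).
#' @param q \code{pblmstl_query}.
#' @return An \code{mstmc_verdict}; confidence components
#'   \code{posterior_variance}, \code{posterior_alpha},
#'   \code{posterior_beta}.
#' @export
bayes_estimate_check <- function(provider, prior_alpha, prior_beta,
                                 variance_threshold, q) {
  check_query_arg(q)
  if (!is.numeric(prior_alpha) || prior_alpha <= 0 ||
      !is.numeric(prior_beta) || prior_beta <= 0)
    abort_parameter("Beta prior parameters must be positive")
  if (!is.numeric(variance_threshold) || variance_threshold <= 0)
    abort_parameter("variance_threshold must be positive")
  if (!is.function(provider)) provider <- outcome_provider(provider)
  a <- prior_alpha
  b <- prior_beta
  n <- 0L
  x <- 0L
  post_var <- function() (a * b) / ((a + b)^2 * (a + b + 1))
  while (post_var() >= variance_threshold) {
    v <- provider()
    if (is.null(v))
      abort_sample(sprintf(
        "provider exhausted after %d outcomes with posterior variance %.3g >= %.3g",
        n, post_var(), variance_threshold))
    n <- n + 1L
    x <- x + as.integer(v)
    if (v) a <- a + 1 else b <- b + 1
  }
  rho <- a / (a + b)
  new_verdict(apply_comparator(q$cmp, rho, q$theta), rho, n, x,
              c(posterior_variance = post_var(), posterior_alpha = a,
                posterior_beta = b), "bayes-estimate")
}

# --- Bayesian hypothesis testing (Bayes factor) -----------------------------

bayes_factor_value <- function(a, b, q) {
  p_upper <- stats::pbeta(q$theta, a, b, lower.tail = FALSE)  # P(p > theta)
  p_h0 <- if (cmp_is_upper(q$cmp)) p_upper else 1 - p_upper
  p_h0 / (1 - p_h0)
}

#' Bayesian hypothesis-testing check
#'
#' Sequentially computes the posterior odds \code{B = P(H0 | data) /
#' P(H1 | data)} for \code{H0: p cmp theta} from the Beta posterior CDF at
#' \code{theta}, consuming outcomes until \code{B > bf_threshold} (holds)
#' or \code{B < 1/bf_threshold} (does not hold). With
#' \code{prior_odds_normalized = TRUE} the statistic reported and
#' thresholded is the Bayes factor proper, i.e. posterior odds divided by
#' prior odds.
#'
#' @inheritParams bayes_estimate_check
#' @param bf_threshold Decision threshold \code{T > 1}.
#' @param prior_odds_normalized Normalize by the prior odds (default FALSE:
#'   raw posterior-confidence ratio).
#' @param max_n Safety cap.
#' @return An \code{mstmc_verdict}; confidence component
#'   \code{bayes_factor}.
#' @export
bayes_factor_check <- function(provider, prior_alpha, prior_beta,
                               bf_threshold, q,
                               prior_odds_normalized = FALSE,
                               max_n = 1e6) {
  check_query_arg(q)
  if (!is.numeric(prior_alpha) || prior_alpha <= 0 ||
      !is.numeric(prior_beta) || prior_beta <= 0)
    abort_parameter("Beta prior parameters must be positive")
  if (!is.numeric(bf_threshold) || bf_threshold <= 1)
    abort_parameter("bf_threshold must be strictly greater than 1")
  if (!is.function(provider)) provider <- outcome_provider(provider)
  a <- prior_alpha
  b <- prior_beta
  prior_odds <- bayes_factor_value(prior_alpha, prior_beta, q)
  n <- 0L
  x <- 0L
  statistic <- function() {
    bf <- bayes_factor_value(a, b, q)
    if (prior_odds_normalized) bf / prior_odds else bf
  }
  repeat {
    B <- statistic()
    if (B > bf_threshold)
      return(new_verdict(TRUE, a / (a + b), n, x,
                         c(bayes_factor = B), "bayes-factor"))
    if (B < 1 / bf_threshold)
      return(new_verdict(FALSE, a / (a + b), n, x,
                         c(bayes_factor = B), "bayes-factor"))
    if (n >= max_n)
      abort_sample(sprintf("Bayes factor undecided after max_n = %d outcomes (B = %.4g)",
                           max_n, B))
    v <- provider()
    if (is.null(v))
      abort_sample(sprintf(
        "provider exhausted after %d outcomes with Bayes factor %.4g", n, B))
    n <- n + 1L
    x <- x + as.integer(v)
    if (v) a <- a + 1 else b <- b + 1
  }
}
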