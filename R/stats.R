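#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided rank-sum test. The statistic `W` is the number of pairs
#' `(x_i, y_j)` with `x_i > y_j`, counting ties as 1/2 (the `wilcox.test`
#' convention with `x` first). The p-value is exact (by enumeration of
#' labelings) when `n1 + n2 <= 12` and the data are tie-free, otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y non-empty numeric samples.
#' @return an object of class `wmw_test`: a list with `W`, `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' wmw_test(c(1, 2), c(3, 4))
#' @export
wmw_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  W <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p_value <- unname(wt$p.value)
  if (is.nan(p_value)) p_value <- 1  # zero-variance fully tied samples
  structure(list(W = W, p_value = p_value,
                 method = if (exact) "exact" else "normal_approx",
                 n1 = n1, n2 = n2),
            class = "wmw_test")
}

#' @export
print.wmw_test <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney: W = %g, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$W, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' @method tidy wmw_test
#' @export
tidy.wmw_test <- function(x, ...) {
  tibble(statistic = x$W, p.value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' Parse a distribution specification
#'
#' Accepts the printed-call string form, e.g. `"lnorm(2.7365304, 0.6243374)"`
#' or `"exp(0.0323741)"`. Supported families: lognormal (`lnorm(meanlog,
#' sdlog)`) and exponential (`exp(rate)`).
#'
#' @param x a specification string, or an already-parsed `dist_spec`.
#' @return a list of class `dist_spec` with `family`, `params`, and a
#'   sampler `r(n)`.
#' @examples
#' dist_spec("exp(0.0323741)")
#' @export
dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  m <- regmatches(x, regexec("^\\s*(lnorm|exp)\\s*\\(([^)]*)\\)\\s*$", x))[[1]]
  if (length(m) != 3) {
    abort("distribution must be 'lnorm(meanlog, sdlog)' or 'exp(rate)'")
  }
  family <- m[2]
  params <- as.numeric(strsplit(m[3], ",")[[1]])
  if (family == "lnorm") {
    if (length(params) != 2 || params[2] <= 0) {
      abort("lnorm needs meanlog and sdlog > 0")
    }
    r <- function(n) rlnorm(n, params[1], params[2])
  } else {
    if (length(params) != 1 || params[1] <= 0) abort("exp needs rate > 0")
    r <- function(n) rexp(n, params[1])
  }
  structure(list(family = family, params = params, r = r),
            class = "dist_spec")
}

#' Monte-Carlo power of the Wilcoxon-Mann-Whitney test
#'
#' Draws `reps` paired samples (`n1` from `dist1`, `n2` from `dist2`), runs
#' the two-sided test at level `alpha`, and reports the rejection
#' proportion. Deterministic under a fixed seed. Results above the
#' conventional 80% sufficiency threshold are flagged, not enforced.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param dist1,dist2 distribution specifications (string or [dist_spec()]).
#' @param alpha significance level in (0, 1).
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @return an object of class `wmw_power`: a list with `power`, `n1`, `n2`,
#'   `dist1`, `dist2`, `alpha`, `reps`, `seed`, `sufficient` (power > 0.8).
#' @examples
#' \donttest{
#' wmw_power(13, 18, "lnorm(2.7365304, 0.6243374)", "exp(0.0323741)",
#'           reps = 1000)
#' }
#' @export
wmw_power <- function(n1, n2, dist1, dist2, alpha = 0.05, reps = 10000L,
                      seed = 1L) {
  if (n1 < 2 || n2 < 2) abort("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (reps < 1000) abort("reps must be >= 1000")
  d1 <- dist_spec(dist1); d2 <- dist_spec(dist2)
  exact <- (n1 + n2) <= 12
  rej <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      x <- d1$r(n1); y <- d2$r(n2)
      p <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)$p.value
      )
      p < alpha
    }, logical(1))
  })
  structure(list(power = mean(rej), n1 = n1, n2 = n2, dist1 = d1, dist2 = d2,
                 alpha = alpha, reps = reps, seed = seed,
                 sufficient = mean(rej) > 0.8),
            class = "wmw_power")
}

#' @export
print.wmw_power <- function(x, ...) {
  cat(sprintf(
    "WMW power: %.3f (n1 = %d %s(%s); n2 = %d %s(%s); alpha = %g, %d reps)%s\n",
    x$power, x$n1, x$dist1$family, paste(x$dist1$params, collapse = ", "),
    x$n2, x$dist2$family, paste(x$dist2$params, collapse = ", "),
    x$alpha, x$reps, if (x$sufficient) " [sufficient]" else ""))
  invisible(x)
}

#' @method tidy wmw_power
#' @export
tidy.wmw_power <- function(x, ...) {
  tibble(power = x$power, n1 = x$n1, n2 = x$n2,
         dist1 = sprintf("%s(%s)", x$dist1$family,
                         paste(x$dist1$params, collapse = ",")),
         dist2 = sprintf("%s(%s)", x$dist2$family,
                         paste(x$dist2$params, collapse = ",")),
         alpha = x$alpha, reps = x$reps, sufficient = x$sufficient)
}

#' @method glance wmw_power
#' @export
glance.wmw_power <- function(x, ...) tidy(x)

#' Summarize array sizes per system class
#'
#' Mean and maximum spacer counts and group sizes per array class:
#' canonical I-E, orphan I-E, I-E pooled, and II-C. Classes with no arrays
#' are absent from the output (missing, not zero).
#'
#' @param arrays array tibble with `subtype` (or `system_type`), `context`,
#'   `n_spacers`.
#' @return a tibble `class`, `n_arrays`, `mean_spacers`, `max_spacers`.
#' @export
array_size_summary <- function(arrays) {
  type <- if ("subtype" %in% names(arrays)) arrays$subtype else arrays$system_type
  base <- tibble(type = type, context = arrays$context,
                 n_spacers = arrays$n_spacers)
  classes <- list(
    `I-E canonical` = base$type == "I-E" & base$context == "canonical",
    `I-E orphan`    = base$type == "I-E" & base$context == "orphan",
    `I-E pooled`    = base$type == "I-E",
    `II-C`          = base$type == "II-C"
  )
  out <- purrr::imap(classes, function(sel, nm) {
    if (!any(sel)) return(NULL)
    tibble(class = nm, n_arrays = sum(sel),
           mean_spacers = mean(base$n_spacers[sel]),
           max_spacers = max(base$n_spacers[sel]))
  })
  bind_rows(out)
}
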