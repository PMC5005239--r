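#' Full analysis report for a record sample
#'
#' Runs every estimator in the package on one lower record sample and
#' collects the results: the four scale estimates (joint MLE, pivotal,
#' vague MAP, hierarchical MAP for each `c`), the four shape estimates
#' (joint MLE, pivotal plug-in, vague-prior and hierarchical-prior
#' posterior means), and the corresponding intervals (Wald,
#' generalized-pivotal, and the two credible intervals) with their lengths.
#'
#' @param sample a [record_sample] (or coercible) with `k >= 3`.
#' @param level interval level.
#' @param prior_shape,prior_rate vague-prior hyperparameters.
#' @param c_list hierarchical-prior upper bounds.
#' @param gpq_draws Monte-Carlo size of the GPQ interval.
#' @param seed seed for the GPQ draw.
#' @param interval credible-interval type, `"hpd"` or `"equal-tail"`.
#' @return object of class `ehld_report`; see [print.ehld_report()] and
#'   [report_json()].
#' @examples
#' f <- system.file("extdata", "la_rainfall_records.txt", package = "ehldrec")
#' ehld_report(read_records(f), gpq_draws = 2000, seed = 1)
#' @export
ehld_report <- function(sample, level = 0.95, prior_shape = 0.01,
                        prior_rate = 0.01, c_list = c(5, 100, 500),
                        gpq_draws = 10000, seed = NULL,
                        interval = c("hpd", "equal-tail")) {
  interval <- match.arg(interval)
  x <- as_record_sample(sample)
  k <- length(x)
  if (k < 3) stop("a full report requires k >= 3 records", call. = FALSE)
  fit <- ehld_mle(x, level = level)
  piv <- lambda_pivotal(x)
  gpq <- gpq_ci_lambda(x, level = level, n_draws = gpq_draws, seed = seed)
  vague <- lambda_posterior_vague(x, prior_shape, prior_rate, level,
                                  interval = interval)
  hier <- lapply(c_list, function(cc)
    lambda_posterior_hier(x, c = cc, level = level, interval = interval))
  names(hier) <- paste0("c", c_list)
  ivals <- list(
    wald = unname(fit$ci["lambda", ]),
    gpq = unname(gpq$interval),
    bayes_vague = unname(vague$interval))
  for (i in seq_along(c_list))
    ivals[[paste0("bayes_hier_c", c_list[i])]] <- unname(hier[[i]]$interval)
  structure(list(
    sample = x, k = k, level = level,
    theta = c(mle = fit$theta, pivotal = piv$theta, map = vague$theta_map,
              stats::setNames(vapply(hier, `[[`, 0, "theta_map"),
                              paste0("hmap_c", c_list))),
    lambda = c(mle = fit$lambda, pivotal = piv$lambda, bayes = vague$mean,
               stats::setNames(vapply(hier, `[[`, 0, "mean"),
                               paste0("hier_c", c_list))),
    intervals = ivals,
    lengths = vapply(ivals, function(v) v[2] - v[1], numeric(1)),
    settings = list(level = level, prior_shape = prior_shape,
                    prior_rate = prior_rate, c_list = c_list,
                    gpq_draws = gpq_draws, seed = seed,
                    interval_type = interval,
                    version = as.character(utils::packageVersion("ehldrec")))),
    class = "ehld_report")
}

#' @rdname ehld_report
#' @param x an `ehld_report`.
#' @param digits decimals in the printed tables.
#' @param ... unused.
#' @export
print.ehld_report <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("EHLD record-value analysis (k = %d records)\n", x$k))
  cat("\nScale (theta) estimates:\n")
  print(round(x$theta, digits))
  cat("\nShape (lambda) estimates:\n")
  print(round(x$lambda, digits))
  cat(sprintf("\n%d%% intervals for lambda (%s credible intervals):\n",
              round(100 * x$level), x$settings$interval_type))
  for (nm in names(x$intervals))
    cat(sprintf("  %-18s (%s, %s)   length %s\n", nm,
                f(x$intervals[[nm]][1]), f(x$intervals[[nm]][2]),
                f(x$lengths[[nm]])))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Full-precision JSON rendering of an [ehld_report()] (the printed table
#' rounds to 3 decimals; the JSON does not).
#'
#' @param report an `ehld_report`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ehld_report"))
  obj <- list(
    k = report$k,
    records = as.numeric(report$sample),
    level = report$level,
    theta = as.list(report$theta),
    lambda = as.list(report$lambda),
    intervals = report$intervals,
    lengths = as.list(report$lengths),
    settings = report$settings[c("prior_shape", "prior_rate", "c_list",
                                 "gpq_draws", "interval_type", "version")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
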