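# shared fixtures and oracle helpers

# Los Angeles Civic Center annual-rainfall lower records (inches), k = 10
rainfall <- function() {
  record_sample(c(21.26, 11.35, 10.40, 9.21, 6.73, 5.59, 5.58, 4.85,
                  4.42, 3.21))
}

rainfall_file <- function() {
  system.file("extdata", "la_rainfall_records.txt", package = "ehldrec")
}

# central finite difference, independent of any analytic derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# direct (textbook) EHLD CDF, written independently of the package internals
cdf_direct <- function(x, theta, lambda)
  ((1 - exp(-theta * x)) / (1 + exp(-theta * x)))^lambda

# direct EHLD density
pdf_direct <- function(x, theta, lambda)
  theta * lambda * cdf_direct(x, theta, lambda) *
    2 * exp(-theta * x) / (1 - exp(-2 * theta * x))
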