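# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

# draw n samples from a bivariate normal with mean 0 and covariance G
rbvnorm <- function(n, G) {
  stopifnot(nrow(G) == 2L, ncol(G) == 2L)
  if (all(G == 0)) return(matrix(0, n, 2))
  MASS::mvrnorm(n, mu = c(0, 0), Sigma = G)
}

# 2x2 covariance from SDs and correlation
re_covariance <- function(sd_intercept, sd_slope, corr) {
  off <- corr * sd_intercept * sd_slope
  matrix(c(sd_intercept^2, off, off, sd_slope^2), 2, 2,
         dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
}

stop_ct <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# sex is stored as "female"/"male" but accepted in several encodings
sex_to_male <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    out <- ifelse(tolower(x) %in% c("male", "m"), 1,
                  ifelse(tolower(x) %in% c("female", "f"), 0, NA_real_))
  } else if (is.logical(x)) {
    out <- as.numeric(x)
  } else {
    out <- as.numeric(x)
    out[!(out %in% c(0, 1) | is.na(out))] <- NA_real_
  }
  out
}
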