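#' @importFrom stats rnorm runif rpois rlnorm rbinom quantile sd var cor
#'   lm glm poisson AIC coef dpois dnorm pnorm qnorm uniroot setNames
#'   aggregate complete.cases
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom methods as is
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive number, got %s", name,
                 deparse(x)), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1], got %s", name, deparse(x)),
         call. = FALSE)
  }
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Largest-remainder apportionment of an integer total among weights; returns
# integers summing exactly to `total` (total may be negative).
apportion_integer <- function(total, weights) {
  if (length(weights) == 0L) return(integer(0))
  weights <- as.numeric(weights)
  if (sum(weights) <= 0) weights <- rep(1, length(weights))
  sgn <- if (total < 0) -1L else 1L
  tot <- abs(total)
  raw <- tot * weights / sum(weights)
  base <- floor(raw)
  rem <- tot - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(sgn * base)
}

# FNV-1a 32-bit hash of a character scalar, for stamping outputs with a
# configuration fingerprint without a cryptographic dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 65536))
    hi <- bitwXor(as.integer(hi), as.integer(b %/% 65536))
    h <- ((hi * 65536 + lo) * 16777619) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

default_age_bands <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

# Midpoint age of a band label such as "20-24" or "85+".
age_band_midpoints <- function(bands) {
  vapply(bands, function(b) {
    if (grepl("\\+$", b)) {
      as.numeric(sub("\\+$", "", b)) + 5
    } else {
      parts <- as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])
      mean(parts) + 0.5
    }
  }, numeric(1), USE.NAMES = FALSE)
}

age_band_lower <- function(bands) {
  vapply(bands, function(b) as.numeric(sub("[-+].*$", "", b)), numeric(1),
         USE.NAMES = FALSE)
}

hrp_cols <- function(bands) paste0("hrp_", bands)
rp_cols <- function(bands) paste0("rp_", bands)

# Age bands present in a county table, in column order.
county_age_bands <- function(counties) {
  cols <- grep("^hrp_", names(counties), value = TRUE)
  sub("^hrp_", "", cols)
}
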