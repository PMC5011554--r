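# Internal helpers: clock arithmetic, seeding, smoothing.

# Parse "HH:MM" to minutes after midnight.
clock_to_minutes <- function(x) {
  stopifnot(is.character(x))
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (any(!ok)) {
    stop("invalid 24-h clock time: ", paste(x[!ok], collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

# Minutes after midnight (possibly fractional, possibly > 1440) to "HH:MM".
minutes_to_clock <- function(m) {
  m <- round(m) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. `seed = NULL` evaluates in the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Stable 31-bit hash of (master seed, string labels) used to derive per-bout
# seeds: reproducible across sessions, independent of R's RNG.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  mod <- 2147483587
  h <- as.numeric(master) %% mod
  for (lab in as.character(c(...))) {
    for (v in utf8ToInt(lab)) h <- (h * 131 + v) %% mod
  }
  as.integer(h %% 2147483399) + 1L
}

# Centered moving-window least-squares slope (units of y per unit of x).
# Windows are truncated near the edges; `window` is in samples (>= 2).
moving_slope <- function(x, y, window = 3) {
  n <- length(y)
  stopifnot(length(x) == n, window >= 2)
  if (window > n) stop("smoothing window larger than trace", call. = FALSE)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    xs <- x[lo:hi]
    ys <- y[lo:hi]
    out[i] <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  }
  out
}

# Centered moving average with edge truncation.
moving_mean <- function(y, window = 3) {
  n <- length(y)
  half <- window %/% 2
  vapply(seq_len(n), function(i) mean(y[max(1, i - half):min(n, i + half)]), numeric(1))
}

# Theil-Sen median slope of y on x; robust to heavy per-sample jitter.
theil_sen_slope <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  stats::median(dy[dx != 0] / dx[dx != 0])
}

# Least-squares hinge fit y = c + beta * (x - b)_+ over a grid of breakpoints.
# Returns list(breakpoint, slope, sse). Used for heart-rate drift onset.
hinge_fit <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 5)
  grid <- seq(x[2], x[n - 2], by = min(0.5, diff(range(x)) / n))
  best <- list(breakpoint = NA_real_, slope = 0, sse = Inf)
  for (b in grid) {
    z <- pmax(x - b, 0)
    fit <- stats::lm.fit(cbind(1, z), y)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse) {
      best <- list(breakpoint = b, slope = unname(fit$coefficients[2]), sse = sse)
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
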