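# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar numeric check; name is used verbatim in the error message
check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# significance marks at the conventional 0.05 / 0.01 thresholds
p_mark <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (is.na(p)) return("none")
  if (p < 0.01) "**" else if (p < 0.05) "*" else "none"
}

# Two-sample equal-variance (Student) two-tailed t-test with guards for
# zero pooled variance, which stats::t.test rejects as "data essentially
# constant". Returns list(t, p, df).
student_t2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 replicates in each group", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = df))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

# round only for report output; full precision is kept internally
report_round <- function(x, digits = 1L) round(x, digits)
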