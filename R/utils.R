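check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open = c(FALSE, FALSE)) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open[1]) x > lower else x >= lower) &&
    (if (open[2]) x < upper else x <= upper)
  if (!ok)
    stop(sprintf("'%s' must be a single number in %s%g, %g%s", name,
                 if (open[1]) "(" else "[", lower, upper,
                 if (open[2]) ")" else "]"), call. = FALSE)
  as.numeric(x)
}

# classed condition for situations where the heterogeneity test cannot be
# performed (e.g. the local fits do not improve on the global fit); the
# Monte-Carlo harness counts these separately instead of dropping them
gwnr_degenerate <- function(msg) {
  stop(structure(class = c("gwnr_degenerate_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

tr <- function(M) sum(diag(M))

fmt_num <- function(x) format(signif(x, 6), trim = TRUE, scientific = FALSE)
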