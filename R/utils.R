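# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-sided p-value from a z statistic.
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

# Two-sided p-value from a t statistic with df degrees of freedom.
p_from_t <- function(t, df) 2 * stats::pt(-abs(t), df = df)

stop_mr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "metabomr_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Median sample size of a dataset, used when a single n is needed (Steiger).
dataset_n <- function(dataset) {
  n <- dataset$n
  if (is.null(n) || all(is.na(n))) return(NA_real_)
  stats::median(n, na.rm = TRUE)
}
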