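# internal helpers shared across stages

`%||%` <- function(x, y) if (is.null(x)) y else x

# mean expression of a gene set on a named vector; absent genes contribute 0
panel_mean <- function(mean_expr, genes) {
  vals <- mean_expr[genes]
  vals[is.na(vals)] <- 0
  mean(vals)
}

# largest-remainder apportionment of n into parts proportional to p
apportion <- function(n, p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

stop_if_not_condition <- function(condition) {
  if (!condition %in% c("unwounded", "wounded")) {
    stop("condition must be 'unwounded' or 'wounded'")
  }
  condition
}
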