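#' @keywords internal
"_PACKAGE"

## Ligand class order used everywhere: columns of label and probability
## matrices are (metal, nucleic, small).
LIGAND_CLASSES <- c("metal", "nucleic", "small")

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

## negative slope 0.01 (common default; the rate is the only thing stated
## upstream of this choice)
leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

## %.17g round-trips IEEE doubles exactly; used by checkpoint and TSV writers
## that must survive write -> read bit-identically.
format_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Derive a stream of distinct 32-bit seeds from one master seed.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% .Machine$integer.max
}
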