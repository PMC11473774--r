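# Classed error conditions used across the package. CLI maps
# validation errors to exit 2 and precondition errors to exit 3.

iris_validation_error <- function(msg, ...) {
  stop(structure(
    class = c("iriscc_validation_error", "iriscc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

iris_precondition_error <- function(msg, ...) {
  stop(structure(
    class = c("iriscc_precondition_error", "iriscc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x surprise: always samples from x itself
sample_exact <- function(x, size = length(x)) x[sample.int(length(x), size)]
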