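## internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(structure(class = c("resistsig_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("resistsig_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    stop_config(name, " = ", x, " outside ",
                if (allow_equal) "[" else "(", lower, ", ", upper,
                if (allow_equal) "]" else ")")
  x
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_config(name, " must be a single integer")
  if (x < min) stop_config(name, " must be >= ", min)
  as.integer(x)
}

## Seeds derived from a master seed must stay below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}

timepoint_levels <- c("PRE", "OTH", "EOT")
effect_class_levels <- c("nonsyn_snv", "indel", "rearrangement", "synonymous")
response_levels <- c("CR", "PR", "SD", "PD")

## stable writer: TSV with fixed column order, no quoting surprises
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
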