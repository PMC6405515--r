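# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg) {
  stop(structure(class = c("hepaflux_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_infeasible <- function(msg, solver_status = NULL) {
  stop(structure(class = c("hepaflux_infeasible_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      solver_status = solver_status)))
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0)
    abort_validation(sprintf("%s: missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# deterministic 31-bit string hash (for per-metabolite RNG substreams and
# config fingerprints); arithmetic kept below 2^53 so doubles are exact
hash_string <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  h
}

# derive an independent substream seed from a master seed and a label,
# so results cannot depend on the order items are processed in
substream_seed <- function(master_seed, label) {
  as.integer((master_seed %% 2147483647) * 2654435 %% 2147483647 +
               hash_string(label)) %% 2147483647L
}
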