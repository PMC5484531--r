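# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character id, for deriving per-genotype RNG
# streams from one master seed. Keeps every derived seed below 2^31.
hash_id <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 0
  for (cp in codes) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

# Combine a master seed with a genotype id; independent of row order.
derive_seed <- function(seed, id) {
  as.integer((as.double(seed) + hash_id(id)) %% 2147483629)
}

# Right-aligned rolling mean over a window of `width` points (shorter at the
# start of the series).
roll_mean_right <- function(x, width) {
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(x)
  for (i in seq_len(n)) {
    lo <- max(1L, i - width + 1L)
    out[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out
}

# Delimited text with a schema-version comment header; all package outputs
# go through these two so files round-trip losslessly.
write_delim_schema <- function(x, path, schema, delim = ",") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# epidil %s v1", schema), con)
  utils::write.table(x, con, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

read_delim_schema <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    first_data <- readLines(path, n = 5L)
    first_data <- first_data[!startsWith(first_data, "#")][1]
    delim <- if (grepl("\t", first_data)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, comment = "#",
                    show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
}

match_tier <- function(tier) {
  match.arg(tier, c("highly-significant", "significant", "none"))
}

tier_levels <- c("none", "significant", "highly-significant")

# sample_range(c(lo, hi), n): n integers uniform on lo..hi, safe for lo == hi
# (base sample() would treat a scalar as 1:x).
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}
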