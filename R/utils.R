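#' @keywords internal
"_PACKAGE"

# Shortest decimal representation that round-trips through as.numeric().
# Needed so write -> read -> write is byte-stable for TSV outputs.
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- as.numeric(out) != x & is.finite(x)
    if (!any(bad)) break
    out[bad] <- sprintf(digits, x[bad])
  }
  out
}

# Tab-separated writer used by all outputs: no quoting, '.' decimal,
# optional '#'-prefixed provenance header lines.
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con, sep = "\n")
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))
  )
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

clamp_pvalues <- function(p, eps = 1e-15) {
  out_of_range <- p <= 0 | p >= 1
  if (any(out_of_range)) {
    warning(sprintf("%d p-value(s) at 0 or 1 clamped to [%g, 1-%g] before quantile transform",
                    sum(out_of_range), eps, eps))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
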